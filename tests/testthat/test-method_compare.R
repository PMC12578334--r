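make_table <- function(values, censor = NULL, residues = NULL) {
  v <- as.matrix(values)
  if (is.null(residues)) residues <- paste0("D", seq_len(nrow(v)))
  cn <- if (is.null(censor)) matrix("none", nrow(v), ncol(v)) else censor
  b <- matrix(NA_real_, nrow(v), ncol(v))
  b[cn != "none"] <- 0
  v[cn != "none"] <- NA
  pka_table(residues, colnames(values), v, cn, b)
}

test_that("rmsd and pearson match hand computations", {
  expect_equal(as.numeric(rmsd(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(as.numeric(rmsd(c(1, 2, 3), c(2, 3, 4))), 1)
  expect_equal(attr(rmsd(c(1, 2, 3), c(2, 3, 4)), "n_used"), 3L)
  expect_error(rmsd(c(NA, NA), c(1, 2)), "no jointly usable")

  expect_equal(as.numeric(pearson(1:5, 1:5)), 1)
  expect_equal(as.numeric(pearson(1:5, -(1:5))), -1)
  ## hand computation: cov = 0.5, both sds 1
  expect_equal(as.numeric(pearson(c(1, 2, 3), c(2, 1, 3))), 0.5)
  expect_error(pearson(c(1, 2), c(2, 1)), "at least 3")
  expect_error(pearson(1:4, rep(2, 4)), "degenerate")
})

test_that("pearson is invariant under positive affine maps", {
  set.seed(4)
  a <- rnorm(20); b <- a + rnorm(20, 0, 0.5)
  expect_equal(as.numeric(pearson(a, 3 * b + 7)),
               as.numeric(pearson(a, b)))
  expect_equal(as.numeric(pearson(a, -2 * b + 1)),
               -as.numeric(pearson(a, b)))
})

test_that("shifts subtract the model pKa and mask censored cells", {
  tab <- make_table(cbind(M1 = c(1.3, 3.65, 5), M2 = c(2, 4, 6)),
                    censor = rbind(c("none", "none"), c("none", "none"),
                                   c("below", "none")),
                    residues = c("D121", "D2", "D3"))
  comp <- data.frame(residue = c("D121", "D2", "D3"), type = "ASP",
                     model_pka = 3.65)
  st <- pka_shifts(tab, comp)
  expect_equal(st$shifts["D121", "M1"], 1.3 - 3.65)
  expect_equal(st$shifts["D2", "M1"], 0)
  expect_false(st$mask["D3", "M1"])
  expect_error(pka_shifts(tab, comp[-1, ]), "missing from composition")
})

test_that("pairwise shift RMSD equals raw pKa RMSD (model pKa cancels)", {
  set.seed(8)
  v <- cbind(A = runif(10, 1, 8), B = runif(10, 1, 8))
  tab <- make_table(v)
  comp <- data.frame(residue = tab$residues, type = "ASP",
                     model_pka = runif(10, 3, 5))
  st <- pka_shifts(tab, comp)
  expect_equal(as.numeric(rmsd(st$shifts[, 1], st$shifts[, 2])),
               as.numeric(rmsd(v[, 1], v[, 2])))
})

test_that("comparison report is symmetric with exact diagonal", {
  set.seed(5)
  v <- cbind(A = runif(8, 2, 6), B = runif(8, 2, 6), C = runif(8, 2, 6))
  rep_ <- compare_report(make_table(v), reference = "A")
  expect_equal(rep_$pairwise_rmsd, t(rep_$pairwise_rmsd))
  expect_equal(diag(rep_$pairwise_rmsd), c(A = 0, B = 0, C = 0))
  expect_equal(diag(rep_$pairwise_r), c(A = 1, B = 1, C = 1))
  expect_error(compare_report(make_table(v), reference = "Z"),
               "unknown reference")

  v2 <- cbind(A = 1:8 + 0.1, B = 1:8 + 0.1)
  rep2 <- compare_report(make_table(v2), reference = "A")
  expect_equal(rep2$pairwise_rmsd["A", "B"], 0)
  expect_equal(rep2$pairwise_r["A", "B"], 1)
})

test_that("masking policies drop censored residues as intended", {
  cn <- matrix("none", 6, 3, dimnames = NULL)
  cn[1, 1] <- "below"; cn[2, 2] <- "above"
  v <- cbind(A = c(2, 3, 4, 5, 3.5, 2.5), B = c(2.5, 3.5, 4, 5.5, 3, 2),
             C = c(2, 3, 4.5, 5, 3.2, 2.2))
  tab <- make_table(v, censor = cn)
  pw <- compare_report(tab, reference = "A", policy = "pairwise")
  expect_equal(pw$n_used["A", "B"], 4)   # residues 1 and 2 censored
  expect_equal(pw$n_used["A", "C"], 5)   # only residue 1 censored
  cc <- compare_report(tab, reference = "A", policy = "complete")
  expect_true(all(cc$n_used == 4))
  expect_setequal(cc$residues_used, paste0("D", 3:6))
})

test_that("a method censored everywhere is excluded with a warning", {
  cn <- matrix("none", 5, 3)
  cn[, 3] <- "below"
  v <- cbind(A = c(2, 3, 4, 5, 6), B = c(2.5, 3.5, 4.5, 5.5, 6.5),
             C = rep(1, 5))
  expect_warning(rep_ <- compare_report(make_table(v, censor = cn),
                                        reference = "A"),
                 "no usable cells")
  expect_true(is.na(rep_$pairwise_rmsd["A", "C"]))
  expect_equal(as.numeric(rep_$pairwise_rmsd["A", "B"]), 0.5)
})
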