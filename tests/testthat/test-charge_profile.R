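test_that("residue charges follow acid/base polarity", {
  expect_equal(residue_charge("ASP", 1), 0)
  expect_equal(residue_charge("ASP", 0), -1)
  expect_equal(residue_charge("GLU", 0.25), -0.75)
  expect_equal(residue_charge("LYS", 1), 1)
  expect_equal(residue_charge("ARG", 0), 0)
  expect_error(residue_charge("TYR", 0.5), "unknown residue type")
  expect_error(residue_charge("ASP", 1.2), "\\[0, 1\\]")
})

test_that("net charge sums closed-form HH contributions", {
  one <- net_charge_curve(data.frame(residue = "D1", type = "ASP", pka = 4),
                          pH_grid = 4)
  expect_equal(one$Q, -0.5)

  comp <- data.frame(residue = c("D1", "D2", "E1", "K1"),
                     type = c("ASP", "ASP", "GLU", "LYS"),
                     pka = c(3.65, 3.65, 4.25, 10.4))
  ## independent oracle: explicit sum of 1/(1+10^(pH-pKa)) terms
  th <- function(pKa) 1 / (1 + 10^(7 - pKa))
  expected <- -2 * (1 - th(3.65)) - (1 - th(4.25)) + th(10.4)
  cc <- net_charge_curve(comp, pH_grid = 7)
  expect_equal(cc$Q, expected)
  expect_equal(cc$Q, -1.998, tolerance = 5e-4)
})

test_that("censored residues enter as fixed charges", {
  asgn <- data.frame(residue = c("D37", "D312"), type = "ASP",
                     value = NA_real_, censor = c("below", "above"),
                     bound = c(1, 8))
  cc <- net_charge_curve(asgn, pH_grid = 1:8)
  ## D37 stays charged (-1), D312 stays neutral (0) on the whole grid
  expect_equal(cc$Q, rep(-1, 8))

  ## a base without an assigned pKa stays fully protonated
  base <- data.frame(residue = "R42", type = "ARG", pka = NA_real_)
  expect_equal(net_charge_curve(base, 1:8)$Q, rep(1, 8))
  acid <- data.frame(residue = "D1", type = "ASP", pka = NA_real_)
  expect_error(net_charge_curve(acid, 1:8), "without pKa")
})

test_that("null model uses model pKa values and is additive", {
  comp1 <- data.frame(residue = "E1", type = "GLU", model_pka = 4.25)
  expect_equal(null_model_curve(comp1, 4.25)$Q, -0.5)

  comp2 <- data.frame(residue = c("D1", "K1"), type = c("ASP", "LYS"),
                      model_pka = c(3.65, 10.4))
  both <- null_model_curve(rbind(comp1, comp2), 1:8)
  expect_equal(both$Q,
               null_model_curve(comp1, 1:8)$Q + null_model_curve(comp2, 1:8)$Q)

  ## an ARG with model pKa 12 is fully protonated on 1-8: uniform +1 shift
  with_arg <- null_model_curve(
    rbind(comp1, data.frame(residue = "R1", type = "ARG", model_pka = 12)),
    1:8)
  expect_equal(with_arg$Q, null_model_curve(comp1, 1:8)$Q + 1,
               tolerance = 1e-4)
})

test_that("net charge is non-increasing in pH and bounded", {
  set.seed(6)
  comp <- data.frame(residue = paste0("R", 1:12),
                     type = sample(c("ASP", "GLU", "LYS", "HIS"), 12,
                                   replace = TRUE),
                     pka = runif(12, 2, 9))
  cc <- net_charge_curve(comp, seq(1, 8, 0.5))
  expect_true(all(diff(cc$Q) <= 1e-12))
  n_acid <- sum(comp$type %in% c("ASP", "GLU"))
  expect_true(all(cc$Q >= -n_acid & cc$Q <= nrow(comp) - n_acid))
})

test_that("normalization anchors curves at the two reference pH values", {
  df <- data.frame(pH = c(2, 4, 8), v = c(10, 2.5, -5))
  norm <- normalize_curve(df)
  expect_equal(norm$value, c(1, 0.5, 0))
  expect_error(normalize_curve(data.frame(pH = 2:8, v = 1)), "equal")
  expect_error(normalize_curve(df, pH_lo = 0), "anchors")
})

test_that("effective Hill fit characterizes aggregate titration", {
  ## identical sites: the aggregate is a single HH curve
  same <- net_charge_curve(
    data.frame(residue = paste0("D", 1:7), type = "ASP", pka = 4),
    seq(1, 8, 0.5))
  eh <- effective_hill(same)
  expect_equal(eh$pKa, 4, tolerance = 0.05)
  expect_equal(eh$n, 1, tolerance = 0.05)

  ## spread pKa values flatten the aggregate: effective n < 1
  spread <- net_charge_curve(
    data.frame(residue = paste0("D", 1:9), type = "ASP",
               pka = seq(2, 6, 0.5)),
    seq(1, 8, 0.5))
  expect_lt(effective_hill(spread)$n, 1)

  ## a single residue reduces to the plain Hill fit
  single <- net_charge_curve(
    data.frame(residue = "D1", type = "ASP", pka = 3.4), seq(1, 8, 0.25))
  expect_equal(effective_hill(single)$pKa, 3.4, tolerance = 0.05)
})
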