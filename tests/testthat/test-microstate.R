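test_that("mixture fit recovers noiseless two-conformer parameters", {
  truth <- titration_model(c(2.5, 4.5))
  fit <- fit_mixture(data.frame(pH = 1:8, theta = theta_true(1:8, truth)))
  expect_equal(fit$k_selected, 2L)
  expect_equal(fit$conformers$pKa, c(2.5, 4.5), tolerance = 0.05)
  expect_equal(fit$conformers$weight, c(0.5, 0.5), tolerance = 0.05)
  expect_lt(fit$apparent_hill$n, 1)
})

test_that("the parsimony guard keeps one component on plain HH data", {
  fit <- fit_mixture(data.frame(pH = 1:8, theta = hh_theta(1:8, 3.4)))
  expect_equal(fit$k_selected, 1L)
  expect_equal(fit$conformers$pKa, 3.4, tolerance = 1e-4)
  expect_equal(fit$conformers$weight, 1)
})

test_that("unequal-weight mixtures show apparent negative cooperativity", {
  set.seed(21)
  truth <- titration_model(data.frame(weight = c(0.8, 0.2), pKa = c(3, 6)))
  th <- theta_true(1:8, truth) + rnorm(8, 0, 0.01)
  fit <- fit_mixture(data.frame(pH = 1:8, theta = pmin(pmax(th, 0), 1)))
  expect_equal(fit$k_selected, 2L)
  expect_lt(fit$apparent_hill$n, 1)
  expect_equal(fit$conformers$pKa, c(3, 6), tolerance = 0.5)
})

test_that("the 0.5 crossing is preserved between Hill and mixture views", {
  truth <- titration_model(data.frame(weight = c(0.6, 0.4),
                                      pKa = c(2.8, 5.2)))
  cv <- data.frame(pH = seq(1, 8, 0.5), theta = theta_true(seq(1, 8, 0.5),
                                                           truth))
  interp <- interpolate_pka(cv)$value
  hill <- fit_hill(cv, force = TRUE)
  expect_equal(hill$pKa, interp, tolerance = 0.1)
})

test_that("apparent Hill n decreases with conformer pKa separation", {
  tab <- apparent_hill_vs_separation(delta_pka = c(0, 1, 2, 3))
  expect_equal(tab$hill_n[1], 1, tolerance = 1e-4)
  expect_true(all(diff(tab$hill_n) < 0))
  ## brute-force global least-squares oracle values (grid search):
  ## n = 0.542 at separation 2, 0.382 at separation 3
  expect_equal(tab$hill_n[3], 0.542, tolerance = 0.01)
  expect_equal(tab$hill_n[4], 0.382, tolerance = 0.01)
  expect_lt(tab$hill_n[4], 0.5)
  ## the fitted midpoint stays at the mixture centre throughout
  expect_equal(tab$pka_fit, rep(4.5, 4), tolerance = 1e-3)
})

test_that("persistent intervals find long single-state episodes", {
  ## alternating states never persist
  n <- 2000
  tr <- lambda_trajectory(time = (seq_len(n) - 1) * 0.01,
                          lam = rep(c(0.1, 0.9), n / 2))
  expect_equal(nrow(persistent_intervals(tr, min_duration = 1)), 0L)

  ## a protonated episode spanning 100-175 ns, deprotonated elsewhere
  t2 <- seq(0, 200, 0.5)
  lam <- ifelse(t2 >= 100 & t2 <= 175, 0.1, 0.9)
  lam[t2 == 130] <- 0.5    # band frame must not break the run
  tr2 <- lambda_trajectory(time = t2, lam = lam)
  iv <- persistent_intervals(tr2, min_duration = 50)
  prot <- iv[iv$state == "protonated", ]
  expect_equal(nrow(prot), 1L)
  expect_equal(prot$start, 100)
  expect_equal(prot$end, 175)

  ## run of exactly min_duration is included (closed threshold)
  iv2 <- persistent_intervals(tr2, min_duration = 75)
  expect_true(any(iv2$state == "protonated"))
})

test_that("protonation tracks the hidden conformer in slow exchange", {
  m <- titration_model(c(3, 6), exchange_time = 50)
  tr <- simulate_lambda(m, pH = 4.5, duration = 200, seed = 11,
                        keep_states = TRUE)
  r <- state_trace_correlation(attr(tr, "conformer"),
                               attr(tr, "protonated"))
  expect_gt(r, 0.5)
})

test_that("trace correlation behaves at its edges and under the null", {
  x <- sin(seq(0, 10, 0.1))
  expect_equal(state_trace_correlation(x, x), 1)
  expect_error(state_trace_correlation(x, x[-1]), "equal length")
  expect_error(state_trace_correlation(rep(1, 10), 1:10), "degenerate")

  set.seed(31)
  hits <- vapply(1:20, function(i)
    abs(state_trace_correlation(rnorm(1e4), rnorm(1e4))) < 0.05,
    logical(1))
  expect_gte(mean(hits), 0.9)
})
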