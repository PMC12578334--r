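test_that("HH/Hill curve obeys its closed forms and symmetry", {
  expect_equal(hh_theta(4, 4), 0.5)
  expect_equal(hh_theta(4, 4, n = 2.7), 0.5)
  expect_equal(hh_theta(5, 4), 1 / 11)
  expect_equal(hh_theta(3, 4), 10 / 11)
  x <- seq(-2, 2, 0.5)
  expect_equal(hh_theta(4 - x, 4), 1 - hh_theta(4 + x, 4))
  ## protonated + deprotonated fractions sum to 1 by construction
  expect_equal(hh_theta(1:8, 3.2, 0.7) + (1 - hh_theta(1:8, 3.2, 0.7)),
               rep(1, 8))
  expect_error(hh_theta(4, 4, n = 0), "n > 0")
})

test_that("interpolation finds the 0.5 crossing on the grid", {
  expect_equal(interpolate_pka(data.frame(pH = c(3, 4),
                                          theta = c(0.909, 0.091)))$value,
               3.5, tolerance = 1e-12)
  ## exact HH with pKa 2.7 on the unit grid: line through (2, 0.8337)
  ## and (3, 0.3339) crosses 0.5 at 2.668
  est <- interpolate_pka(make_hh_curve(2.7))
  expect_equal(est$value, 2.668, tolerance = 1e-3)
  ## grid point exactly at 0.5 resolves to the grid pH
  expect_equal(interpolate_pka(data.frame(pH = 2:4,
                                          theta = c(0.9, 0.5, 0.1)))$value,
               3)
})

test_that("curves that never cross 0.5 censor at the grid endpoints", {
  up <- interpolate_pka(data.frame(pH = 1:8, theta = rep(0.62, 8)))
  expect_true(is_censored(up))
  expect_equal(up$censor, "above")
  expect_equal(up$bound, 8)
  dn <- interpolate_pka(data.frame(pH = 1:8, theta = rep(0.38, 8)))
  expect_equal(dn$censor, "below")
  expect_equal(dn$bound, 1)
  ## crossing right at the low edge is still titrating
  th <- c(0.51, hh_theta(2:8, 1.2))
  est <- interpolate_pka(data.frame(pH = 1:8, theta = th))
  expect_false(is_censored(est))
  expect_true(est$value > 1 && est$value < 2)
})

test_that("noisy non-monotone curves are regularized before interpolation", {
  set.seed(3)
  cv <- make_hh_curve(3.8, noise_sd = 0.05)
  cv$theta[5] <- cv$theta[4] + 0.03   # force a local violation
  est <- interpolate_pka(cv)
  expect_false(is_censored(est))
  expect_equal(est$value, 3.8, tolerance = 0.3)
})

test_that("HH fit recovers exact model data to machine-level precision", {
  expect_equal(fit_hh(make_hh_curve(3.3))$value, 3.3, tolerance = 1e-6)
  expect_equal(fit_hh(make_hh_curve(6.9))$value, 6.9, tolerance = 1e-6)
  expect_error(fit_hh(data.frame(pH = 1:8, theta = rep(0.9, 8))),
               "force")
  expect_equal(fit_hh(data.frame(pH = 1:8, theta = rep(0.9, 8)),
                      force = TRUE)$value > 8, TRUE)
})

test_that("Hill fit recovers HH data and mixture phenomenology", {
  f <- fit_hill(make_hh_curve(4))
  expect_equal(f$pKa, 4, tolerance = 1e-4)
  expect_equal(f$n, 1, tolerance = 1e-4)

  ## symmetric mixture: midpoint exact, apparent n from the brute-force
  ## least-squares oracle (global grid search) is 0.542
  mix <- titration_model(c(2.5, 4.5))
  fm <- fit_hill(data.frame(pH = 1:8, theta = theta_true(1:8, mix)),
                 force = TRUE)
  expect_equal(fm$pKa, 3.5, tolerance = 1e-3)
  expect_equal(fm$n, 0.542, tolerance = 0.01)

  ## degenerate mixture is plain HH
  f0 <- fit_hill(data.frame(
    pH = 1:8,
    theta = theta_true(1:8, titration_model(c(3.5, 3.5)))), force = TRUE)
  expect_equal(f0$n, 1, tolerance = 1e-4)
})

test_that("interpolation, HH fit and Hill fit agree on HH-behaved data", {
  set.seed(11)
  for (pKa in c(2.3, 3.7, 5.1, 6.4)) {
    cv <- make_hh_curve(pKa, noise_sd = 0.01)
    pi_ <- interpolate_pka(cv)$value
    ph <- fit_hh(cv)$value
    pl <- fit_hill(cv)$pKa
    expect_lt(max(abs(c(pi_ - ph, pi_ - pl, ph - pl))), 0.05)
  }
})

test_that("residue classification separates titrating from anomalous", {
  g <- expand.grid(monomer = 1, replica = 1:3, pH = 1:8)
  g$fraction <- hh_theta(g$pH, 3) + 0.01 * (g$replica - 2)
  cl <- classify_residue(build_curve(g, "D107"))
  expect_equal(cl$label, "titrating")
  expect_equal(cl$pka_interp$value, 3, tolerance = 0.05)
  expect_false(is.na(cl$sd))
  expect_equal(cl$hill$n, 1, tolerance = 0.1)

  g$fraction <- 0.3 + 0.05 * sin(g$pH)
  low <- classify_residue(build_curve(g, "D37"))
  expect_equal(low$label, "always_deprotonated")
  expect_equal(format(low$pka_interp), "< 1")
  expect_null(low$pka_hh)

  g$fraction <- hh_theta(g$pH, 10)
  hi <- classify_residue(build_curve(g, "D312"))
  expect_equal(hi$label, "always_protonated")
  expect_equal(format(hi$pka_interp), "> 8")
})
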