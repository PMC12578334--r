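#' Fit a mixture of Henderson-Hasselbalch titration components
#'
#' Models a shallow ("slow") titration curve as a weighted superposition
#' of HH components, `theta(pH) = sum_j w_j * hh_theta(pH, pKa_j)`: the
#' signature of a residue exploring several conformational microstates
#' with distinct pKa values.  Weights are simplex-constrained (softmax
#' parameterization) and the fit is multistarted from quantiles of the
#' curve.  A parsimony guard keeps the single-component fit unless the
#' mixture reduces the residual sum of squares by at least
#' `rss_ratio_guard` (or the single-component fit is already essentially
#' exact).  The Hill fit of the same curve is attached for comparison:
#' a mixture with spread pKa values shows an apparent Hill n < 1 even
#' though every component is ideal HH.
#'
#' @param curve A `titration_curve` or data frame with `pH`, `theta`.
#' @param k Number of mixture components (default 2).
#' @param rss_ratio_guard Required RSS improvement factor of k components
#'   over one (default 4).
#' @return An object of class `mixture_fit`: `conformers` (data frame of
#'   `weight`, `pKa`, sorted by pKa), `k_selected`, `rss`, `rss_k1`,
#'   `apparent_hill` (a [hill_parameters()]).
#' @export
fit_mixture <- function(curve, k = 2L, rss_ratio_guard = 4) {
  xy <- .curve_xy(curve)
  if (length(xy$pH) < 2L * k)
    stop("need at least 2k grid points for a k-component mixture")
  hh1 <- fit_hh(curve, force = TRUE)
  rss1 <- attr(hh1, "rss")
  app_hill <- fit_hill(curve, force = TRUE)
  if (k == 1L || rss1 < 1e-8) {
    return(structure(list(
      conformers = data.frame(weight = 1, pKa = hh1$value),
      k_selected = 1L, rss = rss1, rss_k1 = rss1,
      apparent_hill = app_hill), class = "mixture_fit"))
  }
  lo_pka <- min(xy$pH) - 5; hi_pka <- max(xy$pH) + 5
  obj <- function(p) {
    pkas <- p[seq_len(k)]
    w <- exp(c(p[-seq_len(k)], 0))
    w <- w / sum(w)
    pred <- rowSums(vapply(seq_len(k),
                           function(j) w[j] * hh_theta(xy$pH, pkas[j]),
                           numeric(length(xy$pH))))
    sum((xy$theta - pred)^2)
  }
  ## multistart: invert the (regularized) curve at k interior quantile
  ## levels to seed component pKas, plus symmetric spreads about the HH fit
  th_reg <- .monotone_theta(xy$pH, xy$theta)
  invert <- function(level) {
    if (all(th_reg > level)) return(max(xy$pH))
    if (all(th_reg < level)) return(min(xy$pH))
    stats::approx(th_reg, xy$pH, xout = level, ties = "ordered")$y
  }
  qstart <- vapply((seq_len(k) - 0.5) / k, invert, 0)
  starts <- list(sort(qstart, decreasing = TRUE))
  for (spread in c(0.5, 1.5, 3))
    starts <- c(starts, list(hh1$value +
                               seq(-spread, spread, length.out = k)))
  best <- NULL
  for (s in starts) {
    o <- try(stats::optim(c(s, rep(0, k - 1L)), obj, method = "L-BFGS-B",
                          lower = c(rep(lo_pka, k), rep(-8, k - 1L)),
                          upper = c(rep(hi_pka, k), rep(8, k - 1L))),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("mixture fit did not converge from any start")
  if (rss1 / max(best$value, .Machine$double.eps) < rss_ratio_guard) {
    return(structure(list(
      conformers = data.frame(weight = 1, pKa = hh1$value),
      k_selected = 1L, rss = rss1, rss_k1 = rss1,
      apparent_hill = app_hill), class = "mixture_fit"))
  }
  pkas <- best$par[seq_len(k)]
  w <- exp(c(best$par[-seq_len(k)], 0)); w <- w / sum(w)
  ord <- order(pkas)
  structure(list(
    conformers = data.frame(weight = w[ord], pKa = pkas[ord]),
    k_selected = as.integer(k), rss = best$value, rss_k1 = rss1,
    apparent_hill = app_hill), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("titration mixture fit: %d component(s), rss %.3g (1-component rss %.3g)\n",
              x$k_selected, x$rss, x$rss_k1))
  print(round(x$conformers, 4))
  cat(sprintf("apparent Hill n of the same curve: %.3f\n", x$apparent_hill$n))
  invisible(x)
}

#' Apparent Hill coefficient versus conformer pKa separation
#'
#' Builds symmetric two-conformer mixture curves from the closed-form
#' occupancy at increasing pKa separation and Hill-fits each: the fitted
#' `n` equals 1 at zero separation and decreases as the separation grows
#' — the quantitative face of "apparent negative cooperativity from
#' microstate heterogeneity".
#'
#' @param weights Two positive conformer weights (normalized internally).
#' @param delta_pka Numeric vector of pKa separations (pH units).
#' @param pH_grid pH grid on which curves are evaluated and fitted.
#' @param center Midpoint of the conformer pair (default: grid centre).
#' @return Data frame with columns `delta_pka`, `pka_fit`, `hill_n`.
#' @export
apparent_hill_vs_separation <- function(weights = c(0.5, 0.5), delta_pka,
                                        pH_grid = 1:8, center = NULL) {
  stopifnot(length(weights) == 2L, all(weights > 0))
  if (is.null(center)) center <- mean(range(pH_grid))
  out <- data.frame(delta_pka = as.numeric(delta_pka),
                    pka_fit = NA_real_, hill_n = NA_real_)
  for (i in seq_along(delta_pka)) {
    d <- delta_pka[i]
    model <- titration_model(
      data.frame(weight = weights, pKa = c(center - d / 2, center + d / 2)))
    th <- theta_true(pH_grid, model)
    fit <- fit_hill(data.frame(pH = pH_grid, theta = th), force = TRUE)
    out$pka_fit[i] <- fit$pKa
    out$hill_n[i] <- fit$n
  }
  out
}

#' Persistent protonation-state intervals of a trajectory
#'
#' Finds maximal time intervals during which the assigned protonation
#' state does not change; frames inside the threshold band (no state
#' assigned) do not break a run.  Intervals at least `min_duration` long
#' (closed threshold) are returned — e.g. a residue staying protonated
#' for tens of ns at a pH where it should titrate freely is the hallmark
#' of a long-lived conformational microstate.
#'
#' @param traj A [lambda_trajectory()].
#' @param lo,hi Assignment thresholds (default 0.2 / 0.8).
#' @param min_duration Minimum interval length in ns (> 0).
#' @return Data frame with columns `start`, `end` (ns), `state`
#'   (`"protonated"` / `"deprotonated"`).
#' @export
persistent_intervals <- function(traj, lo = 0.2, hi = 0.8, min_duration) {
  stopifnot(inherits(traj, "lambda_trajectory"), min_duration > 0)
  state <- ifelse(traj$lam < lo, 1L, ifelse(traj$lam > hi, 0L, NA_integer_))
  idx <- which(!is.na(state))
  if (length(idx) == 0L)
    return(data.frame(start = numeric(), end = numeric(),
                      state = character()))
  r <- rle(state[idx])
  stop_i <- cumsum(r$lengths)
  start_i <- c(1L, utils::head(stop_i, -1L) + 1L)
  start_t <- traj$time[idx[start_i]]
  end_t <- traj$time[idx[stop_i]]
  keep <- (end_t - start_t) >= min_duration
  data.frame(start = start_t[keep], end = end_t[keep],
             state = ifelse(r$values[keep] == 1L, "protonated",
                            "deprotonated"),
             stringsAsFactors = FALSE)
}

#' Correlation between a protonation trace and a structural trace
#'
#' Sample Pearson correlation of two aligned time series — typically a
#' per-frame protonation indicator against a conformational observable
#' (RMSD-like or dihedral-like trace, or the hidden conformer index of a
#' synthetic trajectory).  A high correlation says the protonation state
#' tracks the conformational microstate.
#'
#' @param x,y Numeric series of equal length (>= 3), non-degenerate.
#' @return Pearson correlation coefficient.
#' @export
state_trace_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate (zero-variance) series")
  stats::cor(x, y)
}
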