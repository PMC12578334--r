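#' Henderson-Hasselbalch / Hill protonation fraction
#'
#' Protonated fraction of an acid as a function of pH:
#' `theta = 1 / (1 + 10^(n * (pH - pKa)))`.  Strictly decreasing in pH,
#' with `theta(pKa) = 0.5` for any Hill coefficient `n`; `n = 1` is the
#' plain Henderson-Hasselbalch curve.  (Written so that theta -> 1 at low
#' pH, i.e. theta is the *protonated* fraction; some published statements
#' of the Hill equation carry the opposite sign convention.)
#'
#' @param pH Numeric vector.
#' @param pKa Midpoint in pH units.
#' @param n Hill coefficient, > 0.
#' @return Protonation probabilities in (0, 1).
#' @export
hh_theta <- function(pH, pKa, n = 1) {
  stopifnot(all(n > 0))
  1 / (1 + 10^(n * (pH - pKa)))
}

.curve_xy <- function(curve) {
  if (inherits(curve, "titration_curve"))
    list(pH = curve$pH, theta = curve$theta)
  else if (is.data.frame(curve) && all(c("pH", "theta") %in% names(curve)))
    list(pH = curve$pH, theta = curve$theta)
  else stop("expected a titration_curve or a data frame with pH and theta")
}

## Pooled-adjacent-violators regularization: smallest-deviation
## non-increasing curve (sampling noise can make theta locally increase,
## which would create multiple 0.5 crossings).
.monotone_theta <- function(pH, theta) {
  if (length(theta) < 2L) return(theta)
  -stats::isoreg(pH, -theta)$yf
}

#' Estimate pKa by linear interpolation at protonation fraction 0.5
#'
#' The curve is first regularized to be non-increasing
#' (pooled-adjacent-violators), then the pH where theta crosses 0.5 is
#' found by linear interpolation between the bracketing grid points.
#' Curves that never cross 0.5 are censored at the scanned grid
#' endpoints: always-protonated curves report `"> max(pH)"`,
#' always-deprotonated ones `"< min(pH)"`.  A grid point at exactly 0.5
#' resolves to that grid pH.
#'
#' @param curve A `titration_curve` or data frame with `pH`, `theta`.
#' @return A [pka_estimate()] (censored when the curve never crosses 0.5).
#' @export
interpolate_pka <- function(curve) {
  xy <- .curve_xy(curve)
  pH <- xy$pH
  if (length(pH) < 2L) stop("need at least 2 grid points")
  th <- .monotone_theta(pH, xy$theta)
  if (all(th > 0.5))
    return(pka_estimate(censor = "above", bound = max(pH),
                        method = "interpolation"))
  if (all(th < 0.5))
    return(pka_estimate(censor = "below", bound = min(pH),
                        method = "interpolation"))
  hit <- which(th == 0.5)
  if (length(hit) > 0L)
    return(pka_estimate(value = pH[hit[1]], method = "interpolation"))
  i <- which(th[-length(th)] > 0.5 & th[-1] < 0.5)[1]
  val <- pH[i] + (th[i] - 0.5) / (th[i] - th[i + 1]) * (pH[i + 1] - pH[i])
  pka_estimate(value = val, method = "interpolation")
}

.fit_start <- function(curve, force) {
  est <- interpolate_pka(curve)
  if (is_censored(est)) {
    if (!force)
      stop("curve does not cross theta = 0.5 (censored ",
           format(est), "); use force = TRUE to fit anyway")
    est$value <- est$bound
  }
  est$value
}

#' Fit the Henderson-Hasselbalch model (n = 1) by least squares
#'
#' Unweighted least squares of `hh_theta(pH, pKa)` over the grid points,
#' with the pKa as the only free parameter, initialized (and bracketed)
#' around the interpolated pKa.  Replica SDs are reported alongside but
#' never used as weights.
#'
#' @param curve A `titration_curve` or data frame with `pH`, `theta`.
#' @param force Fit even when the curve never crosses 0.5.
#' @return A [pka_estimate()] with attribute `"rss"` (residual sum of
#'   squares).
#' @export
fit_hh <- function(curve, force = FALSE) {
  xy <- .curve_xy(curve)
  start <- .fit_start(curve, force)
  rss <- function(p) sum((xy$theta - hh_theta(xy$pH, p))^2)
  opt <- stats::optim(start, rss, method = "Brent",
                      lower = min(xy$pH) - 5, upper = max(xy$pH) + 5)
  est <- pka_estimate(value = opt$par, method = "hh_fit")
  attr(est, "rss") <- opt$value
  est
}

#' Hill-fit parameters
#' @param pKa Midpoint (pH units).
#' @param n Hill coefficient (> 0).
#' @param rss Residual sum of squares of the fit, if any.
#' @return An object of class `hill_parameters`.
#' @export
hill_parameters <- function(pKa, n, rss = NA_real_) {
  if (n <= 0) stop("Hill coefficient must be > 0")
  structure(list(pKa = as.numeric(pKa), n = as.numeric(n),
                 rss = as.numeric(rss)), class = "hill_parameters")
}

#' @export
print.hill_parameters <- function(x, ...) {
  cat(sprintf("Hill fit: pKa %.3f, n %.3f (rss %.3g)\n", x$pKa, x$n, x$rss))
  invisible(x)
}

#' Fit the Hill equation (pKa and n free) by least squares
#'
#' Bounded least squares with `n` in \[0.05, 5\] and pKa within 5 units of
#' the scanned grid, initialized at the interpolated pKa and `n = 1`.
#' Hill coefficients below 1 indicate shallower-than-HH titration:
#' genuine negative cooperativity, or the signature of a mixture of
#' conformational microstates with distinct pKa values (see
#' [fit_mixture()]).
#'
#' @inheritParams fit_hh
#' @return A [hill_parameters()].
#' @export
fit_hill <- function(curve, force = FALSE) {
  xy <- .curve_xy(curve)
  start <- .fit_start(curve, force)
  rss <- function(p) sum((xy$theta - hh_theta(xy$pH, p[1], p[2]))^2)
  lower <- c(min(xy$pH) - 5, 0.05)
  upper <- c(max(xy$pH) + 5, 5)
  opt <- stats::optim(c(start, 1), rss, method = "L-BFGS-B",
                      lower = lower, upper = upper)
  if (opt$convergence != 0) {
    ## L-BFGS-B line searches can fail right at a (near-)exact optimum;
    ## polish with Nelder-Mead (bounds enforced by clamping) and accept
    ## whichever iterate is better
    rss_c <- function(p) rss(pmin(pmax(p, lower), upper))
    opt2 <- stats::optim(opt$par, rss_c)
    if (opt2$value <= opt$value)
      opt <- list(par = pmin(pmax(opt2$par, lower), upper),
                  value = opt2$value, convergence = opt2$convergence)
    if (opt$convergence != 0 && opt$value > 1e-6)
      stop(sprintf(
        "Hill fit did not converge (best iterate pKa %.4f, n %.4f, rss %.3g)",
        opt$par[1], opt$par[2], opt$value))
  }
  hill_parameters(pKa = opt$par[1], n = opt$par[2], rss = opt$value)
}

#' Classify a residue's titration behaviour over the scanned pH range
#'
#' A residue is `titrating` when its (regularized) curve crosses theta =
#' 0.5 inside the grid; otherwise it is `always_protonated` (theta > 0.5
#' throughout, pKa censored above the top of the grid, reported "> 8" on
#' the default grid) or `always_deprotonated` ("< 1").  For titrating
#' residues, HH and Hill fits are attached and the replica SD of the pKa
#' is computed from per-replica interpolations.
#'
#' @param curve A [titration_curve()] (per-replica columns are used for
#'   the SD when present).
#' @return An object of class `residue_call`: fields `residue_id`,
#'   `label`, `pka_interp`, `pka_hh`, `hill` (titrating only), `sd`.
#' @export
classify_residue <- function(curve) {
  interp <- interpolate_pka(curve)
  label <- switch(interp$censor,
                  none = "titrating",
                  below = "always_deprotonated",
                  above = "always_protonated")
  pka_hh <- NULL
  hill <- NULL
  sdv <- NA_real_
  if (label == "titrating") {
    pka_hh <- fit_hh(curve)
    hill <- fit_hill(curve)
    if (inherits(curve, "titration_curve") && curve$n_replicas > 1L) {
      per_rep <- apply(curve$theta_by_replica, 2, function(th) {
        est <- interpolate_pka(data.frame(pH = curve$pH, theta = th))
        if (is_censored(est)) NA_real_ else est$value
      })
      if (sum(!is.na(per_rep)) >= 2L) sdv <- stats::sd(per_rep, na.rm = TRUE)
    }
    interp$sd <- sdv
  }
  structure(list(
    residue_id = if (inherits(curve, "titration_curve")) curve$residue_id
                 else NA_character_,
    label = label, pka_interp = interp, pka_hh = pka_hh, hill = hill,
    sd = sdv), class = "residue_call")
}

#' @export
print.residue_call <- function(x, ...) {
  cat(sprintf("%s: %s; pKa(interp) %s", x$residue_id, x$label,
              format(x$pka_interp)))
  if (!is.null(x$pka_hh))
    cat(sprintf(", pKa(HH) %s, Hill n %.2f", format(x$pka_hh), x$hill$n))
  cat("\n")
  invisible(x)
}
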