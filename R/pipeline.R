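#' Titrate a whole lambda-trajectory dataset
#'
#' Runs the full per-residue analysis over a dataset tree written by
#' [generate_dataset()] (or any directory with a compatible manifest):
#' reads every xvg file, computes the protonation fraction of each
#' (monomer, replica, pH) trajectory, builds the hierarchically averaged
#' titration curve per residue, and attaches pKa estimates
#' (interpolation, HH fit, Hill fit) and the titrating /
#' always-protonated / always-deprotonated classification.
#'
#' @param dataset A manifest list from [read_manifest()], or a path to a
#'   dataset directory / manifest file.
#' @param estimator `"lambda_mean"` (default) or `"threshold"`.
#' @param burn_in Burn-in time in ns discarded from every trajectory
#'   (default 0: whole production runs are averaged).
#' @param lo,hi Thresholds for the threshold estimator.
#' @return A list with `curves` (named list of [build_curve()] results),
#'   `calls` (named list of [classify_residue()] results), and `table`,
#'   a per-residue summary data frame with columns `residue`, `label`,
#'   `pka_interp`, `pka_hh`, `hill_pka`, `hill_n`, `sd`, `pka_report`
#'   (formatted, censor-aware).
#' @export
titrate_dataset <- function(dataset, estimator = c("lambda_mean", "threshold"),
                            burn_in = 0, lo = 0.2, hi = 0.8) {
  estimator <- match.arg(estimator)
  man <- if (is.character(dataset)) read_manifest(dataset) else dataset
  entries <- man$entries
  fr_fun <- if (estimator == "threshold")
    function(tr) fraction_threshold(tr, lo = lo, hi = hi,
                                    burn_in = burn_in)$fraction
  else function(tr) fraction_lambda_mean(tr, burn_in = burn_in)$fraction
  entries$fraction <- vapply(seq_len(nrow(entries)), function(i) {
    e <- entries[i, ]
    tr <- read_lambda_xvg(file.path(man$dir, e$file), residue_id = e$residue,
                          monomer = e$monomer, replica = e$replica, pH = e$pH)
    fr_fun(tr)
  }, numeric(1))
  residues <- unique(entries$residue)
  curves <- calls <- stats::setNames(vector("list", length(residues)),
                                     residues)
  rows <- vector("list", length(residues))
  for (r in seq_along(residues)) {
    sub <- entries[entries$residue == residues[r], ]
    curves[[r]] <- build_curve(sub, residue_id = residues[r])
    calls[[r]] <- classify_residue(curves[[r]])
    cl <- calls[[r]]
    rows[[r]] <- data.frame(
      residue = residues[r], label = cl$label,
      pka_interp = if (is_censored(cl$pka_interp)) NA_real_
                   else cl$pka_interp$value,
      pka_hh = if (is.null(cl$pka_hh)) NA_real_ else cl$pka_hh$value,
      hill_pka = if (is.null(cl$hill)) NA_real_ else cl$hill$pKa,
      hill_n = if (is.null(cl$hill)) NA_real_ else cl$hill$n,
      sd = cl$sd,
      pka_report = format(cl$pka_interp),
      stringsAsFactors = FALSE)
  }
  list(curves = curves, calls = calls, table = do.call(rbind, rows))
}

#' Tidy long-format table of a set of titration curves
#'
#' @param curves Named list of [build_curve()] results (as returned in
#'   `titrate_dataset()$curves`).
#' @return Data frame with one row per (residue, pH): `residue`, `pH`,
#'   `theta`, `sd`, plus one column per replica.
#' @export
curve_table <- function(curves) {
  do.call(rbind, lapply(curves, as.data.frame))
}
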