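#' pKa shifts relative to model-compound pKa
#'
#' `shift = predicted pKa - model pKa` per cell; censored cells are masked
#' out and never enter statistics.  Note that in *pairwise* comparisons
#' the model pKa cancels, so shift RMSD equals raw pKa RMSD for any model
#' pKa assignment; Pearson correlations, however, do depend on it.
#'
#' @param table A [pka_table()].
#' @param composition Composition data frame (see [read_composition()])
#'   providing `model_pka` for every residue in `table`.
#' @return An object of class `shift_table`: fields `residues`, `methods`,
#'   `shifts` (matrix), `mask` (TRUE where usable), `model_pka`.
#' @export
pka_shifts <- function(table, composition) {
  stopifnot(inherits(table, "pka_table"))
  idx <- match(table$residues, composition$residue)
  if (anyNA(idx))
    stop("residues missing from composition: ",
         paste(table$residues[is.na(idx)], collapse = ", "))
  model <- composition$model_pka[idx]
  shifts <- sweep(table$value, 1, model, "-")
  mask <- table$censor == "none"
  structure(list(residues = table$residues, methods = table$methods,
                 shifts = shifts, mask = mask, model_pka = model),
            class = "shift_table")
}

#' Root-mean-square deviation between two value vectors under a mask
#'
#' @param a,b Numeric vectors of equal length.
#' @param mask Logical vector of jointly usable entries (default: entries
#'   where both are non-`NA`).
#' @return RMSD as a number, with attribute `"n_used"`.
#' @export
rmsd <- function(a, b, mask = NULL) {
  stopifnot(length(a) == length(b))
  if (is.null(mask)) mask <- !is.na(a) & !is.na(b)
  use <- mask & !is.na(a) & !is.na(b)
  if (sum(use) < 1L) stop("no jointly usable cells")
  out <- sqrt(mean((a[use] - b[use])^2))
  attr(out, "n_used") <- sum(use)
  out
}

#' Pearson correlation between two value vectors under a mask
#'
#' @inheritParams rmsd
#' @return Sample Pearson correlation, with attribute `"n_used"`.
#' @export
pearson <- function(a, b, mask = NULL) {
  stopifnot(length(a) == length(b))
  if (is.null(mask)) mask <- !is.na(a) & !is.na(b)
  use <- mask & !is.na(a) & !is.na(b)
  if (sum(use) < 3L) stop("need at least 3 jointly usable cells")
  if (stats::sd(a[use]) == 0 || stats::sd(b[use]) == 0)
    stop("degenerate (zero-variance) input")
  out <- stats::cor(a[use], b[use])
  attr(out, "n_used") <- sum(use)
  out
}

#' Cross-method pKa comparison report
#'
#' Pairwise RMSD and Pearson matrices over all method pairs, plus the
#' per-method RMSD against a designated reference method.  Censored cells
#' are excluded according to `policy`:
#' \describe{
#'   \item{`"pairwise"`}{a residue is dropped only from pairs where it is
#'     censored in either member (pairwise-complete deletion);}
#'   \item{`"complete"`}{a residue censored in *any* method is dropped from
#'     every pair, so all statistics share one residue set — the
#'     convention used when a common set of anomalously ionizing residues
#'     is excluded from a whole benchmark.}
#' }
#' When a composition is supplied, statistics are computed on pKa shifts
#' (deviation from model pKa); pairwise RMSDs are identical either way
#' because the model pKa cancels in the difference.
#'
#' @param table A [pka_table()].
#' @param composition Optional composition with `model_pka` (shifts mode).
#' @param reference Method label used for the reference RMSD column.
#' @param policy Censor-masking policy, `"pairwise"` or `"complete"`.
#' @return An object of class `comparison_report`: `pairwise_rmsd`,
#'   `pairwise_r`, `n_used` (method x method matrices), `reference`,
#'   `reference_rmsd` (named vector), `policy`, `residues_used`.
#' @export
compare_report <- function(table, composition = NULL, reference,
                           policy = c("pairwise", "complete")) {
  stopifnot(inherits(table, "pka_table"))
  policy <- match.arg(policy)
  if (!reference %in% table$methods)
    stop("unknown reference method: ", reference)
  if (!is.null(composition)) {
    st <- pka_shifts(table, composition)
    vals <- st$shifts
    usable <- st$mask
  } else {
    vals <- table$value
    usable <- table$censor == "none"
  }
  m <- length(table$methods)
  dead <- colSums(usable) == 0L
  if (any(dead))
    warning("method(s) with no usable cells excluded from statistics: ",
            paste(table$methods[dead], collapse = ", "))
  common <- rowSums(usable[, !dead, drop = FALSE]) == sum(!dead)
  mk <- function() matrix(NA_real_, m, m,
                          dimnames = list(table$methods, table$methods))
  R <- mk(); P <- mk(); N <- mk()
  for (i in seq_len(m)) {
    for (j in seq_len(i)) {
      if (dead[i] || dead[j]) next
      msk <- if (policy == "complete") common else usable[, i] & usable[, j]
      if (i == j) {
        R[i, i] <- 0; P[i, i] <- 1; N[i, i] <- sum(msk)
        next
      }
      R[i, j] <- R[j, i] <- as.numeric(rmsd(vals[, i], vals[, j], msk))
      P[i, j] <- P[j, i] <- as.numeric(pearson(vals[, i], vals[, j], msk))
      N[i, j] <- N[j, i] <- sum(msk & !is.na(vals[, i]) & !is.na(vals[, j]))
    }
  }
  ref_rmsd <- R[reference, setdiff(table$methods, reference)]
  structure(list(pairwise_rmsd = R, pairwise_r = P, n_used = N,
                 reference = reference, reference_rmsd = ref_rmsd,
                 policy = policy,
                 residues_used = if (policy == "complete")
                   table$residues[common] else NULL),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 2, ...) {
  cat(sprintf("cross-method pKa comparison (policy: %s; reference: %s)\n",
              x$policy, x$reference))
  cat("\npairwise RMSD (pKa units):\n")
  print(round(x$pairwise_rmsd, digits))
  cat("\npairwise Pearson R:\n")
  print(round(x$pairwise_r, digits))
  cat(sprintf("\nRMSD from %s:\n", x$reference))
  print(round(sort(x$reference_rmsd), digits))
  invisible(x)
}
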