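#' Charge of one ionizable residue at a given protonation fraction
#'
#' Acids (Asp, Glu) are neutral when protonated and -1 when deprotonated:
#' `charge = -(1 - theta)`.  Bases (His, Arg, Lys) are +1 when protonated:
#' `charge = +theta`.
#'
#' @param res_type Residue type(s): `"ASP"`, `"GLU"`, `"HIS"`, `"ARG"`,
#'   `"LYS"`.
#' @param theta Protonation probability in \[0, 1\] (recycled against
#'   `res_type`).
#' @return Charge in elementary units.
#' @export
residue_charge <- function(res_type, theta) {
  res_type <- toupper(res_type)
  bad <- !res_type %in% .res_types
  if (any(bad)) stop("unknown residue type: ", res_type[bad][1])
  if (any(theta < 0 | theta > 1)) stop("theta must lie in [0, 1]")
  ifelse(res_type %in% c("ASP", "GLU"), -(1 - theta), theta)
}

.assign_theta <- function(type, pka, censor, bound, pH_grid) {
  if (!is.na(censor) && censor == "below") return(rep(0, length(pH_grid)))
  if (!is.na(censor) && censor == "above") return(rep(1, length(pH_grid)))
  if (is.na(pka)) {
    ## bases stay protonated across the acidic scan by default; an acid
    ## without a pKa is a data error
    if (toupper(type) %in% c("HIS", "ARG", "LYS"))
      return(rep(1, length(pH_grid)))
    stop("acidic residue without pKa or censor state")
  }
  hh_theta(pH_grid, pka)
}

#' Net charge versus pH from a per-residue pKa assignment
#'
#' Sums [residue_charge()] over all residues, with each residue's
#' protonation fraction following the Henderson-Hasselbalch curve at its
#' assigned pKa.  Censored residues enter as fixed charges: censored
#' below the scan (always deprotonated) contribute their deprotonated
#' charge on the whole grid, censored above contribute their protonated
#' charge.  Basic residues with no assigned pKa stay fully protonated.
#'
#' @param assignments Data frame with columns `residue`, `type`, and
#'   either a numeric `pka` column, or `value`/`censor`/`bound` columns as
#'   produced from a [pka_table()].
#' @param pH_grid Numeric pH grid.
#' @param method Label attached to the curve.
#' @return An object of class `charge_curve`: a data frame with columns
#'   `pH` and `Q` (net charge per monomer, elementary units), attribute
#'   `"method"`.
#' @export
net_charge_curve <- function(assignments, pH_grid, method = "assigned") {
  assignments <- as.data.frame(assignments)
  stopifnot("type" %in% names(assignments))
  if (!"value" %in% names(assignments)) {
    if (!"pka" %in% names(assignments))
      stop("assignments need a pka column or value/censor/bound columns")
    assignments$value <- assignments$pka
  }
  if (!"censor" %in% names(assignments)) assignments$censor <- "none"
  if (!"bound" %in% names(assignments)) assignments$bound <- NA_real_
  Q <- rep(0, length(pH_grid))
  for (i in seq_len(nrow(assignments))) {
    th <- .assign_theta(assignments$type[i], assignments$value[i],
                        assignments$censor[i], assignments$bound[i], pH_grid)
    Q <- Q + residue_charge(rep(assignments$type[i], length(pH_grid)), th)
  }
  structure(data.frame(pH = as.numeric(pH_grid), Q = Q),
            class = c("charge_curve", "data.frame"), method = method)
}

#' Extract one method's per-residue assignment from a pKa table
#'
#' @param table A [pka_table()].
#' @param method Method (column) label.
#' @param composition Composition data frame supplying residue types.
#' @return An assignment data frame for [net_charge_curve()].
#' @export
assignment_from_table <- function(table, method, composition) {
  stopifnot(inherits(table, "pka_table"))
  if (!method %in% table$methods) stop("unknown method: ", method)
  idx <- match(table$residues, composition$residue)
  if (anyNA(idx))
    stop("residues missing from composition: ",
         paste(table$residues[is.na(idx)], collapse = ", "))
  data.frame(residue = table$residues,
             type = composition$type[idx],
             value = table$value[, method],
             censor = table$censor[, method],
             bound = table$bound[, method],
             stringsAsFactors = FALSE)
}

#' Net-charge null model from model-compound pKa values
#'
#' Assigns every residue its model pKa, i.e. what the charge/pH profile
#' would look like with no environment-induced pKa shifts.
#'
#' @param composition Composition data frame with `type` and `model_pka`.
#' @param pH_grid Numeric pH grid.
#' @return A `charge_curve` labelled `"null_model"`.
#' @export
null_model_curve <- function(composition, pH_grid) {
  if (nrow(composition) == 0L)
    return(structure(data.frame(pH = as.numeric(pH_grid),
                                Q = rep(0, length(pH_grid))),
                     class = c("charge_curve", "data.frame"),
                     method = "null_model"))
  net_charge_curve(
    data.frame(residue = composition$residue, type = composition$type,
               pka = composition$model_pka, stringsAsFactors = FALSE),
    pH_grid, method = "null_model")
}

#' Normalize a curve to its values at two anchor pH points
#'
#' `v'(pH) = (v(pH) - v(pH_hi)) / (v(pH_lo) - v(pH_hi))`, so the curve is
#' exactly 1 at the low-pH anchor and 0 at the high-pH anchor.  Used to
#' overlay net-charge predictions with measured reversal-potential series
#' on a common scale.  Anchor values are linearly interpolated when not
#' on the grid.
#'
#' @param curve A `charge_curve`, or any data frame whose first two
#'   columns are pH and a value.
#' @param pH_lo,pH_hi Anchor pH values (defaults 2 and 8).
#' @return Data frame with columns `pH`, `value` (normalized).
#' @export
normalize_curve <- function(curve, pH_lo = 2, pH_hi = 8) {
  df <- as.data.frame(curve)
  pH <- df[[1]]; v <- df[[2]]
  if (pH_lo < min(pH) || pH_hi > max(pH) || pH_lo >= pH_hi)
    stop("anchors must lie inside the pH range, with pH_lo < pH_hi")
  v_lo <- stats::approx(pH, v, xout = pH_lo)$y
  v_hi <- stats::approx(pH, v, xout = pH_hi)$y
  if (v_lo == v_hi) stop("anchor values are equal: cannot normalize")
  data.frame(pH = pH, value = (v - v_hi) / (v_lo - v_hi))
}

#' Effective Hill characterization of an aggregate charge curve
#'
#' Normalizes the curve at its grid endpoints and fits the Hill equation,
#' yielding an *effective* pKa and Hill coefficient for the whole-protein
#' titration.  Aggregating sites with a spread of pKa values makes the
#' effective `n` smaller than 1 even when every site is ideal HH.
#'
#' @param curve A `charge_curve`.
#' @return A [hill_parameters()].
#' @export
effective_hill <- function(curve) {
  df <- as.data.frame(curve)
  norm <- normalize_curve(df, pH_lo = min(df[[1]]), pH_hi = max(df[[1]]))
  fit_hill(data.frame(pH = norm$pH, theta = norm$value), force = TRUE)
}
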