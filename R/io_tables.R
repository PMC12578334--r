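#' pKa estimate, possibly censored
#'
#' A pKa is either a number, or a censored bound when the titration curve
#' never crosses protonation fraction 0.5 inside the scanned pH range:
#' `below` means the residue stayed deprotonated down to the lowest pH
#' (reported as e.g. "< 1"), `above` that it stayed protonated up to the
#' highest pH ("> 8").  The censor limit is kept per estimate because
#' published tables mix limits (e.g. "< 1" and "< 0").
#'
#' @param value Numeric pKa, or `NA` when censored.
#' @param censor One of `"none"`, `"below"`, `"above"`.
#' @param bound Censor limit in pH units (`NA` when `censor = "none"`).
#' @param sd Replica standard deviation of the estimate, if known.
#' @param hill_n Hill coefficient attached by a Hill fit, if any.
#' @param method Free-text tag of the estimation route.
#'
#' @return An object of class `pka_estimate`.
#' @export
pka_estimate <- function(value = NA_real_, censor = "none", bound = NA_real_,
                         sd = NA_real_, hill_n = NA_real_, method = NA_character_) {
  censor <- match.arg(censor, c("none", "below", "above"))
  if (censor == "none" && is.na(value))
    stop("an uncensored estimate needs a numeric value")
  if (censor != "none" && is.na(bound))
    stop("a censored estimate needs its censor bound")
  if (!is.na(sd) && sd < 0) stop("sd must be >= 0")
  structure(list(value = as.numeric(value), censor = censor,
                 bound = as.numeric(bound), sd = as.numeric(sd),
                 hill_n = as.numeric(hill_n), method = method),
            class = "pka_estimate")
}

#' @export
format.pka_estimate <- function(x, digits = 2, ...) {
  out <- switch(x$censor,
                none = formatC(x$value, digits = digits, format = "f"),
                below = sprintf("< %g", x$bound),
                above = sprintf("> %g", x$bound))
  if (!is.na(x$sd)) out <- sprintf("%s +/- %.2f", out, x$sd)
  out
}

#' @export
print.pka_estimate <- function(x, ...) {
  cat("pKa", format(x), if (!is.na(x$method)) paste0("[", x$method, "]"), "\n")
  invisible(x)
}

#' Is a pKa estimate censored?
#' @param x A [pka_estimate()].
#' @return `TRUE` when the estimate is a bound rather than a number.
#' @export
is_censored <- function(x) {
  stopifnot(inherits(x, "pka_estimate"))
  x$censor != "none"
}

## Token grammar for table cells: a number, "<"number or ">"number,
## whitespace tolerated.  Everything else is rejected.
parse_pka_token <- function(token) {
  tok <- trimws(token)
  m <- regmatches(tok, regexec("^([<>])?\\s*([-+]?[0-9]*\\.?[0-9]+)$", tok))[[1]]
  if (length(m) == 0L) return(NULL)
  num <- as.numeric(m[3])
  if (m[2] == "<") list(value = NA_real_, censor = "below", bound = num)
  else if (m[2] == ">") list(value = NA_real_, censor = "above", bound = num)
  else list(value = num, censor = "none", bound = NA_real_)
}

#' pKa table: residues x methods
#'
#' The unit of cross-method benchmarking: one row per residue, one column
#' per prediction method, every cell a numeric pKa or a censored bound.
#' Stored as parallel matrices (`value`, `censor`, `bound`) so that masking
#' operations stay vectorised.
#'
#' @param residues Character vector of residue labels (unique).
#' @param methods Character vector of method labels (unique).
#' @param value Numeric residues x methods matrix (`NA` where censored).
#' @param censor Character matrix over `{"none","below","above"}`.
#' @param bound Numeric matrix of censor limits (`NA` where uncensored).
#' @return An object of class `pka_table`.
#' @export
pka_table <- function(residues, methods, value, censor, bound) {
  residues <- as.character(residues); methods <- as.character(methods)
  if (anyDuplicated(residues)) stop("duplicate residue labels")
  if (anyDuplicated(methods)) stop("duplicate method labels")
  dm <- c(length(residues), length(methods))
  for (m in list(value, censor, bound))
    if (!identical(dim(m), as.integer(dm))) stop("matrix dimensions mismatch")
  if (!all(censor %in% c("none", "below", "above")))
    stop("censor entries must be none/below/above")
  if (any(censor == "none" & is.na(value)))
    stop("every cell must carry a value or a censor bound")
  dimnames(value) <- dimnames(censor) <- dimnames(bound) <-
    list(residues, methods)
  structure(list(residues = residues, methods = methods, value = value,
                 censor = censor, bound = bound), class = "pka_table")
}

#' @export
print.pka_table <- function(x, ...) {
  cat(sprintf("pKa table: %d residues x %d methods (%d censored cells)\n",
              length(x$residues), length(x$methods), sum(x$censor != "none")))
  cat("methods:", paste(x$methods, collapse = ", "), "\n")
  invisible(x)
}

#' Read a residues x methods pKa table with censored entries
#'
#' First column: residue labels; remaining columns: one per method.  Cells
#' are numbers or censored tokens `"<x"` / `"> x"` (whitespace tolerated).
#' The delimiter is auto-detected (tab if the header contains one,
#' otherwise comma) unless given.
#'
#' @param path Path to the delimited text file.
#' @param sep Field delimiter; `NULL` to auto-detect.
#' @return A [pka_table()].
#' @export
read_pka_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  if (ncol(df) < 2L) stop("need a residue column plus at least one method")
  residues <- trimws(df[[1]])
  if (anyDuplicated(residues))
    stop("duplicate residue label: ",
         residues[duplicated(residues)][1])
  methods <- colnames(df)[-1]
  value <- bound <- matrix(NA_real_, nrow(df), length(methods))
  censor <- matrix("none", nrow(df), length(methods))
  for (j in seq_along(methods)) {
    for (i in seq_len(nrow(df))) {
      p <- parse_pka_token(df[[j + 1L]][i])
      if (is.null(p))
        stop(sprintf("unparseable pKa cell for residue %s, method %s: '%s'",
                     residues[i], methods[j], df[[j + 1L]][i]))
      value[i, j] <- p$value; censor[i, j] <- p$censor; bound[i, j] <- p$bound
    }
  }
  pka_table(residues, methods, value, censor, bound)
}

.res_types <- c(acid = "ASP", acid = "GLU", base = "HIS", base = "ARG",
                base = "LYS")

#' Read a residue composition table
#'
#' Composition tables list the ionizable residues entering net-charge and
#' pKa-shift calculations: label, residue type (Asp/Glu/His/Arg/Lys) and
#' the model-compound pKa used as the shift reference.  Model pKa values
#' are carried explicitly per residue rather than hard-coded.
#'
#' @param path Path to a CSV/TSV file with columns `residue` (or `label`),
#'   `type`, `model_pka`.
#' @param sep Field delimiter; `NULL` to auto-detect.
#' @return A data frame with columns `residue`, `type`, `model_pka`.
#' @export
read_composition <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    return(data.frame(residue = character(), type = character(),
                      model_pka = numeric(), stringsAsFactors = FALSE))
  if (is.null(sep)) sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, strip.white = TRUE,
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if ("label" %in% names(df) && !"residue" %in% names(df))
    names(df)[names(df) == "label"] <- "residue"
  need <- c("residue", "type", "model_pka")
  if (!all(need %in% names(df)))
    stop("composition needs columns residue/label, type, model_pka")
  out <- data.frame(residue = as.character(df$residue),
                    type = toupper(as.character(df$type)),
                    model_pka = suppressWarnings(as.numeric(df$model_pka)),
                    stringsAsFactors = FALSE)
  bad <- !out$type %in% .res_types
  if (any(bad))
    stop("unsupported residue type '", out$type[bad][1], "' for ",
         out$residue[bad][1], " (supported: ASP, GLU, HIS, ARG, LYS)")
  if (anyNA(out$model_pka))
    stop("missing model_pka for ", out$residue[is.na(out$model_pka)][1])
  out
}
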