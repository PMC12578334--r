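#' Generative titration model of one titratable site
#'
#' Describes how a site's lambda trajectory is generated: a mixture of
#' conformers (each with its own pKa and a weight), slow Markov exchange
#' between conformers, fast two-state protonation kinetics inside a
#' conformer, and Gaussian emission of lambda around 0 (protonated) or 1
#' (deprotonated).  The mixture is what produces shallow, apparently
#' negatively cooperative titration curves when conformer pKa values
#' differ; a single conformer gives exact Henderson-Hasselbalch behaviour.
#'
#' Conformers with identical pKa are merged at construction, so a
#' degenerate mixture is exactly the single-conformer model (including its
#' random stream, because conformer exchange draws are bypassed when only
#' one conformer remains).
#'
#' @param conformers Either a numeric vector of pKa values (equal weights),
#'   or a data frame / list with fields `weight` and `pKa`.  Weights must
#'   be positive; they are normalized to sum to 1.
#' @param exchange_time Mean conformer dwell time in ns.
#' @param proto_relax_time Protonation-state relaxation time
#'   1/(k_on + k_off) in ns.
#' @param emission_sd Gaussian spread of lambda around 0/1 (lambda units);
#'   must lie in \[0, 0.15\] so the 0.2/0.8 assignment thresholds separate
#'   the two states.
#' @param frame_interval Time between frames in ns.
#' @return An object of class `titration_model`.
#' @export
titration_model <- function(conformers, exchange_time = 50,
                            proto_relax_time = 0.5, emission_sd = 0.05,
                            frame_interval = 0.01) {
  if (is.numeric(conformers))
    conformers <- data.frame(weight = rep(1, length(conformers)),
                             pKa = as.numeric(conformers))
  conformers <- as.data.frame(conformers)
  stopifnot(all(c("weight", "pKa") %in% names(conformers)),
            nrow(conformers) >= 1L)
  if (any(conformers$weight <= 0)) stop("conformer weights must be > 0")
  ## merge equal-pKa conformers: degenerate mixtures collapse exactly
  w <- tapply(conformers$weight, conformers$pKa, sum)
  conformers <- data.frame(weight = as.numeric(w) / sum(w),
                           pKa = as.numeric(names(w)))
  conformers <- conformers[order(conformers$pKa), , drop = FALSE]
  rownames(conformers) <- NULL
  if (exchange_time <= 0 || proto_relax_time <= 0 || frame_interval <= 0)
    stop("all time constants must be > 0")
  if (emission_sd < 0 || emission_sd > 0.15)
    stop("emission_sd must be in [0, 0.15]")
  structure(list(conformers = conformers, exchange_time = exchange_time,
                 proto_relax_time = proto_relax_time,
                 emission_sd = emission_sd, frame_interval = frame_interval),
            class = "titration_model")
}

#' @export
print.titration_model <- function(x, ...) {
  cat(sprintf(
    "titration model: %d conformer(s); exchange %g ns, relax %g ns, emission sd %g, frame %g ns\n",
    nrow(x$conformers), x$exchange_time, x$proto_relax_time, x$emission_sd,
    x$frame_interval))
  print(x$conformers)
  invisible(x)
}

#' Closed-form protonation probability of a titration model
#'
#' The stationary protonated fraction of the generative model: a weighted
#' mixture of Henderson-Hasselbalch terms, one per conformer,
#' `theta(pH) = sum_k w_k / (1 + 10^(pH - pKa_k))`.  This is the oracle
#' every simulated trajectory and every downstream estimator is validated
#' against.
#'
#' @param pH Numeric vector of pH values.
#' @param model A [titration_model()].
#' @return Protonation probabilities, same length as `pH`.
#' @export
theta_true <- function(pH, model) {
  stopifnot(inherits(model, "titration_model"))
  cf <- model$conformers
  th <- vapply(seq_len(nrow(cf)),
               function(k) cf$weight[k] * hh_theta(pH, cf$pKa[k]),
               numeric(length(pH)))
  if (length(pH) == 1L) sum(th) else rowSums(matrix(th, nrow = length(pH)))
}

## Deterministic 32-bit sub-seed from the master seed and file coordinates.
## A stable string hash (no external digest dependency): per-file seeds are
## reproducible and decorrelated across residues/monomers/replicas/pH.
sub_seed <- function(master, ...) {
  key <- paste(c(format(master), vapply(list(...), format, "")),
               collapse = "|")
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}

#' Simulate a lambda trajectory with prescribed titration behaviour
#'
#' The hidden dynamics are two coupled Markov chains sampled per frame:
#' a conformer chain that re-draws the conformer from the mixture weights
#' at rate `1/exchange_time`, and a protonation chain that re-draws the
#' protonation state from its conformer-conditional stationary probability
#' `hh_theta(pH, pKa_conformer)` at rate `1/proto_relax_time`.  Both
#' chains therefore have exact stationary distributions and exponential
#' autocorrelation with the stated time constants; no attempt is made to
#' mimic the inertial dynamics of the lambda coordinate itself, because
#' downstream analysis only senses occupancy and correlation time.
#' Emitted lambda is 0 (protonated) or 1 (deprotonated) plus Gaussian
#' noise of sd `emission_sd` truncated symmetrically to 0.1 either side
#' of the state centre, so lambda stays in \[-0.1, 1.1\] and the
#' per-state emission mean sits exactly at 0 or 1 (an asymmetric cut
#' would bias lambda-averaged fractions near the curve extremes).
#'
#' @param model A [titration_model()].
#' @param pH Solution pH.
#' @param duration Trajectory length in ns (at least 10 frame intervals).
#' @param seed Integer seed; identical arguments give bit-identical output.
#' @param residue_id,monomer,replica Metadata for the returned trajectory.
#' @param keep_states If `TRUE`, attach the hidden conformer and
#'   protonation-state traces as attributes `"conformer"` and
#'   `"protonated"` (used by microstate diagnostics).
#' @return A [lambda_trajectory()].
#' @export
simulate_lambda <- function(model, pH, duration, seed,
                            residue_id = "site", monomer = 1L, replica = 1L,
                            keep_states = FALSE) {
  stopifnot(inherits(model, "titration_model"))
  dt <- model$frame_interval
  if (duration < 10 * dt) stop("duration must be >= 10 frame intervals")
  n <- as.integer(round(duration / dt))
  cf <- model$conformers
  k <- nrow(cf)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ## conformer chain (bypassed when a single conformer)
  if (k == 1L) {
    conf <- rep(1L, n)
  } else {
    q_c <- 1 - exp(-dt / model$exchange_time)
    ev_c <- stats::runif(n) < q_c
    ev_c[1] <- TRUE
    draw_c <- sample.int(k, n, replace = TRUE, prob = cf$weight)
    idx_c <- cummax(ifelse(ev_c, seq_len(n), 0L))
    conf <- draw_c[idx_c]
  }
  ## protonation chain: re-equilibrate to the conformer-conditional
  ## stationary probability at rate 1/proto_relax_time
  q_p <- 1 - exp(-dt / model$proto_relax_time)
  ev_p <- stats::runif(n) < q_p
  ev_p[1] <- TRUE
  u <- stats::runif(n)
  idx_p <- cummax(ifelse(ev_p, seq_len(n), 0L))
  theta <- hh_theta(pH, cf$pKa[conf])
  proto <- u[idx_p] < theta[idx_p]
  ## emission noise: Gaussian, truncated symmetrically to +/- 0.1 around
  ## the state centre (so lambda always lies in [-0.1, 1.1]); symmetric
  ## truncation keeps the per-state mean exactly at 0 or 1, which is what
  ## lets threshold counting and lambda averaging agree to < 1%
  centre <- ifelse(proto, 0, 1)
  if (model$emission_sd > 0) {
    p_edge <- stats::pnorm(0.1 / model$emission_sd)
    noise <- model$emission_sd *
      stats::qnorm(stats::runif(n, 1 - p_edge, p_edge))
    lam <- centre + noise
  } else {
    lam <- centre
  }
  traj <- lambda_trajectory(time = (seq_len(n) - 1L) * dt, lam = lam,
                            residue_id = residue_id, monomer = monomer,
                            replica = replica, pH = pH)
  if (keep_states) {
    attr(traj, "conformer") <- conf
    attr(traj, "protonated") <- as.integer(proto)
  }
  traj
}

#' Specification of a synthetic titration panel
#'
#' Describes the full simulated study layout: a set of residues (each a
#' [titration_model()]), the pH grid, and the monomer x replica hierarchy.
#' Defaults mirror the design of the emulated study: pH 1-8 in unit steps,
#' 3 monomers x 3 replicas, 200 ns per trajectory.
#'
#' @param residues Named list of [titration_model()] objects; names are
#'   residue labels.
#' @param pH_grid Strictly increasing pH values.
#' @param n_monomers,n_replicas Positive counts.
#' @param duration Trajectory length in ns.
#' @param seed Master integer seed; per-file sub-seeds derive from it.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(residues, pH_grid = 1:8, n_monomers = 3L,
                       n_replicas = 3L, duration = 200, seed = 1L) {
  stopifnot(is.list(residues), length(residues) >= 1L,
            !is.null(names(residues)), all(nzchar(names(residues))))
  for (m in residues) stopifnot(inherits(m, "titration_model"))
  if (anyDuplicated(names(residues))) stop("duplicate residue labels")
  pH_grid <- as.numeric(pH_grid)
  if (length(pH_grid) < 1L || any(diff(pH_grid) <= 0))
    stop("pH grid must be strictly increasing")
  if (n_monomers < 1L || n_replicas < 1L) stop("counts must be >= 1")
  structure(list(residues = residues, pH_grid = pH_grid,
                 n_monomers = as.integer(n_monomers),
                 n_replicas = as.integer(n_replicas),
                 duration = as.numeric(duration), seed = as.integer(seed)),
            class = "panel_spec")
}

#' Generate a synthetic lambda-trajectory dataset on disk
#'
#' Writes one xvg file per (residue, monomer, replica, pH) cell of the
#' panel, plus a JSON manifest recording every file, its sub-seed and the
#' true generating parameters (the recovery target for validation).
#' Sub-seeds are a stable hash of the master seed and the cell indices, so
#' regenerating with the same master seed reproduces the tree bit for bit
#' while different cells remain independent.
#'
#' @param spec A [panel_spec()].
#' @param out_dir Output directory (created if needed).
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return The manifest, invisibly (also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
generate_dataset <- function(spec, out_dir, overwrite = FALSE) {
  stopifnot(inherits(spec, "panel_spec"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !overwrite)
    stop("output directory exists and is not empty: ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- expand.grid(residue = names(spec$residues),
                      monomer = seq_len(spec$n_monomers),
                      replica = seq_len(spec$n_replicas),
                      pH = spec$pH_grid,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$seed <- NA_integer_
  grid$file <- NA_character_
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sd_i <- sub_seed(spec$seed, g$residue, g$monomer, g$replica, g$pH)
    fn <- sprintf("%s_m%d_r%d_pH%g.xvg", g$residue, g$monomer, g$replica, g$pH)
    traj <- simulate_lambda(spec$residues[[g$residue]], pH = g$pH,
                            duration = spec$duration, seed = sd_i,
                            residue_id = g$residue, monomer = g$monomer,
                            replica = g$replica)
    write_lambda_xvg(traj, file.path(out_dir, fn))
    grid$seed[i] <- sd_i
    grid$file[i] <- fn
  }
  models <- lapply(spec$residues, function(m)
    list(conformers = m$conformers, exchange_time = m$exchange_time,
         proto_relax_time = m$proto_relax_time, emission_sd = m$emission_sd,
         frame_interval = m$frame_interval))
  manifest <- list(seed = spec$seed, pH_grid = spec$pH_grid,
                   n_monomers = spec$n_monomers, n_replicas = spec$n_replicas,
                   duration = spec$duration, models = models, entries = grid)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

#' Read a dataset manifest written by [generate_dataset()]
#'
#' @param path Manifest file or the dataset directory containing
#'   `manifest.json`.
#' @return The manifest as a list; `entries` is a data frame.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  man$entries <- as.data.frame(man$entries, stringsAsFactors = FALSE)
  man$dir <- dirname(path)
  man
}
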