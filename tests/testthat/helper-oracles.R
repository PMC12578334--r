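## Shared helpers: small independent oracles and curve builders.

## Noiseless or noisy single-site HH curve on a grid.
make_hh_curve <- function(pKa, grid = 1:8, noise_sd = 0, n = 1) {
  th <- hh_theta(grid, pKa, n)
  if (noise_sd > 0) th <- pmin(pmax(th + rnorm(length(grid), 0, noise_sd), 0), 1)
  data.frame(pH = grid, theta = th)
}

## Standard error of the time-averaged protonation fraction of the
## generator, from the linearized spectral formula for a jump process:
## Var[mean] = (2/T) * (tau_p * E_conf[theta(1-theta)] + tau_c * Var_conf[theta]),
## the first term from protonation flips inside a conformer, the second
## from slow conformer exchange (absent for single-conformer models).
se_time_average <- function(model, pH, duration, n_traces = 1) {
  cf <- model$conformers
  th_k <- hh_theta(pH, cf$pKa)
  within <- sum(cf$weight * th_k * (1 - th_k))
  between <- sum(cf$weight * th_k^2) - sum(cf$weight * th_k)^2
  v <- (2 / duration) * (model$proto_relax_time * within +
                           model$exchange_time * between)
  sqrt(v / n_traces)
}

## Monomer/replica fraction table for one residue of a simulated panel.
simulate_fraction_table <- function(model, grid, n_monomers, n_replicas,
                                    duration, master_seed, residue = "X") {
  cells <- expand.grid(monomer = seq_len(n_monomers),
                       replica = seq_len(n_replicas), pH = grid)
  cells$fraction <- vapply(seq_len(nrow(cells)), function(i) {
    s <- phtitr:::sub_seed(master_seed, residue, cells$monomer[i],
                           cells$replica[i], cells$pH[i])
    tr <- simulate_lambda(model, pH = cells$pH[i], duration = duration,
                          seed = s)
    fraction_lambda_mean(tr)$fraction
  }, numeric(1))
  cells
}
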