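# Experiment drivers: parameter scans, phase-boundary bisection, and
# temperature sweeps. Every driver is a pure function of its arguments plus
# a single master seed, from which per-run seeds are derived.

derive_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# apply one swept value to a list of sim_params() arguments
apply_swept <- function(base, parameter, value) {
  switch(parameter,
    r = { base$r <- value; base$rB <- NULL; base$rV <- NULL },
    rB = base$rB <- value,
    rV = base$rV <- value,
    L = base$L <- value,
    N = { base$NB <- value; base$NV <- NULL },
    stop("unknown swept parameter: ", parameter))
  base
}

#' Scan a parameter over replicated simulations
#'
#' Runs `replicates` simulations at every value of the swept parameter,
#' classifies each run, and records first-loss times (horizon-censored rows
#' carry `NA` times and `censored = TRUE`; they are never treated as
#' losses). Individual run failures are recorded in the `error` column and
#' the scan continues.
#'
#' @param parameter one of `"r"`, `"rB"`, `"rV"`, `"L"`, `"N"`.
#' @param values strictly increasing vector of swept values.
#' @param base named list of [sim_params()] arguments shared by all runs
#'   (without the swept parameter and without `seed`).
#' @param replicates runs per value.
#' @param master_seed seed from which all per-run seeds are derived.
#' @param fit also fit Gamma temperatures to each run's pooled abundances
#'   (`NA` where the fit is not possible).
#' @param stop_on passed to [run_simulation()]; `"any_loss"` (default) ends
#'   each run at its first loss, which is all a persistence scan needs.
#' @return data.frame with one row per run: value, replicate, seed, regime,
#'   t_first_gene_loss, t_first_genotype_loss, censored flags, and (if
#'   `fit`) Theta_fit / theta_fit.
#' @export
scan_parameter <- function(parameter, values, base, replicates = 5,
                           master_seed = 1, fit = FALSE,
                           stop_on = "any_loss") {
  if (is.unsorted(values, strictly = TRUE))
    stop("`values` must be strictly increasing")
  if (replicates < 1) stop("`replicates` must be >= 1")
  grid <- expand.grid(replicate = seq_len(replicates), value = values)
  seeds <- derive_seeds(master_seed, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    args <- apply_swept(base, parameter, grid$value[i])
    args$seed <- seeds[i]
    row <- data.frame(value = grid$value[i], replicate = grid$replicate[i],
                      seed = seeds[i], regime = NA_character_,
                      t_first_gene_loss = NA_real_,
                      t_first_genotype_loss = NA_real_,
                      gene_censored = NA, genotype_censored = NA,
                      Theta_fit = NA_real_, theta_fit = NA_real_,
                      error = NA_character_)
    res <- tryCatch({
      traj <- run_simulation(do.call(sim_params, args), stop_on = stop_on)
      pt <- persistence_times(traj)
      row$regime <- classify_regime(traj)$label
      row$t_first_gene_loss <- pt$gene
      row$t_first_genotype_loss <- pt$genotype
      row$gene_censored <- is.na(pt$gene)
      row$genotype_censored <- is.na(pt$genotype)
      if (fit) {
        f <- tryCatch({
          sm <- sample_abundances(traj)
          c(fit_gamma(sm$genotype)$theta, fit_gamma(sm$gene)$theta)
        }, error = function(e) c(NA_real_, NA_real_))
        row$Theta_fit <- f[1]; row$theta_fit <- f[2]
      }
      row
    }, error = function(e) { row$error <- conditionMessage(e); row })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean persistence times per scanned value
#'
#' Censored runs enter the mean at the horizon (a lower bound, flagged via
#' the censored fraction), mirroring the "upper limit at the maximum
#' simulation length" convention of persistence-time curves.
#'
#' @param scan result of [scan_parameter()].
#' @return data.frame with per-value mean gene/genotype persistence times
#'   and censored fractions.
#' @export
summarize_scan <- function(scan) {
  horizon_fill <- function(t, cens, horizon) ifelse(cens, horizon, t)
  do.call(rbind, lapply(split(scan, scan$value), function(d) {
    data.frame(
      value = d$value[1],
      mean_gene_persistence = mean(ifelse(d$gene_censored, Inf, d$t_first_gene_loss)),
      mean_genotype_persistence = mean(ifelse(d$genotype_censored, Inf,
                                              d$t_first_genotype_loss)),
      gene_censored_fraction = mean(d$gene_censored, na.rm = TRUE),
      genotype_censored_fraction = mean(d$genotype_censored, na.rm = TRUE))
  }))
}

# majority vote: is this parameter value above the boundary (i.e. diverse)?
classify_point <- function(value, parameter, base, replicates, threshold,
                           stop_on, seeds) {
  ok <- logical(replicates)
  for (j in seq_len(replicates)) {
    args <- apply_swept(base, parameter, value)
    args$seed <- seeds[j]
    args$T <- threshold
    traj <- run_simulation(do.call(sim_params, args), stop_on = stop_on)
    ok[j] <- traj$termination == "horizon"  # survived the whole window
  }
  mean(ok) > 0.5
}

#' Locate a regime boundary by bisection
#'
#' A parameter value is "above" the I/II boundary if the majority of
#' replicate runs lose no gene within `persistence_threshold` generations,
#' and above the II/III boundary if the majority lose no genotype. The
#' bracket endpoints must classify to different sides (verified by pilot
#' runs); bisection proceeds in log space until at least `min_steps` splits
#' have been made or the bracket is narrower than 10% of its midpoint.
#'
#' @param boundary_kind `"I_II"` (gene maintenance) or `"II_III"` (genotype
#'   maintenance).
#' @param parameter swept parameter, usually `"r"` or `"rB"`.
#' @param bracket length-2 numeric, initial (low, high).
#' @param base named list of [sim_params()] arguments (without the swept
#'   parameter, `seed`, `T`).
#' @param replicates runs per bisection point (majority vote).
#' @param persistence_threshold survival window in generations.
#' @param master_seed master seed; each bisection point reuses the same
#'   derived replicate seeds so the vote is a function of the value alone.
#' @param min_steps minimum bisection steps.
#' @return object of class `boundary_estimate`: `boundary_kind`,
#'   `parameter`, `estimate` (geometric midpoint of the final bracket),
#'   `bracket`, `replicates_per_point`, `persistence_threshold`, `history`.
#' @export
find_boundary <- function(boundary_kind = c("I_II", "II_III"),
                          parameter = "r", bracket, base, replicates = 5,
                          persistence_threshold = 1e4, master_seed = 1,
                          min_steps = 6) {
  boundary_kind <- match.arg(boundary_kind)
  stop_on <- if (boundary_kind == "I_II") "gene_loss" else "genotype_loss"
  if (length(bracket) != 2 || bracket[1] <= 0 || bracket[1] >= bracket[2])
    stop("`bracket` must be positive and increasing")
  seeds <- derive_seeds(master_seed, replicates)
  lo <- bracket[1]; hi <- bracket[2]
  above_lo <- classify_point(lo, parameter, base, replicates,
                             persistence_threshold, stop_on, seeds)
  above_hi <- classify_point(hi, parameter, base, replicates,
                             persistence_threshold, stop_on, seeds)
  if (above_lo == above_hi)
    stop("bracket endpoints classify to the same side; widen the bracket")
  if (above_lo) stop("expected the low endpoint below the boundary")
  history <- data.frame(value = c(lo, hi), above = c(above_lo, above_hi))
  steps <- 0
  while (steps < min_steps && (hi - lo) > 0.1 * (lo + hi) / 2) {
    mid <- sqrt(lo * hi)
    above <- classify_point(mid, parameter, base, replicates,
                            persistence_threshold, stop_on, seeds)
    history <- rbind(history, data.frame(value = mid, above = above))
    if (above) hi <- mid else lo <- mid
    steps <- steps + 1
  }
  structure(list(boundary_kind = boundary_kind, parameter = parameter,
                 estimate = sqrt(lo * hi), bracket = c(lo, hi),
                 replicates_per_point = replicates,
                 persistence_threshold = persistence_threshold,
                 history = history),
            class = "boundary_estimate")
}

#' @export
print.boundary_estimate <- function(x, ...) {
  cat(sprintf("boundary_estimate (%s in %s): %.4g, bracket [%.4g, %.4g]\n",
              x$boundary_kind, x$parameter, x$estimate,
              x$bracket[1], x$bracket[2]))
  invisible(x)
}

#' Effective-temperature sweep across HGT rates
#'
#' For each rate: run, classify the regime, fit Gamma temperatures to the
#' pooled genotype and gene abundances, and attach the closed-form
#' predictions for the classified regime. Runs that end in Regime I are
#' flagged and carry no fits.
#'
#' @param r_values HGT rates to sweep (should span Regimes II and III).
#' @param base named list of [sim_params()] arguments.
#' @param master_seed master seed.
#' @param burn_in_fraction burn-in for sampling and classification.
#' @return data.frame with r, regime, Theta_fit, theta_fit, Theta_pred,
#'   theta_pred.
#' @export
temperature_sweep <- function(r_values, base, master_seed = 1,
                              burn_in_fraction = 0.1) {
  seeds <- derive_seeds(master_seed, length(r_values))
  rows <- lapply(seq_along(r_values), function(i) {
    r <- r_values[i]
    args <- apply_swept(base, "r", r)
    args$seed <- seeds[i]
    traj <- run_simulation(do.call(sim_params, args))
    regime <- classify_regime(traj, burn_in_fraction)$label
    row <- data.frame(r = r, regime = regime, Theta_fit = NA_real_,
                      theta_fit = NA_real_, Theta_pred = NA_real_,
                      theta_pred = NA_real_)
    if (regime != "I") {
      fits <- tryCatch({
        sm <- sample_abundances(traj, burn_in_fraction)
        c(fit_gamma(sm$genotype)$theta, fit_gamma(sm$gene)$theta)
      }, error = function(e) c(NA_real_, NA_real_))
      pred <- predicted_temperatures(r, regime)
      row$Theta_fit <- fits[1]; row$theta_fit <- fits[2]
      row$Theta_pred <- pred$Theta_pred; row$theta_pred <- pred$theta_pred
    }
    row
  })
  do.call(rbind, rows)
}
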