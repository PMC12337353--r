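#' Lyapunov energy of a bacteria-phage pair
#'
#' `E(B, V) = (B - n* log(B/n*)) + (V - n* log(V/n*))`, the conserved
#' quantity of the deterministic pair dynamics. It measures distance from
#' the coexistence fixed point: minimized at `B = V = n*` with value `2 n*`,
#' diverging as either abundance approaches zero, symmetric in B and V.
#' Under demographic noise the ensemble average of E drifts upward, which is
#' what eventually kills an unregulated pair.
#'
#' @param B,V positive abundances (vectorized).
#' @param n_star characteristic strain size `N/K`.
#' @return energy, in individuals.
#' @export
lyapunov <- function(B, V, n_star) {
  if (any(B <= 0) || any(V <= 0) || any(n_star <= 0))
    stop("`lyapunov` requires strictly positive abundances")
  (B - n_star * log(B / n_star)) + (V - n_star * log(V / n_star))
}

#' First-loss (persistence) times of genes and genotypes
#'
#' Persistence time is the simulation time until the first gene or genotype
#' is lost. Gene losses are reported per side (bacterial / phage) and
#' combined as the minimum; likewise genotype zero-touches. `NA` means the
#' event never happened before the run ended (horizon-censored); the horizon
#' actually reached is returned alongside.
#'
#' @param traj a [run_simulation()] record.
#' @return list with elements `gene_B`, `gene_V`, `gene`, `genotype_B`,
#'   `genotype_V`, `genotype`, and `horizon`.
#' @export
persistence_times <- function(traj) {
  stopifnot(inherits(traj, "trajectory_record"))
  mins <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  gB <- mins(traj$first_gene_zero_B)
  gV <- mins(traj$first_gene_zero_V)
  GB <- mins(traj$first_genotype_zero_B)
  GV <- mins(traj$first_genotype_zero_V)
  list(gene_B = gB, gene_V = gV, gene = mins(c(gB, gV)),
       genotype_B = GB, genotype_V = GV, genotype = mins(c(GB, GV)),
       horizon = traj$t_end)
}

#' Pool decorrelated abundance snapshots from a trajectory
#'
#' Takes recorded snapshots after a burn-in, thinned so consecutive
#' snapshots are at least `spacing` apart in model time (default `1/s`,
#' about one bacterial doubling time), and pools genotype and gene
#' abundances across strains and times.
#'
#' @param traj a [run_simulation()] record.
#' @param burn_in_fraction fraction of the realized horizon to discard.
#' @param spacing minimum model-time separation of snapshots.
#' @param side pool abundances from the bacterial side (default), the phage
#'   side, or both.
#' @return list with numeric vectors `genotype` and `gene`, and
#'   `n_snapshots`.
#' @export
sample_abundances <- function(traj, burn_in_fraction = 0.1, spacing = NULL,
                              side = c("bacteria", "phage", "both")) {
  stopifnot(inherits(traj, "trajectory_record"))
  side <- match.arg(side)
  if (is.null(spacing)) spacing <- 1 / traj$params$s
  t_burn <- burn_in_fraction * traj$t_end
  keep <- which(traj$times >= t_burn)
  if (length(keep) > 1) {
    sel <- keep[1]
    last_t <- traj$times[keep[1]]
    for (i in keep[-1]) {
      if (traj$times[i] - last_t >= spacing) { sel <- c(sel, i); last_t <- traj$times[i] }
    }
    keep <- sel
  }
  if (length(keep) < 10)
    stop(errorCondition(
      sprintf("insufficient data: only %d snapshots after burn-in/spacing", length(keep)),
      class = c("insufficient_data", "error", "condition")))
  take <- function(mb, mv) switch(side,
    bacteria = as.vector(mb[keep, , drop = FALSE]),
    phage = as.vector(mv[keep, , drop = FALSE]),
    both = c(as.vector(mb[keep, , drop = FALSE]), as.vector(mv[keep, , drop = FALSE])))
  list(genotype = take(traj$B, traj$V), gene = take(traj$gene_B, traj$gene_V),
       n_snapshots = length(keep))
}

#' Maximum-likelihood Gamma fit of an abundance ensemble
#'
#' Fits a two-parameter Gamma by MLE on the strictly positive samples
#' (exact zeros are excluded -- Gamma support is positive and the zeros
#' carry the extinction signal, reported separately as `zero_fraction`).
#' The fitted scale is the "effective temperature" of the ensemble.
#'
#' The shape MLE solves `log(k) - digamma(k) = log(mean) - mean(log)` by
#' Newton iteration from the standard closed-form starting point.
#'
#' @param samples numeric vector of abundances (zeros allowed, negatives
#'   not).
#' @return object of class `gamma_fit`: `mean`, `theta` (scale), `shape`,
#'   `n_samples`, `zero_fraction`, `loglik`.
#' @export
fit_gamma <- function(samples) {
  if (any(samples < 0)) stop("abundances must be nonnegative")
  zero_fraction <- mean(samples == 0)
  x <- samples[samples > 0]
  if (length(x) < 100)
    stop(errorCondition(
      sprintf("insufficient data: %d positive samples (need >= 100)", length(x)),
      class = c("insufficient_data", "error", "condition")))
  if (stats::var(x) == 0)
    stop(errorCondition("degenerate fit: all positive samples identical",
                        class = c("degenerate_fit", "error", "condition")))
  m <- mean(x)
  s0 <- log(m) - mean(log(x))
  k <- (3 - s0 + sqrt((s0 - 3)^2 + 24 * s0)) / (12 * s0)
  for (i in 1:50) {
    step <- (log(k) - digamma(k) - s0) / (1 / k - trigamma(k))
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-10 * k) { k <- k_new; break }
    k <- k_new
  }
  theta <- m / k
  structure(list(mean = m, theta = theta, shape = k,
                 n_samples = length(samples), zero_fraction = zero_fraction,
                 loglik = sum(dgamma(x, shape = k, scale = theta, log = TRUE))),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf(paste0("gamma_fit: mean = %.4g, theta (scale) = %.4g, ",
                     "shape = %.4g | n = %d, zero fraction = %.3f\n"),
              x$mean, x$theta, x$shape, x$n_samples, x$zero_fraction))
  invisible(x)
}

#' Classify a trajectory into dynamical regime I, II, or III
#'
#' Regime I (unstable coexistence): some gene was lost from the community at
#' any time on either side. Regime II (genotype turnover, gene persistence):
#' no gene lost, but some genotype abundance touched zero after burn-in.
#' Regime III (stable coexistence): every genotype stayed positive after
#' burn-in on both sides.
#'
#' @param traj a [run_simulation()] record.
#' @param burn_in_fraction fraction of the realized horizon treated as
#'   transient for the genotype zero-touch test.
#' @return object of class `regime_label`: `label` ("I"/"II"/"III"),
#'   `first_gene_loss` (`NA` if none), `genotype_zero_events` (count after
#'   burn-in), `evidence` (free text).
#' @export
classify_regime <- function(traj, burn_in_fraction = 0.1) {
  stopifnot(inherits(traj, "trajectory_record"))
  pt <- persistence_times(traj)
  t_burn <- burn_in_fraction * traj$t_end
  # zero-touch transitions after burn-in, from the recorded cumulative count
  before <- traj$cum_zero_touch[traj$times <= t_burn]
  base <- if (length(before)) before[length(before)] else 0L
  zt_after <- as.integer(traj$zero_touch_total - base)
  touched_after <- any(traj$last_genotype_zero_B >= t_burn, na.rm = TRUE) ||
    any(traj$last_genotype_zero_V >= t_burn, na.rm = TRUE)
  if (!is.na(pt$gene)) {
    label <- "I"
    evidence <- sprintf("first gene lost at t = %g", pt$gene)
  } else if (touched_after) {
    label <- "II"
    evidence <- sprintf("no gene lost; %d genotype zero-touch events after burn-in (t > %g)",
                        zt_after, t_burn)
  } else {
    label <- "III"
    evidence <- sprintf("no gene lost and no genotype at zero after burn-in (t > %g)", t_burn)
  }
  structure(list(label = label, first_gene_loss = pt$gene,
                 genotype_zero_events = zt_after, evidence = evidence),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("regime %s: %s\n", x$label, x$evidence))
  invisible(x)
}

#' Boom-bust peak statistics of bacterial genotype trajectories
#'
#' A boom is a maximal contiguous excursion of one bacterial genotype above
#' `threshold_multiple * n*`; its peak is the maximum abundance within the
#' excursion. The heights above threshold of kill-the-winner booms are
#' predicted to be exponentially distributed with rate `2 r`, so the
#' maximum-likelihood exponential rate `1/mean(peak - threshold)` is
#' reported.
#'
#' @param traj a [run_simulation()] record, or a plain numeric matrix of
#'   abundances (rows = times, columns = genotypes; then `n_star` and
#'   `times` must be given).
#' @param threshold_multiple boom threshold in units of `n*` (default 5).
#' @param n_star,times required when `traj` is a bare matrix.
#' @param min_peaks minimum number of booms required for the tail fit.
#' @return object of class `peak_stats`: `peaks` (data.frame with genotype,
#'   time, height), `exp_rate`, `threshold`.
#' @export
boom_peaks <- function(traj, threshold_multiple = 5, n_star = NULL,
                       times = NULL, min_peaks = 20) {
  if (inherits(traj, "trajectory_record")) {
    mat <- traj$B
    times <- traj$times
    n_star <- traj$params$NB / traj$params$K
  } else {
    mat <- as.matrix(traj)
    if (is.null(n_star) || is.null(times))
      stop("`n_star` and `times` are required for a bare matrix")
  }
  thr <- threshold_multiple * n_star
  peaks <- list()
  for (k in seq_len(ncol(mat))) {
    above <- mat[, k] > thr
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (i in which(runs$values)) {
      seg <- starts[i]:ends[i]
      j <- seg[which.max(mat[seg, k])]
      peaks[[length(peaks) + 1L]] <-
        data.frame(genotype = k, time = times[j], height = mat[j, k])
    }
  }
  if (length(peaks) < min_peaks)
    stop(errorCondition(
      sprintf("insufficient data: %d boom peaks above threshold (need >= %d)",
              length(peaks), min_peaks),
      class = c("insufficient_data", "error", "condition")))
  peaks <- do.call(rbind, peaks)
  exp_rate <- 1 / mean(peaks$height - thr)
  structure(list(peaks = peaks, exp_rate = exp_rate, threshold = thr),
            class = "peak_stats")
}

#' @export
print.peak_stats <- function(x, ...) {
  cat(sprintf("peak_stats: %d booms above %.4g, exponential tail rate = %.4g\n",
              nrow(x$peaks), x$threshold, x$exp_rate))
  invisible(x)
}
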