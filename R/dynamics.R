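#' Simulation parameters for the stochastic bacteria-phage community
#'
#' Time is measured in model "generations"; all rates are per capita per
#' generation. The deterministic skeleton is the antisymmetric Lotka-Volterra
#' pair dynamics with per-capita bacterial fitness `s (1 - V/nV*)` and phage
#' fitness `omega (B/nB* - 1)`, where the characteristic strain sizes are
#' `nB* = NB/K` and `nV* = NV/K` (burst size and adsorption rate are absorbed
#' by this reparameterization and are not independent inputs). On top of the
#' demographic updates, three HGT channels move single genes between genomes
#' at per-capita rates `rB` (bacteria-to-bacteria) and `rV` (into phage,
#' either from bacteria or phage-to-phage).
#'
#' Scaling ratios can be given instead of absolute values: `rho_s = omega/s`,
#' `rho_n = NV/NB`, `rho_r = rV/rB`. The fully antisymmetric reference case
#' is `rho_s = rho_n = rho_r = 1`, obtained by giving just `r` (which sets
#' `rB = rV = r`) and `NB`.
#'
#' @param L gene-pool size.
#' @param g genes per genome (2 or 3).
#' @param NB target total bacterial population size (held fixed by the
#'   regulator).
#' @param NV target total phage population size; `NV = 0` disables the phage
#'   side entirely (the model then reduces to neutral Wright-Fisher drift).
#' @param s bacterial per-capita division rate per generation.
#' @param rho_s ratio `omega/s`; `omega` overrides it if given.
#' @param omega phage per-capita death rate.
#' @param r shorthand setting `rB = rV = r`.
#' @param rB per-capita inter-bacteria HGT rate.
#' @param rho_r ratio `rV/rB`; `rV` overrides it if given.
#' @param rV per-capita phage-side HGT rate.
#' @param rho_n ratio `NV/NB`; `NV` overrides it if given.
#' @param phage_hgt gene source for the phage HGT channel:
#'   `"from_bacteria"` (antitoxin picked up from an abundance-weighted
#'   bacterial donor), `"interphage"` (mean-field phage-to-phage transfer),
#'   or `"off"`.
#' @param dt time step in generations. The construction enforces
#'   `s*dt <= 0.1` and `omega*dt <= 0.1` so baseline per-capita event
#'   probabilities per leap stay small.
#' @param T simulation horizon in generations.
#' @param record_every record abundances every this many steps; default
#'   `ceiling(1/(s*dt))`, roughly once per bacterial doubling time.
#'   Gene/genotype extinction times are always detected at step resolution.
#' @param regulate `"exact"` projects totals back to `NB`/`NV` after every
#'   step by multinomial correction; `"none"` lets totals drift (used for
#'   single-pair experiments where a total-population regulator is
#'   meaningless).
#' @param seed RNG seed for the run.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(L, g = 2, NB, NV = NULL, s = 5e-3, rho_s = 1,
                       omega = NULL, r = NULL, rB = NULL, rho_r = 1,
                       rV = NULL, rho_n = 1,
                       phage_hgt = c("from_bacteria", "interphage", "off"),
                       dt = 1, T = 1e4, record_every = NULL,
                       regulate = c("exact", "none"), seed = 1L) {
  phage_hgt <- match.arg(phage_hgt)
  regulate <- match.arg(regulate)
  if (is.null(omega)) omega <- rho_s * s
  if (!is.null(r)) { if (is.null(rB)) rB <- r; if (is.null(rV)) rV <- r }
  if (is.null(rB)) rB <- 0
  if (is.null(rV)) rV <- rho_r * rB
  if (is.null(NV)) NV <- round(rho_n * NB)
  if (any(c(s, omega, rB, rV) < 0)) stop("rates must be nonnegative")
  if (dt <= 0 || T <= 0) stop("`dt` and `T` must be positive")
  if (s * dt > 0.1 || omega * dt > 0.1)
    stop("`dt` too large: require s*dt <= 0.1 and omega*dt <= 0.1")
  K <- choose(L, g)
  if (NB < K || (NV > 0 && NV < K))
    warning("population size below K: many genotypes start empty")
  if (is.null(record_every)) record_every <- max(1L, ceiling(1 / (s * dt)))
  structure(list(L = as.integer(L), g = as.integer(g), K = as.integer(K),
                 NB = as.integer(NB), NV = as.integer(NV),
                 s = s, omega = omega, rB = rB, rV = rV,
                 rho_s = omega / s, rho_r = if (rB > 0) rV / rB else NA_real_,
                 rho_n = if (NB > 0) NV / NB else NA_real_,
                 phage_hgt = phage_hgt, dt = dt, T = T,
                 record_every = as.integer(record_every),
                 regulate = regulate, seed = as.integer(seed)),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_params: L=%d g=%d K=%d | NB=%d NV=%d | s=%g omega=%g | ",
    "rB=%g rV=%g (%s) | dt=%g T=%g | regulate=%s seed=%d\n"),
    x$L, x$g, x$K, x$NB, x$NV, x$s, x$omega, x$rB, x$rV, x$phage_hgt,
    x$dt, x$T, x$regulate, x$seed))
  invisible(x)
}

characteristic_sizes <- function(params) {
  list(nB_star = params$NB / params$K,
       nV_star = if (params$NV > 0) params$NV / params$K else Inf)
}

#' Community state: integer abundances of every genotype on both sides
#'
#' @param B,V nonnegative integer vectors of length K.
#' @param t elapsed model time.
#' @export
community_state <- function(B, V, t = 0) {
  if (length(B) != length(V)) stop("B and V must have equal length")
  if (any(B < 0) || any(V < 0)) stop("abundances must be nonnegative")
  structure(list(B = as.integer(B), V = as.integer(V), t = t),
            class = "community_state")
}

#' Per-capita fitnesses of every genotype
#'
#' `fB[k] = s (1 - (M V)[k] / nV*)` and `fV[k] = omega ((M' B)[k] / nB* - 1)`.
#' In matched mode `M` is the identity and these are the per-pair
#' expressions: a bacterial strain whose matching phage is absent grows at
#' the full rate `s`; a phage whose host sits at `nB*` has zero fitness.
#'
#' @param state a [community_state()].
#' @param params a [sim_params()].
#' @param M an [build_interaction()] object or `NULL` (matched).
#' @return list with numeric vectors `fB` and `fV`.
#' @export
per_capita_fitness <- function(state, params, M = NULL) {
  ch <- characteristic_sizes(params)
  if (is.null(M) || M$mode == "matched") {
    MV <- state$V
    MtB <- state$B
  } else {
    MV <- as.vector(M$M %*% state$V)
    MtB <- as.vector(crossprod(M$M, state$B))
  }
  list(fB = params$s * (1 - MV / ch$nV_star),
       fV = params$omega * (MtB / ch$nB_star - 1))
}

#' One tau-leap of births and deaths (Poisson reproduction)
#'
#' Each individual of a genotype with per-capita fitness `f` leaves a
#' Poisson(1 + f dt) number of descendants, so the genotype is resampled as
#' `n' ~ Pois(n (1 + f dt))` (mean clamped at zero). Empty strains receive
#' no events, so demographic extinction is absorbing. The per-step variance
#' is approximately `n` regardless of the fitness, the demographic-noise
#' floor that drives the Lyapunov energy upward even at the coexistence
#' fixed point.
#'
#' @param state a [community_state()].
#' @param fB,fV per-capita fitness vectors from [per_capita_fitness()].
#' @param dt time step.
#' @return updated [community_state()] (time not advanced; callers advance
#'   it after the full composite step).
#' @export
demographic_step <- function(state, fB, fV, dt) {
  state$B <- demographic_step_cpp(state$B, fB, dt)
  state$V <- demographic_step_cpp(state$V, fV, dt)
  state
}

#' Inter-bacteria HGT tau-leap
#'
#' Draws `Poisson(rB * sum(B) * dt)` attempted transfer events. Each event
#' samples a recipient and a donor genotype independently in proportion to
#' current bacterial abundances, a donor gene uniformly among the donor's `g`
#' genes, and a replaced slot uniformly among the recipient's; if the product
#' genotype differs from the recipient (see [hgt_product()]) one individual
#' moves recipient -> product. Total bacterial abundance is conserved.
#'
#' @inheritParams demographic_step
#' @param params a [sim_params()].
#' @param space a [build_space()] object.
#' @export
hgt_step_bacteria <- function(state, params, space, dt) {
  if (params$rB == 0) return(state)
  state$B <- hgt_step_cpp(state$B, state$B, TRUE, space$genotypes,
                          space$idx_lookup, space$L, space$g, params$rB, dt)
  state
}

#' Phage-side HGT tau-leap
#'
#' As [hgt_step_bacteria()], with `Poisson(rV * sum(V) * dt)` events into the
#' phage side. The gene donor pool depends on `params$phage_hgt`:
#' `"from_bacteria"` samples donors proportional to bacterial abundances (a
#' phage picks the antitoxin up from an infected host's TA locus),
#' `"interphage"` samples proportional to phage abundances (mean-field
#' coinfection approximation), `"off"` is a no-op.
#'
#' @inheritParams hgt_step_bacteria
#' @export
hgt_step_phage <- function(state, params, space, dt) {
  if (params$rV == 0 || params$phage_hgt == "off") return(state)
  donors <- if (params$phage_hgt == "from_bacteria") state$B else state$V
  same <- params$phage_hgt == "interphage"
  state$V <- hgt_step_cpp(state$V, donors, same, space$genotypes,
                          space$idx_lookup, space$L, space$g, params$rV, dt)
  state
}

#' Project total population sizes back to their targets
#'
#' Restores `sum(B) = NB` and `sum(V) = NV` exactly: surplus individuals are
#' removed by sequential draws proportional to current abundances (capped at
#' abundance, resampled among survivors); deficits are filled by multinomial
#' draws proportional to abundances at entry. Strain frequencies are
#' unchanged in expectation and empty strains never gain individuals.
#'
#' If a side with a positive target has died out entirely, a condition of
#' class `global_extinction` is signalled.
#'
#' @inheritParams hgt_step_bacteria
#' @export
regulate <- function(state, params) {
  resB <- regulate_cpp(state$B, params$NB)
  if (resB$extinct)
    stop(errorCondition("global bacterial extinction",
                        class = c("global_extinction", "error", "condition")))
  state$B <- resB$n
  if (params$NV > 0) {
    resV <- regulate_cpp(state$V, params$NV)
    if (resV$extinct)
      stop(errorCondition("global phage extinction",
                          class = c("global_extinction", "error", "condition")))
    state$V <- resV$n
  }
  state
}

uniform_init <- function(N, K) {
  base <- rep.int(N %/% K, K)
  rem <- N - sum(base)
  if (rem > 0) base <- base + as.integer(rmultinom(1, rem, rep(1, K)))
  base
}

#' Run a full simulation
#'
#' Iterates fitness -> demography -> HGT (bacterial then phage channel) ->
#' regulation, detecting gene and genotype extinctions at every step and
#' recording abundances at the configured cadence. The whole run is a pure
#' function of `params` (including its seed): identical inputs give
#' bit-identical records.
#'
#' @param params a [sim_params()].
#' @param space optional [build_space()]; built from `params$L`, `params$g`
#'   if missing.
#' @param M optional [build_interaction()]; `NULL` means matched (identity).
#' @param init `"uniform"` (each genotype starts at `floor(N/K)` with the
#'   remainder spread by a multinomial draw) or a [community_state()].
#' @param stop_on optionally end the run early at the first gene loss, the
#'   first genotype zero-touch, or either (used by persistence-time scans
#'   where nothing after the first loss matters).
#' @return object of class `trajectory_record`; see Details.
#' @details The record holds the sampling times, `B`, `V` (samples x K),
#'   per-gene abundances on both sides (samples x L), the cumulative count of
#'   genotype zero-touch events, first/last zero times for every gene and
#'   genotype on both sides (step-resolution; `NA` = never), the termination
#'   reason, and the parameters.
#' @export
run_simulation <- function(params, space = NULL, M = NULL, init = "uniform",
                           stop_on = c("none", "gene_loss", "genotype_loss",
                                       "any_loss")) {
  stopifnot(inherits(params, "sim_params"))
  stop_on <- match.arg(stop_on)
  stop_mode <- switch(stop_on, none = 0L, gene_loss = 1L,
                      genotype_loss = 2L, any_loss = 3L)
  if (is.null(space)) space <- build_space(params$L, params$g)
  if (space$L != params$L || space$g != params$g)
    stop("`space` does not match `params`")
  set.seed(params$seed)
  if (identical(init, "uniform")) {
    B0 <- uniform_init(params$NB, space$K)
    V0 <- if (params$NV > 0) uniform_init(params$NV, space$K)
          else rep.int(0L, space$K)
  } else {
    stopifnot(inherits(init, "community_state"))
    if (length(init$B) != space$K)
      stop(sprintf("init has %d genotypes but the space has K = %d",
                   length(init$B), space$K))
    B0 <- init$B; V0 <- init$V
  }
  ch <- characteristic_sizes(params)
  Mmat <- if (is.null(M) || M$mode == "matched") NULL else M$M
  phage_mode <- switch(params$phage_hgt, off = 0L, from_bacteria = 1L,
                       interphage = 2L)
  n_steps <- as.integer(ceiling(params$T / params$dt))
  raw <- run_core(space$genotypes, space$idx_lookup, space$L, space$g,
                  Mmat, B0, V0,
                  params$s, params$omega, params$rB, params$rV, phage_mode,
                  params$NB, params$NV, ch$nB_star,
                  if (is.finite(ch$nV_star)) ch$nV_star else 1,
                  params$dt, n_steps, params$record_every,
                  params$regulate == "exact", stop_mode)
  na_ify <- function(v) { v[v < 0] <- NA_real_; v }
  structure(list(
    times = raw$times, B = raw$B, V = raw$V,
    gene_B = raw$gene_B, gene_V = raw$gene_V,
    cum_zero_touch = raw$cum_zero_touch,
    first_gene_zero_B = na_ify(raw$first_gene_zero_B),
    first_gene_zero_V = na_ify(raw$first_gene_zero_V),
    first_genotype_zero_B = na_ify(raw$first_genotype_zero_B),
    first_genotype_zero_V = na_ify(raw$first_genotype_zero_V),
    last_genotype_zero_B = na_ify(raw$last_genotype_zero_B),
    last_genotype_zero_V = na_ify(raw$last_genotype_zero_V),
    zero_touch_total = raw$zero_touch_total,
    termination = c("horizon", "extinct_bacteria", "extinct_phage",
                    "gene_loss_stop", "genotype_loss_stop")[raw$termination + 1L],
    t_end = raw$t_end, steps_done = raw$steps_done,
    params = params, space_dims = c(L = space$L, g = space$g, K = space$K)),
    class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat(sprintf(paste0("trajectory_record: %d samples over t = [0, %g] ",
                     "(K = %d), termination: %s\n"),
              length(x$times), x$t_end, ncol(x$B), x$termination))
  pt <- persistence_times(x)
  cat(sprintf("  first gene loss: %s | first genotype zero: %s | zero-touch events: %d\n",
              if (is.na(pt$gene)) "none" else format(pt$gene),
              if (is.na(pt$genotype)) "none" else format(pt$genotype),
              as.integer(x$zero_touch_total)))
  invisible(x)
}
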