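#' Gamma abundance density in mean/temperature parameterization
#'
#' The canonical-ensemble ansatz for strain abundances: a Gamma with mean
#' `n_star` and scale ("effective temperature") `theta`, i.e. shape
#' `n_star/theta`.
#'
#' @param n abundance (vectorized, positive).
#' @param n_star mean abundance.
#' @param theta effective temperature (Gamma scale), individuals.
#' @return density values.
#' @export
gamma_pdf <- function(n, n_star, theta) {
  if (any(n <= 0) || n_star <= 0 || theta <= 0)
    stop("`gamma_pdf` requires positive arguments")
  dgamma(n, shape = n_star / theta, scale = theta)
}

#' Predicted effective temperatures for genotypes and genes
#'
#' Boom-bust regime (II): genotype and gene fluctuations share the
#' exponential peak-size scale, `Theta = theta = 1/(2r)`. Stochastic
#' oscillation regime (III): `Theta = 1/(2r)` but biased gene-level sampling
#' amplifies gene fluctuations to `theta = 2/r` (a factor-4 ratio).
#'
#' @param r per-capita HGT rate (per generation).
#' @param regime `"II"` or `"III"`.
#' @return list with `Theta_pred` (genotype) and `theta_pred` (gene), in
#'   individuals.
#' @export
predicted_temperatures <- function(r, regime = c("II", "III")) {
  regime <- match.arg(regime)
  if (r <= 0) stop("`r` must be positive")
  Theta <- 1 / (2 * r)
  theta <- if (regime == "II") 1 / (2 * r) else 2 / r
  list(Theta_pred = Theta, theta_pred = theta)
}

#' Shape-positivity margins of the Gamma abundance distributions
#'
#' The Gamma power exponent must be positive for the abundance PDF to have
#' an interior mode; otherwise the mode sits at zero and the strain (or
#' gene) is headed for extinction. The margins are `N/(K Theta) - 1` for
#' genotypes and `2N/(L theta) - 1` for genes; zero crossings demarcate the
#' I/II and II/III regime transitions.
#'
#' @param N total population size per side.
#' @param K genotype count.
#' @param L gene count.
#' @param Theta,theta effective temperatures.
#' @return list with `genotype_shape_margin` and `gene_shape_margin`.
#' @export
extinction_criteria <- function(N, K, L, Theta, theta) {
  if (any(c(N, K, L, Theta, theta) <= 0)) stop("all arguments must be positive")
  list(genotype_shape_margin = N / (K * Theta) - 1,
       gene_shape_margin = 2 * N / (L * theta) - 1)
}

#' Critical HGT rates for gene and genotype maintenance
#'
#' `rcg = c_g L / N` (below it genes are lost: regime I) and
#' `rcG = c_G K / N` (below it genotypes turn over: regime II). The scaling
#' argument fixes the exponents, not the order-1 prefactors `c_g`, `c_G`,
#' which default to 1 and can be calibrated from simulation.
#'
#' @param L gene count; @param K genotype count; @param N population size.
#' @param c_g,c_G order-1 prefactors.
#' @return list with `rcg` and `rcG` (per generation).
#' @export
critical_hgt_rates <- function(L, K, N, c_g = 1, c_G = 1) {
  if (any(c(L, K, N, c_g, c_G) <= 0)) stop("all arguments must be positive")
  list(rcg = c_g * L / N, rcG = c_G * K / N)
}

# invert K = choose(L, g) for L
invert_genotype_count <- function(K, g = 2) {
  if (g == 2) (1 + sqrt(1 + 8 * K)) / 2
  else uniroot(function(L) L * (L - 1) * (L - 2) / 6 - K,
               c(g, 10 * (6 * K)^(1 / 3) + 10))$root
}

#' Maximum sustainable gene and genotype diversity at a given HGT rate
#'
#' Inverting the critical rates: `Lmax = rN/c_g` genes can be maintained
#' (the gene-diversity carrying capacity), and `Kmax = rN/c_G` genotypes
#' can persist without turnover. `L_at_Kmax` converts the genotype capacity
#' back to the gene-pool size whose full space it corresponds to.
#'
#' @param r HGT rate; @param N population size.
#' @param c_g,c_G order-1 prefactors; @param g genes per genome.
#' @return list with `Lmax`, `Kmax`, `L_at_Kmax`.
#' @export
max_diversity <- function(r, N, c_g = 1, c_G = 1, g = 2) {
  if (r <= 0 || N <= 0) stop("`r` and `N` must be positive")
  Kmax <- r * N / c_G
  list(Lmax = r * N / c_g, Kmax = Kmax,
       L_at_Kmax = invert_genotype_count(Kmax, g))
}

#' Minimum inter-bacteria HGT rate to escape phage predation
#'
#' At saturating phage-side HGT the I/II boundary is set by the bacterial
#' "escape" rate alone: a booming clone must seed at least one established
#' resistant lineage per boom, giving `rB > L / NB` (the y = x line when
#' plotted as `rB NB` against `L`).
#'
#' @param L gene count; @param NB total bacterial population size.
#' @return the critical rate `L / NB`.
#' @export
min_interbacteria_rate <- function(L, NB) {
  if (L <= 0 || NB <= 0) stop("`L` and `NB` must be positive")
  L / NB
}

#' Mean-field drift and noise scale of the Lyapunov energy
#'
#' The qualitative contract of the energy dynamics: demographic noise
#' contributes strictly positive drift `n*^2/(2B) + n*^2/(2V)` (equal to
#' `n*` at the fixed point), while mean-field HGT at strength `rN/K`
#' contributes a restoring term (mean-field HGT strength `rN/K`) that is
#' nonpositive whenever both abundances sit below `n*`. The diffusion scale
#' vanishes at the fixed point.
#'
#' @param B,V positive abundances.
#' @param n_star characteristic strain size.
#' @param r HGT rate; @param N population size; @param K genotype count.
#' @return list with `drift` and `diffusion_scale`.
#' @export
mean_field_drift <- function(B, V, n_star, r, N, K) {
  if (any(B <= 0) || any(V <= 0)) stop("abundances must be positive")
  drift <- n_star^2 / (2 * B) + n_star^2 / (2 * V) -
    (r * N / K) * ((n_star - B) / B + (n_star - V) / V)
  diffusion_scale <- sqrt((B - n_star)^2 / B + (V - n_star)^2 / V)
  list(drift = drift, diffusion_scale = diffusion_scale)
}

#' Bundle of closed-form predictions for one parameter set
#'
#' @param L gene count; @param g genes per genome; @param N population size.
#' @param r HGT rate.
#' @param regime `"II"` or `"III"` for the temperature branch.
#' @param c_g,c_G order-1 prefactors.
#' @param s bacterial division rate (for the boom-period estimate
#'   `tau_boom = log(s N / L) / s`).
#' @return object of class `theory_prediction` with fields `Theta_pred`,
#'   `theta_pred`, `rcg`, `rcG`, `Lmax`, `Kmax`, `tau_boom`, `n_boom`
#'   (estimated number of concurrently booming strains, `rN`).
#' @export
theory_prediction <- function(L, g = 2, N, r, regime = c("II", "III"),
                              c_g = 1, c_G = 1, s = 5e-3) {
  regime <- match.arg(regime)
  K <- choose(L, g)
  temps <- predicted_temperatures(r, regime)
  rates <- critical_hgt_rates(L, K, N, c_g, c_G)
  divs <- max_diversity(r, N, c_g, c_G, g)
  structure(c(temps, rates, divs[c("Lmax", "Kmax")],
              list(tau_boom = log(s * N / L) / s, n_boom = r * N,
                   L = L, g = g, K = K, N = N, r = r, regime = regime,
                   c_g = c_g, c_G = c_G)),
            class = "theory_prediction")
}

#' @export
print.theory_prediction <- function(x, ...) {
  cat(sprintf(paste0("theory_prediction (regime %s): Theta = %.4g, theta = %.4g | ",
                     "rcg = %.3g, rcG = %.3g | Lmax = %.3g, Kmax = %.3g\n"),
              x$regime, x$Theta_pred, x$theta_pred, x$rcg, x$rcG,
              x$Lmax, x$Kmax))
  invisible(x)
}
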