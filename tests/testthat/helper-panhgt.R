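# Shared fixtures built in code.

# tiny matched-pair world used by several dynamics tests
quick_params <- function(...) {
  defaults <- list(L = 4, NB = 2000, s = 5e-3, r = 0, T = 100, seed = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

# minimal hand-built trajectory_record for definition-level observable tests
fake_traj <- function(times, B, V, params, first_gene_zero_B = NULL,
                      first_gene_zero_V = NULL, last_genotype_zero_B = NULL,
                      last_genotype_zero_V = NULL, cum_zero_touch = NULL) {
  K <- ncol(B); L <- params$L
  sp <- build_space(params$L, params$g)
  gB <- B %*% sp$membership
  gV <- V %*% sp$membership
  nil <- function(x, n) if (is.null(x)) rep(NA_real_, n) else x
  first_of <- function(m, times) apply(m, 2, function(col) {
    i <- which(col == 0)[1]
    if (is.na(i)) NA_real_ else times[i]
  })
  structure(list(
    times = times, B = B, V = V, gene_B = gB, gene_V = gV,
    cum_zero_touch = if (is.null(cum_zero_touch)) rep(0L, length(times))
                     else cum_zero_touch,
    first_gene_zero_B = nil(first_gene_zero_B, L),
    first_gene_zero_V = nil(first_gene_zero_V, L),
    first_genotype_zero_B = first_of(B, times),
    first_genotype_zero_V = first_of(V, times),
    last_genotype_zero_B = nil(last_genotype_zero_B, K),
    last_genotype_zero_V = nil(last_genotype_zero_V, K),
    zero_touch_total = if (is.null(cum_zero_touch)) 0
                       else max(cum_zero_touch),
    termination = "horizon", t_end = max(times),
    steps_done = length(times), params = params,
    space_dims = c(L = params$L, g = params$g, K = K)),
    class = "trajectory_record")
}
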