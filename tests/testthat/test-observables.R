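test_that("lyapunov energy has the closed form, minimum, and symmetry", {
  expect_equal(lyapunov(100, 100, 100), 200)
  expect_equal(lyapunov(50, 200, 100), 250)  # log terms cancel
  expect_equal(lyapunov(10, 100, 100), 10 - 100 * log(10 / 100) + 100)
  expect_equal(lyapunov(30, 70, 50), lyapunov(70, 30, 50))
  expect_error(lyapunov(0, 10, 10), "positive")
  # grid search: minimum at (n*, n*), increasing along rays
  nst <- 80
  grid <- expand.grid(B = seq(10, 300, by = 10), V = seq(10, 300, by = 10))
  E <- lyapunov(grid$B, grid$V, nst)
  expect_equal(unlist(grid[which.min(E), ]), c(B = 80, V = 80))
  ray <- lyapunov(nst * 2^(0:5), nst * 2^(0:5), nst)
  expect_true(all(diff(ray) > 0))
})

test_that("persistence_times reports per-side first losses with censoring", {
  p <- quick_params(T = 1000)
  K <- 6
  times <- seq(0, 1000, by = 100)
  Bm <- matrix(50L, length(times), K); Vm <- Bm
  tr <- fake_traj(times, Bm, Vm, p)
  tr$first_genotype_zero_B[2] <- 137
  pt <- persistence_times(tr)
  expect_true(is.na(pt$gene))
  expect_equal(pt$genotype, 137)
  # all-positive constant trajectory: fully censored
  pt2 <- persistence_times(fake_traj(times, Bm, Vm, p))
  expect_true(is.na(pt2$gene) && is.na(pt2$genotype))
  expect_equal(pt2$horizon, 1000)
  # single-carrier coupling: losing the only carrier of a gene loses both
  p3 <- suppressWarnings(sim_params(L = 3, NB = 60, NV = 60, r = 0, T = 1))
  B3 <- matrix(c(30L, 30L, 0L, 30L, 30L, 0L), 2, 3, byrow = TRUE)
  tr3 <- fake_traj(c(0, 50), B3, B3, p3,
                   first_gene_zero_B = c(NA, NA, 50))
  tr3$first_genotype_zero_B <- c(NA, NA, 50)
  tr3$first_genotype_zero_V <- c(NA, NA, 50)
  pt3 <- persistence_times(tr3)
  expect_equal(pt3$gene, pt3$genotype)
})

test_that("sample_abundances respects burn-in, spacing, and minimum snapshots", {
  p <- quick_params(T = 1000, s = 5e-3)
  times <- seq(0, 1000, by = 10)
  K <- 6
  Bm <- matrix(rep(100L, length(times) * K), ncol = K)
  tr <- fake_traj(times, Bm, Bm, p)
  sm <- sample_abundances(tr, burn_in_fraction = 0.1, spacing = 10)
  expect_true(all(sm$genotype == 100))
  expect_equal(length(sm$genotype), sm$n_snapshots * K)
  # burn-in removes everything before 0.1 T
  expect_equal(sm$n_snapshots, sum(times >= 100))
  expect_error(sample_abundances(tr, spacing = 2000), class = "insufficient_data")
})

test_that("fit_gamma recovers parameters and enforces its error contract", {
  set.seed(12)
  g <- fit_gamma(rgamma(1e4, shape = 2, scale = 50))
  expect_gt(g$theta, 45); expect_lt(g$theta, 55)
  expect_gt(g$shape, 1.8); expect_lt(g$shape, 2.2)
  e <- fit_gamma(rexp(1e4, rate = 1 / 100))
  expect_gt(e$shape, 0.9); expect_lt(e$shape, 1.1)
  expect_error(fit_gamma(rep(5, 200)), class = "degenerate_fit")
  expect_error(fit_gamma(rgamma(50, 2, 1)), class = "insufficient_data")
  # zeros are excluded and reported
  z <- fit_gamma(c(rgamma(900, shape = 2, scale = 50), rep(0, 100)))
  expect_equal(z$zero_fraction, 0.1)
  expect_equal(z$n_samples, 1000)
})

test_that("fit_gamma error shrinks roughly as 1/sqrt(n)", {
  set.seed(21)
  err <- sapply(c(1e2, 1e3, 1e4), function(n) {
    median(replicate(50, abs(fit_gamma(rgamma(n, 2, scale = 50))$theta - 50)))
  })
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], err[1] / 3)  # 10x n -> ~3x error, twice
})

test_that("classify_regime implements the three-regime definitions", {
  p <- quick_params(T = 1000)
  times <- seq(0, 1000, by = 100); K <- 6
  Bm <- matrix(50L, length(times), K)
  base <- fake_traj(times, Bm, Bm, p)
  # gene lost at any time -> I
  tr1 <- base; tr1$first_gene_zero_B[2] <- 500
  expect_equal(classify_regime(tr1)$label, "I")
  # genotype zero after burn-in, no gene lost -> II
  tr2 <- base
  tr2$last_genotype_zero_B[3] <- 900
  tr2$cum_zero_touch <- c(rep(0L, 5), rep(40L, 6))
  tr2$zero_touch_total <- 40
  c2 <- classify_regime(tr2)
  expect_equal(c2$label, "II")
  expect_equal(c2$genotype_zero_events, 40)
  # all strains positive after burn-in -> III (even if a zero fell in burn-in)
  tr3 <- base; tr3$last_genotype_zero_B[1] <- 50
  expect_equal(classify_regime(tr3)$label, "III")
})

test_that("boom_peaks finds contiguous excursions and recovers the tail rate", {
  nst <- 100; thr <- 5 * nst
  # synthetic booms: isolated spikes with Exp(2r) heights over threshold
  set.seed(31)
  r <- 1e-3
  heights <- thr + rexp(500, rate = 2 * r)
  mat <- matrix(0, 3 * 500, 1)
  mat[3 * seq_len(500) - 1, 1] <- heights
  ps <- boom_peaks(mat, threshold_multiple = 5, n_star = nst,
                   times = seq_len(nrow(mat)))
  expect_equal(nrow(ps$peaks), 500)
  expect_gt(ps$exp_rate, 1.6e-3); expect_lt(ps$exp_rate, 2.4e-3)
  # a double-crest excursion that never dips below threshold is one peak
  m2 <- matrix(c(0, 600, 550, 620, 0, rep(0, 55)), ncol = 1)
  m2 <- cbind(m2, c(rep(0, 30), 700, rep(0, 29)))
  ps2 <- boom_peaks(m2, 5, n_star = nst, times = seq_len(60), min_peaks = 2)
  expect_equal(nrow(ps2$peaks), 2)
  expect_equal(sort(ps2$peaks$height), c(620, 700))
  # never above threshold
  expect_error(boom_peaks(matrix(1, 50, 2), 5, n_star = nst,
                          times = 1:50), class = "insufficient_data")
})
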