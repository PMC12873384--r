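make_sans_fluor <- function(t_grid = seq(5, 100, by = 5)) {
  q <- default_q_grid(50)
  frames <- lapply(t_grid, function(t) scattering_curve(
    q, eval_gel_model(c(a = 1e-4, n = 2.5, c = 1 + t / 100, eta = 50,
                        m = 2.7, b = 0.03), q), time_min = t))
  sans <- curve_series(frames)
  ax <- seq(420, 540, by = 4)
  sp <- outer(exp(-(ax - 485)^2 / 500), 1 + t_grid / 50)
  fluor <- spectrum_series(ax, sp, t_grid)
  list(sans = sans, fluor = fluor)
}

test_that("the joint matrix has the right blocks, weights and variance balance", {
  d <- make_sans_fluor()
  jm <- build_joint_matrix(d$sans, d$fluor)
  expect_equal(dim(jm$D), c(20, 50 + 31))
  expect_equal(as.integer(table(jm$block)), c(50, 31))
  # max of each block equals its weighting
  expect_equal(max(jm$D[, jm$block == "sans"]),
               1)
  # equal total variance across blocks
  vs <- sum(apply(jm$D[, jm$block == "sans"], 2, var))
  vf <- sum(apply(jm$D[, jm$block == "fluor"], 2, var))
  expect_equal(vs / vf, 1, tolerance = 1e-6)
  # no temporal overlap is an error
  late <- spectrum_series(d$fluor$axis, d$fluor$spectra, d$fluor$time_min + 1000)
  expect_error(build_joint_matrix(d$sans, late), "overlap")
})

test_that("rank selection reads the singular spectrum", {
  set.seed(61)
  A <- matrix(runif(40), 20, 2); B <- matrix(runif(60), 30, 2)
  M <- A %*% t(B)
  expect_equal(select_rank(M, 0.999)$k, 2)
  expect_equal(select_rank(M, 0.5)$k, 1)
  # rank 3 + 1% noise at threshold 0.99
  A3 <- matrix(runif(60, 0.5, 1.5), 20); B3 <- matrix(runif(90, 0.5, 1.5), 30)
  M3 <- A3 %*% t(B3)
  M3 <- M3 + matrix(rnorm(length(M3), 0, 0.01 * mean(M3)), nrow(M3))
  expect_equal(select_rank(M3, 0.9999)$k, 3)
  expect_error(select_rank(matrix(0, 4, 4)), "variance")
})

test_that("an exact rank-1 matrix is recovered up to scale with ~zero lack of fit", {
  t <- seq_len(30)
  cc <- exp(-t / 10)
  ss <- c(runif(20, 0.1, 1))
  M <- cc %*% t(ss)
  res <- mcr_als_solve(M, k = 1)
  expect_lt(res$lack_of_fit, 1e-6)
  expect_gt(abs(cor(res$C[, 1], cc)), 1 - 1e-9)
  expect_gt(abs(cor(res$S[, 1], ss)), 1 - 1e-9)
  # unit-max signature with compensating scale in C: reconstruction intact
  expect_equal(max(res$S[, 1]), 1)
  expect_equal(res$C %*% t(res$S), M, tolerance = 1e-8)
})

test_that("three-component recovery with non-negativity and monotone lack of fit", {
  dm <- simulate_mcr_dataset(seed = 5, noise = 0.01)
  res <- mcr_als_solve(dm$jm, k = 3)
  expect_true(res$converged)
  # all factors non-negative
  expect_gte(min(res$C), 0)
  expect_gte(min(res$S), 0)
  # lack of fit non-increasing across iterations
  expect_true(all(diff(res$lof_trace) <= 1e-9))
  # profiles match truth up to permutation and scale
  perm <- vapply(1:3, function(i) which.max(abs(cor(dm$C_truth[, i], res$C))),
                 integer(1))
  expect_equal(sort(perm), 1:3)
  cors <- vapply(1:3, function(i) cor(dm$C_truth[, i], res$C[, perm[i]]),
                 numeric(1))
  expect_true(all(cors > 0.98))
  # lack of fit at the injected noise level (percent scale)
  expect_lt(res$lack_of_fit, 100 * dm$noise * 1.5)
  expect_gt(res$lack_of_fit, 100 * dm$noise * 0.3)
})

test_that("overparameterised and degenerate calls behave per contract", {
  M <- matrix(runif(40, 0.5, 1), 5, 8)
  expect_warning(res <- mcr_als_solve(M, k = 5), "overparameterised")
  expect_equal(dim(res$C), c(5, 5))
  expect_error(mcr_als_solve(matrix(0, 4, 4), k = 2), "variance")
})

test_that("restart envelopes bracket the best fit and collapse for exact data", {
  t <- seq_len(25)
  M <- cbind(exp(-t / 8)) %*% t(runif(30, 0.2, 1))
  blk <- factor(rep("sans", 30), levels = c("sans", "fluor"))
  jm <- structure(list(D = M, time_min = t, block = blk,
                       col_axis = seq_len(30),
                       block_weights = c(sans = 1, fluor = 1)),
                  class = "joint_matrix")
  env <- mcr_envelopes(jm, k = 1, n_restarts = 4, seed = 2)
  expect_gte(env$n_kept, 2)
  # exact rank-1: every restart converges to the same profile
  expect_lt(max(env$C_upper - env$C_lower), 1e-6 * max(env$C_upper))
  # envelopes contain the best profiles
  dm <- simulate_mcr_dataset(t_grid = seq(5, 200, by = 10),
                             q_grid = default_q_grid(40),
                             axis = seq(430, 540, 5), seed = 5, noise = 0.02)
  env3 <- mcr_envelopes(dm$jm, k = 3, n_restarts = 4, seed = 3)
  expect_true(all(env3$C_lower <= env3$best$C + 1e-9))
  expect_true(all(env3$best$C <= env3$C_upper + 1e-9))
})

test_that("correlation maps respect sign, resampling and degenerate signals", {
  t <- seq(0, 90, by = 10)
  C <- cbind(seq_along(t), rev(seq_along(t)))
  # the profile itself: r = 1; its negation: r = -1 (min-max keeps sign)
  sigs <- list(self = kinetic_trace(t, C[, 1], "tht"),
               neg = kinetic_trace(t, -C[, 1], "tht"),
               flat = kinetic_trace(t, rep(2, length(t)), "turbidity"))
  expect_warning(cm <- correlation_map(C, sigs, time_min = t), "constant")
  expect_equal(cm["C1", "self"], 1)
  expect_equal(cm["C1", "neg"], -1)
  expect_true(is.na(cm["C1", "flat"]))
  # hand Pearson oracle on a 3-point example
  cm2 <- correlation_map(cbind(c(1, 2, 3)),
                         list(s = c(2, 4, 7)), time_min = c(1, 2, 3))
  expect_equal(cm2[1, 1], 5 / sqrt(2 * 12.6667), tolerance = 1e-4)
  # signals on a finer grid are resampled onto the C grid
  fine <- kinetic_trace(seq(0, 90, by = 1), seq(0, 90, by = 1) * 2, "tht")
  cm3 <- correlation_map(C, list(ramp = fine), time_min = t)
  expect_equal(cm3["C1", "ramp"], 1)
  expect_error(correlation_map(cbind(1:2), list(x = 1:2), time_min = 1:2), "3 matched")
})
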