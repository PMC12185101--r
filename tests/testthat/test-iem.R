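test_that("basis channels peak at 1, vanish opposite, and have ~63.2 deg FWHM", {
  b <- make_basis(0)
  expect_equal(length(b$centers), 18L)
  expect_equal(diff(b$centers)[1], 20)
  for (ctr in c(0, 40, 180)) {
    expect_equal(b$fn(ctr, ctr), 1)
    expect_equal(b$fn(ctr + 180, ctr), 0, tolerance = 1e-12)
  }
  # FWHM by root-finding on the tuning curve (derived oracle)
  half <- uniroot(function(d) b$fn(d, 0) - 0.5, c(0, 180), tol = 1e-10)$root
  expect_equal(2 * half, 63.2, tolerance = 0.05)
  # periodicity and symmetry
  th <- seq(0, 359)
  expect_equal(b$fn(th, 100), b$fn(th + 360, 100))
  expect_equal(b$fn(100 + th, 100), b$fn(100 - th, 100))
  # shifted basis moves the centers
  expect_equal(make_basis(7)$centers, wrap360(b$centers + 7))
  C <- channel_design(b, c(5, 125, 355))
  expect_true(all(C >= 0 & C <= 1))
})

test_that("OLS training is exact on noiseless data and matches qr.solve", {
  fx <- make_forward_fixture(n_trials = 50)
  W_hat <- train_weights(fx$B, fx$C)
  expect_equal(W_hat, fx$W, tolerance = 1e-8)
  # orthogonality of residuals (here zero) and oracle equivalence with noise
  set.seed(7)
  Bn <- fx$B + matrix(rnorm(length(fx$B)), nrow(fx$B))
  W_n <- train_weights(Bn, fx$C)
  expect_equal(W_n, qr.solve(fx$C, Bn), tolerance = 1e-10)
  resid <- Bn - fx$C %*% W_n
  expect_lt(max(abs(crossprod(fx$C, resid))) / max(abs(Bn)), 1e-8)
  # degenerate designs are refused with useful messages
  expect_error(train_weights(fx$B[1:10, ], fx$C[1:10, ]), "fewer trials")
  C_bad <- fx$C; C_bad[, 2] <- C_bad[, 1]
  expect_error(train_weights(fx$B, C_bad), "rank-deficient")
})

test_that("model inversion round-trips and reduces to identity weights", {
  fx <- make_forward_fixture(n_trials = 80)
  W_hat <- train_weights(fx$B, fx$C)
  C2 <- estimate_channels(W_hat, fx$B)
  expect_equal(C2, fx$C, tolerance = 1e-8)
  # identity case: sensors == channels, W = I
  expect_equal(estimate_channels(diag(18), fx$C), fx$C, tolerance = 1e-10)
})

test_that("direction-space projection is linear and reproduces tuning curves", {
  b <- make_basis(0)
  ind <- rep(0, 18); ind[which(b$centers == 180)] <- 1
  expect_equal(to_direction_space(ind, b), b$fn(0:359, 180), tolerance = 1e-12)
  # all-ones channel vector gives a near-constant profile
  flat <- to_direction_space(rep(1, 18), b)
  expect_lt(diff(range(flat)) / mean(flat), 1e-6)
  # linearity
  set.seed(2)
  C1 <- matrix(runif(36), 2); C2 <- matrix(runif(36), 2)
  expect_equal(to_direction_space(2 * C1 + 3 * C2, b),
               2 * to_direction_space(C1, b) + 3 * to_direction_space(C2, b),
               tolerance = 1e-12)
})

test_that("alignment centers the labeled direction and inverts cleanly", {
  p <- to_direction_space(c(1, rep(0, 17)), make_basis(0))  # peak at 0 deg
  expect_equal(align_profile(p, 180), p[c(181:360, 1:180)][c(181:360, 1:180)])
  expect_equal(align_profile(p, 180), p[wrap360(180 + (0:359) - 180) + 1])
  al <- align_profile(p, 0)
  expect_equal(which.max(al) - 1L, 180L)
  # aligning by d then by (360 - d + 360/2)... simpler: label 180 is identity
  expect_equal(align_profile(p, 180), p[wrap360((0:359)) + 1])
  # matrix form agrees with the vector form row by row
  P <- rbind(p, rev(p))
  labs <- c(40, 300)
  A <- align_profile(P, labs)
  expect_equal(A[1, ], align_profile(p, 40))
  expect_equal(A[2, ], align_profile(rev(p), 300))
})

test_that("time binning yields the documented bin counts per epoch", {
  mk <- function(epoch, t0, t1) {
    times <- seq(t0, t1 - 1, by = 10)
    dat <- array(rnorm(4 * 3 * length(times)), c(4, 3, length(times)))
    sensor_epochs(dat, times, data.frame(session = rep(1:2, 2)), epoch,
                  binned = FALSE)
  }
  expect_equal(length(time_bin(mk("s1", -200, 1500))$times_ms), 13L)
  expect_equal(length(time_bin(mk("s2", -200, 1500))$times_ms), 13L)
  expect_equal(length(time_bin(mk("retrocue", -200, 1600))$times_ms), 15L)
  expect_equal(length(time_bin(mk("iti_trial", -1000, 4100))$times_ms), 51L)
  expect_equal(time_bin(mk("s1", -200, 1500))$times_ms, seq(50, 1250, 100))
  # window not covered by the samples
  expect_error(time_bin(mk("retrocue", -200, 1000)), "not covered")
  # binning actually averages: constant data stay constant
  ep <- mk("s1", 0, 1300)
  ep$data[] <- 3
  expect_equal(unique(as.vector(time_bin(ep)$data)), 3)
})

test_that("reconstruction is insensitive to the generating basis offset", {
  # generate with one offset, reconstruct averaging the usual 20: the
  # aligned peak must stay within 1 degree of the center
  cfg <- sim_config(n_subjects = 1, seed = 31, snr = Inf, sensor_count = 24)
  d <- generate_design(cfg, 1)
  ep <- generate_meg(d, cfg, "s1")
  rec5 <- reconstruct(ep, "s1", offsets = c(3, 11, 17))
  peaks <- apply(rec5$profile, 1, serialshift:::profile_peak)
  expect_true(all(abs(wrap_signed(peaks - 180)) <= 1))
  expect_true(is.finite(rec5$condition))
})

test_that("label shuffling destroys reconstruction fidelity", {
  cfg <- sim_config(n_subjects = 1, seed = 33, snr = 1, sensor_count = 24)
  d <- generate_design(cfg, 1)
  ep <- generate_meg(d, cfg, "s1")
  rec_true <- reconstruct(ep, "s1", offsets = c(0, 10))
  set.seed(1)
  ep$trials$s1_dir <- sample(ep$trials$s1_dir)
  rec <- reconstruct(ep, "s1", offsets = c(0, 10))
  # a single shuffle leaves O(1/sqrt(n_trials)) sampling fluctuation, so the
  # check is relative: shuffled fidelity collapses to < 10% of the intact one
  expect_lt(mean(rec$fidelity), 0.1 * mean(rec_true$fidelity))
  expect_gt(mean(rec_true$fidelity), 0.3)
})
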