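test_that("fidelity matches closed forms and the direct summation oracle", {
  expect_equal(fidelity(rep(1, 360)), 0)
  expect_equal(fidelity(rep(-3.7, 360)), 0, tolerance = 1e-12)
  cosprof <- cos((0:359 - 180) * pi / 180)
  expect_equal(fidelity(cosprof), 0.5)
  # a single channel tuning centered at 180: direct 1-degree summation
  b <- make_basis(0)
  prof <- b$fn(0:359, 180)
  acc <- 0
  for (th in 0:359) acc <- acc + prof[th + 1] * cos((th - 180) * pi / 180)
  expect_equal(fidelity(prof), acc / 360)
  expect_gt(fidelity(prof), 0)
  # matrix form
  expect_equal(fidelity(rbind(cosprof, rep(1, 360))), c(0.5, 0))
  # invariant under reflection about the center
  noisy <- prof + sin(7 * (0:359) * pi / 180) * 0.2
  expect_equal(fidelity(serialshift:::mirror_profile(noisy)), fidelity(noisy))
})

test_that("cluster test finds planted clusters with exact extent and floor p", {
  # strong constant positive signal in bins 3-6 only
  set.seed(4)
  X <- matrix(rnorm(10 * 13, 0, 0.1), 10, 13)
  X[, 3:6] <- X[, 3:6] + 2
  ct <- cluster_test(X)
  expect_equal(nrow(ct$clusters), 1L)
  expect_equal(c(ct$clusters$start, ct$clusters$end), c(3L, 6L))
  expect_equal(ct$sig_bins, 3:6)
  expect_equal(ct$n_perm, 1024L)           # exhaustive for n = 10
  expect_lt(ct$clusters$p, 0.002)          # the permutation floor
  expect_gte(ct$clusters$p, 1 / 1024)
  # all-zero data: no clusters at all
  expect_null(cluster_test(matrix(0, 10, 13))$clusters)
  expect_error(cluster_test(matrix(1, 1, 5)), ">= 2 subjects")
})

test_that("flip-and-average mirrors CCW trials and is an involution", {
  b <- make_basis(0)
  shifted <- function(delta) align_profile(b$fn(0:359, wrap360(100 + delta)), 100)
  # CW trials displaced +10, CCW trials displaced -10 about their label
  P <- rbind(shifted(10), shifted(-10), shifted(10), shifted(-10))
  labs <- c(100, 100, 100, 100)
  rel <- c(1, -1, 1, -1)
  avg <- flip_and_average(P, labs, rel)
  expect_equal(serialshift:::profile_peak(avg), 190)
  # flipping twice restores the profile
  m <- serialshift:::mirror_profile(P[2, ])
  expect_equal(serialshift:::mirror_profile(m), P[2, ])
  # symmetric displacements without flipping cancel instead
  expect_equal(serialshift:::profile_peak(colMeans(P)), 180)
  # relation class 0 rows are excluded; all-zero relation errors
  expect_error(flip_and_average(P, labs, rep(0, 4)), "no trials")
})

test_that("shift_from_max reads displacement with attraction positive", {
  b <- make_basis(0)
  centered <- b$fn(0:359, 180)
  expect_equal(shift_from_max(centered)$shift, 0)
  at170 <- b$fn(0:359, 170)
  expect_equal(shift_from_max(at170)$shift, -10)
  at190 <- b$fn(0:359, 190)
  expect_equal(shift_from_max(at190)$shift, 10)
  # reflection about the center flips the sign of the shift
  expect_equal(shift_from_max(serialshift:::mirror_profile(at190))$shift, -10)
  # averaging restricted to significant bins
  M <- rbind(at190, centered, at190)
  expect_equal(shift_from_max(M, sig_bins = c(1, 3))$shift, 10)
  # no significant bins: explicit null result, not an error
  ns <- shift_from_max(M, sig_bins = integer(0))
  expect_true(is.na(ns$shift))
})

test_that("bootstrap shift hits its floor on fully separated fixtures", {
  b <- make_basis(0)
  P <- matrix(rep(b$fn(0:359, 190), 6), 6, byrow = TRUE)
  bs <- bootstrap_shift(P, n_boot = 200, seed = 3)
  expect_equal(bs$shift, 10)
  expect_equal(bs$p, 1 / 200)              # the reporting floor
  expect_equal(unname(bs$ci), c(10, 10))   # degenerate interval
  expect_true(bs$significant)
  bs2 <- bootstrap_shift(P, n_boot = 200, seed = 3)
  expect_identical(bs$boot, bs2$boot)
  expect_output(print(bs), "attraction")
})

test_that("brain-behavior circular correlation recovers a planted coupling", {
  # hand-built recon object: deviations equal the response error in bins 2-3,
  # pure noise in bin 1
  set.seed(9)
  n <- 80
  trials <- data.frame(session = rep(1:2, each = n / 2),
                       target_pos = "S1",
                       target_dir = 100,
                       response_dir = wrap360(100 + rnorm(n, 0, 20)))
  err <- wrap_signed(trials$response_dir - trials$target_dir)
  dev <- cbind(runif(n, -180, 180), err, err + rnorm(n, 0, 2))
  rec <- structure(list(deviations = dev, trial_rows = seq_len(n),
                        label_source = "cued"), class = "iem_recon")
  r <- circ_corr_behavior(rec, trials)
  expect_lt(abs(r[1]), 0.4)
  expect_equal(r[2], 1)
  expect_gt(r[3], 0.9)
  # identical behavior restricted to cued trials for S1 labels
  rec$label_source <- "s1"
  trials$target_pos <- rep(c("S1", "S2"), n / 2)
  r2 <- circ_corr_behavior(rec, trials)
  expect_equal(r2[2], 1)
})

test_that("multiple-comparison corrections match hand-stepped values", {
  # BH step-up on {0.01, 0.02, 0.03}: 0.03*3/3, 0.02*3/2, 0.01*3/1 -> all 0.03
  expect_equal(correct_multiple(c(0.01, 0.02, 0.03), "bh_fdr"),
               c(0.03, 0.03, 0.03))
  expect_equal(correct_multiple(0.2, "bh_fdr"), 0.2)   # single p unchanged
  expect_equal(correct_multiple(0.005, "bonferroni", n = 3), 0.015)
  expect_equal(correct_multiple(c(0.5, 0.9), "bonferroni", n = 3), c(1, 1))
  # BH against a second, independent hand computation
  p <- c(0.04, 0.001, 0.03, 0.8)
  o <- order(p)
  stepup <- p[o] * length(p) / seq_along(p)
  stepup <- rev(cummin(rev(stepup)))
  expected <- numeric(4); expected[o] <- pmin(1, stepup)
  expect_equal(correct_multiple(p, "bh_fdr"), expected)
})
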