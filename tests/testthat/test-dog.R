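test_that("DoG curve has the analytic peak and antisymmetry", {
  expect_equal(dog(0, 3.51, 0.024), 0)
  x <- seq(-180, 180, by = 0.37)
  expect_equal(dog(-x, 2.2, 0.05), -dog(x, 2.2, 0.05), tolerance = 1e-12)
  # peak at x = 1/(w sqrt(2)) with height exactly a
  for (w in c(0.01, 0.024, 0.046, 0.1)) {
    a <- 3.51
    xp <- 1 / (w * sqrt(2))
    expect_equal(dog(xp, a, w), a, tolerance = 1e-9 * a)
    # dense-grid oracle for the argmax
    grid <- seq(0, 180, by = 0.01)
    expect_equal(grid[which.max(dog(grid, a, w))], xp, tolerance = 0.011)
    expect_lte(max(dog(grid, a, w)), a * (1 + 1e-9))
  }
})

test_that("FWHM scales inversely with w and matches half-maximum crossings", {
  w <- 0.03
  expect_equal(dog_fwhm(2 * w), dog_fwhm(w) / 2, tolerance = 1e-10)
  # independent check: crossings located on a dense grid
  grid <- seq(0.01, 120, by = 0.001)
  y <- dog(grid, 1, w)
  above <- grid[y >= 0.5]
  expect_equal(dog_fwhm(w), max(above) - min(above), tolerance = 0.01)
})

test_that("preprocessing excludes outliers, long RTs and first-of-block trials", {
  # 40 well-behaved trials plus one planted outlier well past 3 SDs
  set.seed(3)
  base <- rnorm(40, 0, 5)
  tab <- make_trial_table(c(base, 60))
  cl <- preprocess_behavior(tab)
  expect_s3_class(cl, "cleaned_errors")
  expect_equal(nrow(cl), 40)             # exactly the planted row removed
  expect_equal(unname(attr(cl, "exclusions")["outlier_or_rt"]), 1)

  # all responses too slow: every non-first trial excluded
  tab2 <- make_trial_table(rnorm(10), rts = rep(30, 10))
  expect_error(preprocess_behavior(tab2), "no trials survive")

  # constant error demeans to exactly zero
  tab3 <- make_trial_table(rep(7, 12))
  expect_equal(preprocess_behavior(tab3)$error, rep(0, 12))
})

test_that("fit recovers generating parameters from noise-free curves", {
  x <- rep(seq(-170, 180, 10), times = 3)
  for (truth in list(c(3.51, 0.024), c(-1.02, 0.046), c(5, 0.08))) {
    y <- dog(x, truth[1], truth[2])
    f <- fit_dog(data.frame(x = x, y = y, subject = rep(1:3, each = 36)))
    expect_equal(unname(coef(f)), truth, tolerance = 1e-4)
    expect_equal(f$r.squared, 1, tolerance = 1e-8)
    expect_equal(unname(residuals(f)), rep(0, length(x)), tolerance = 1e-8)
    expect_equal(predict(f, newdata = c(0, 30)), dog(c(0, 30), truth[1], truth[2]),
                 tolerance = 1e-3)
  }
  expect_error(fit_dog(data.frame(x = c(0, 10), y = c(0, 1))), "3 distinct")
})

test_that("fit is invariant to subject order and pre-demeaning offsets", {
  cfg <- tiny_config()
  sim <- simulate_experiment(cfg)
  cl <- preprocess_behavior(sim$trials)
  f1 <- fit_dog(cl)
  shuf <- cl[rev(seq_len(nrow(cl))), ]
  class(shuf) <- class(cl)
  expect_equal(coef(fit_dog(shuf)), coef(f1))
  # a constant added to every response before preprocessing is demeaned
  # away (low-noise cohort, so the offset cannot move trials across the
  # absolute-error exclusion boundary)
  cfg2 <- tiny_config(response_noise_sd = 0.1)
  sim2 <- simulate_experiment(cfg2)
  f2 <- fit_dog(preprocess_behavior(sim2$trials))
  tr2 <- sim2$trials
  tr2$response_dir <- wrap360(tr2$response_dir + 9)
  expect_equal(coef(fit_dog(preprocess_behavior(tr2))), coef(f2),
               tolerance = 1e-6)
})

test_that("bootstrap needs >= 2 resamples and collapses on zero noise", {
  x <- rep(seq(-170, 180, 10), 2)
  y <- dog(x, 3, 0.03)
  f <- fit_dog(data.frame(x = x, y = y, subject = rep(1:2, each = 36)))
  expect_error(bootstrap_dog(f, n_boot = 1), "n_boot")
  fb <- bootstrap_dog(f, n_boot = 50, seed = 5)
  expect_lt(fb$boot$sd_a, 1e-4)
  # reproducible under a fixed seed
  fb2 <- bootstrap_dog(f, n_boot = 50, seed = 5)
  expect_identical(fb$boot$a, fb2$boot$a)
})

test_that("sign flips negate the amplitude and strong bias hits the p floor", {
  # enough subjects that the participant sign-flip null can resolve p < 0.01
  cfg <- tiny_config(n_subjects = 8)
  sim <- simulate_experiment(cfg)
  cl <- preprocess_behavior(sim$trials)
  f <- fit_dog(cl)
  # flipping the whole dataset negates a (antisymmetry of the curve)
  neg <- cl; neg$error <- -neg$error
  class(neg) <- class(cl)
  expect_equal(unname(coef(fit_dog(neg))["a"]), -unname(coef(f)["a"]),
               tolerance = 1e-6)
  fp <- permutation_test_dog(f, n_perm = 500, seed = 11)
  expect_lte(fp$perm$p, 0.01)
  expect_gte(fp$perm$p, 1 / 500)
  fp2 <- permutation_test_dog(f, n_perm = 500, seed = 11)
  expect_identical(fp$perm$a, fp2$perm$a)
})

test_that("congruence analysis is symmetric in its level labels", {
  cfg <- tiny_config(congruence_delta = 2)
  sim <- simulate_experiment(cfg)
  cl <- preprocess_behavior(sim$trials)
  res <- congruence_analysis(cl, n_perm = 50, seed = 2)
  swapped <- cl; swapped$congruent <- !swapped$congruent
  class(swapped) <- class(cl)
  res2 <- congruence_analysis(swapped, n_perm = 50, seed = 2)
  expect_equal(res2$difference, -res$difference, tolerance = 1e-10)
  expect_gt(res$difference, 0)   # generated congruent trials are more biased
})

test_that("dog_fit behaves like a standard model object", {
  x <- rep(seq(-170, 180, 10), 2)
  set.seed(8)
  y <- dog(x, 3, 0.03) + rnorm(length(x), 0, 2)
  f <- fit_dog(data.frame(x = x, y = y, subject = rep(1:2, each = 36)))
  expect_output(print(f), "amplitude")
  expect_output(print(summary(f)), "sigma")
  expect_equal(length(fitted(f)), length(x))
  expect_s3_class(logLik(f), "logLik")
  s <- simulate(f, nsim = 2, seed = 4)
  expect_equal(dim(s), c(length(x), 2L))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})
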