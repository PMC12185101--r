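# Derivative-of-Gaussian (DoG) model of serial dependence.
#
# The response error on the current trial is modeled as a function of the
# signed circular distance x between the previous target direction and the
# current target direction:
#
#   y(x) = x * a * w * c * exp(-(w x)^2),   c = sqrt(2) * exp(0.5)
#
# The constant c makes `a` the height of the curve peak, which sits at
# x = 1/(w*sqrt(2)). `w` (1/degrees) scales the curve width.

.dog_const <- sqrt(2) * exp(0.5)

#' First derivative of a Gaussian (DoG) bias curve
#'
#' @param x signed distance(s) in degrees.
#' @param a peak amplitude in degrees.
#' @param w width scale (1/degrees).
#' @return predicted response bias in degrees; antisymmetric in `x`.
#' @export
#' @examples
#' dog(0, 3.51, 0.024)                  # 0
#' dog(1 / (0.024 * sqrt(2)), 3.51, 0.024)  # the peak: 3.51
dog <- function(x, a, w) {
  x * a * w * .dog_const * exp(-(w * x)^2)
}

#' Full width at half maximum of the DoG positive lobe
#'
#' Found by numeric root-finding on the two half-maximum crossings of
#' u * exp(-u^2) (u = w*x) and scaling by 1/w; the crossing locations in
#' u-space are a universal constant, so FWHM is exactly inversely
#' proportional to `w`.
#'
#' @param w width scale(s), must be > 0.
#' @return FWHM in degrees.
#' @export
#' @examples
#' dog_fwhm(0.024)  # ~47.2 degrees
dog_fwhm <- function(w) {
  stopifnot(all(w > 0))
  half <- function(u) u * exp(-u^2) - 0.5 * exp(-0.5) / sqrt(2)
  u1 <- stats::uniroot(half, c(1e-12, 1 / sqrt(2)), tol = 1e-12)$root
  u2 <- stats::uniroot(half, c(1 / sqrt(2), 20), tol = 1e-12)$root
  (u2 - u1) / w
}

#' Preprocess behavioral trial tables for serial-dependence analysis
#'
#' Drops the first trial of each block (no previous-trial target exists),
#' excludes trials whose absolute response error exceeds the subject's mean
#' absolute error by more than `sd_limit` standard deviations or whose
#' response time exceeds `rt_limit` seconds, and demeans the remaining
#' errors per subject to remove idiosyncratic constant biases.
#'
#' @param trials data frame in the trial-table schema produced by
#'   [generate_design()] / [generate_behavior()] (or read via
#'   [read_trials()]), with filled `response_dir` and `response_time`.
#' @param sd_limit outlier criterion in standard deviations (default 3).
#' @param rt_limit response-time exclusion bound in seconds (default 20).
#' @return a `cleaned_errors` data frame with columns `subject`, `session`,
#'   `signed_dist` (to the previous target), `signed_dist_nontarget`,
#'   `error` (demeaned, degrees) and `congruent` (current target color equals
#'   previous cue color). Exclusion counts are stored in attribute
#'   `"exclusions"`.
#' @export
preprocess_behavior <- function(trials, sd_limit = 3, rt_limit = 20) {
  stopifnot(is.data.frame(trials))
  need <- c("subject", "block", "trial_in_block", "target_dir",
            "response_dir", "response_time", "prev_target_dir",
            "signed_dist_target", "signed_dist_nontarget")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("missing trial columns: ", paste(miss, collapse = ", "))

  d <- trials[!is.na(trials$prev_target_dir), , drop = FALSE]
  d$error_raw <- wrap_signed(d$response_dir - d$target_dir)
  d$congruent <- if (all(c("cue_color", "prev_cue_color") %in% names(d))) {
    d$cue_color == d$prev_cue_color
  } else NA

  out <- do.call(rbind, lapply(split(d, d$subject), function(s) {
    ab <- abs(s$error_raw)
    keep <- ab <= mean(ab) + sd_limit * stats::sd(ab) &
      s$response_time <= rt_limit
    s <- s[keep, , drop = FALSE]
    if (nrow(s) == 0L) {
      stop("subject ", s$subject[1], ": no trials survive exclusion")
    }
    s$error <- s$error_raw - mean(s$error_raw)
    s
  }))
  n_first <- sum(is.na(trials$prev_target_dir))
  res <- out[, c("subject", if ("session" %in% names(out)) "session",
                 "signed_dist_target", "signed_dist_nontarget",
                 "error", "congruent")]
  names(res)[names(res) == "signed_dist_target"] <- "signed_dist"
  rownames(res) <- NULL
  attr(res, "exclusions") <- c(first_of_block = n_first,
                               outlier_or_rt = nrow(d) - nrow(res))
  class(res) <- c("cleaned_errors", "data.frame")
  res
}

# Aggregate cleaned trial-level errors to one data point per subject and
# signed distance (the fitting unit).
pool_subject_means <- function(cleaned, distance = c("target", "nontarget")) {
  distance <- match.arg(distance)
  x <- if (distance == "target") cleaned$signed_dist else cleaned$signed_dist_nontarget
  ag <- stats::aggregate(cleaned$error,
                         by = list(subject = cleaned$subject, x = x),
                         FUN = mean)
  names(ag)[3] <- "y"
  ag[order(ag$subject, ag$x), ]
}

# Core profile fit: amplitude has a closed form given w (the model is linear
# in a), so the optimization is a bounded 1-D search over w: coarse grid plus
# local refinement with optimize(). Returns point estimates and RSS.
dog_fit_core <- function(x, y, w_bounds = c(0.01, 0.1), n_grid = 181L,
                         refine = TRUE) {
  wgrid <- seq(w_bounds[1], w_bounds[2], length.out = n_grid)
  FF <- outer(x, wgrid, function(x, w) x * w * .dog_const * exp(-(w * x)^2))
  den <- colSums(FF^2)
  num <- colSums(FF * y)
  score <- ifelse(den > 0, num^2 / den, 0)   # RSS = sum(y^2) - score
  i <- which.max(score)
  w_hat <- wgrid[i]
  if (refine) {
    step <- wgrid[2] - wgrid[1]
    lo <- max(w_bounds[1], w_hat - step)
    hi <- min(w_bounds[2], w_hat + step)
    rss_w <- function(w) {
      f <- x * w * .dog_const * exp(-(w * x)^2)
      d <- sum(f^2)
      if (d <= 0) return(sum(y^2))
      sum(y^2) - sum(f * y)^2 / d
    }
    w_hat <- stats::optimize(rss_w, c(lo, hi), tol = 1e-9)$minimum
  }
  f <- x * w_hat * .dog_const * exp(-(w_hat * x)^2)
  d <- sum(f^2)
  a_hat <- if (d > 0) sum(f * y) / d else 0
  list(a = a_hat, w = w_hat, rss = sum((y - a_hat * f)^2), fitted = a_hat * f)
}

# Vectorized amplitude fits for many response vectors sharing the same x
# (used by the permutation test): Y is n x m.
dog_fit_amps <- function(x, Y, w_bounds = c(0.01, 0.1), n_grid = 181L) {
  wgrid <- seq(w_bounds[1], w_bounds[2], length.out = n_grid)
  FF <- outer(x, wgrid, function(x, w) x * w * .dog_const * exp(-(w * x)^2))
  den <- colSums(FF^2)
  NUM <- crossprod(FF, Y)                        # n_grid x m
  score <- NUM^2 / ifelse(den > 0, den, Inf)
  best <- max.col(t(score), ties.method = "first")
  NUM[cbind(best, seq_len(ncol(Y)))] / den[best]
}

#' Fit the DoG serial-dependence model
#'
#' Fits the bias curve to pooled per-subject mean response errors (one data
#' point per subject and signed distance) by maximum likelihood under a
#' Gaussian residual model with the noise variance profiled out, which makes
#' the point estimates coincide with least squares. The width `w` is
#' constrained to \[0.01, 0.1\]; the amplitude `a` is unbounded and has a
#' closed form given `w`, so fitting reduces to a bounded one-dimensional
#' search (grid plus local refinement).
#'
#' @param data a `cleaned_errors` object from [preprocess_behavior()], or a
#'   data frame with numeric columns `x` (signed distance, degrees), `y`
#'   (response error, degrees) and optionally `subject`.
#' @param distance which signed distance to model when `data` is a
#'   `cleaned_errors` object: to the previous `"target"` (default) or to the
#'   previous `"nontarget"`.
#' @param w_bounds lower/upper bound for the width scale.
#' @return an object of class `dog_fit` with components `coefficients`
#'   (`a`, `w`), `fwhm`, `r.squared`, `logLik`, `sigma`, `fitted.values`,
#'   `residuals`, `data` (the fitting points), `n`.
#' @seealso [bootstrap_dog()], [permutation_test_dog()], [congruence_analysis()]
#' @export
fit_dog <- function(data, distance = c("target", "nontarget"),
                    w_bounds = c(0.01, 0.1)) {
  if (inherits(data, "cleaned_errors")) {
    pts <- pool_subject_means(data, match.arg(distance))
  } else {
    stopifnot(all(c("x", "y") %in% names(data)))
    pts <- data.frame(subject = if ("subject" %in% names(data)) data$subject else 1L,
                      x = data$x, y = data$y)
  }
  if (length(unique(pts$x)) < 3L) {
    stop("fit_dog needs at least 3 distinct signed distances")
  }
  core <- dog_fit_core(pts$x, pts$y, w_bounds)
  n <- nrow(pts)
  sigma2 <- core$rss / n
  tss <- sum((pts$y - mean(pts$y))^2)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  structure(list(
    coefficients = c(a = core$a, w = core$w),
    fwhm = dog_fwhm(core$w),
    r.squared = if (tss > 0) 1 - core$rss / tss else NA_real_,
    logLik = ll,
    sigma = sqrt(sigma2),
    fitted.values = core$fitted,
    residuals = pts$y - core$fitted,
    data = pts,
    n = n,
    w_bounds = w_bounds,
    call = match.call()
  ), class = "dog_fit")
}

#' @export
print.dog_fit <- function(x, digits = 3, ...) {
  cat("Serial-dependence DoG fit\n")
  cat(sprintf("  amplitude a = %.*f deg, width w = %.*f (FWHM %.*f deg)\n",
              digits, x$coefficients["a"], digits + 1, x$coefficients["w"],
              digits, x$fwhm))
  cat(sprintf("  n = %d subject-by-distance points, R^2 = %.*f\n",
              x$n, digits, x$r.squared))
  invisible(x)
}

#' @export
summary.dog_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.dog_fit")
}

#' @export
print.summary.dog_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  sigma = %.3f deg, logLik = %.2f (profiled Gaussian)\n",
              f$sigma, f$logLik))
  if (!is.null(f$boot)) {
    cat(sprintf("  bootstrap SD(a) = %.3f deg (%d resamples)\n",
                f$boot$sd_a, length(f$boot$a)))
  }
  if (!is.null(f$perm)) {
    cat(sprintf("  one-sided permutation p = %.4g (%d permutations)\n",
                f$perm$p, length(f$perm$a)))
  }
  invisible(x)
}

#' @export
coef.dog_fit <- function(object, ...) object$coefficients

#' @export
#' @importFrom stats predict
predict.dog_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) {
    object$data$x
  } else if (is.data.frame(newdata)) {
    newdata[[intersect(c("x", "signed_dist"), names(newdata))[1]]]
  } else {
    newdata
  }
  dog(x, object$coefficients["a"], object$coefficients["w"])
}

#' @export
residuals.dog_fit <- function(object, ...) object$residuals

#' @export
fitted.dog_fit <- function(object, ...) object$fitted.values

#' @export
logLik.dog_fit <- function(object, ...) {
  structure(object$logLik, df = 3, nobs = object$n, class = "logLik")
}

#' @export
simulate.dog_fit <- function(object, nsim = 1, seed = NULL, ...) {
  run <- function() {
    as.data.frame(replicate(nsim, object$fitted.values +
                              stats::rnorm(object$n, 0, object$sigma)))
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.dog_fit <- function(x, ...) {
  pts <- x$data
  xx <- seq(-180, 180, by = 1)
  plot(pts$x, pts$y, pch = 16, cex = 0.5, col = "grey60",
       xlab = "signed distance to previous target (deg)",
       ylab = "response error (deg)", ...)
  mm <- stats::aggregate(y ~ x, data = pts, FUN = mean)
  points(mm$x, mm$y, pch = 16, col = "grey20")
  lines(xx, dog(xx, x$coefficients["a"], x$coefficients["w"]),
        col = "firebrick", lwd = 2)
  abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

#' Bootstrap the DoG fit
#'
#' Resamples the fitting data points (subject-by-distance rows) with
#' replacement and refits the curve, giving the sampling variability of the
#' amplitude.
#'
#' @param fit a [fit_dog()] result (or a `cleaned_errors` object, which is
#'   fitted first).
#' @param n_boot number of bootstrap resamples (default 1000; must be >= 2).
#' @param seed optional RNG seed for reproducibility.
#' @return the `dog_fit` with a `boot` component: vectors `a`, `w`, scalar
#'   `sd_a`, and percentile intervals `ci_a` (2.5/97.5%).
#' @export
bootstrap_dog <- function(fit, n_boot = 1000, seed = NULL) {
  if (inherits(fit, "cleaned_errors")) fit <- fit_dog(fit)
  stopifnot(inherits(fit, "dog_fit"))
  if (n_boot < 2) stop("n_boot must be >= 2 (SD undefined otherwise)")
  pts <- fit$data
  run <- function() {
    res <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(pts), replace = TRUE)
      core <- dog_fit_core(pts$x[idx], pts$y[idx], fit$w_bounds, refine = FALSE)
      c(core$a, core$w)
    }, numeric(2))
    list(a = res[1, ], w = res[2, ])
  }
  b <- if (is.null(seed)) run() else with_seed(seed, run())
  fit$boot <- list(a = b$a, w = b$w, sd_a = stats::sd(b$a),
                   ci_a = stats::quantile(b$a, c(0.025, 0.975), names = FALSE))
  fit
}

#' Participant-level sign-flip permutation test of the DoG amplitude
#'
#' Under the null of no serial dependence the bias curve is antisymmetric
#' noise, so each participant's mean response errors can have their signs
#' flipped. Each permutation draws one random sign per participant, applies
#' it to all of that participant's data points, refits the pooled model and
#' records the amplitude. The p-value is the fraction of permuted amplitudes
#' greater than or equal to the observed one (one-sided, attraction), floored
#' at 1/`n_perm`.
#'
#' @param fit a [fit_dog()] result or `cleaned_errors` object; needs >= 2
#'   subjects.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional RNG seed.
#' @return the `dog_fit` with a `perm` component: `a` (permutation
#'   distribution), `p`, and `quantiles` (2.5, 5, 95, 97.5%).
#' @export
permutation_test_dog <- function(fit, n_perm = 1000, seed = NULL) {
  if (inherits(fit, "cleaned_errors")) fit <- fit_dog(fit)
  stopifnot(inherits(fit, "dog_fit"))
  pts <- fit$data
  subj <- factor(pts$subject)
  if (nlevels(subj) < 2L) stop("permutation test needs >= 2 subjects")
  run <- function() {
    S <- matrix(sample(c(-1, 1), nlevels(subj) * n_perm, replace = TRUE),
                nrow = nlevels(subj))
    Y <- pts$y * S[as.integer(subj), , drop = FALSE]
    dog_fit_amps(pts$x, Y, fit$w_bounds)
  }
  a_perm <- if (is.null(seed)) run() else with_seed(seed, run())
  p <- max(mean(a_perm >= fit$coefficients["a"]), 1 / n_perm)
  fit$perm <- list(a = a_perm, p = p,
                   quantiles = stats::quantile(a_perm,
                                               c(0.025, 0.05, 0.95, 0.975)))
  fit
}

#' Color-congruence modulation of serial dependence
#'
#' Fits the DoG model separately for trials whose current target had the
#' same color as the previously cued item ("congruent") versus a different
#' color, and tests the amplitude difference by permuting the congruence
#' labels within each subject (both levels refitted per permutation).
#'
#' @param cleaned a `cleaned_errors` object with congruence labels.
#' @param n_perm number of label permutations (default 1000).
#' @param seed optional RNG seed.
#' @return list with `fit_same`, `fit_diff` (`dog_fit` objects),
#'   `difference` (a_same - a_diff), `perm_diff` (null distribution) and `p`
#'   (two-sided).
#' @export
congruence_analysis <- function(cleaned, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(cleaned, "cleaned_errors"))
  if (anyNA(cleaned$congruent)) stop("congruence labels missing")
  lv <- split(seq_len(nrow(cleaned)), cleaned$congruent)
  fits <- lapply(lv, function(i) fit_dog(cleaned[i, , drop = FALSE]))
  for (f in fits) {
    if (length(unique(f$data$x)) < 3L) stop("a congruence level has < 3 distances")
  }
  obs <- unname(coef(fits[["TRUE"]])["a"] - coef(fits[["FALSE"]])["a"])

  amp_for <- function(keep) {
    g <- interaction(cleaned$subject[keep], cleaned$signed_dist[keep], drop = TRUE)
    n_g <- as.vector(rowsum(rep(1, sum(keep)), g))
    ym <- as.vector(rowsum(cleaned$error[keep], g)) / n_g
    xm <- as.vector(rowsum(cleaned$signed_dist[keep], g)) / n_g
    dog_fit_core(xm, ym, refine = FALSE)$a
  }

  run <- function() {
    subj_rows <- split(seq_len(nrow(cleaned)), cleaned$subject)
    vapply(seq_len(n_perm), function(i) {
      perm_lab <- logical(nrow(cleaned))
      for (rows in subj_rows) perm_lab[rows] <- sample(cleaned$congruent[rows])
      amp_for(perm_lab) - amp_for(!perm_lab)
    }, numeric(1))
  }
  pd <- if (is.null(seed)) run() else with_seed(seed, run())
  p <- max(mean(abs(pd) >= abs(obs)), 1 / n_perm)
  list(fit_same = fits[["TRUE"]], fit_diff = fits[["FALSE"]],
       difference = obs, perm_diff = pd, p = p)
}
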