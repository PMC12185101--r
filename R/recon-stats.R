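# Statistics on aligned direction reconstructions: fidelity, cluster-based
# sign-flip permutation tests over time, flip-and-average shift estimation,
# participant bootstrap, circular brain-behavior correlation, and multiple
# comparison correction.

#' Reconstruction fidelity
#'
#' Projects an aligned direction profile onto its common center:
#' `F = mean_theta r(theta) * cos(theta - 180)`. A flat profile has fidelity
#' 0; a profile concentrated at the center has positive fidelity.
#'
#' @param profile aligned profile: length-360 vector (directions 0..359) or
#'   a matrix with 360 columns (one profile per row).
#' @return scalar fidelity, or one value per row.
#' @export
#' @examples
#' fidelity(rep(1, 360))                      # 0
#' fidelity(cos((0:359 - 180) * pi / 180))    # 0.5
fidelity <- function(profile) {
  ck <- cos((0:359 - 180) * pi / 180)
  if (is.null(dim(profile))) {
    stopifnot(length(profile) == 360L)
    mean(profile * ck)
  } else {
    stopifnot(ncol(profile) == 360L)
    as.vector(profile %*% ck) / 360
  }
}

# peak location (degrees 0..359) of a profile; exact ties are resolved by
# the circular mean of the tied maxima
profile_peak <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, 1L)
  pk <- max.col(p, ties.method = "first") - 1L
  mx <- p[cbind(seq_len(nrow(p)), pk + 1L)]
  nt <- rowSums(p == mx)
  for (i in which(nt > 1L)) pk[i] <- circ_mean_deg(which(p[i, ] == mx[i]) - 1L)
  if (length(pk) == 1L) pk[[1L]] else pk
}

# contiguous runs of above-threshold bins with their summed statistic
find_clusters <- function(t_vals, thresh) {
  above <- !is.na(t_vals) & t_vals > thresh
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep],
             stat = vapply(keep, function(k) {
               sum(t_vals[starts[k]:ends[k]])
             }, numeric(1)))
}

#' One-sided cluster-based sign-flip permutation test over time
#'
#' Tests a subjects x bins matrix of values against zero. Per-bin one-sample
#' t statistics above the one-sided alpha threshold form contiguous candidate
#' clusters whose statistic is the sum of t values. The null distribution of
#' the maximum cluster statistic is built by flipping the sign of whole
#' subjects: exhaustively (all 2^n flips) for n <= 12 subjects, otherwise by
#' `max_perm` random flips. With 10 subjects the permutation floor is
#' 1/1024 < 0.002.
#'
#' @param values numeric matrix, subjects x bins (>= 2 subjects).
#' @param alpha cluster-forming threshold level (one-sided; default 0.05).
#' @param max_perm number of random sign flips when exhaustive enumeration
#'   is infeasible.
#' @param seed optional RNG seed (only used in the random regime).
#' @return list with `t` (per-bin t values), `threshold`, `clusters` (data
#'   frame: `start`, `end`, `stat`, `p`), `sig_bins` (bins in clusters with
#'   p < 0.05), `n_perm`.
#' @export
cluster_test <- function(values, alpha = 0.05, max_perm = 4096, seed = NULL) {
  X <- as.matrix(values)
  n <- nrow(X)
  if (n < 2L) stop("cluster_test needs >= 2 subjects")
  thr <- stats::qt(1 - alpha, df = n - 1)
  tv <- function(m) {
    v <- (ss - n * m^2) / (n - 1)
    t <- m / sqrt(v / n)
    t[!is.finite(t)] <- 0
    t
  }
  ss <- colSums(X^2)
  t_obs <- tv(colMeans(X))
  cl <- find_clusters(t_obs, thr)

  S <- if (n <= 12L) {
    # exhaustive sign flips (includes the identity)
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    signs
  } else {
    draw <- function() matrix(sample(c(1, -1), n * max_perm, replace = TRUE),
                              max_perm, n, byrow = TRUE)
    if (is.null(seed)) draw() else with_seed(seed, draw())
  }
  M <- (S %*% X) / n
  null_max <- vapply(seq_len(nrow(S)), function(i) {
    ci <- find_clusters(tv(M[i, ]), thr)
    if (is.null(ci)) 0 else max(ci$stat)
  }, numeric(1))

  if (!is.null(cl)) {
    # tolerance keeps the identity flip counted despite floating-point noise
    cl$p <- vapply(cl$stat, function(s) mean(null_max >= s - 1e-8), numeric(1))
    sig <- unlist(lapply(which(cl$p < 0.05), function(k) cl$start[k]:cl$end[k]))
  } else {
    sig <- integer(0)
  }
  list(t = t_obs, threshold = thr, clusters = cl,
       sig_bins = sort(unique(sig)), n_perm = nrow(S))
}

#' Flip-and-average aligned reconstructions
#'
#' Mirrors the profiles of counter-clockwise trials (previous target
#' counter-clockwise of the labeled direction, `relation < 0`) about the
#' 180-degree center so that an attractive displacement points the same way
#' for all trials, then averages within each labeled direction (count- or
#' weight-adjusted) and across directions.
#'
#' @param profiles aligned profiles, rows x 360.
#' @param labels labeled direction per row (degrees).
#' @param relation +1 for clockwise, -1 for counter-clockwise; rows with 0
#'   or NA (no previous target, or exactly 180 degrees away) are excluded.
#' @param weights optional trial counts per row (when rows are group means).
#' @return mean profile, length 360.
#' @export
flip_and_average <- function(profiles, labels, relation, weights = NULL) {
  P <- as.matrix(profiles)
  stopifnot(ncol(P) == 360L, nrow(P) == length(labels),
            length(relation) == length(labels))
  if (is.null(weights)) weights <- rep(1, nrow(P))
  keep <- !is.na(relation) & relation != 0
  if (!any(keep)) stop("no trials with a defined CW/CCW relation")
  P <- P[keep, , drop = FALSE]
  lab <- labels[keep]; rel <- relation[keep]; wt <- weights[keep]
  ccw <- rel < 0
  if (any(ccw)) P[ccw, ] <- mirror_profile(P[ccw, , drop = FALSE])
  per_dir <- rowsum(P * wt, lab) / as.vector(rowsum(wt, lab))
  colMeans(per_dir)
}

#' Shift of the mean reconstruction maximum from the common center
#'
#' Averages flip-and-average profiles over the time bins with significant
#' reconstruction fidelity and measures the signed displacement of the
#' resulting maximum from 180 degrees. Under this package's conventions a
#' positive shift means attraction toward the previous trial's target. With
#' no significant bins the shift is an explicit null result (`NA`), not an
#' error.
#'
#' @param profiles bins x 360 matrix of flip-and-average profiles (or a
#'   single length-360 profile).
#' @param sig_bins indices of significant bins (e.g. from [cluster_test()]
#'   on the fidelity timecourse).
#' @return list with `shift` (degrees, positive = attraction; `NA` if no
#'   significant bins), `peak` (degrees) and `profile` (the bin-averaged
#'   profile).
#' @export
shift_from_max <- function(profiles, sig_bins = NULL) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, 1L)
  if (is.null(sig_bins)) sig_bins <- seq_len(nrow(profiles))
  if (length(sig_bins) == 0L) {
    return(list(shift = NA_real_, peak = NA_real_, profile = NULL))
  }
  avg <- colMeans(profiles[sig_bins, , drop = FALSE])
  pk <- profile_peak(avg)
  list(shift = wrap_signed(pk - 180), peak = pk, profile = avg)
}

#' Participant-resampling bootstrap for the reconstruction shift
#'
#' Resamples participants with replacement, averages their profiles and
#' records the shift of the maximum, on `n_boot` iterations. The shift is
#' significant (one-sided, attraction) when at least 95% of iterations give
#' a shift >= 0; the reported p is the fraction of iterations with a
#' negative shift, floored at 1/`n_boot`. The central 95% of the bootstrap
#' distribution is reported as the interval.
#'
#' @param profiles subjects x 360 matrix: per-subject flip-and-average
#'   profiles already averaged over the significant time bins.
#' @param n_boot number of bootstrap iterations (default 10000).
#' @param seed optional RNG seed.
#' @return object of class `shift_estimate`: `shift` (group estimate),
#'   `boot` (bootstrap shifts), `p`, `ci` (central 95%), `significant`,
#'   `n_boot`.
#' @export
bootstrap_shift <- function(profiles, n_boot = 10000, seed = NULL) {
  P <- as.matrix(profiles)
  stopifnot(ncol(P) == 360L)
  n <- nrow(P)
  if (n < 2L) stop("bootstrap_shift needs >= 2 subjects")
  obs <- wrap_signed(profile_peak(colMeans(P)) - 180)
  run <- function() {
    vapply(seq_len(n_boot), function(i) {
      m <- colMeans(P[sample.int(n, n, replace = TRUE), , drop = FALSE])
      wrap_signed(profile_peak(m) - 180)
    }, numeric(1))
  }
  bs <- if (is.null(seed)) run() else with_seed(seed, run())
  p <- max(mean(bs < 0), 1 / n_boot)
  structure(list(shift = obs, boot = bs, p = p,
                 ci = stats::quantile(bs, c(0.025, 0.975), names = FALSE),
                 significant = mean(bs >= 0) >= 0.95,
                 n_boot = n_boot),
            class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("shift = %.*f deg (positive = attraction), p = %.4g%s\n",
              digits, x$shift, x$p,
              if (x$significant) " *" else ""))
  cat(sprintf("  central 95%% of %d bootstrap shifts: [%.*f, %.*f]\n",
              x$n_boot, digits, x$ci[1], digits, x$ci[2]))
  invisible(x)
}

#' Circular correlation between reconstruction deviations and behavior
#'
#' For one subject, correlates the per-trial deviation of the reconstructed
#' maximum from the presented direction (before any CW/CCW flipping) with
#' the behavioral response error, per session and time bin, then averages
#' the two sessions. Trials whose absolute response error exceeds the
#' subject's mean by more than `sd_limit` SDs are removed; for S1/S2 epochs
#' only trials where that item was the retro-cued target are used.
#'
#' @param recon an [reconstruct()] result with `per_trial = TRUE`.
#' @param trials the subject's trial table (the same one the epochs were
#'   built from).
#' @param sd_limit behavioral outlier criterion (default 3 SDs).
#' @param cued_only restrict to trials where the labeled item was cued
#'   (automatic for `label_source` `"s1"`/`"s2"`).
#' @return numeric vector of circular correlations, one per time bin (NA
#'   where fewer than 3 trials remain in a session).
#' @export
circ_corr_behavior <- function(recon, trials, sd_limit = 3, cued_only = NULL) {
  stopifnot(inherits(recon, "iem_recon"))
  if (is.null(recon$deviations)) {
    stop("reconstruct() must be run with per_trial = TRUE")
  }
  d <- trials[recon$trial_rows, , drop = FALSE]
  dev <- recon$deviations
  err <- wrap_signed(d$response_dir - d$target_dir)
  ab <- abs(err)
  keep <- ab <= mean(ab) + sd_limit * stats::sd(ab)
  if (is.null(cued_only)) cued_only <- recon$label_source %in% c("s1", "s2")
  if (cued_only) {
    want <- switch(recon$label_source, s1 = "S1", s2 = "S2", NA)
    if (!is.na(want)) keep <- keep & d$target_pos == want
  }
  nb <- ncol(dev)
  sess <- sort(unique(d$session))
  r_sess <- vapply(sess, function(s) {
    rows <- which(keep & d$session == s)
    vapply(seq_len(nb), function(b) {
      if (length(rows) < 3L) return(NA_real_)
      circ_corr(dev[rows, b], err[rows])
    }, numeric(1))
  }, numeric(nb))
  rowMeans(r_sess, na.rm = TRUE)
}

#' Multiple-comparison correction
#'
#' Benjamini-Hochberg step-up FDR for families of per-epoch tests, or a
#' Bonferroni multiplication by the number of epochs compared.
#'
#' @param p vector of p-values.
#' @param method `"bh_fdr"` or `"bonferroni"`.
#' @param n number of comparisons for Bonferroni (defaults to `length(p)`).
#' @return adjusted p-values.
#' @export
#' @examples
#' correct_multiple(c(0.01, 0.02, 0.03), "bh_fdr")
#' correct_multiple(0.005, "bonferroni", n = 3)  # 0.015
correct_multiple <- function(p, method = c("bh_fdr", "bonferroni"), n = NULL) {
  method <- match.arg(method)
  if (method == "bh_fdr") {
    stats::p.adjust(p, method = "BH")
  } else {
    pmin(1, p * (if (is.null(n)) length(p) else n))
  }
}
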