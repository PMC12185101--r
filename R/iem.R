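# Inverted encoding model (IEM) for direction reconstruction.
#
# Forward model: the signal of each sensor is a weighted sum of 18
# direction-tuned channel responses, B1 = C1 W (trials x sensors =
# [trials x channels][channels x sensors]). W is estimated by OLS on a
# training session, the model is inverted on the held-out session to
# estimate channel responses, and those are projected back to direction
# space at 1-degree resolution. Reconstruction is repeated for 20 basis-
# center offsets (0..19 degrees) so the effective channel centers tile the
# circle in 1-degree steps, and for both train/test session assignments.

#' Construct a direction-tuned channel basis set
#'
#' 18 channels with centers spaced 20 degrees apart (plus a global offset),
#' each a half-angle cosine raised to the 18th power:
#' `channel(theta) = cos((theta - center)/2)^18`. The even exponent makes
#' the response 360-degree periodic with a single peak of 1 at the center
#' and a zero at the opposite direction.
#'
#' @param offset center offset in degrees (0-19 across the shifted-basis
#'   iterations).
#' @return object of class `iem_basis`: `centers` (18), `matrix` (360 x 18,
#'   rows are directions 0..359), and `fn(theta, center)`.
#' @export
make_basis <- function(offset = 0) {
  stopifnot(length(offset) == 1L, is.finite(offset))
  centers <- wrap360(offset + seq(0, 340, by = 20))
  fn <- function(theta, center) cos((theta - center) * pi / 360)^18
  M <- outer(0:359, centers, fn)
  structure(list(offset = offset, centers = centers, matrix = M, fn = fn),
            class = "iem_basis")
}

#' Predicted channel responses for labeled directions
#'
#' @param basis an [make_basis()] basis set.
#' @param directions direction labels in degrees.
#' @return matrix, trials x 18 channels, entries in \[0, 1\].
#' @export
channel_design <- function(basis, directions) {
  stopifnot(inherits(basis, "iem_basis"))
  outer(directions, basis$centers, basis$fn)
}

# solve(A, B) with a silent pseudo-inverse fallback for (near-)singular A,
# e.g. zero-signal time bins in noiseless synthetic data
safe_solve <- function(A, B) {
  k <- suppressWarnings(kappa(A, exact = FALSE))
  if (!is.finite(k) || k > 1e8) return(pinv(A) %*% B)
  solve(A, B)
}

# svd pseudo-inverse used as a guarded fallback for ill-conditioned solves
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Train IEM channel weights by ordinary least squares
#'
#' The OLS solution `W = (C1' C1)^{-1} C1' B1`, computed by QR decomposition
#' of the design rather than the normal equations: the 18th-power cosine
#' basis makes `C1' C1` intrinsically ill-conditioned (its highest circular
#' harmonics carry tiny coefficients), and QR avoids squaring that condition
#' number. A design whose own condition number exceeds 1e8 falls back to an
#' SVD pseudo-inverse with a warning; a rank-deficient design is an error
#' naming the dependent channels.
#'
#' @param B1 training sensor data, trials x sensors.
#' @param C1 channel design matrix from [channel_design()], trials x channels.
#' @return weight matrix, channels x sensors.
#' @export
train_weights <- function(B1, C1) {
  B1 <- as.matrix(B1); C1 <- as.matrix(C1)
  stopifnot(nrow(B1) == nrow(C1))
  if (nrow(C1) < ncol(C1)) stop("fewer trials than channels")
  q <- qr(C1)
  if (q$rank < ncol(C1)) {
    dep <- q$pivot[(q$rank + 1L):ncol(C1)]
    stop("rank-deficient channel design; dependent channel(s): ",
         paste(dep, collapse = ", "))
  }
  if (kappa(C1, exact = FALSE) > 1e8) {
    warning("ill-conditioned channel design (condition > 1e8); using pseudo-inverse")
    return(pinv(C1) %*% B1)
  }
  W <- qr.coef(q, B1)
  dimnames(W) <- NULL
  W
}

#' Estimate channel responses from test data by model inversion
#'
#' Least-squares inversion of the forward model on independent test data:
#' each test trial's channel response estimate solves `b = W' c`, i.e.
#' `Chat2 = B2 W' (W W')^{-1}`.
#'
#' @param W trained weight matrix, channels x sensors.
#' @param B2 test sensor data, trials x sensors.
#' @return estimated channel responses, trials x channels.
#' @export
estimate_channels <- function(W, B2) {
  W <- as.matrix(W); B2 <- as.matrix(B2)
  stopifnot(ncol(B2) == ncol(W))
  M <- tcrossprod(W)
  if (kappa(M, exact = FALSE) > 1e8) {
    warning("nearly singular weight matrix; using pseudo-inverse")
    return(B2 %*% t(pinv(M) %*% W))
  }
  B2 %*% t(solve(M, W))
}

#' Project channel estimates into direction space
#'
#' `r(theta) = sum_i Chat2_i * channel_i(theta)` evaluated at integer
#' directions 0..359.
#'
#' @param chan_est estimated channel responses (vector of 18, or trials x 18).
#' @param basis the basis set used for estimation.
#' @return direction profile(s): vector of length 360 or trials x 360 matrix,
#'   column j holding direction j-1.
#' @export
to_direction_space <- function(chan_est, basis) {
  stopifnot(inherits(basis, "iem_basis"))
  if (is.null(dim(chan_est))) {
    drop(basis$matrix %*% chan_est)
  } else {
    as.matrix(chan_est) %*% t(basis$matrix)
  }
}

#' Align direction profiles to a common center
#'
#' Circularly shifts a profile so that index 180 corresponds to the labeled
#' direction: `aligned(theta') = r(label + theta' - 180)`.
#'
#' @param profile length-360 vector (directions 0..359), or trials x 360
#'   matrix with one label per row.
#' @param label_dir labeled direction(s) in degrees.
#' @return aligned profile(s), same shape as the input.
#' @export
align_profile <- function(profile, label_dir) {
  if (is.null(dim(profile))) {
    stopifnot(length(profile) == 360L, length(label_dir) == 1L)
    src <- wrap360(round(label_dir) + (0:359) - 180) + 1L
    profile[src]
  } else {
    P <- as.matrix(profile)
    stopifnot(ncol(P) == 360L, length(label_dir) == nrow(P))
    src <- outer(round(label_dir), (0:359) - 180, "+") %% 360 + 1L
    matrix(P[cbind(rep(seq_len(nrow(P)), 360L), as.vector(src))],
           nrow(P), 360L)
  }
}

# mirror a profile (or matrix of profiles) about the 180-degree center
mirror_profile <- function(p) {
  idx <- (360L - (0:359)) %% 360L + 1L
  if (is.null(dim(p))) p[idx] else p[, idx, drop = FALSE]
}

#' Average sensor epochs into 100-ms analysis bins
#'
#' Non-overlapping means over the epoch's analysis window only (S1/S2:
#' 0-1300 ms post-onset, 13 bins; retro-cue: 0-1500 ms, 15 bins; ITI+trial:
#' -1000-4100 ms, 51 bins), with bin centers at 50, 150, ... ms.
#'
#' @param epochs a [sensor_epochs()] object with sample-level data.
#' @param width bin width in ms (default 100).
#' @return a binned [sensor_epochs()] object.
#' @export
time_bin <- function(epochs, width = 100) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  if (isTRUE(epochs$binned)) return(epochs)
  w <- epoch_window(epochs$epoch_type)
  edges <- seq(w[1], w[2], by = width)
  centers <- edges[-length(edges)] + width / 2
  out <- array(0, dim = c(dim(epochs$data)[1:2], length(centers)))
  for (b in seq_along(centers)) {
    sel <- epochs$times_ms >= edges[b] & epochs$times_ms < edges[b + 1]
    if (!any(sel)) {
      stop("analysis window not covered by data: empty bin at ",
           centers[b], " ms")
    }
    out[, , b] <- if (sum(sel) == 1L) epochs$data[, , sel] else
      apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  }
  sensor_epochs(out, centers, epochs$trials, epochs$epoch_type,
                binned = TRUE, seed = epochs$seed)
}

recon_labels <- function(trials, label_source) {
  switch(label_source,
         s1 = trials$s1_dir,
         s2 = trials$s2_dir,
         cued = trials$target_dir,
         prev = trials$prev_target_dir,
         noncued = trials$nontarget_dir,
         stop("unknown label_source: ", label_source))
}

#' Cross-session IEM reconstruction for one subject
#'
#' Runs the full reconstruction: for each of the 20 basis-center offsets and
#' each train/test assignment of the two sessions, trains channel weights on
#' the training session's labeled directions, inverts the model on the test
#' session, projects to direction space, aligns each reconstruction to the
#' common center (180 degrees), averages trials first within each labeled
#' direction and then across directions (equalizing unequal presentation
#' counts), and finally averages folds and offsets.
#'
#' Two group profiles are produced per time bin: the plain aligned mean, and
#' the clockwise/counter-clockwise flip-and-average profile in which trials
#' whose previous target was counter-clockwise of the labeled direction are
#' mirrored about 180 degrees before averaging, so that an attractive shift
#' displaces the maximum consistently to one side (above 180 under this
#' package's axis convention; see [shift_from_max()]). Trials at exactly 180
#' degrees distance, which have no clockwise/counter-clockwise relation, are
#' excluded from the flipped average.
#'
#' @param epochs a binned [sensor_epochs()] object holding both sessions of
#'   one subject.
#' @param label_source which direction labels the model is trained and
#'   aligned on: `"s1"`, `"s2"`, `"cued"` (the retro-cued target), `"prev"`
#'   (the previous trial's target) or `"noncued"`.
#' @param offsets basis-center offsets to average over (default 0:19).
#' @param per_trial if `TRUE`, also return per-trial aligned peak deviations
#'   (for brain-behavior correlations; slower).
#' @return an object of class `iem_recon`: `bins` (ms), `profile`
#'   (bins x 360 aligned mean), `flipped` (bins x 360 flip-and-average, or
#'   NULL when the label has no previous-target relation), `fidelity`
#'   (per-bin, from `profile`), `n_trials`, `condition` (design condition
#'   number), and optionally `deviations` (trials x bins, degrees) with
#'   `trial_rows`.
#' @export
reconstruct <- function(epochs,
                        label_source = c("s1", "s2", "cued", "prev", "noncued"),
                        offsets = 0:19, per_trial = FALSE) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  label_source <- match.arg(label_source)
  if (!isTRUE(epochs$binned)) epochs <- time_bin(epochs)
  trials <- epochs$trials
  sessions <- sort(unique(trials$session))
  if (length(sessions) != 2L) stop("reconstruct needs exactly two sessions")
  labels_all <- recon_labels(trials, label_source)
  keep <- which(!is.na(labels_all))
  labels <- labels_all[keep]
  prev <- trials$prev_target_dir[keep]
  sd_prev <- wrap_signed(prev - labels)
  rel <- ifelse(is.na(sd_prev) | sd_prev == 180, 0L, sign(sd_prev))
  sess <- trials$session[keep]
  ns <- dim(epochs$data)[2]
  nb <- dim(epochs$data)[3]
  n360 <- 360L
  bases <- lapply(offsets, make_basis)

  for (s in sessions) {
    miss <- setdiff(unique(labels), unique(labels[sess == s]))
    if (length(miss)) {
      warning("session ", s, " is missing labeled direction(s): ",
              paste(miss, collapse = ", "), "; averaging over available ones")
    }
  }

  fold_profile <- matrix(0, nb, n360)
  fold_flipped <- matrix(0, nb, n360)
  n_flip_groups <- 0L
  cond_num <- NA_real_
  dev <- if (per_trial) matrix(NA_real_, length(keep), nb) else NULL

  for (fold in 1:2) {
    tr_s <- sessions[fold]; te_s <- sessions[3 - fold]
    tr_i <- which(sess == tr_s); te_i <- which(sess == te_s)
    B1 <- matrix(epochs$data[keep[tr_i], , , drop = FALSE],
                 length(tr_i), ns * nb)
    B2 <- matrix(epochs$data[keep[te_i], , , drop = FALSE],
                 length(te_i), ns * nb)
    g <- interaction(labels[te_i], rel[te_i], drop = TRUE)
    cnt <- as.vector(rowsum(rep(1, length(te_i)), g))
    B2g <- rowsum(B2, g) / cnt
    lab_g <- as.vector(rowsum(labels[te_i], g)) / cnt
    rel_g <- as.vector(rowsum(as.numeric(rel[te_i]), g)) / cnt
    ngr <- nrow(B2g)

    prof_g <- array(0, dim = c(ngr, n360, nb))
    prof_t <- if (per_trial) array(0, dim = c(length(te_i), n360, nb)) else NULL

    for (o in seq_along(bases)) {
      basis <- bases[[o]]
      C1 <- channel_design(basis, labels[tr_i])
      if (is.na(cond_num)) cond_num <- kappa(C1, exact = FALSE)
      W_all <- qr.coef(qr(C1), B1)            # 18 x (ns*nb), multi-RHS OLS
      tM <- t(basis$matrix)                   # 18 x 360
      for (b in seq_len(nb)) {
        cols <- ((b - 1L) * ns + 1L):(b * ns)
        W <- W_all[, cols, drop = FALSE]
        Ginv_W <- safe_solve(tcrossprod(W), W)  # 18 x ns
        C2g <- B2g[, cols, drop = FALSE] %*% t(Ginv_W)
        prof_g[, , b] <- prof_g[, , b] + C2g %*% tM
        if (per_trial) {
          C2t <- B2[, cols, drop = FALSE] %*% t(Ginv_W)
          prof_t[, , b] <- prof_t[, , b] + C2t %*% tM
        }
      }
    }
    prof_g <- prof_g / length(bases)

    # align groups to the common center, then combine: within each labeled
    # direction a count-weighted mean over relation subgroups, then an
    # unweighted mean across directions
    ulab <- unique(lab_g)
    for (b in seq_len(nb)) {
      al <- align_profile(prof_g[, , b, drop = TRUE], lab_g)
      if (ngr == 1L) al <- matrix(al, 1L)
      per_dir <- rowsum(al * cnt, lab_g) / as.vector(rowsum(cnt, lab_g))
      fold_profile[b, ] <- fold_profile[b, ] + colMeans(per_dir)
      fl <- rel_g != 0
      if (any(fl)) {
        alf <- al[fl, , drop = FALSE]
        ccw <- rel_g[fl] < 0
        if (any(ccw)) alf[ccw, ] <- mirror_profile(alf[ccw, , drop = FALSE])
        per_dir_f <- rowsum(alf * cnt[fl], lab_g[fl]) /
          as.vector(rowsum(cnt[fl], lab_g[fl]))
        fold_flipped[b, ] <- fold_flipped[b, ] + colMeans(per_dir_f)
        if (b == 1L) n_flip_groups <- n_flip_groups + sum(fl)
      }
    }

    if (per_trial) {
      prof_t <- prof_t / length(bases)
      for (b in seq_len(nb)) {
        alt <- align_profile(prof_t[, , b, drop = TRUE], labels[te_i])
        peaks <- profile_peak(alt)
        dev[te_i, b] <- wrap_signed(peaks - 180)
      }
    }
  }

  profile <- fold_profile / 2
  flipped <- if (n_flip_groups > 0L) fold_flipped / 2 else NULL
  structure(list(
    bins = epochs$times_ms,
    profile = profile,
    flipped = flipped,
    fidelity = apply(profile, 1, fidelity),
    deviations = dev,
    trial_rows = keep,
    n_trials = length(keep),
    label_source = label_source,
    offsets = offsets,
    epoch_type = epochs$epoch_type,
    condition = cond_num
  ), class = "iem_recon")
}

#' @export
print.iem_recon <- function(x, ...) {
  cat(sprintf("iem_recon [%s, label %s]: %d trials, %d bins, %d offsets\n",
              x$epoch_type, x$label_source, x$n_trials, length(x$bins),
              length(x$offsets)))
  cat(sprintf("  fidelity range %.3f .. %.3f; design condition number %.1f\n",
              min(x$fidelity), max(x$fidelity), x$condition))
  invisible(x)
}
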