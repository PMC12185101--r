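# Synthetic two-item retro-cue experiment generator.
#
# Emulates the balanced delayed-estimation design: per subject, 2 sessions x
# 7 blocks x 73 trials; motion directions drawn from 5:10:355 (no cardinals);
# the 36 signed distances (-170:10:180) between each current item and the
# previous trial's target occur equally often; the two items of a trial never
# share a color or a distance to the previous target; color and temporal
# congruence between consecutive targets are balanced. Behavioral responses
# carry an injected DoG-shaped attraction plus wrapped-normal noise; sensor
# epochs carry direction-tuned signal through a fixed random channel-to-sensor
# mixing, optionally with attractive rotations or previous-target
# reactivations in chosen components.

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic experiment. Defaults reproduce
#' the study conditions: 10 subjects, 2 sessions of 7 blocks x 73 trials
#' (1022 trials/subject), generating DoG amplitude 3.51 degrees and width
#' 0.024 (the fitted behavioral bias toward the previous target),
#' wrapped-normal response noise with SD 15 degrees, and 30 synthetic
#' sensors. The default signal-to-noise ratio (0.035) is calibrated so the
#' plateau reconstruction fidelity of the simulated group lies around 0.12,
#' the magnitude observed in MEG delayed-estimation data.
#'
#' @param n_subjects number of subjects.
#' @param n_sessions,blocks_per_session,trials_per_block design sizes.
#' @param a_gen generating DoG amplitude (degrees).
#' @param w_gen generating DoG width scale, in \[0.01, 0.1\].
#' @param congruence_delta extra amplitude (degrees) when the current target
#'   has the same color as the previously cued item.
#' @param response_noise_sd wrapped-normal response noise SD (degrees).
#' @param sensor_count number of synthetic sensors.
#' @param snr dimensionless signal-to-noise: sensor noise SD is 1/snr
#'   (`Inf` for noiseless data).
#' @param injected_shift named numeric vector of attractive rotations
#'   (degrees) applied to the direction-tuned signal, names from
#'   `"s1"`, `"s2"`, `"retrocue"`, `"s1_in_s2"`. Each named component's
#'   represented direction is rotated toward the previous target.
#' @param s1_in_s2_gain relative gain of the maintained S1 representation
#'   during the S2 epoch.
#' @param reactivation_gain gain of an additive previous-target-tuned
#'   component in `reactivation_windows` (ITI + trial epoch only).
#' @param reactivation_windows list of `c(start, end)` ms windows relative
#'   to S1 onset.
#' @param seed integer; fully determines all generated data.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10,
                       n_sessions = 2,
                       blocks_per_session = 7,
                       trials_per_block = 73,
                       a_gen = 3.51,
                       w_gen = 0.024,
                       congruence_delta = 0,
                       response_noise_sd = 15,
                       sensor_count = 30,
                       snr = 0.035,
                       injected_shift = c(),
                       s1_in_s2_gain = 0.5,
                       reactivation_gain = 0,
                       reactivation_windows = list(c(-200, 100), c(2700, 2900)),
                       seed = 1) {
  stopifnot(w_gen >= 0.01, w_gen <= 0.1, snr > 0,
            n_subjects >= 1, sensor_count >= 19)
  if (length(injected_shift)) {
    bad <- setdiff(names(injected_shift),
                   c("s1", "s2", "retrocue", "s1_in_s2"))
    if (length(bad)) stop("unknown injected_shift component(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d subjects, %d x %d x %d trials, seed %d\n",
              x$n_subjects, x$n_sessions, x$blocks_per_session,
              x$trials_per_block, x$seed))
  cat(sprintf("  behavior: a = %g deg (+%g congruent), w = %g, noise SD %g\n",
              x$a_gen, x$congruence_delta, x$w_gen, x$response_noise_sd))
  cat(sprintf("  sensors: %d, snr = %g", x$sensor_count, x$snr))
  if (length(x$injected_shift)) {
    cat(", injected shifts: ",
        paste(sprintf("%s=%g", names(x$injected_shift), x$injected_shift),
              collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

direction_pool <- function() seq(5, 355, by = 10)
distance_pool <- function() seq(-170, 180, by = 10)

#' Generate a balanced trial design for one subject
#'
#' Builds the full trial sequence with balanced signed distances of both
#' current items to the previous trial's target, balanced color/temporal
#' congruence between consecutive targets, distinct colors within a trial,
#' and no cardinal directions. The first trial of each block has no previous
#' target. Balancing is constructive (shuffled balanced attribute pools
#' chained through the blocks) with a bounded repair pass for the
#' target/non-target distance collision constraint.
#'
#' @param cfg a [sim_config()].
#' @param subject subject index (determines the per-subject RNG stream).
#' @return data frame of trials (`n_sessions * blocks_per_session *
#'   trials_per_block` rows) in the trial-table schema.
#' @export
generate_design <- function(cfg, subject = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, 1L, subject), {
    pool <- direction_pool()
    dists <- distance_pool()
    n_blocks <- cfg$n_sessions * cfg$blocks_per_session
    tpb <- cfg$trials_per_block
    n_non <- n_blocks * (tpb - 1L)

    balanced_pool <- function() {
      base <- rep(dists, n_non %/% length(dists))
      extra <- sample(dists, n_non %% length(dists))
      sample(c(base, extra))
    }
    d_t <- balanced_pool()
    d_n <- balanced_pool()
    # repair collisions d_t == d_n by swapping d_n entries
    tries <- 0L
    repeat {
      bad <- which(d_t == d_n)
      if (!length(bad)) break
      for (i in bad) {
        j <- sample.int(n_non, 1L)
        if (d_n[j] != d_t[i] && d_n[i] != d_t[j]) {
          tmp <- d_n[i]; d_n[i] <- d_n[j]; d_n[j] <- tmp
        }
        tries <- tries + 1L
        if (tries > 10000L) {
          stop("design balancing failed after 10000 repair steps (seed ",
               cfg$seed, ", subject ", subject, ")")
        }
      }
    }
    cells <- sample(rep_len(1:4, n_non))
    col_congr <- cells %in% c(1L, 2L)
    tmp_congr <- cells %in% c(1L, 3L)

    n <- n_blocks * tpb
    S <- list(session = integer(n), block = integer(n),
              trial_in_block = integer(n),
              s1_dir = numeric(n), s2_dir = numeric(n),
              s1_color = character(n), s2_color = character(n),
              cue_color = character(n), target_pos = character(n),
              target_dir = numeric(n), nontarget_dir = numeric(n),
              prev_target_dir = rep(NA_real_, n),
              prev_cue_color = rep(NA_character_, n),
              signed_dist_target = rep(NA_real_, n),
              signed_dist_nontarget = rep(NA_real_, n))
    other_col <- function(x) ifelse(x == "red", "green", "red")
    other_pos <- function(x) ifelse(x == "S1", "S2", "S1")

    k <- 0L   # index into the non-first-trial attribute pools
    row <- 0L
    for (bl in seq_len(n_blocks)) {
      for (tr in seq_len(tpb)) {
        row <- row + 1L
        S$session[row] <- (bl - 1L) %/% cfg$blocks_per_session + 1L
        S$block[row] <- (bl - 1L) %% cfg$blocks_per_session + 1L
        S$trial_in_block[row] <- tr
        if (tr == 1L) {
          t_dir <- sample(pool, 1L)
          nt_dir <- sample(setdiff(pool, t_dir), 1L)
          t_pos <- sample(c("S1", "S2"), 1L)
          t_col <- sample(c("red", "green"), 1L)
        } else {
          k <- k + 1L
          prev_t <- S$target_dir[row - 1L]
          t_dir <- wrap360(prev_t - d_t[k])
          nt_dir <- wrap360(prev_t - d_n[k])
          t_pos <- if (tmp_congr[k]) S$target_pos[row - 1L] else
            other_pos(S$target_pos[row - 1L])
          t_col <- if (col_congr[k]) S$cue_color[row - 1L] else
            other_col(S$cue_color[row - 1L])
          S$prev_target_dir[row] <- prev_t
          S$prev_cue_color[row] <- S$cue_color[row - 1L]
          S$signed_dist_target[row] <- d_t[k]
          S$signed_dist_nontarget[row] <- d_n[k]
        }
        S$target_dir[row] <- t_dir
        S$nontarget_dir[row] <- nt_dir
        S$target_pos[row] <- t_pos
        S$cue_color[row] <- t_col
        if (t_pos == "S1") {
          S$s1_dir[row] <- t_dir; S$s2_dir[row] <- nt_dir
          S$s1_color[row] <- t_col; S$s2_color[row] <- other_col(t_col)
        } else {
          S$s2_dir[row] <- t_dir; S$s1_dir[row] <- nt_dir
          S$s2_color[row] <- t_col; S$s1_color[row] <- other_col(t_col)
        }
      }
    }
    out <- as.data.frame(S, stringsAsFactors = FALSE)
    out <- cbind(subject = subject, out,
                 response_dir = NA_real_, response_time = NA_real_)
    out
  })
}

#' Fill in behavioral responses for a generated design
#'
#' The response error is an injected DoG-shaped attraction toward the
#' previous target plus wrapped-normal noise:
#' `error = dog(signed_dist_target; a_eff, w_gen) + noise`, where
#' `a_eff = a_gen + congruence_delta` when the current target has the same
#' color as the previously cued item. First trials of a block receive pure
#' noise.
#'
#' @param design trial table from [generate_design()] (one or more subjects).
#' @param cfg the [sim_config()] used to generate it.
#' @return the design with `response_dir` and `response_time` filled.
#' @export
generate_behavior <- function(design, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  parts <- lapply(split(design, design$subject), function(d) {
    with_seed(derive_seed(cfg$seed, 2L, d$subject[1]), {
      n <- nrow(d)
      congr <- !is.na(d$prev_cue_color) & d$cue_color == d$prev_cue_color
      a_eff <- cfg$a_gen + cfg$congruence_delta * congr
      bias <- ifelse(is.na(d$signed_dist_target), 0,
                     dog(ifelse(is.na(d$signed_dist_target), 0,
                                d$signed_dist_target), a_eff, cfg$w_gen))
      noise <- wrap_signed(stats::rnorm(n, 0, cfg$response_noise_sd))
      d$response_dir <- wrap360(d$target_dir + bias + noise)
      d$response_time <- stats::rlnorm(n, log(2), 0.35)
      d
    })
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$subject, out$session, out$block, out$trial_in_block), ]
}

# Epoch timing (ms). The trial timeline relative to S1 onset: S1 at 0 ms
# (200 ms + 100 ms mask), ISI to S2 at 1300 ms, retro-cue at 2600 ms for
# 1500 ms; the ITI+trial epoch spans the last second of the ITI through the
# end of the retro-cue delay.
epoch_window <- function(epoch) {
  switch(epoch,
         s1 = c(0, 1300), s2 = c(0, 1300),
         retrocue = c(0, 1500), iti_trial = c(-1000, 4100),
         stop("unknown epoch type: ", epoch))
}

epoch_bin_centers <- function(epoch) {
  w <- epoch_window(epoch)
  seq(w[1] + 50, w[2] - 50, by = 100)
}

# ramp-plateau temporal gain: 0 before onset, linear ramp over the first
# 300 ms, plateau at 1 until the window closes
ramp_gain <- function(t, onset, window) {
  ifelse(t >= window[1] & t < window[2], pmin(1, pmax(0, (t - onset) / 300)), 0)
}

# signal components of each epoch: label column, gain, onset and active
# window on the epoch's own time axis
epoch_components <- function(epoch, cfg) {
  switch(epoch,
    s1 = list(list(name = "s1", label = "s1_dir", gain = 1,
                   onset = 0, window = c(0, 1300))),
    s2 = list(list(name = "s2", label = "s2_dir", gain = 1,
                   onset = 0, window = c(0, 1300)),
              list(name = "s1_in_s2", label = "s1_dir", gain = cfg$s1_in_s2_gain,
                   onset = 0, window = c(0, 1300))),
    retrocue = list(list(name = "retrocue", label = "target_dir", gain = 1,
                         onset = 0, window = c(0, 1500))),
    iti_trial = c(
      list(list(name = "s1", label = "s1_dir", gain = 1,
                onset = 0, window = c(0, 1300)),
           list(name = "s2", label = "s2_dir", gain = 1,
                onset = 1300, window = c(1300, 2600)),
           list(name = "s1_in_s2", label = "s1_dir", gain = cfg$s1_in_s2_gain,
                onset = 1300, window = c(1300, 2600)),
           list(name = "retrocue", label = "target_dir", gain = 1,
                onset = 2600, window = c(2600, 4100))),
      if (cfg$reactivation_gain > 0) {
        lapply(cfg$reactivation_windows, function(w) {
          list(name = "reactivation", label = "prev_target_dir",
               gain = cfg$reactivation_gain, onset = NA, window = w)
        })
      }
    ),
    stop("unknown epoch type: ", epoch))
}

# Rotate represented directions toward the previous target by delta degrees;
# trials with no previous target keep their direction, trials at exactly 180
# degrees distance get a random rotation sign.
rotate_toward_prev <- function(dirs, prev, delta) {
  if (delta == 0) return(dirs)
  sd <- wrap_signed(prev - dirs)
  sgn <- sign(sd)
  at180 <- !is.na(sd) & sd == 180
  if (any(at180)) sgn[at180] <- sample(c(-1, 1), sum(at180), replace = TRUE)
  out <- ifelse(is.na(prev), dirs, wrap360(dirs + delta * sgn))
  out
}

#' Sensor epoch container
#'
#' @param data numeric array, trials x sensors x time points.
#' @param times_ms time stamps (bin centers when `binned`).
#' @param trials the trial table rows the epochs belong to.
#' @param epoch_type one of `"s1"`, `"s2"`, `"retrocue"`, `"iti_trial"`.
#' @param binned whether `data` is already averaged into 100-ms bins.
#' @param seed generator seed recorded for provenance (or NA).
#' @return an object of class `sensor_epochs`.
#' @export
sensor_epochs <- function(data, times_ms, trials, epoch_type,
                          binned = TRUE, seed = NA_integer_) {
  stopifnot(length(dim(data)) == 3L, dim(data)[3] == length(times_ms),
            dim(data)[1] == nrow(trials))
  structure(list(data = data, times_ms = times_ms, trials = trials,
                 epoch_type = epoch_type, binned = binned, seed = seed),
            class = "sensor_epochs")
}

#' @export
print.sensor_epochs <- function(x, ...) {
  cat(sprintf("sensor_epochs [%s]: %d trials x %d sensors x %d %s (%g..%g ms)\n",
              x$epoch_type, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              if (x$binned) "bins" else "samples",
              min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

#' Generate direction-tuned sensor epochs for one subject
#'
#' For every trial and 100-ms bin the sensor vector is
#' `g(t) * C(theta_eff) * W + noise`, where `C` is the 18-channel tuning
#' basis evaluated at the (possibly rotated) represented direction, `W` a
#' fixed standard-normal channel-to-sensor mixing per subject (with a small
#' session-specific perturbation so cross-session generalization is
#' nontrivial), `g(t)` a ramp-plateau temporal gain (linear over the first
#' 300 ms after component onset), and the noise SD is `1/snr`. Components
#' named in `cfg$injected_shift` have their directions rotated toward the
#' previous trial's target; the ITI+trial epoch can carry additive
#' previous-target reactivations in configured windows.
#'
#' @param design trial table for a single subject, with directions.
#' @param cfg a [sim_config()].
#' @param epoch epoch type: `"s1"`, `"s2"`, `"retrocue"` or `"iti_trial"`.
#' @return a [sensor_epochs()] object (trials x sensors x bins).
#' @export
generate_meg <- function(design, cfg,
                         epoch = c("s1", "s2", "retrocue", "iti_trial")) {
  stopifnot(inherits(cfg, "sim_config"))
  epoch <- match.arg(epoch)
  if (length(unique(design$subject)) != 1L) {
    stop("generate_meg expects the design of a single subject")
  }
  subject <- design$subject[1]
  centers <- epoch_bin_centers(epoch)
  comps <- Filter(Negate(is.null), epoch_components(epoch, cfg))
  basis <- make_basis(0)
  ns <- cfg$sensor_count
  noise_sd <- if (is.finite(cfg$snr)) 1 / cfg$snr else 0

  with_seed(derive_seed(cfg$seed, 3L, subject, match(epoch, c("s1", "s2", "retrocue", "iti_trial"))), {
    W_base <- matrix(stats::rnorm(18 * ns), 18, ns)
    dat <- array(0, dim = c(nrow(design), ns, length(centers)))
    for (sess in sort(unique(design$session))) {
      idx <- which(design$session == sess)
      d <- design[idx, , drop = FALSE]
      W_s <- W_base + 0.1 * matrix(stats::rnorm(18 * ns), 18, ns)
      for (comp in comps) {
        dirs <- d[[comp$label]]
        delta <- if (comp$name %in% names(cfg$injected_shift)) {
          unname(cfg$injected_shift[comp$name])
        } else 0
        th <- rotate_toward_prev(dirs, d$prev_target_dir, delta)
        ok <- !is.na(th)
        if (!any(ok)) next
        CW <- channel_design(basis, th[ok]) %*% W_s
        for (b in seq_along(centers)) {
          g <- if (is.na(comp$onset)) {
            # boxcar window (reactivation)
            as.numeric(centers[b] >= comp$window[1] &
                         centers[b] < comp$window[2])
          } else {
            ramp_gain(centers[b], comp$onset, comp$window)
          }
          if (g > 0) {
            dat[idx[ok], , b] <- dat[idx[ok], , b] + comp$gain * g * CW
          }
        }
      }
    }
    if (noise_sd > 0) {
      dat <- dat + array(stats::rnorm(length(dat), 0, noise_sd), dim = dim(dat))
    }
    sensor_epochs(dat, centers, design, epoch, binned = TRUE, seed = cfg$seed)
  })
}

#' Simulate a full experiment
#'
#' Convenience wrapper: balanced designs and behavioral responses for all
#' subjects, plus sensor epochs for the requested epoch types.
#'
#' @param cfg a [sim_config()].
#' @param epochs character vector of epoch types to generate (possibly empty).
#' @return list with `trials` (all subjects) and `epochs` (per subject, a
#'   named list of [sensor_epochs()]).
#' @export
simulate_experiment <- function(cfg, epochs = character(0)) {
  designs <- lapply(seq_len(cfg$n_subjects), function(s) generate_design(cfg, s))
  trials <- generate_behavior(do.call(rbind, designs), cfg)
  eps <- NULL
  if (length(epochs)) {
    eps <- lapply(seq_len(cfg$n_subjects), function(s) {
      d <- trials[trials$subject == s, , drop = FALSE]
      stats::setNames(lapply(epochs, function(e) generate_meg(d, cfg, e)), epochs)
    })
  }
  list(trials = trials, epochs = eps, config = cfg)
}
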