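# Shared fixtures, all built in code.

# Noiseless forward-model data: trials x sensors from known weights.
make_forward_fixture <- function(n_trials = 60, n_sensors = 24, seed = 42,
                                 offset = 0) {
  set.seed(seed)
  # cover the direction pool evenly so the channel design stays well
  # conditioned even at small trial counts
  dirs <- sample(rep_len(seq(5, 355, 10), n_trials))
  basis <- make_basis(offset)
  W <- matrix(rnorm(18 * n_sensors), 18, n_sensors)
  C <- channel_design(basis, dirs)
  list(dirs = dirs, basis = basis, W = W, C = C, B = C %*% W)
}

# Minimal behavioral trial table for preprocessing tests: one subject,
# `n` trials in one block (plus the block-initial trial).
make_trial_table <- function(errors, rts = NULL, subject = 1L) {
  n <- length(errors)
  if (is.null(rts)) rts <- rep(1.5, n)
  target <- rep(180, n + 1)
  data.frame(
    subject = subject, session = 1L, block = 1L,
    trial_in_block = seq_len(n + 1),
    target_dir = target,
    response_dir = wrap360(target + c(0, errors)),
    response_time = c(1.5, rts),
    prev_target_dir = c(NA, rep(200, n)),
    signed_dist_target = c(NA, rep(20, n)),
    signed_dist_nontarget = c(NA, rep(-30, n)),
    cue_color = "red", prev_cue_color = c(NA, rep("red", n)))
}

# Small sim_config for fast end-to-end tests. Note: with fewer than 5
# subjects the exhaustive sign-flip floor (1/2^n) cannot reach p < 0.05.
tiny_config <- function(n_subjects = 3, ...) {
  sim_config(n_subjects = n_subjects, sensor_count = 20, seed = 99, ...)
}
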