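# End-to-end orchestration: simulate -> behavioral DoG fit -> IEM
# reconstruction -> fidelity / shift / correlation statistics -> summary.

analysis_catalog <- function() {
  list(
    s1 = list(epoch = "s1", label = "s1", shift = TRUE, corr = TRUE),
    s2 = list(epoch = "s2", label = "s2", shift = TRUE, corr = TRUE),
    retrocue = list(epoch = "retrocue", label = "cued", shift = TRUE, corr = TRUE),
    s1_in_s2 = list(epoch = "s2", label = "s1", shift = TRUE, corr = FALSE),
    prev_reactivation = list(epoch = "iti_trial", label = "prev",
                             shift = FALSE, corr = FALSE)
  )
}

# stable short hash of the configuration (polynomial rolling hash over its
# deparsed form; provenance marker, not cryptographic)
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are [sim_config()] fields plus optional `analyses`,
#' `n_perm`, `n_boot_dog`, `n_boot_shift`, `do_corr`.
#'
#' @param path YAML file.
#' @return list with `sim` (a `sim_config`) and the analysis options.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  opts <- y[intersect(names(y), c("analyses", "n_perm", "n_boot_dog",
                                  "n_boot_shift", "do_corr"))]
  simargs <- y[setdiff(names(y), names(opts))]
  if (!is.null(simargs$injected_shift)) {
    simargs$injected_shift <- unlist(simargs$injected_shift)
  }
  c(list(sim = do.call(sim_config, simargs)), opts)
}

#' Run the full synthetic serial-dependence analysis pipeline
#'
#' Simulates the experiment from a [sim_config()], fits the behavioral DoG
#' model (with bootstrap, permutation test and congruence split), runs the
#' IEM reconstruction for the requested epoch/label analyses, tests
#' reconstruction fidelity with cluster-based sign-flip permutation tests,
#' estimates attractive shifts over the significant bins with participant-
#' bootstrap inference, optionally computes circular brain-behavior
#' correlations, and applies multiple-comparison corrections
#' (Benjamini-Hochberg over the per-epoch shift tests of the three
#' current-item analyses; Bonferroni x3 for fidelity cluster p-values above
#' the permutation floor). Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param analyses subset of `c("s1", "s2", "retrocue", "s1_in_s2",
#'   "prev_reactivation")`.
#' @param n_perm permutations for the behavioral tests.
#' @param n_boot_dog bootstrap resamples for the DoG fit.
#' @param n_boot_shift bootstrap iterations for the shift tests.
#' @param do_corr compute single-trial brain-behavior correlations (slower).
#' @param do_behavior fit the behavioral model.
#' @return object of class `serialshift_run` with components `config`,
#'   `hash`, `behavior`, `analyses` (per analysis: fidelity matrix, cluster
#'   test, shift estimate, correlation timecourse) and `summary` (data
#'   frame, one row per analysis).
#' @export
run_all <- function(cfg, analyses = names(analysis_catalog()),
                    n_perm = 1000, n_boot_dog = 1000, n_boot_shift = 10000,
                    do_corr = TRUE, do_behavior = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  catalog <- analysis_catalog()
  analyses <- match.arg(analyses, names(catalog), several.ok = TRUE)
  specs <- catalog[analyses]
  epoch_types <- unique(vapply(specs, `[[`, "", "epoch"))

  designs <- lapply(seq_len(cfg$n_subjects), function(s) generate_design(cfg, s))
  trials <- generate_behavior(do.call(rbind, designs), cfg)

  behavior <- NULL
  if (do_behavior) {
    cleaned <- preprocess_behavior(trials)
    fit <- fit_dog(cleaned)
    fit <- bootstrap_dog(fit, n_boot_dog, seed = derive_seed(cfg$seed, 10L))
    fit <- permutation_test_dog(fit, n_perm, seed = derive_seed(cfg$seed, 11L))
    congr <- congruence_analysis(cleaned, n_perm,
                                 seed = derive_seed(cfg$seed, 12L))
    behavior <- list(fit = fit, congruence = congr, cleaned = cleaned)
  }

  # per-subject reconstructions (epochs generated once per type, then freed)
  recons <- stats::setNames(vector("list", length(specs)), names(specs))
  for (s in seq_len(cfg$n_subjects)) {
    d <- trials[trials$subject == s, , drop = FALSE]
    eps <- stats::setNames(
      lapply(epoch_types, function(e) generate_meg(d, cfg, e)), epoch_types)
    for (an in names(specs)) {
      sp <- specs[[an]]
      rec <- reconstruct(eps[[sp$epoch]], label_source = sp$label,
                         per_trial = do_corr && sp$corr)
      recons[[an]]$recs[[s]] <- rec
      if (do_corr && sp$corr) {
        recons[[an]]$corr[[s]] <- circ_corr_behavior(rec, d)
      }
    }
    rm(eps)
  }

  results <- list()
  for (an in names(specs)) {
    sp <- specs[[an]]
    recs <- recons[[an]]$recs
    nb <- length(recs[[1]]$bins)
    fid <- do.call(rbind, lapply(recs, `[[`, "fidelity"))
    ct <- cluster_test(fid, seed = derive_seed(cfg$seed, 20L, match(an, names(specs))))
    res <- list(spec = sp, bins = recs[[1]]$bins, fidelity = fid, cluster = ct)
    if (sp$shift && !is.null(recs[[1]]$flipped) && length(ct$sig_bins)) {
      subj_prof <- do.call(rbind, lapply(recs, function(r) {
        colMeans(r$flipped[ct$sig_bins, , drop = FALSE])
      }))
      res$shift <- bootstrap_shift(subj_prof, n_boot_shift,
                                   seed = derive_seed(cfg$seed, 30L,
                                                      match(an, names(specs))))
      res$subject_profiles <- subj_prof
    }
    if (!is.null(recons[[an]]$corr)) {
      rmat <- do.call(rbind, recons[[an]]$corr)
      res$corr <- list(
        r = rmat,
        cluster = cluster_test(rmat, seed = derive_seed(cfg$seed, 40L,
                                                        match(an, names(specs)))))
    }
    results[[an]] <- res
  }

  # multiple-comparison corrections
  fam <- intersect(c("s1", "s2", "retrocue"), names(results))
  shift_p <- vapply(fam, function(an) {
    if (is.null(results[[an]][["shift"]])) NA_real_ else results[[an]][["shift"]]$p
  }, numeric(1))
  p_fdr <- rep(NA_real_, length(fam))
  ok <- !is.na(shift_p)
  p_fdr[ok] <- correct_multiple(shift_p[ok], "bh_fdr")
  names(p_fdr) <- fam
  for (an in names(results)) {
    results[[an]]$shift_p_fdr <- if (an %in% fam) p_fdr[[an]] else NA_real_
    cl <- results[[an]]$cluster$clusters
    if (!is.null(cl)) {
      floor_p <- 1 / results[[an]]$cluster$n_perm
      results[[an]]$cluster$clusters$p_bonf <-
        ifelse(cl$p <= floor_p, cl$p, correct_multiple(cl$p, "bonferroni", n = 3))
    }
  }

  summary_df <- do.call(rbind, lapply(names(results), function(an) {
    r <- results[[an]]
    sb <- r$cluster$sig_bins
    data.frame(
      analysis = an, epoch = r$spec$epoch, label = r$spec$label,
      n_bins = length(r$bins),
      sig_from_ms = if (length(sb)) r$bins[min(sb)] - 50 else NA_real_,
      sig_to_ms = if (length(sb)) r$bins[max(sb)] + 50 else NA_real_,
      mean_fidelity = if (length(sb)) mean(r$fidelity[, sb]) else NA_real_,
      cluster_p = if (!is.null(r$cluster$clusters)) min(r$cluster$clusters$p)
                  else NA_real_,
      shift = if (!is.null(r[["shift"]])) r[["shift"]]$shift else NA_real_,
      shift_p = if (!is.null(r[["shift"]])) r[["shift"]]$p else NA_real_,
      shift_p_fdr = r$shift_p_fdr,
      stringsAsFactors = FALSE)
  }))

  structure(list(config = cfg, hash = config_hash(cfg), trials = trials,
                 behavior = behavior, analyses = results,
                 summary = summary_df),
            class = "serialshift_run")
}

#' @export
print.serialshift_run <- function(x, ...) {
  cat("serialshift pipeline run (config hash ", x$hash, ", seed ",
      x$config$seed, ")\n", sep = "")
  if (!is.null(x$behavior)) {
    f <- x$behavior$fit
    cat(sprintf("behavior: a = %.2f deg (boot SD %.3f), w = %.4f (FWHM %.1f), perm p = %.4g\n",
                coef(f)["a"], f$boot$sd_a, coef(f)["w"], f$fwhm, f$perm$p))
    cg <- x$behavior$congruence
    cat(sprintf("  congruence: a_same = %.2f, a_diff = %.2f, diff = %.2f (p = %.3f)\n",
                coef(cg$fit_same)["a"], coef(cg$fit_diff)["a"],
                cg$difference, cg$p))
  }
  cat("\nreconstruction analyses:\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Human-readable and machine-readable pipeline report
#'
#' @param x a [run_all()] result.
#' @param path optional output stem: writes `<path>.md` and `<path>.json`.
#' @return list with `text` (markdown lines) and `json` (list serialized by
#'   jsonlite), invisibly when `path` is given.
#' @export
report <- function(x, path = NULL) {
  stopifnot(inherits(x, "serialshift_run"))
  lines <- c(
    "# serialshift pipeline report",
    sprintf("config hash: %s, seed: %d", x$hash, x$config$seed), "")
  gen <- list(a_gen = x$config$a_gen, w_gen = x$config$w_gen,
              congruence_delta = x$config$congruence_delta,
              injected_shift = as.list(x$config$injected_shift))
  j <- list(hash = x$hash, seed = x$config$seed, generator_truth = gen)
  if (!is.null(x$behavior)) {
    f <- x$behavior$fit; cg <- x$behavior$congruence
    lines <- c(lines, "## Behavioral serial dependence",
               sprintf("- amplitude a = %.3f deg (generator: %.3f), bootstrap SD %.3f",
                       coef(f)["a"], x$config$a_gen, f$boot$sd_a),
               sprintf("- width w = %.4f (FWHM %.2f deg), R^2 = %.3f",
                       coef(f)["w"], f$fwhm, f$r.squared),
               sprintf("- one-sided permutation p = %.4g", f$perm$p),
               sprintf("- congruence: a_same = %.3f, a_diff = %.3f, diff = %.3f, p = %.3f",
                       coef(cg$fit_same)["a"], coef(cg$fit_diff)["a"],
                       cg$difference, cg$p), "")
    j$behavior <- list(a = unname(coef(f)["a"]), w = unname(coef(f)["w"]),
                       fwhm = f$fwhm, r2 = f$r.squared,
                       boot_sd_a = f$boot$sd_a, perm_p = f$perm$p,
                       a_same = unname(coef(cg$fit_same)["a"]),
                       a_diff = unname(coef(cg$fit_diff)["a"]),
                       congruence_p = cg$p)
  } else {
    lines <- c(lines, "## Behavioral serial dependence", "- not run", "")
  }
  lines <- c(lines, "## Reconstruction analyses", "")
  for (an in names(analysis_catalog())) {
    r <- x$analyses[[an]]
    if (is.null(r)) {
      lines <- c(lines, sprintf("- %s: not run", an))
      next
    }
    sb <- r$cluster$sig_bins
    ln <- sprintf("- %s (epoch %s, label %s): ", an, r$spec$epoch, r$spec$label)
    ln <- paste0(ln, if (length(sb)) {
      sprintf("fidelity cluster %g-%g ms (p = %.4g), mean fidelity %.3f",
              r$bins[min(sb)] - 50, r$bins[max(sb)] + 50,
              min(r$cluster$clusters$p), mean(r$fidelity[, sb]))
    } else "no significant fidelity cluster")
    if (!is.null(r[["shift"]])) {
      ln <- paste0(ln, sprintf("; shift %.2f deg (p = %.4g, p_FDR = %.4g)",
                               r[["shift"]]$shift, r[["shift"]]$p, r$shift_p_fdr))
    }
    lines <- c(lines, ln)
    j$analyses[[an]] <- list(
      sig_bins = sb,
      cluster_p = if (!is.null(r$cluster$clusters)) r$cluster$clusters$p else NULL,
      mean_fidelity = if (length(sb)) mean(r$fidelity[, sb]) else NULL,
      shift = if (!is.null(r[["shift"]])) r[["shift"]]$shift else NULL,
      shift_p = if (!is.null(r[["shift"]])) r[["shift"]]$p else NULL,
      shift_p_fdr = if (!is.null(r[["shift"]])) r$shift_p_fdr else NULL,
      shift_ci = if (!is.null(r[["shift"]])) r[["shift"]]$ci else NULL,
      corr_cluster_p = if (!is.null(r$corr) && !is.null(r$corr$cluster$clusters))
        r$corr$cluster$clusters$p else NULL)
  }
  out <- list(text = lines, json = j)
  if (!is.null(path)) {
    writeLines(lines, paste0(path, ".md"))
    jsonlite::write_json(j, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    return(invisible(out))
  }
  out
}
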