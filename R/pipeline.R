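#' Experiment configuration
#'
#' Plain-list configuration of an end-to-end simulated experiment. Defaults
#' mirror the study layout: 29 subjects, 6 runs of 400 trials, TR 1.5 s,
#' ISI 1.75 s, 475 volumes per run. Serializes losslessly to JSON
#' (\code{load(dump(c)) = c}).
#'
#' @param n_subjects simulated cohort size.
#' @param n_runs,n_trials,n_volumes,tr,isi session layout.
#' @param conditions assignment per run, or \code{NULL} for random.
#' @param conditional_tol,overall_tol sequence validation tolerances.
#' @param noise list of \code{\link{noise_spec}} arguments.
#' @param whitening GLM whitening option.
#' @param ppi_mode PPI interaction mode.
#' @return Object of class \code{experiment_config} (a list).
#' @export
experiment_config <- function(n_subjects = 29L, n_runs = 6L, n_trials = 400L,
                              n_volumes = 475L, tr = 1.5, isi = 1.75,
                              conditions = NULL,
                              conditional_tol = 0.005, overall_tol = 0.025,
                              noise = list(rho = 0.3, sigma = 1,
                                           drift_order = 2, drift_sd = 0.5),
                              whitening = "ar1",
                              ppi_mode = "deconvolved") {
  structure(list(n_subjects = as.integer(n_subjects),
                 n_runs = as.integer(n_runs),
                 n_trials = as.integer(n_trials),
                 n_volumes = as.integer(n_volumes),
                 tr = tr, isi = isi, conditions = conditions,
                 conditional_tol = conditional_tol,
                 overall_tol = overall_tol,
                 noise = noise, whitening = whitening, ppi_mode = ppi_mode),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param config an \code{experiment_config}.
#' @param path JSON file.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(experiment_config, x)
}

config_tol <- function(config) {
  tolerance_spec(conditional_tol = config$conditional_tol,
                 overall_tol = config$overall_tol)
}

simulate_subject <- function(config, seed, region_specs, participant_id) {
  session <- build_session(seed, conditions = config$conditions,
                           n_runs = config$n_runs,
                           n_trials = config$n_trials,
                           tol = config_tol(config),
                           participant_id = participant_id)
  generate_dataset(session, region_specs = region_specs,
                   noise = do.call(noise_spec, config$noise),
                   n_volumes = config$n_volumes, tr = config$tr,
                   isi = config$isi)
}

#' Run the parameter-recovery experiment
#'
#' Simulates a cohort under the configured ground truth, fits both
#' first-level GLM variants per subject, performs the second-level tests and
#' the modality conjunction, runs the PPI analysis for each sensory seed,
#' and reports estimated versus injected effects together with type-I
#' behaviour at the null regions.
#'
#' @param config an \code{experiment_config}.
#' @param seed master seed; subject seeds derive from it.
#' @param region_specs ground-truth region map.
#' @param out optional output directory for TSV/JSON reports.
#' @return List of report tables (class \code{recovery_report}).
#' @export
run_recovery_experiment <- function(config = experiment_config(), seed = 1L,
                                    region_specs = default_region_specs(),
                                    out = NULL) {
  set.seed(seed)
  subj_seeds <- sample.int(.Machine$integer.max, config$n_subjects)
  regions <- names(region_specs)
  nS <- config$n_subjects
  mm_est <- array(NA_real_, c(nS, 3L, length(regions)),
                  dimnames = list(NULL, MODALITIES, regions))
  tl_est <- mm_est
  ppi_est <- matrix(NA_real_, nS, 3L, dimnames = list(NULL, MODALITIES))
  for (i in seq_len(nS)) {
    ds <- simulate_subject(config, subj_seeds[i], region_specs,
                           sprintf("sub-%02d", i))
    events <- do.call(rbind, ds$events)
    Y <- do.call(rbind, ds$bold)
    Xm <- build_design_matrix(events, "modulator", n_volumes = config$n_volumes,
                              tr = config$tr)
    fm <- fit_glm(Y, Xm, whitening = config$whitening)
    Xt <- build_design_matrix(events, "trainbins", n_volumes = config$n_volumes,
                              tr = config$tr)
    ft <- fit_glm(Y, Xt, whitening = config$whitening)
    for (mi in seq_len(3L)) {
      m <- MODALITIES[mi]
      cn <- paste0("mismatch_", m)
      if (cn %in% rownames(fm$beta)) {
        mm_est[i, mi, ] <- t_contrast(fm, stats::setNames(1, cn))$estimate
      }
      tl <- suppressWarnings(train_length_contrast(ft, m))
      tl_est[i, mi, ] <- tl$estimate
    }
    for (mi in seq_len(3L)) {
      m <- MODALITIES[mi]
      target <- sprintf("PPI_target_%s", m)
      if (!target %in% regions) next
      pp <- fit_ppi(ds, seed = sprintf("%s1_left", m), modality = m,
                    mode = config$ppi_mode, targets = target)
      ppi_est[i, mi] <- pp$beta_ppi
    }
  }
  group_mm <- lapply(seq_len(3L), function(mi) second_level(mm_est[, mi, ]))
  names(group_mm) <- MODALITIES
  conj <- conjunction_global_null(group_mm)
  truth_mm <- vapply(region_specs, function(s) mean(s$mismatch_effect), 1)
  recovery <- data.frame(
    region = regions,
    true_mismatch = truth_mm,
    est_mismatch = colMeans(apply(mm_est, c(1L, 3L), mean)),
    true_trainslope = vapply(region_specs,
                             function(s) mean(s$trainlength_slope), 1),
    est_trainslope_contrast = colMeans(apply(tl_est, c(1L, 3L), mean)),
    row.names = NULL)
  nulls <- grep("^null_", regions, value = TRUE)
  typeI <- vapply(seq_len(3L), function(mi) {
    g <- group_mm[[mi]]
    mean(g$p[g$region %in% nulls] < 0.05)
  }, 1)
  report <- structure(
    list(recovery = recovery, group_mismatch = group_mm,
         conjunction = conj,
         ppi = data.frame(modality = MODALITIES,
                          mean_beta_ppi = colMeans(ppi_est),
                          detection_rate = colMeans(ppi_est > 0)),
         null_region_rejection_rate = stats::setNames(typeI, MODALITIES),
         config = config, seed = seed),
    class = "recovery_report")
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(recovery, file.path(out, "recovery.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(conj), file.path(out, "conjunction.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(seed = seed,
                              null_rejection = as.list(typeI)),
                         file.path(out, "report.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  report
}

#' Recompute the sequence-statistics acceptance checks
#'
#' Generates validated runs for each condition, pools their transitions
#' across runs and modalities, and compares the empirical probabilities with
#' the generative values: conditional change probabilities per context,
#' repetition complements, and intensity balance.
#'
#' @param seed RNG seed.
#' @param n_runs validated runs per condition (default 200).
#' @param n_trials trials per run.
#' @param tol a \code{tolerance_spec}.
#' @return Data frame (class \code{target_report}) with target id, observed
#'   value, nominal value, tolerance used for the pass flag, and pass.
#' @export
reproduce_targets <- function(seed = 1L, n_runs = 200L, n_trials = 400L,
                              tol = tolerance_spec()) {
  set.seed(seed)
  pooled <- list()
  for (cond in c("C1", "C2", "C3")) {
    runs <- vector("list", n_runs)
    for (i in seq_len(n_runs)) {
      runs[[i]] <- sample_valid_run(cond, n_trials, tol = tol)
    }
    pooled[[cond]] <- compute_stats(runs)$pooled
  }
  c3both <- c(pooled$C3$p_change_given_congruent,
              pooled$C3$p_change_given_incongruent)
  phigh <- mean(c(pooled$C1$p_high, pooled$C2$p_high, pooled$C3$p_high))
  rows <- rbind(
    data.frame(id = "t1", quantity = "C1 p(change|congruent)",
               observed = pooled$C1$p_change_given_congruent, nominal = 0.15),
    data.frame(id = "t2", quantity = "C1 p(change|incongruent)",
               observed = pooled$C1$p_change_given_incongruent, nominal = 0.025),
    data.frame(id = "t3", quantity = "C3 p(change|either context)",
               observed = mean(c3both), nominal = 0.0875),
    data.frame(id = "t4", quantity = "C2 p(repetition|congruent)",
               observed = 1 - pooled$C2$p_change_given_congruent,
               nominal = 0.975),
    # nominal is the complement of the C3 change probability (1 - 0.0875);
    # a sometimes-quoted 0.925 for this quantity is inconsistent with it
    data.frame(id = "t5", quantity = "C3 p(repetition|either context)",
               observed = 1 - mean(c3both), nominal = 0.9125),
    data.frame(id = "t6", quantity = "p(high intensity)",
               observed = phigh, nominal = 0.5),
    data.frame(id = "t9", quantity = "C2 p(change|congruent)",
               observed = pooled$C2$p_change_given_congruent, nominal = 0.025)
  )
  rows$tolerance <- 0.01
  rows$pass <- abs(rows$observed - rows$nominal) <= rows$tolerance
  structure(rows, class = c("target_report", "data.frame"))
}
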