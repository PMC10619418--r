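#' Tolerance settings for sequence validation
#'
#' Accepted sequences must reproduce the generative probabilities within
#' these bands: \code{conditional_tol} bounds the deviation of the empirical
#' conditional change probabilities (congruent / incongruent context) from
#' their nominal values, \code{overall_tol} bounds the deviation of the
#' overall change probability from its matrix-implied marginal and of the
#' high-intensity proportion from 0.5.
#'
#' @param conditional_tol band for the conditional change probabilities
#'   (default 0.005).
#' @param overall_tol band for overall change probability and intensity
#'   balance (default 0.025).
#' @param unit pooling unit over which statistics are computed before being
#'   checked: a single \code{"run"} (default) or a whole \code{"session"}.
#' @param per_modality check every modality separately instead of pooling
#'   statistics across the three modalities (default \code{FALSE}; see the
#'   methods vignette for why pooled checking is the default).
#' @param use_difference check the congruent-minus-incongruent difference
#'   against its nominal difference instead of each conditional separately.
#' @return Object of class \code{tolerance_spec}.
#' @export
tolerance_spec <- function(conditional_tol = 0.005, overall_tol = 0.025,
                           unit = c("run", "session"),
                           per_modality = FALSE, use_difference = FALSE) {
  unit <- match.arg(unit)
  stopifnot(conditional_tol >= 0, overall_tol >= 0)
  structure(list(conditional_tol = conditional_tol,
                 overall_tol = overall_tol,
                 unit = unit,
                 per_modality = per_modality,
                 use_difference = use_difference),
            class = "tolerance_spec")
}

#' Sample one tri-modal sequence run
#'
#' Draws \code{n_trials} joint states from the condition's Markov chain,
#' starting from a uniformly drawn initial state. With
#' \code{enforce_min_repetition} (the default) a proposed transition that
#' would change a modality which already changed on the immediately preceding
#' transition is rejected and redrawn, guaranteeing at least one repetition
#' between successive deviants within each modality.
#'
#' Randomness is taken from R's global RNG; seed with \code{set.seed()} for
#' reproducibility.
#'
#' @param matrix a \code{transition_matrix}.
#' @param n_trials number of trials (default 400).
#' @param enforce_min_repetition apply the minimum-one-repetition rule.
#' @param rejection_cap maximum redraws per trial before erroring.
#' @return Object of class \code{sequence_run}: list with \code{states}
#'   (length \code{n_trials}, values 0--7), \code{obs}
#'   (\code{n_trials} x 3 binary matrix), \code{forced}
#'   (\code{n_trials} x 3 logical; TRUE where the minimum-repetition rule
#'   forced that modality to repeat at that trial), \code{condition},
#'   and \code{n_trials}.
#' @export
sample_run <- function(matrix, n_trials = 400L,
                       enforce_min_repetition = TRUE,
                       rejection_cap = 1000L) {
  stopifnot(inherits(matrix, "transition_matrix"), n_trials >= 2L)
  P <- unclass(matrix)
  cum <- t(apply(P, 1L, cumsum))      # 8 x 8 cumulative rows
  # destination state of a single-modality change, per source state
  bit <- c(4L, 2L, 1L)
  states <- integer(n_trials)
  forced <- matrix(FALSE, n_trials, 3L, dimnames = list(NULL, MODALITIES))
  s <- sample.int(8L, 1L) - 1L
  states[1L] <- s
  blocked <- 0L                       # 0 = none, else modality index 1..3
  # pre-drawn uniform pool; redraw probability per trial is small, so one
  # modest refill block suffices almost always
  pool <- stats::runif(n_trials + 63L)
  pi_ <- 0L
  npool <- length(pool)
  for (t in 2:n_trials) {
    repeat_ok <- FALSE
    row <- cum[s + 1L, ]
    for (draw in seq_len(rejection_cap)) {
      pi_ <- pi_ + 1L
      if (pi_ > npool) {
        pool <- stats::runif(256L)
        npool <- 256L
        pi_ <- 1L
      }
      u <- pool[pi_]
      nxt <- sum(u > row)            # count of cumulative entries below u
      changed <- bitwXor(s, nxt)
      if (enforce_min_repetition && blocked > 0L &&
          changed == bit[blocked]) next
      repeat_ok <- TRUE
      break
    }
    if (!repeat_ok) {
      stop("rejection cap (", rejection_cap, ") exceeded at trial ", t)
    }
    if (enforce_min_repetition && blocked > 0L) forced[t, blocked] <- TRUE
    blocked <- if (changed == 0L) 0L else match(changed, bit)
    s <- nxt
    states[t] <- s
  }
  obs <- state_to_obs(states)
  structure(list(states = states, obs = obs, forced = forced,
                 condition = attr(matrix, "condition"),
                 n_trials = as.integer(n_trials)),
            class = "sequence_run")
}

#' @export
print.sequence_run <- function(x, ...) {
  cat(sprintf("sequence_run: %d trials, condition %s\n",
              x$n_trials, x$condition$id))
  if (!is.null(x$attempts)) cat("  accepted after", x$attempts, "attempt(s)\n")
  invisible(x)
}

#' Empirical sequence statistics
#'
#' Computes, per modality and pooled across modalities, the empirical change
#' probabilities overall and conditional on the cross-modal context at the
#' preceding trial, plus the proportion of high-intensity trials. Transitions
#' are counted from the second trial onward; the context is read from the
#' state at t-1.
#'
#' When \code{exclude_forced} is \code{TRUE} (the default) transitions on
#' which the minimum-repetition rule forced the modality to repeat are
#' excluded from the change statistics: on those slots a change was
#' impossible by construction, so including them biases the empirical
#' conditionals about 11\% below their generative values (see the methods
#' vignette). Intensity balance always uses all trials.
#'
#' @param runs a \code{sequence_run} or a list of them (pooled).
#' @param exclude_forced drop constraint-forced repetitions from change
#'   statistics.
#' @return Object of class \code{sequence_stats}: list with per-modality and
#'   pooled counts and probabilities. Empty context cells yield \code{NaN},
#'   never 0.
#' @export
compute_stats <- function(runs, exclude_forced = TRUE) {
  if (inherits(runs, "sequence_run")) runs <- list(runs)
  stopifnot(length(runs) >= 1L, all(vapply(runs, inherits, TRUE, "sequence_run")))
  cong_n <- cong_ch <- incong_n <- incong_ch <-
    stats::setNames(numeric(3L), MODALITIES)
  high <- trials <- stats::setNames(numeric(3L), MODALITIES)
  other1 <- c(2L, 1L, 1L)            # the two context modalities per modality
  other2 <- c(3L, 3L, 2L)
  for (run in runs) {
    if (run$n_trials < 2L) stop("need at least 2 trials")
    o <- run$obs
    n <- run$n_trials
    prev <- o[-n, , drop = FALSE]
    for (mi in seq_along(MODALITIES)) {
      m <- MODALITIES[mi]
      chg <- o[-1L, mi] != prev[, mi]
      cong <- prev[, other1[mi]] == prev[, other2[mi]]
      if (exclude_forced) {
        keep <- !run$forced[-1L, mi]
        cong_keep <- cong & keep
        incong_keep <- !cong & keep
      } else {
        cong_keep <- cong
        incong_keep <- !cong
      }
      cong_n[m] <- cong_n[m] + sum(cong_keep)
      incong_n[m] <- incong_n[m] + sum(incong_keep)
      cong_ch[m] <- cong_ch[m] + sum(chg & cong_keep)
      incong_ch[m] <- incong_ch[m] + sum(chg & incong_keep)
      high[m] <- high[m] + sum(o[, mi])
      trials[m] <- trials[m] + n
    }
  }
  rat <- function(a, b) ifelse(b > 0, a / b, NaN)
  # direct construction: this runs once per sampling attempt
  per <- structure(
    list(modality = MODALITIES,
         n_congruent = unname(cong_n), n_incongruent = unname(incong_n),
         p_change_given_congruent = unname(rat(cong_ch, cong_n)),
         p_change_given_incongruent = unname(rat(incong_ch, incong_n)),
         p_change_overall = unname(rat(cong_ch + incong_ch,
                                       cong_n + incong_n)),
         p_high = unname(rat(high, trials))),
    class = "data.frame", row.names = c(NA_integer_, -3L))
  pooled <- list(
    n_congruent = sum(cong_n), n_incongruent = sum(incong_n),
    p_change_given_congruent = rat(sum(cong_ch), sum(cong_n)),
    p_change_given_incongruent = rat(sum(incong_ch), sum(incong_n)),
    p_change_overall = rat(sum(cong_ch + incong_ch), sum(cong_n + incong_n)),
    p_high = rat(sum(high), sum(trials))
  )
  structure(list(per_modality = per, pooled = pooled,
                 exclude_forced = exclude_forced,
                 n_runs = length(runs)),
            class = "sequence_stats")
}

#' @export
print.sequence_stats <- function(x, ...) {
  cat("sequence_stats over", x$n_runs, "run(s)",
      if (x$exclude_forced) "(forced repetitions excluded)" else "", "\n")
  print(x$per_modality, digits = 4)
  with(x$pooled, cat(sprintf(
    "pooled: p(ch|cong) = %.4f  p(ch|incong) = %.4f  p(ch) = %.4f  p(high) = %.4f\n",
    p_change_given_congruent, p_change_given_incongruent,
    p_change_overall, p_high)))
  invisible(x)
}

#' Validate empirical statistics against a condition's nominal values
#'
#' Nominal values are the condition's configured conditionals and the
#' matrix-implied stationary marginal change probability
#' \code{(p_cc + p_ci) / 2}; intensity balance is checked against 0.5.
#' By default the pooled-across-modalities statistics are checked; set
#' \code{per_modality} in the tolerance spec for the stricter
#' modality-by-modality variant.
#'
#' @param stats a \code{sequence_stats}.
#' @param condition a \code{condition_setting} (or id string).
#' @param tol a \code{tolerance_spec}.
#' @return Object of class \code{validation_report}: list with \code{pass}
#'   and a data frame \code{checks} (check, modality, value, nominal,
#'   tolerance, pass). Undefined (NaN) statistics fail their check.
#' @export
validate_stats <- function(stats, condition, tol = tolerance_spec()) {
  if (is.character(condition)) condition <- condition_setting(condition)
  stopifnot(inherits(stats, "sequence_stats"),
            inherits(tol, "tolerance_spec"))
  pcc <- condition$p_change_congruent
  pci <- condition$p_change_incongruent
  marginal <- (pcc + pci) / 2
  chk_check <- chk_mod <- character(0)
  chk_val <- chk_nom <- chk_tol <- numeric(0)
  add <- function(check, modality, value, nominal, tolerance) {
    chk_check[length(chk_check) + 1L] <<- check
    chk_mod[length(chk_mod) + 1L] <<- modality
    chk_val[length(chk_val) + 1L] <<- value
    chk_nom[length(chk_nom) + 1L] <<- nominal
    chk_tol[length(chk_tol) + 1L] <<- tolerance
  }
  emit <- function(label, s) {
    if (tol$use_difference) {
      add("change_congruent_minus_incongruent", label,
          s$p_change_given_congruent - s$p_change_given_incongruent,
          pcc - pci, tol$conditional_tol)
    } else {
      add("change_given_congruent", label, s$p_change_given_congruent,
          pcc, tol$conditional_tol)
      add("change_given_incongruent", label, s$p_change_given_incongruent,
          pci, tol$conditional_tol)
    }
    add("change_overall", label, s$p_change_overall, marginal,
        tol$overall_tol)
    add("high_intensity", label, s$p_high, 0.5, tol$overall_tol)
  }
  if (tol$per_modality) {
    for (i in seq_len(3L)) {
      emit(MODALITIES[i], as.list(stats$per_modality[i, ]))
    }
  } else {
    emit("pooled", stats$pooled)
  }
  pass_vec <- is.finite(chk_val) & abs(chk_val - chk_nom) <= chk_tol
  checks <- data.frame(check = chk_check, modality = chk_mod,
                       value = chk_val, nominal = chk_nom,
                       tolerance = chk_tol, pass = pass_vec)
  structure(list(pass = all(pass_vec), checks = checks,
                 condition = condition$id),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation against condition", x$condition, "->",
      if (x$pass) "PASS" else "FAIL", "\n")
  print(x$checks, digits = 4)
  invisible(x)
}

#' Sample runs until one passes validation
#'
#' Repeatedly draws runs with \code{\link{sample_run}} and accepts the first
#' whose \code{\link{compute_stats}} pass \code{\link{validate_stats}}.
#'
#' @param condition a \code{condition_setting} or id string.
#' @param n_trials trials per run.
#' @param tol a \code{tolerance_spec}.
#' @param max_attempts sampling attempts before giving up (default 10000).
#' @param enforce_min_repetition,exclude_forced passed through to the sampler
#'   and statistics.
#' @return An accepted \code{sequence_run} with elements \code{attempts},
#'   \code{stats} and \code{report} added.
#' @export
sample_valid_run <- function(condition, n_trials = 400L,
                             tol = tolerance_spec(),
                             max_attempts = 10000L,
                             enforce_min_repetition = TRUE,
                             exclude_forced = TRUE) {
  if (is.character(condition)) condition <- condition_setting(condition)
  stopifnot(max_attempts >= 1L)
  P <- build_transition_matrix(condition)
  best <- NULL
  best_fails <- Inf
  for (attempt in seq_len(max_attempts)) {
    run <- sample_run(P, n_trials,
                      enforce_min_repetition = enforce_min_repetition)
    st <- compute_stats(run, exclude_forced = exclude_forced)
    rep_ <- validate_stats(st, condition, tol)
    if (rep_$pass) {
      run$attempts <- attempt
      run$stats <- st
      run$report <- rep_
      return(run)
    }
    nfail <- sum(!rep_$checks$pass)
    if (nfail < best_fails) {
      best_fails <- nfail
      best <- rep_
    }
  }
  stop(structure(
    class = c("sampling_error", "error", "condition"),
    list(message = paste0("no run passed validation in ", max_attempts,
                          " attempts (best report had ", best_fails,
                          " failing check(s))"),
         call = sys.call(-1L), best_report = best)))
}

#' Place catch trials within a run
#'
#' Chooses unique trial indices (never the first trial, so a "most recent
#' stimulus" exists) and assigns each a queried modality, balancing the three
#' modalities as evenly as the number of catch trials allows (2/2/2 for the
#' default six).
#'
#' @param n_trials trials in the run.
#' @param n_catch number of catch trials (default 6).
#' @return Data frame with columns \code{trial} (1-based index in
#'   \code{[2, n_trials]}) and \code{modality}.
#' @export
place_catch_trials <- function(n_trials = 400L, n_catch = 6L) {
  if (n_catch >= n_trials) stop("n_catch must be smaller than n_trials")
  idx <- sort(sample(2:n_trials, n_catch))
  mods <- sample(rep_len(MODALITIES, n_catch))
  data.frame(trial = idx, modality = mods)
}

#' Assemble a participant session
#'
#' Derives one RNG seed per run from the master seed, samples each run with
#' \code{\link{sample_valid_run}} under its assigned condition, and places
#' catch trials. Condition assignment is random (uniform over C1/C2/C3 with
#' replacement, as in a per-participant randomization) unless given
#' explicitly.
#'
#' @param master_seed integer master seed for the whole session.
#' @param conditions character vector of length \code{n_runs} or \code{NULL}
#'   for random assignment.
#' @param n_runs runs per session (default 6).
#' @param n_trials trials per run (default 400).
#' @param n_catch catch trials per run (default 6).
#' @param tol,max_attempts,enforce_min_repetition,exclude_forced passed to
#'   \code{\link{sample_valid_run}}.
#' @param participant_id optional label stored in the session.
#' @return Object of class \code{session}: list with \code{runs} (list of
#'   accepted \code{sequence_run}s, each carrying \code{catch_trials}),
#'   \code{conditions}, \code{seeds}, \code{master_seed},
#'   \code{participant_id}.
#' @export
build_session <- function(master_seed, conditions = NULL, n_runs = 6L,
                          n_trials = 400L, n_catch = 6L,
                          tol = tolerance_spec(), max_attempts = 10000L,
                          enforce_min_repetition = TRUE,
                          exclude_forced = TRUE,
                          participant_id = "sub-01") {
  set.seed(master_seed)
  run_seeds <- sample.int(.Machine$integer.max, n_runs)
  if (is.null(conditions)) {
    conditions <- sample(c("C1", "C2", "C3"), n_runs, replace = TRUE)
  }
  stopifnot(length(conditions) == n_runs)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    run <- sample_valid_run(conditions[r], n_trials, tol = tol,
                            max_attempts = max_attempts,
                            enforce_min_repetition = enforce_min_repetition,
                            exclude_forced = exclude_forced)
    run$catch_trials <- place_catch_trials(n_trials, n_catch)
    run$run_index <- r
    run$seed <- run_seeds[r]
    runs[[r]] <- run
  }
  structure(list(runs = runs, conditions = conditions, seeds = run_seeds,
                 master_seed = master_seed, participant_id = participant_id,
                 n_trials = as.integer(n_trials)),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("session %s: %d runs x %d trials, conditions: %s\n",
              x$participant_id, length(x$runs), x$n_trials,
              paste(x$conditions, collapse = " ")))
  invisible(x)
}

#' Write a session's provenance log
#'
#' @param session a \code{session}.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
write_session_json <- function(session, path) {
  jsonlite::write_json(
    list(participant_id = session$participant_id,
         master_seed = session$master_seed,
         run_seeds = session$seeds,
         conditions = session$conditions,
         n_trials = session$n_trials,
         attempts = vapply(session$runs, function(r) r$attempts, 1L)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
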