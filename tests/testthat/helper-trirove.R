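# Shared fixtures: small geometries keep unit tests fast; acceptance tests
# use the full study layout.

# tiny session: 2 runs x 60 trials, loose tolerances so sampling is instant
tiny_session <- function(seed = 11L, conditions = c("C1", "C2"),
                         n_trials = 60L) {
  build_session(seed, conditions = conditions, n_runs = length(conditions),
                n_trials = n_trials, tol = tolerance_spec(1, 1))
}

# volumes covering a tiny run: onsets end at (n_trials-1)*1.75 s
tiny_volumes <- function(n_trials = 60L, tr = 1.5) {
  as.integer(ceiling(((n_trials - 1) * 1.75 + 2 * tr) / tr))
}

tiny_dataset <- function(session, specs = NULL, noise = noise_spec(0, 0, 0),
                         n_trials = 60L) {
  if (is.null(specs)) {
    specs <- list(
      act = region_effect_spec("act", baseline_response = 1,
                               intensity_effect = c(A = 0.8, S = 0, V = 0),
                               mismatch_effect = c(A = 1, S = 0, V = 0)),
      null_1 = region_effect_spec("null_1")
    )
  }
  generate_dataset(session, specs, noise = noise,
                   n_volumes = tiny_volumes(n_trials))
}

# run constructor for hand-written observation sequences (one modality's
# pattern in all three modalities would violate single-change; build states
# directly from a per-modality observation matrix)
run_from_obs <- function(obs, condition = "C1") {
  obs <- as.matrix(obs)
  structure(list(states = obs_to_state(obs), obs = obs,
                 forced = matrix(FALSE, nrow(obs), 3L,
                                 dimnames = list(NULL, MODALITIES)),
                 condition = condition_setting(condition),
                 n_trials = nrow(obs)),
            class = "sequence_run")
}

# random feasible condition setting
random_condition <- function() {
  repeat {
    pcc <- stats::runif(1, 0, 0.33)
    pci <- stats::runif(1, 0, 0.33)
    ok <- tryCatch({
      condition_setting("rand", pcc, pci)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(condition_setting("rand", pcc, pci))
  }
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / stats::sd(x)^3
}
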