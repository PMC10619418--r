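test_that("sample_run is deterministic under a fixed seed", {
  P <- build_transition_matrix("C1")
  set.seed(5)
  a <- sample_run(P, 200)
  set.seed(5)
  b <- sample_run(P, 200)
  expect_identical(a$states, b$states)
  set.seed(6)
  expect_false(identical(sample_run(P, 200)$states, a$states))
})

test_that("a zero-change matrix yields a constant sequence", {
  P <- build_transition_matrix(condition_setting("frozen", 0, 0))
  set.seed(1)
  run <- sample_run(P, 100)
  expect_equal(length(unique(run$states)), 1L)
})

test_that("the min-repetition rule forbids same-modality changes on consecutive transitions", {
  P <- build_transition_matrix("C1")
  set.seed(2)
  # pool several runs to reach ~1e5 trials
  for (i in 1:5) {
    run <- sample_run(P, 20000)
    ch <- run$obs[-1, ] != run$obs[-nrow(run$obs), ]
    consec <- ch[-1, ] & ch[-nrow(ch), ]
    expect_equal(sum(consec), 0L)
  }
})

test_that("unconstrained sampling matches the stationary-implied marginal", {
  P <- build_transition_matrix("C1")
  set.seed(3)
  run <- sample_run(P, 1e5, enforce_min_repetition = FALSE)
  ch <- run$obs[-1, ] != run$obs[-1e5, ]
  p0 <- 0.0875                       # eigenvector oracle marginal
  se <- sqrt(p0 * (1 - p0) / (1e5 - 1))
  for (m in 1:3) {
    expect_lt(abs(mean(ch[, m]) - p0), 3 * se)
  }
})

test_that("compute_stats counts transitions as specified", {
  # single-modality toy sequence L L H H H L in A; S and V constant
  obs <- cbind(A = c(0, 0, 1, 1, 1, 0), S = 0, V = 0)
  run <- run_from_obs(obs)
  st <- compute_stats(run, exclude_forced = FALSE)
  expect_equal(st$per_modality$p_change_overall[1], 2 / 5)
  expect_equal(st$per_modality$p_high[1], 3 / 6)
  # all-low run
  st0 <- compute_stats(run_from_obs(cbind(A = rep(0, 10), S = 0, V = 0)))
  expect_equal(st0$pooled$p_high, 0)
  # law of total probability on the same sample
  set.seed(4)
  run2 <- sample_run(build_transition_matrix("C1"), 400)
  s2 <- compute_stats(run2)
  pm <- s2$per_modality
  for (i in 1:3) {
    w <- pm$n_congruent[i] / (pm$n_congruent[i] + pm$n_incongruent[i])
    expect_equal(pm$p_change_overall[i],
                 w * pm$p_change_given_congruent[i] +
                   (1 - w) * pm$p_change_given_incongruent[i],
                 tolerance = 1e-12)
  }
})

test_that("empty context cells are flagged undefined, not zero", {
  # constant sequence: S and V never incongruent with each other... build a
  # run whose A context is always congruent (S = V throughout)
  obs <- cbind(A = c(0, 1, 1, 0, 0), S = c(0, 0, 0, 0, 0), V = c(0, 0, 0, 0, 0))
  st <- compute_stats(run_from_obs(obs), exclude_forced = FALSE)
  expect_true(is.nan(st$per_modality$p_change_given_incongruent[1]))
})

test_that("validate_stats applies the documented tolerance rules", {
  nominal <- function(pc, pi_, pall, ph) {
    structure(list(
      per_modality = data.frame(
        modality = MODALITIES, n_congruent = 500, n_incongruent = 500,
        p_change_given_congruent = pc, p_change_given_incongruent = pi_,
        p_change_overall = pall, p_high = ph),
      pooled = list(n_congruent = 1500, n_incongruent = 1500,
                    p_change_given_congruent = pc,
                    p_change_given_incongruent = pi_,
                    p_change_overall = pall, p_high = ph),
      exclude_forced = TRUE, n_runs = 1L), class = "sequence_stats")
  }
  cond <- condition_setting("C1")
  # exactly nominal -> pass
  expect_true(validate_stats(nominal(0.15, 0.025, 0.0875, 0.5), cond)$pass)
  # overall change deviating by 0.03 (> 0.025) -> fail on that check
  rep1 <- validate_stats(nominal(0.15, 0.025, 0.1175, 0.5), cond)
  expect_false(rep1$pass)
  failed <- rep1$checks[!rep1$checks$pass, ]
  expect_equal(failed$check, "change_overall")
  # conditional deviating by 0.004 (<= 0.005) -> pass
  expect_true(validate_stats(nominal(0.154, 0.025, 0.0875, 0.5), cond)$pass)
  # conditional deviating by 0.006 -> fail
  expect_false(validate_stats(nominal(0.156, 0.025, 0.0875, 0.5), cond)$pass)
  # intensity imbalance beyond 0.025 -> fail
  expect_false(validate_stats(nominal(0.15, 0.025, 0.0875, 0.53), cond)$pass)
  # per-modality mode exercises 12 checks
  repm <- validate_stats(nominal(0.15, 0.025, 0.0875, 0.5), cond,
                         tolerance_spec(per_modality = TRUE))
  expect_equal(nrow(repm$checks), 12L)
  # difference reading
  repd <- validate_stats(nominal(0.153, 0.028, 0.0875, 0.5), cond,
                         tolerance_spec(use_difference = TRUE))
  expect_true(repd$pass)   # difference 0.125 exactly
})

test_that("sample_valid_run returns a validated run and records attempts", {
  set.seed(8)
  run <- sample_valid_run("C1", 400)
  expect_true(run$report$pass)
  expect_gte(run$attempts, 1L)
  # re-validation of the returned run agrees
  expect_true(validate_stats(compute_stats(run), "C1")$pass)
  # tolerance widened to 1 accepts the first draw
  set.seed(8)
  easy <- sample_valid_run("C1", 400, tol = tolerance_spec(1, 1))
  expect_equal(easy$attempts, 1L)
})

test_that("sample_valid_run errors with the best report when attempts run out", {
  set.seed(9)
  err <- tryCatch(
    sample_valid_run("C1", 400, tol = tolerance_spec(1e-6, 1e-6),
                     max_attempts = 3L),
    error = function(e) e)
  expect_s3_class(err, "sampling_error")
  expect_match(conditionMessage(err), "3 attempts")
  expect_s3_class(err$best_report, "validation_report")
})

test_that("catch trials are unique, avoid trial 1, and balance modalities", {
  set.seed(10)
  ct <- place_catch_trials(400, 6)
  expect_equal(nrow(ct), 6L)
  expect_equal(anyDuplicated(ct$trial), 0L)
  expect_true(all(ct$trial >= 2 & ct$trial <= 400))
  expect_equal(as.integer(sort(table(ct$modality))), c(2L, 2L, 2L))
  set.seed(10)
  expect_identical(place_catch_trials(400, 6), ct)
  expect_error(place_catch_trials(5, 6), "smaller")
})

test_that("sessions are reproducible and honor explicit condition assignment", {
  s1 <- tiny_session(21, c("C1", "C1", "C2"))
  s2 <- tiny_session(21, c("C1", "C1", "C2"))
  expect_identical(s1$runs[[1]]$states, s2$runs[[1]]$states)
  expect_identical(s1$runs[[3]]$catch_trials, s2$runs[[3]]$catch_trials)
  expect_equal(s1$conditions, c("C1", "C1", "C2"))
  expect_equal(vapply(s1$runs, function(r) r$condition$id, ""),
               c("C1", "C1", "C2"))
  # byte-identical events TSV from identical seeds
  f1 <- tempfile(); f2 <- tempfile()
  write_events_tsv(build_session_events(s1), f1)
  write_events_tsv(build_session_events(s2), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("random condition assignment is uniform in expectation", {
  set.seed(30)
  # assignment only: draw many sessions' worth of labels the way
  # build_session does
  counts <- table(replicate(300, sample(c("C1", "C2", "C3"), 1)))
  phat <- counts / 300
  ci <- 1.96 * sqrt(1 / 3 * 2 / 3 / 300)
  expect_true(all(abs(phat - 1 / 3) < ci + 0.02))
})
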