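test_that("design matrices have the documented shape", {
  session <- tiny_session(60, c("C1", "C2"), n_trials = 400L)
  ev <- build_session_events(session)
  X <- build_design_matrix(ev, "modulator", n_volumes = 475L)
  expect_equal(nrow(X), 2L * 475L)
  expect_equal(length(attr(X, "task_cols")), 1L + 9L)
  expect_true(all(c("onset", "mismatch_A", "predictability_V") %in% colnames(X)))
  # per-run intercept + drift blocks
  expect_equal(length(attr(X, "nuisance_cols")), 2L * 3L)
  Xt <- build_design_matrix(ev, "trainbins", n_volumes = 475L)
  expect_equal(length(attr(Xt, "task_cols")), 18L + 1L)
})

test_that("a C3-only session drops the degenerate predictability columns", {
  s3 <- build_session(61, c("C3", "C3"), n_runs = 2L, n_trials = 60L,
                      tol = tolerance_spec(1, 1))
  ev <- build_session_events(s3)
  nv <- tiny_volumes()
  expect_warning(X <- build_design_matrix(ev, "modulator", n_volumes = nv),
                 "predictability")
  expect_false("predictability_A" %in% colnames(X))
  expect_error(build_design_matrix(ev, "modulator", n_volumes = nv,
                                   drop_degenerate = FALSE),
               "degenerate")
})

test_that("collinear designs raise an error naming the columns", {
  session <- tiny_session(62, "C1")
  ev <- build_session_events(session)
  nv <- tiny_volumes()
  X <- build_design_matrix(ev, "modulator", n_volumes = nv)
  dup <- cbind(unclass(X)[, ], copy = unclass(X)[, "mismatch_A"])
  expect_error(fit_glm(matrix(rnorm(nrow(dup)), ncol = 1), dup),
               "full rank")
})

test_that("OLS agrees with the closed-form solve on a random instance", {
  set.seed(63)
  X <- cbind(1, matrix(rnorm(20 * 4), 20, 4))
  colnames(X) <- paste0("c", 1:5)
  Y <- matrix(rnorm(20 * 2), 20, 2)
  fit <- fit_glm(Y, X, whitening = "none")
  oracle <- solve(t(X) %*% X) %*% t(X) %*% Y
  expect_lt(max(abs(fit$beta - oracle)), 1e-10)
  expect_equal(fit$df, 15L)
  # residuals orthogonal to the design
  expect_lt(max(abs(crossprod(X, fit$residuals))) / max(abs(Y)), 1e-8)
})

test_that("noiseless synthetic data recovers injected amplitudes to 1e-6", {
  session <- tiny_session(64, c("C1", "C2"))
  specs <- list(
    act = region_effect_spec("act", baseline_response = 1,
                             intensity_effect = c(A = 0.8, S = 0, V = 0),
                             mismatch_effect = c(A = 1, S = 0.3, V = 0),
                             misprediction_effect = c(A = 0, S = 0, V = 0.6)),
    null_1 = region_effect_spec("null_1"))
  d <- generate_dataset(session, specs, noise_spec(0, 0, 0),
                        n_volumes = tiny_volumes())
  ev <- do.call(rbind, d$events)
  Y <- do.call(rbind, d$bold)
  X <- build_design_matrix(ev, "modulator", n_volumes = tiny_volumes())
  fit <- fit_glm(Y, X, whitening = "none")
  truth <- c(mismatch_A = 1, mismatch_S = 0.3, intensity_A = 0.8,
             predictability_V = 0.6, mismatch_V = 0)
  for (w in names(truth)) {
    ct <- t_contrast(fit, setNames(1, w))
    expect_lt(abs(ct$estimate[ct$region == "act"] - truth[[w]]), 1e-6)
    expect_lt(abs(ct$estimate[ct$region == "null_1"]), 1e-6)
  }
})

test_that("t_contrast matches the textbook regression-slope t", {
  set.seed(65)
  x <- c(1.2, 2.3, 3.1, 4.8, 5.5, 6.1, 7.9, 8.2)
  y <- c(2.1, 2.9, 4.2, 5.1, 5.8, 7.2, 8.1, 9.3)
  X <- cbind(intercept = 1, slope = x)
  fit <- fit_glm(matrix(y, ncol = 1), X, whitening = "none")
  ct <- t_contrast(fit, c(slope = 1))
  # independent formula: t = r sqrt((n-2)/(1-r^2))
  r <- cor(x, y)
  expect_equal(ct$t, r * sqrt(6 / (1 - r^2)), tolerance = 1e-10)
  # zero contrast
  c0 <- t_contrast(fit, c(0, 0))
  expect_equal(c0$estimate, 0)
  expect_equal(c0$t, 0)
})

test_that("AR(1) prewhitening estimates rho and preserves recovery", {
  session <- tiny_session(66, "C1", n_trials = 400L)
  specs <- list(act = region_effect_spec("act", mismatch_effect = c(A = 1, S = 0, V = 0)),
                null_1 = region_effect_spec("null_1"))
  set.seed(66)
  d <- generate_dataset(session, specs, noise_spec(0.45, 0.6, 1),
                        n_volumes = 475L)
  X <- build_design_matrix(do.call(rbind, d$events), "modulator",
                           n_volumes = 475L)
  fit <- fit_glm(do.call(rbind, d$bold), X, whitening = "ar1")
  expect_gt(fit$rho, 0.3)
  ct <- t_contrast(fit, c(mismatch_A = 1))
  expect_lt(abs(ct$estimate[ct$region == "act"] - 1), 0.35)
})

test_that("train-length linear contrast uses sum-zero centered weights", {
  session <- tiny_session(67, c("C1", "C3"), n_trials = 400L)
  specs <- list(tr = region_effect_spec("tr", trainlength_slope = c(A = 0.2, S = 0, V = 0)),
                null_1 = region_effect_spec("null_1"))
  d <- generate_dataset(session, specs, noise_spec(0, 0, 0),
                        n_volumes = 475L)
  Xt <- build_design_matrix(do.call(rbind, d$events), "trainbins",
                            n_volumes = 475L)
  ft <- fit_glm(do.call(rbind, d$bold), Xt, whitening = "none")
  tl <- train_length_contrast(ft, "A")
  pb <- attr(tl, "per_bin")
  expect_equal(nrow(pb), 6L)
  # centered ramp: sums to zero, so equal bin estimates give contrast 0
  w <- (1:6) - 3.5
  expect_equal(sum(w), 0)
  expect_equal(tl$estimate[tl$region == "tr"],
               sum(w * pb[, "tr"]), tolerance = 1e-10)
  # noiseless slope recovery (normalized by the ramp's sum of squares)
  expect_lt(abs(tl$estimate[tl$region == "tr"] / sum(w * w) - 0.2), 1e-6)
  expect_lt(abs(tl$estimate[tl$region == "null_1"]), 1e-10)
  # missing bins re-center the remaining weights with a warning
  keep <- !grepl("dev_A_bin1$", rownames(ft$beta))
  ft2 <- ft
  ft2$beta <- ft$beta[keep, , drop = FALSE]
  ft2$XtXinv <- ft$XtXinv[keep, keep]
  expect_warning(tl2 <- train_length_contrast(ft2, "A"), "re-centered")
})

test_that("second level matches the one-sample t oracle", {
  est <- matrix(c(1.2, 0.8, 1.0, 1.4, 0.6), ncol = 1,
                dimnames = list(NULL, "r1"))
  g <- second_level(est)
  # hand formula: mean 1.0, sd sqrt(0.1), se sd/sqrt(5)
  expect_equal(g$estimate, 1.0)
  expect_equal(g$t, 1.0 / (sqrt(0.1) / sqrt(5)), tolerance = 1e-12)
  expect_equal(g$df, 4L)
  # degenerate: identical estimates
  same <- matrix(rep(0.7, 4), ncol = 1, dimnames = list(NULL, "r1"))
  gs <- second_level(same)
  expect_true(is.infinite(gs$t))
  expect_equal(attr(gs, "degenerate"), "r1")
  expect_error(second_level(est[1, , drop = FALSE]), "at least 2")
  # repeated-measures variant reduces over the modality dimension
  arr <- array(rnorm(5 * 3 * 2), c(5, 3, 2),
               dimnames = list(NULL, MODALITIES, c("r1", "r2")))
  gr <- second_level(arr, method = "repeated")
  expect_equal(gr$estimate, colMeans(apply(arr, c(1, 3), mean)),
               ignore_attr = TRUE)
})

test_that("conjunction against the global null uses the minimum statistic", {
  t1 <- data.frame(region = c("a", "b"), t = c(3, 1), df = 10)
  t2 <- data.frame(region = c("a", "b"), t = c(2, 4), df = 10)
  cj <- conjunction_global_null(list(t1, t2))
  expect_equal(cj$min_t, c(2, 1))
  # k identical maps: min-t equals the map
  cj2 <- conjunction_global_null(list(t1, t1))
  expect_equal(cj2$min_t, t1$t)
  # p = component upper-tail p of min-t raised to k
  expect_equal(cj$p, pt(c(2, 1), 10, lower.tail = FALSE)^2)
  # the global-null p is never smaller than the k-th power of the smallest
  # component p (equality when all components equal the minimum)
  expect_true(all(cj$p >= pt(c(3, 4), 10, lower.tail = FALSE)^2 - 1e-15))
  # monotonicity: adding a component can only decrease min-t
  t3 <- data.frame(region = c("a", "b"), t = c(0.5, 9), df = 10)
  cj3 <- conjunction_global_null(list(t1, t2, t3))
  expect_true(all(cj3$min_t <= cj$min_t))
  # mismatched df error
  t4 <- data.frame(region = c("a", "b"), t = c(1, 1), df = 8)
  expect_error(conjunction_global_null(list(t1, t4)), "df differ")
})

test_that("multiple comparison adjustment behaves as documented", {
  expect_equal(multiple_comparison_adjust(0.04), 0.04)     # m = 1
  expect_equal(multiple_comparison_adjust(c(0.01, 0.5)), c(0.02, 1))
  expect_equal(multiple_comparison_adjust(rep(0.01, 20))[1], 0.2)
  # permutation and Bonferroni agree in ordering on independent null data
  set.seed(68)
  est <- matrix(rnorm(12 * 6), 12, 6)
  tt <- abs(colMeans(est) / (apply(est, 2, sd) / sqrt(12)))
  p <- 2 * pt(tt, 11, lower.tail = FALSE)
  pp <- multiple_comparison_adjust(p, "permutation", estimates = est,
                                   n_perm = 2000)
  # both are monotone in the unadjusted p (permutation up to MC ties)
  expect_gte(cor(p, pp, method = "spearman"), 0.9)
})

test_that("contrasts are invariant to orthogonal nuisance columns", {
  set.seed(69)
  X <- cbind(1, matrix(rnorm(60 * 3), 60, 3))
  colnames(X) <- c("i", "a", "b", "c")
  y <- matrix(X %*% c(0.5, 1, -1, 0.2) + rnorm(60, sd = 0.1), ncol = 1)
  fit <- fit_glm(y, X, whitening = "none")
  ct <- t_contrast(fit, c(a = 1))
  # orthogonalize a new column against X, then refit
  z <- rnorm(60)
  z <- z - X %*% solve(crossprod(X)) %*% crossprod(X, z)
  X2 <- cbind(X, z = z)
  fit2 <- fit_glm(y, X2, whitening = "none")
  ct2 <- t_contrast(fit2, c(a = 1))
  expect_lt(abs(ct2$estimate - ct$estimate), 1e-8)
})
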