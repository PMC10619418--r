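#' Build a first-level design matrix
#'
#' Two variants, both with runs concatenated and per-run intercept + drift
#' blocks:
#' \describe{
#'   \item{modulator}{one onset regressor over all trials plus nine
#'     parametric modulators (intensity, mismatch, predictability for each
#'     modality), each modulator mean-centered across its run before
#'     convolution and \emph{not} serially orthogonalized.}
#'   \item{trainbins}{eighteen deviant regressors (six train-length bins by
#'     three modalities) plus one regressor for all remaining trials.}
#' }
#' Task regressors are convolved with the canonical HRF on the microtime
#' grid and sampled at the volume times.
#'
#' @param events event table covering one or more runs (column \code{run}).
#' @param variant \code{"modulator"} or \code{"trainbins"}.
#' @param hrf an \code{hrf_spec}.
#' @param n_volumes volumes per run.
#' @param tr repetition time (s).
#' @param drift_order polynomial drift order per run.
#' @param motion optional matrix of nuisance columns (total volumes x k).
#' @param drop_degenerate drop all-zero task columns (e.g. the
#'   predictability modulator of a C3-only session) with a warning instead
#'   of erroring.
#' @return Object of class \code{design_matrix}: the numeric matrix with
#'   attributes \code{task_cols}, \code{nuisance_cols}, \code{runs},
#'   \code{variant}, \code{dropped}.
#' @export
build_design_matrix <- function(events, variant = c("modulator", "trainbins"),
                                hrf = hrf_spec(), n_volumes = 475L, tr = 1.5,
                                drift_order = 2L, motion = NULL,
                                drop_degenerate = TRUE) {
  variant <- match.arg(variant)
  kernel <- canonical_hrf(hrf)
  dt <- hrf$dt
  vol_bins <- as.integer(round((seq_len(n_volumes) - 1L) * tr / dt)) + 1L
  n_micro <- max(vol_bins)
  runs <- sort(unique(events$run))
  # modulators are centered by their grand mean over all runs: the single
  # all-trials onset regressor then spans the removed component exactly
  mod_means <- list()
  if (variant == "modulator") {
    for (m in MODALITIES) {
      em <- events[events$modality == m, ]
      for (mod in c("intensity", "mismatch", "predictability")) {
        mod_means[[paste0(mod, "_", m)]] <- mean(em[[paste0("mod_", mod)]])
      }
    }
  }
  blocks <- vector("list", length(runs))
  for (ri in seq_along(runs)) {
    ev <- events[events$run == runs[ri], ]
    onset_bin <- function(e) as.integer(round(e$onset / dt)) + 1L
    conv_col <- function(bins, heights) {
      x <- numeric(n_micro)
      x[bins] <- x[bins] + heights
      convolve_hrf(x, kernel)[vol_bins]
    }
    cols <- list()
    if (variant == "modulator") {
      trials <- ev[ev$modality == "A", ]
      trials <- trials[order(trials$trial), ]
      tb <- onset_bin(trials)
      cols[["onset"]] <- conv_col(tb, rep(1, nrow(trials)))
      for (m in MODALITIES) {
        e <- ev[ev$modality == m, ]
        e <- e[order(e$trial), ]
        eb <- onset_bin(e)
        for (mod in c("intensity", "mismatch", "predictability")) {
          code <- e[[paste0("mod_", mod)]]
          code <- code - mod_means[[paste0(mod, "_", m)]]  # centered, not orthogonalized
          cols[[paste0(mod, "_", m)]] <- conv_col(eb, code)
        }
      }
    } else {
      is_binned_dev <- ev$role == "deviant" & !is.na(ev$train_bin)
      for (m in MODALITIES) {
        for (b in TRAIN_BIN_LEVELS) {
          sel <- ev$modality == m & is_binned_dev & ev$train_bin == b
          e <- ev[sel, ]
          nm <- paste0("dev_", m, "_bin", b)
          cols[[nm]] <- if (nrow(e) > 0L) {
            conv_col(onset_bin(e), rep(1, nrow(e)))
          } else {
            numeric(n_volumes)
          }
        }
      }
      # every trial-modality event not covered by a binned-deviant regressor
      rest <- ev[!is_binned_dev, ]
      rest <- rest[!duplicated(rest$trial), ]
      cols[["other_trials"]] <- conv_col(onset_bin(rest),
                                         rep(1, nrow(rest)))
    }
    task <- do.call(cbind, cols)
    db <- drift_basis(n_volumes, drift_order)
    nuis <- cbind(intercept = rep(1, n_volumes), db)
    colnames(nuis) <- c("intercept",
                        if (drift_order >= 1L) paste0("drift", seq_len(drift_order)))
    blocks[[ri]] <- list(task = task, nuis = nuis)
  }
  task <- do.call(rbind, lapply(blocks, `[[`, "task"))
  nuis_list <- lapply(seq_along(blocks), function(i) blocks[[i]]$nuis)
  nuis <- matrix(0, nrow(task), length(runs) * ncol(nuis_list[[1L]]))
  nn <- character(0)
  for (i in seq_along(runs)) {
    rows <- (i - 1L) * n_volumes + seq_len(n_volumes)
    cols_i <- (i - 1L) * ncol(nuis_list[[1L]]) + seq_len(ncol(nuis_list[[1L]]))
    nuis[rows, cols_i] <- nuis_list[[i]]
    nn <- c(nn, paste0("run", runs[i], "_", colnames(nuis_list[[1L]])))
  }
  colnames(nuis) <- nn
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == nrow(task))
    if (is.null(colnames(motion))) {
      colnames(motion) <- paste0("motion", seq_len(ncol(motion)))
    }
    nuis <- cbind(nuis, motion)
  }
  dropped <- character(0)
  zero <- apply(task, 2L, function(x) all(abs(x) < 1e-12))
  if (any(zero)) {
    dropped <- colnames(task)[zero]
    if (!drop_degenerate) {
      stop("degenerate (all-zero) task columns: ",
           paste(dropped, collapse = ", "))
    }
    warning("dropping degenerate task column(s): ",
            paste(dropped, collapse = ", "))
    task <- task[, !zero, drop = FALSE]
  }
  X <- cbind(task, nuis)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  structure(X, class = c("design_matrix", "matrix"),
            task_cols = colnames(task), nuisance_cols = colnames(nuis),
            runs = runs, n_volumes = as.integer(n_volumes),
            variant = variant, dropped = dropped)
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix (%s): %d volumes x %d regressors (%d task)\n",
              attr(x, "variant"), nrow(x), ncol(x),
              length(attr(x, "task_cols"))))
  invisible(x)
}

#' Write a design matrix as TSV
#' @param X a \code{design_matrix}.
#' @param path output file.
#' @export
write_design_tsv <- function(X, path) {
  utils::write.table(as.data.frame(unclass(X)[, ]), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

ar1_whiten <- function(M, rho, run_id) {
  W <- M
  for (r in unique(run_id)) {
    rows <- which(run_id == r)
    Wr <- M[rows, , drop = FALSE]
    n <- length(rows)
    Wr[2:n, ] <- Wr[2:n, , drop = FALSE] - rho * Wr[1:(n - 1L), , drop = FALSE]
    Wr[1L, ] <- sqrt(1 - rho^2) * Wr[1L, , drop = FALSE]
    W[rows, ] <- Wr
  }
  W
}

#' Fit the mass-univariate GLM
#'
#' Ordinary least squares per region, optionally after AR(1) prewhitening
#' with a single coefficient per run estimated from the lag-1 autocorrelation
#' of the pooled OLS residuals.
#'
#' @param Y numeric matrix, volumes x regions (runs stacked in the same
#'   order as the design).
#' @param X a \code{design_matrix} (or plain full-rank matrix).
#' @param whitening \code{"ar1"} (default) or \code{"none"}.
#' @return Object of class \code{glm_fit}: list with \code{beta}
#'   (regressors x regions), \code{sigma2}, \code{df}, \code{XtXinv},
#'   \code{whitening}, \code{rho}, \code{X}, \code{residuals}.
#' @export
fit_glm <- function(Y, X, whitening = c("ar1", "none")) {
  whitening <- match.arg(whitening)
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("region", seq_len(ncol(Y)))
  if (!all(is.finite(Y))) stop("non-finite values in the data")
  if (!all(is.finite(X))) stop("non-finite values in the design")
  stopifnot(nrow(Y) == nrow(X))
  n_volumes <- attr(X, "n_volumes") %||% nrow(X)
  run_id <- rep(seq_len(nrow(X) / n_volumes), each = n_volumes)
  Xm <- unclass(X)[, , drop = FALSE]
  ols <- function(Xw, Yw) {
    qrX <- qr(Xw)
    if (qrX$rank < ncol(Xw)) stop("design not full rank")
    beta <- qr.coef(qrX, Yw)
    res <- Yw - Xw %*% beta
    df <- nrow(Xw) - ncol(Xw)
    list(beta = beta, res = res, df = df,
         XtXinv = solve(crossprod(Xw)))
  }
  fit <- ols(Xm, Y)
  rho <- 0
  if (whitening == "ar1") {
    num <- den <- 0
    for (r in unique(run_id)) {
      res_r <- fit$res[run_id == r, , drop = FALSE]
      n <- nrow(res_r)
      num <- num + sum(res_r[-1L, ] * res_r[-n, ])
      den <- den + sum(res_r[-n, ]^2)
    }
    rho <- if (den > 0) num / den else 0
    rho <- max(min(rho, 0.95), -0.95)
    Xw <- ar1_whiten(Xm, rho, run_id)
    Yw <- ar1_whiten(Y, rho, run_id)
    fit <- ols(Xw, Yw)
  }
  sigma2 <- colSums(fit$res^2) / fit$df
  structure(list(beta = fit$beta, sigma2 = sigma2, df = fit$df,
                 XtXinv = fit$XtXinv, whitening = whitening, rho = rho,
                 X = Xm, run_id = run_id, residuals = fit$res),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("glm_fit: %d regressors x %d regions, df = %d, whitening = %s (rho = %.3f)\n",
              nrow(x$beta), ncol(x$beta), x$df, x$whitening, x$rho))
  invisible(x)
}

#' t contrast on a fitted GLM
#'
#' @param fit a \code{glm_fit}.
#' @param weights contrast vector, either full length or named over a subset
#'   of regressors (others 0).
#' @param alternative \code{"two.sided"} (default), \code{"greater"},
#'   \code{"less"}.
#' @return Object of class \code{contrast_result}: data frame with region,
#'   estimate, se, t, p, df. Zero-residual-variance regions get \code{NA}
#'   t and p and are flagged in the \code{degenerate} attribute.
#' @export
t_contrast <- function(fit, weights,
                       alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  p <- nrow(fit$beta)
  if (!is.null(names(weights)) && length(weights) < p) {
    w <- stats::setNames(numeric(p), rownames(fit$beta))
    miss <- setdiff(names(weights), names(w))
    if (length(miss)) stop("unknown regressor(s): ", paste(miss, collapse = ", "))
    w[names(weights)] <- weights
    weights <- w
  }
  if (length(weights) != p) stop("contrast length must equal #betas (", p, ")")
  est <- drop(crossprod(weights, fit$beta))
  cvc <- drop(crossprod(weights, fit$XtXinv %*% weights))
  se <- sqrt(fit$sigma2 * cvc)
  tval <- ifelse(se > 0, est / se, ifelse(est == 0, 0, NA_real_))
  pval <- switch(alternative,
    two.sided = 2 * stats::pt(abs(tval), fit$df, lower.tail = FALSE),
    greater = stats::pt(tval, fit$df, lower.tail = FALSE),
    less = stats::pt(tval, fit$df))
  out <- data.frame(region = colnames(fit$beta), estimate = est, se = se,
                    t = tval, p = pval, df = fit$df, row.names = NULL)
  structure(out, class = c("contrast_result", "data.frame"),
            degenerate = colnames(fit$beta)[se == 0 & est != 0],
            alternative = alternative)
}

#' Linear train-length contrast
#'
#' Applies a centered linear ramp over the six train-length bins of one
#' modality (weights \code{(1:6) - 3.5}, summing to zero). Bins whose
#' regressor was dropped (no deviants observed) are removed and the
#' remaining weights re-centered, with a warning.
#'
#' @param fit a \code{glm_fit} of the trainbins design.
#' @param modality one of A, S, V.
#' @return A \code{contrast_result}; attribute \code{per_bin} holds the
#'   per-bin estimates (bins x regions) for train-length profile plots.
#' @export
train_length_contrast <- function(fit, modality) {
  modality <- match.arg(modality, MODALITIES)
  bins <- paste0("dev_", modality, "_bin", TRAIN_BIN_LEVELS)
  present <- bins %in% rownames(fit$beta)
  if (!all(present)) {
    warning("missing train-length bin(s) ",
            paste(bins[!present], collapse = ", "),
            "; weights re-centered over remaining bins")
  }
  idx <- seq_along(TRAIN_BIN_LEVELS)[present]
  w <- idx - mean(idx)
  weights <- stats::setNames(w, bins[present])
  out <- t_contrast(fit, weights)
  attr(out, "per_bin") <- fit$beta[bins[present], , drop = FALSE]
  out
}

#' Second-level (group) test of subject contrast estimates
#'
#' One-sample t test across subjects per region, or a repeated-measures
#' variant testing the mean across modality-specific estimates with subjects
#' as blocks.
#'
#' @param estimates subjects x regions matrix of first-level contrast
#'   estimates; for \code{method = "repeated"}, a 3-dimensional array
#'   subjects x modalities x regions.
#' @param method \code{"one_sample"} or \code{"repeated"}.
#' @param alternative passed to the t test.
#' @return A \code{contrast_result}-like data frame (region, estimate, se,
#'   t, p, df). Identical estimates across subjects give infinite t, flagged
#'   via the \code{degenerate} attribute.
#' @export
second_level <- function(estimates, method = c("one_sample", "repeated"),
                         alternative = c("two.sided", "greater", "less")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (method == "repeated") {
    stopifnot(length(dim(estimates)) == 3L)
    estimates <- apply(estimates, c(1L, 3L), mean)  # subject means over modalities
  }
  estimates <- as.matrix(estimates)
  n <- nrow(estimates)
  if (n < 2L) stop("second level needs at least 2 subjects")
  m <- colMeans(estimates)
  se <- apply(estimates, 2L, stats::sd) / sqrt(n)
  tval <- ifelse(se > 0, m / se, ifelse(m == 0, 0, Inf))
  df <- n - 1L
  pval <- switch(alternative,
    two.sided = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
    greater = stats::pt(tval, df, lower.tail = FALSE),
    less = stats::pt(tval, df))
  out <- data.frame(region = colnames(estimates) %||% seq_len(ncol(estimates)),
                    estimate = m, se = se, t = tval, p = pval, df = df,
                    row.names = NULL)
  structure(out, class = c("contrast_result", "data.frame"),
            degenerate = out$region[!is.finite(tval) | se == 0],
            alternative = alternative)
}

#' Minimum-statistic conjunction against the global null
#'
#' The conjunction statistic per region is the minimum over the k component
#' t values; under independent components its upper-tail p value is the k-th
#' power of the component upper-tail p of the minimum. A sign-flip
#' permutation option covers dependent components.
#'
#' @param tmats matrix of component t values (regions x k) or list of
#'   \code{contrast_result}s with equal df.
#' @param df error degrees of freedom (taken from the contrast results if
#'   given there).
#' @param method \code{"independence"} (default) or \code{"permutation"}.
#' @param estimates for \code{method = "permutation"}: list of k
#'   subjects x regions matrices of first-level estimates.
#' @param n_perm permutation draws.
#' @return Object of class \code{conjunction_result}: data frame with
#'   region, min_t, p.
#' @export
conjunction_global_null <- function(tmats, df = NULL,
                                    method = c("independence", "permutation"),
                                    estimates = NULL, n_perm = 2000L) {
  method <- match.arg(method)
  if (is.list(tmats) && !is.data.frame(tmats) && !is.matrix(tmats)) {
    dfs <- vapply(tmats, function(x) x$df[1L], 1)
    if (length(unique(dfs)) != 1L) stop("component df differ")
    df <- dfs[1L]
    regions <- tmats[[1L]]$region
    tmats <- do.call(cbind, lapply(tmats, function(x) x$t))
    rownames(tmats) <- regions
  }
  tmats <- as.matrix(tmats)
  k <- ncol(tmats)
  min_t <- apply(tmats, 1L, min)
  if (method == "independence") {
    if (is.null(df)) stop("df required")
    p <- stats::pt(min_t, df, lower.tail = FALSE)^k
  } else {
    if (is.null(estimates)) stop("permutation needs subject-level estimates")
    n <- nrow(estimates[[1L]])
    min_obs <- min_t
    exceed <- numeric(length(min_t))
    one_t <- function(E, signs) {
      Es <- E * signs
      m <- colMeans(Es)
      se <- apply(Es, 2L, stats::sd) / sqrt(n)
      m / se
    }
    for (b in seq_len(n_perm)) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      tperm <- do.call(cbind, lapply(estimates, one_t, signs = signs))
      mt <- apply(tperm, 1L, min)
      exceed <- exceed + (max(mt) >= min_obs)  # max over regions: FWE-style null
    }
    p <- (exceed + 1) / (n_perm + 1)
  }
  out <- data.frame(region = rownames(tmats) %||% seq_along(min_t),
                    min_t = min_t, p = p, row.names = NULL)
  structure(out, class = c("conjunction_result", "data.frame"),
            k = k, method = method)
}

#' Family-wise error adjustment across regions
#'
#' @param p vector of per-region p values, or (for permutation) observed t
#'   values via \code{t_obs} plus subject estimates.
#' @param method \code{"bonferroni"} or \code{"permutation"} (sign-flip
#'   max-statistic across regions).
#' @param estimates subjects x regions matrix (permutation only).
#' @param n_perm permutation draws.
#' @return Adjusted p values.
#' @export
multiple_comparison_adjust <- function(p, method = c("bonferroni", "permutation"),
                                       estimates = NULL, n_perm = 2000L) {
  method <- match.arg(method)
  if (method == "bonferroni") {
    return(pmin(1, length(p) * p))
  }
  if (is.null(estimates)) stop("permutation needs subject-level estimates")
  estimates <- as.matrix(estimates)
  n <- nrow(estimates)
  m <- colMeans(estimates)
  se <- apply(estimates, 2L, stats::sd) / sqrt(n)
  t_obs <- abs(m / se)
  maxnull <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    signs <- sample(c(-1, 1), n, replace = TRUE)
    Es <- estimates * signs
    mb <- colMeans(Es)
    seb <- apply(Es, 2L, stats::sd) / sqrt(n)
    maxnull[b] <- max(abs(mb / seb))
  }
  vapply(t_obs, function(t0) (sum(maxnull >= t0) + 1) / (n_perm + 1), 1)
}
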