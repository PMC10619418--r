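#' Extract a seed time series from a BOLD dataset
#'
#' Mean over the named region(s), per run.
#'
#' @param dataset a \code{bold_dataset}.
#' @param region region name or character vector of regions to average
#'   (the region-level analogue of a sphere).
#' @param scale variance-normalize each run's series.
#' @return List of per-run numeric vectors.
#' @export
extract_seed_timeseries <- function(dataset, region, scale = FALSE) {
  stopifnot(inherits(dataset, "bold_dataset"))
  known <- colnames(dataset$bold[[1L]])
  if (!all(region %in% known)) {
    stop("unknown region(s): ", paste(setdiff(region, known), collapse = ", "))
  }
  lapply(dataset$bold, function(y) {
    s <- rowMeans(y[, region, drop = FALSE])
    if (scale) s <- s / stats::sd(s)
    s
  })
}

.deconv_cache <- new.env(parent = emptyenv())

# observation-space ridge deconvolution of a volume-sampled series through
# the HRF convolution operator; lambda chosen by generalized cross-validation.
# The operator eigendecomposition depends only on (n, kernel) and is cached.
deconvolve_ridge <- function(y, kernel_tr, lambdas = 10^seq(-4, 2, length.out = 25)) {
  n <- length(y)
  key <- paste(n, length(kernel_tr),
               format(sum(kernel_tr * seq_along(kernel_tr)), digits = 15))
  if (!is.null(.deconv_cache[[key]])) {
    cached <- .deconv_cache[[key]]
    C <- cached$C
    e <- cached$e
  } else {
    C <- matrix(0, n, n)
    k <- kernel_tr
    for (i in seq_len(n)) {
      j <- i:min(n, i + length(k) - 1L)
      C[j, i] <- k[seq_along(j)]
    }
    # x_hat = C' (CC' + lambda I)^-1 y via eigen decomposition of CC'
    e <- eigen(tcrossprod(C), symmetric = TRUE)
    .deconv_cache[[key]] <- list(C = C, e = e)
  }
  z <- crossprod(e$vectors, y)
  best <- NULL
  best_gcv <- Inf
  for (lam in lambdas) {
    d <- e$values / (e$values + lam)
    # orthonormal basis: residual norm computable in coefficient space
    gcv <- sum(((1 - d) * z)^2) / (n - sum(d))^2
    if (gcv < best_gcv) {
      best_gcv <- gcv
      best <- lam
    }
  }
  alpha <- e$vectors %*% (z / (e$values + best))
  x <- drop(crossprod(C, alpha))
  list(x = x, lambda = best)
}

#' Build PPI regressors for one seed and modality
#'
#' The psychological regressor is the modality's +1/-1 deviant/standard code
#' convolved to the volume grid and mean-centered. The physiological
#' regressor is the centered seed series. The interaction is either the
#' element-wise BOLD-level product (\code{mode = "bold_product"}) or, closer
#' to SPM's PPI, formed at the neural level (\code{mode = "deconvolved"}):
#' the seed is ridge-deconvolved through the HRF (regularization by GCV),
#' multiplied by the trial-level psychological impulses, and re-convolved.
#'
#' @param seed_run seed series of one run (volumes).
#' @param events_run event table of that run.
#' @param modality modality whose mismatch code defines the psychological
#'   variable.
#' @param mode \code{"deconvolved"} (default) or \code{"bold_product"}.
#' @param hrf an \code{hrf_spec}.
#' @param tr repetition time (s).
#' @return List with \code{physiological}, \code{psychological},
#'   \code{interaction} (all length \code{n_volumes}) and \code{lambda}
#'   (deconvolved mode).
#' @export
build_ppi_regressors <- function(seed_run, events_run, modality,
                                 mode = c("deconvolved", "bold_product"),
                                 hrf = hrf_spec(), tr = 1.5) {
  mode <- match.arg(mode)
  modality <- match.arg(modality, MODALITIES)
  n <- length(seed_run)
  dt <- hrf$dt
  kernel <- canonical_hrf(hrf)
  vol_bins <- as.integer(round((seq_len(n) - 1L) * tr / dt)) + 1L
  n_micro <- max(vol_bins)
  e <- events_run[events_run$modality == modality, ]
  e <- e[order(e$trial), ]
  if (!any(e$mod_mismatch > 0)) {
    stop("degenerate psychological vector: no deviants for modality ",
         modality)
  }
  psych_micro <- numeric(n_micro)
  bins <- as.integer(round(e$onset / dt)) + 1L
  psych_micro[bins] <- e$mod_mismatch
  psych_vol <- convolve_hrf(psych_micro, kernel)[vol_bins]
  psych_vol <- psych_vol - mean(psych_vol)
  physio <- seed_run - mean(seed_run)
  lambda <- NA_real_
  if (mode == "bold_product") {
    interaction <- physio * psych_vol
  } else {
    kernel_tr <- convolve_hrf(c(1, numeric(n_micro - 1L)), kernel)[vol_bins]
    kernel_tr <- kernel_tr[seq_len(min(n, ceiling(hrf$duration / tr) + 1L))]
    dec <- deconvolve_ridge(physio, kernel_tr)
    lambda <- dec$lambda
    # neural-level product: expand the deconvolved (TR-grid) neural estimate
    # to microtime, gate it with the trial impulses, re-convolve
    neural_micro <- stats::approx(vol_bins, dec$x, xout = seq_len(n_micro),
                                  rule = 2L)$y
    inter_micro <- numeric(n_micro)
    inter_micro[bins] <- neural_micro[bins] * e$mod_mismatch
    interaction <- convolve_hrf(inter_micro, kernel)[vol_bins]
  }
  interaction <- interaction - mean(interaction)
  list(physiological = physio, psychological = psych_vol,
       interaction = interaction, mode = mode, lambda = lambda)
}

#' Fit a PPI model across target regions
#'
#' Per run, builds the PPI regressors for the seed and modality and fits a
#' first-level GLM on every target region containing the interaction, the
#' seed's physiological signal, and all task regressors of the modulator
#' design (which include the psychological mismatch regressor), plus per-run
#' intercept/drift.
#'
#' @param dataset a \code{bold_dataset}.
#' @param seed seed region name.
#' @param modality modality of the psychological variable.
#' @param mode interaction construction, see
#'   \code{\link{build_ppi_regressors}}.
#' @param targets target region names (default: all regions except the
#'   seed).
#' @param hrf,drift_order design options.
#' @param whitening passed to \code{\link{fit_glm}}.
#' @param X_task optional precomputed modulator \code{design_matrix} for the
#'   dataset's events (avoids rebuilding it in repeated fits).
#' @return Object of class \code{ppi_result}: data frame (seed, target,
#'   beta_ppi, se, t, p, df) with the fitted \code{glm_fit} in attribute
#'   \code{fit}.
#' @export
fit_ppi <- function(dataset, seed, modality,
                    mode = c("deconvolved", "bold_product"),
                    targets = NULL, hrf = hrf_spec(), drift_order = 2L,
                    whitening = "ar1", X_task = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "bold_dataset"))
  regions <- colnames(dataset$bold[[1L]])
  if (is.null(targets)) targets <- setdiff(regions, seed)
  seed_series <- extract_seed_timeseries(dataset, seed)
  if (is.null(X_task)) {
    events <- do.call(rbind, dataset$events)
    X_task <- build_design_matrix(events, variant = "modulator", hrf = hrf,
                                  n_volumes = dataset$n_volumes,
                                  tr = dataset$tr, drift_order = drift_order)
  }
  ppi_cols <- lapply(seq_along(dataset$bold), function(r) {
    reg <- build_ppi_regressors(seed_series[[r]], dataset$events[[r]],
                                modality, mode = mode, hrf = hrf,
                                tr = dataset$tr)
    cbind(ppi_interaction = reg$interaction, seed_physio = reg$physiological)
  })
  ppi_block <- do.call(rbind, ppi_cols)
  X <- cbind(ppi_block, unclass(X_task)[, ])
  attr(X, "n_volumes") <- dataset$n_volumes
  Y <- do.call(rbind, dataset$bold)[, targets, drop = FALSE]
  fit <- fit_glm(Y, X, whitening = whitening)
  cr <- t_contrast(fit, c(ppi_interaction = 1))
  out <- data.frame(seed = seed, modality = modality, target = cr$region,
                    beta_ppi = cr$estimate, se = cr$se, t = cr$t, p = cr$p,
                    df = cr$df, row.names = NULL)
  structure(out, class = c("ppi_result", "data.frame"), fit = fit,
            mode = mode)
}
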