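#' Canonical double-gamma HRF specification
#'
#' @param peak_delay response gamma mode parameter (shape * dispersion, s).
#' @param undershoot_delay undershoot gamma parameter (s).
#' @param peak_disp,undershoot_disp dispersions (s).
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param duration kernel support (s).
#' @param dt microtime step (s); both the 1.75 s ISI and the 1.5 s TR are
#'   multiples of the default 0.05 s.
#' @return Object of class \code{hrf_spec}.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_disp = 1, undershoot_disp = 1,
                     ratio = 6, duration = 32, dt = 0.05) {
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                 ratio = ratio, duration = duration, dt = dt),
            class = "hrf_spec")
}

#' Sample the canonical HRF on the microtime grid
#'
#' Difference of two gamma densities (response minus scaled undershoot),
#' normalized to peak amplitude 1. With the default parameters the mode sits
#' at 5 s and the undershoot minimum near 15--16 s.
#'
#' @param spec an \code{hrf_spec}.
#' @return Numeric kernel sampled at \code{seq(0, duration, by = dt)}, with
#'   attributes \code{dt} and \code{time}.
#' @export
canonical_hrf <- function(spec = hrf_spec()) {
  t <- seq(0, spec$duration, by = spec$dt)
  h <- stats::dgamma(t, shape = spec$peak_delay / spec$peak_disp,
                     rate = 1 / spec$peak_disp) -
    stats::dgamma(t, shape = spec$undershoot_delay / spec$undershoot_disp,
                  rate = 1 / spec$undershoot_disp) / spec$ratio
  h <- h / max(h)
  structure(h, dt = spec$dt, time = t)
}

#' Ground-truth effect specification of one region
#'
#' Amplitudes are in arbitrary BOLD units per unit modulator code. Modality
#' amplitudes may be a single number (shared across A/S/V) or a named
#' 3-vector.
#'
#' @param name region label.
#' @param baseline_response impulse height common to every trial.
#' @param intensity_effect,mismatch_effect,misprediction_effect per-modality
#'   amplitudes multiplying the signed modulator codes.
#' @param trainlength_slope per-modality slope on the centered train-bin
#'   index (deviants with a binned train only).
#' @param ppi_seed,ppi_coupling_base,ppi_coupling_mismatch optional coupling
#'   of this region to a seed region's neural signal: constant coupling plus
#'   a component gated by the seed modality's mismatch code
#'   (\code{ppi_modality}).
#' @param ppi_modality modality whose deviant/standard code modulates the
#'   coupling.
#' @return Object of class \code{region_effect_spec}.
#' @export
region_effect_spec <- function(name, baseline_response = 0,
                               intensity_effect = 0, mismatch_effect = 0,
                               trainlength_slope = 0,
                               misprediction_effect = 0,
                               ppi_seed = NULL, ppi_coupling_base = 0,
                               ppi_coupling_mismatch = 0,
                               ppi_modality = "A") {
  expand <- function(x) {
    if (length(x) == 1L) x <- stats::setNames(rep(as.numeric(x), 3L), MODALITIES)
    stopifnot(length(x) == 3L, all(is.finite(x)))
    if (is.null(names(x))) names(x) <- MODALITIES
    x[MODALITIES]
  }
  structure(list(name = name,
                 baseline_response = baseline_response,
                 intensity_effect = expand(intensity_effect),
                 mismatch_effect = expand(mismatch_effect),
                 trainlength_slope = expand(trainlength_slope),
                 misprediction_effect = expand(misprediction_effect),
                 ppi_seed = ppi_seed,
                 ppi_coupling_base = ppi_coupling_base,
                 ppi_coupling_mismatch = ppi_coupling_mismatch,
                 ppi_modality = match.arg(ppi_modality, MODALITIES)),
            class = "region_effect_spec")
}

#' Noise specification for synthetic BOLD
#'
#' AR(1) noise plus polynomial drift. Drift regression coefficients are drawn
#' per run and region as N(0, drift_sd^2) on Legendre-like centered
#' polynomial terms of orders 1..drift_order.
#'
#' @param rho AR(1) coefficient, |rho| < 1.
#' @param sigma innovation standard deviation (> 0, or 0 for noiseless).
#' @param drift_order polynomial drift order (0 disables drift).
#' @param drift_sd standard deviation of the random drift amplitudes.
#' @return Object of class \code{noise_spec}.
#' @export
noise_spec <- function(rho = 0.3, sigma = 1, drift_order = 2, drift_sd = 0.5) {
  stopifnot(abs(rho) < 1, sigma >= 0, drift_order >= 0, drift_sd >= 0)
  structure(list(rho = rho, sigma = sigma, drift_order = drift_order,
                 drift_sd = drift_sd), class = "noise_spec")
}

#' Default region map of the synthetic dataset
#'
#' Twenty regions: six sensory-specific mismatch regions (bilateral A/S/V),
#' four shared fronto-parietal mismatch regions, one IPS-like misprediction
#' region, three PPI target regions coupled to the left sensory seeds, and
#' six null regions for type-I checks. Amplitudes are the package's stated
#' default-SNR world (see the methods vignette).
#'
#' @return Named list of \code{region_effect_spec}s.
#' @export
default_region_specs <- function() {
  one_hot <- function(m, a) stats::setNames(ifelse(MODALITIES == m, a, 0),
                                            MODALITIES)
  specs <- list()
  for (m in MODALITIES) {
    for (side in c("left", "right")) {
      nm <- sprintf("%s1_%s", m, side)
      specs[[nm]] <- region_effect_spec(
        nm, baseline_response = 1,
        intensity_effect = one_hot(m, 0.8),
        mismatch_effect = one_hot(m, 1.0),
        trainlength_slope = one_hot(m, 0.2))
    }
  }
  for (nm in c("IFG_left", "IFG_right", "TPJ_left", "TPJ_right")) {
    specs[[nm]] <- region_effect_spec(
      nm, baseline_response = 1, mismatch_effect = 0.8,
      trainlength_slope = 0.15)
  }
  specs[["IPS"]] <- region_effect_spec(
    "IPS", baseline_response = 1, mismatch_effect = 0.5,
    misprediction_effect = 0.6)
  for (m in MODALITIES) {
    nm <- sprintf("PPI_target_%s", m)
    specs[[nm]] <- region_effect_spec(
      nm, baseline_response = 0.5,
      ppi_seed = sprintf("%s1_left", m),
      ppi_coupling_base = 0.8, ppi_coupling_mismatch = 0.6,
      ppi_modality = m)
  }
  for (k in 1:6) {
    nm <- sprintf("null_%d", k)
    specs[[nm]] <- region_effect_spec(nm)
  }
  specs
}

# trial-level impulse heights for one run and effect spec
trial_impulses <- function(events_run, effect) {
  mods <- split(events_run, events_run$modality)
  n <- max(events_run$trial)
  h <- rep(effect$baseline_response, n)
  for (m in MODALITIES) {
    e <- mods[[m]]
    e <- e[order(e$trial), ]
    h <- h + e$mod_intensity * effect$intensity_effect[[m]] +
      e$mod_mismatch * effect$mismatch_effect[[m]] +
      e$mod_predictability * effect$misprediction_effect[[m]]
    if (effect$trainlength_slope[[m]] != 0) {
      binned <- !is.na(e$train_bin) & e$role == "deviant"
      centered <- match(e$train_bin, TRAIN_BIN_LEVELS) - 3.5
      h[binned] <- h[binned] +
        centered[binned] * effect$trainlength_slope[[m]]
    }
  }
  h
}

#' Neural impulse series of one region on the microtime grid
#'
#' Places one impulse per trial at the trial onsets, with height
#' baseline + sum over modalities of the signed modulator codes times the
#' region's amplitudes (train-length term on binned deviants only). Linear in
#' all amplitudes.
#'
#' @param events_run event table of a single run.
#' @param effect a \code{region_effect_spec}.
#' @param n_microtime length of the microtime grid.
#' @param dt microtime step (s).
#' @return Numeric vector of length \code{n_microtime}.
#' @export
build_neural_signal <- function(events_run, effect, n_microtime, dt = 0.05) {
  onsets <- sort(unique(events_run$onset))
  bins <- onsets / dt
  if (any(abs(bins - round(bins)) > 1e-8)) {
    stop("trial onsets must lie on the microtime grid (dt = ", dt, " s)")
  }
  bins <- as.integer(round(bins)) + 1L
  if (any(bins > n_microtime)) stop("onset beyond the run's microtime grid")
  h <- trial_impulses(events_run, effect)
  x <- numeric(n_microtime)
  x[bins] <- h
  x
}

.fft_cache <- new.env(parent = emptyenv())

# causal convolution truncated to the input length; FFT on a padded
# power-of-two length (raw n + kernel lengths here factor badly), with the
# kernel transform cached per (length, kernel) pair
convolve_hrf <- function(x, kernel) {
  n <- length(x)
  m <- length(kernel)
  L <- stats::nextn(n + m - 1L, 2L)
  key <- paste(L, m, format(sum(kernel * seq_len(m)), digits = 15))
  kf <- .fft_cache[[key]]
  if (is.null(kf)) {
    kf <- stats::fft(c(as.numeric(kernel), numeric(L - m)))
    .fft_cache[[key]] <- kf
  }
  xf <- stats::fft(c(x, numeric(L - n)))
  Re(stats::fft(xf * kf, inverse = TRUE))[seq_len(n)] / L
}

# AR(1) noise with stationary start
ar1_noise <- function(n, rho, sigma) {
  if (sigma == 0) return(numeric(n))
  innov <- stats::rnorm(n, sd = sigma)
  x <- stats::filter(innov, rho, method = "recursive",
                     init = stats::rnorm(1L, sd = sigma / sqrt(1 - rho^2)))
  as.numeric(x)
}

# centered polynomial drift basis (volumes x order), no intercept column
drift_basis <- function(n_volumes, order) {
  if (order < 1L) return(matrix(0, n_volumes, 0L))
  t <- seq_len(n_volumes)
  stats::poly(t, degree = order, raw = FALSE) * sqrt(n_volumes)
}

#' Generate a synthetic region-level BOLD dataset
#'
#' For every run and region: build the neural impulse series, add any PPI
#' coupling to the seed region at the neural level (constant plus
#' mismatch-gated product, before convolution), convolve with the canonical
#' HRF on the microtime grid, sample at the volume acquisition times
#' (\code{k * TR}), and add polynomial drift and AR(1) noise.
#'
#' @param session an (annotated) \code{session}; event tables are built on
#'   the fly.
#' @param region_specs named list of \code{region_effect_spec}s.
#' @param noise a \code{noise_spec}.
#' @param n_volumes volumes per run (default 475).
#' @param tr repetition time (s, default 1.5).
#' @param isi inter-stimulus interval (s, default 1.75).
#' @param hrf an \code{hrf_spec}.
#' @return Object of class \code{bold_dataset}: list with \code{bold}
#'   (list per run of volumes x regions matrices), \code{neural} (noiseless
#'   BOLD, same layout), \code{events} (list per run), \code{region_specs},
#'   \code{noise}, \code{tr}, \code{n_volumes}, \code{hrf}.
#' @export
generate_dataset <- function(session, region_specs = default_region_specs(),
                             noise = noise_spec(), n_volumes = 475L,
                             tr = 1.5, isi = 1.75, hrf = hrf_spec()) {
  stopifnot(inherits(session, "session"), inherits(noise, "noise_spec"))
  kernel <- canonical_hrf(hrf)
  dt <- hrf$dt
  steps_tr <- tr / dt
  if (abs(steps_tr - round(steps_tr)) > 1e-8) stop("TR must be a multiple of dt")
  vol_bins <- as.integer(round((seq_len(n_volumes) - 1L) * steps_tr)) + 1L
  n_micro <- max(vol_bins)
  rnames <- names(region_specs)
  for (spec in region_specs) {
    if (!is.null(spec$ppi_seed) && !spec$ppi_seed %in% rnames) {
      stop("ppi_seed '", spec$ppi_seed, "' of region '", spec$name,
           "' is not in the region map")
    }
  }
  events <- lapply(seq_along(session$runs), function(r) {
    build_event_table(session$runs[[r]], run_index = r, isi = isi)
  })
  bold <- neural_out <- vector("list", length(session$runs))
  for (r in seq_along(session$runs)) {
    ev <- events[[r]]
    neural <- vapply(region_specs, build_neural_signal, numeric(n_micro),
                     events_run = ev, n_microtime = n_micro, dt = dt)
    # neural-level PPI coupling: base + mismatch-gated product with the seed
    for (j in seq_along(region_specs)) {
      spec <- region_specs[[j]]
      if (is.null(spec$ppi_seed)) next
      seed <- neural[, spec$ppi_seed]
      psych <- psych_microtime(ev, spec$ppi_modality, n_micro, dt)
      neural[, j] <- neural[, j] + spec$ppi_coupling_base * seed +
        spec$ppi_coupling_mismatch * seed * psych
    }
    clean <- apply(neural, 2L, convolve_hrf,
                   kernel = kernel)[vol_bins, , drop = FALSE]
    db <- drift_basis(n_volumes, noise$drift_order)
    y <- clean
    for (j in seq_len(ncol(y))) {
      drift <- if (ncol(db) > 0L) {
        drop(db %*% stats::rnorm(ncol(db), sd = noise$drift_sd))
      } else 0
      y[, j] <- y[, j] + drift + ar1_noise(n_volumes, noise$rho, noise$sigma)
    }
    colnames(y) <- colnames(clean) <- rnames
    bold[[r]] <- y
    neural_out[[r]] <- clean
  }
  structure(list(bold = bold, neural = neural_out, events = events,
                 region_specs = region_specs, noise = noise,
                 tr = tr, n_volumes = as.integer(n_volumes),
                 hrf = hrf, session = session),
            class = "bold_dataset")
}

# +1 / -1 deviant-standard code of one modality placed at trial bins
psych_microtime <- function(events_run, modality, n_microtime, dt = 0.05) {
  e <- events_run[events_run$modality == modality, ]
  e <- e[order(e$trial), ]
  bins <- as.integer(round(e$onset / dt)) + 1L
  x <- numeric(n_microtime)
  x[bins] <- e$mod_mismatch
  x
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat(sprintf("bold_dataset: %d run(s) x %d volumes x %d regions (TR %.2f s)\n",
              length(x$bold), x$n_volumes, ncol(x$bold[[1L]]), x$tr))
  invisible(x)
}

#' Write BOLD matrices as TSV
#'
#' One file per run: volumes x regions with a header of region names.
#'
#' @param dataset a \code{bold_dataset}.
#' @param dir output directory.
#' @return The file paths, invisibly.
#' @export
write_bold_tsv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(dataset$bold))
  for (r in seq_along(dataset$bold)) {
    paths[r] <- file.path(dir, sprintf("bold_run-%02d.tsv", r))
    utils::write.table(dataset$bold[[r]], paths[r], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
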