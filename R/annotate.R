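TRAIN_BIN_LEVELS <- c("1", "2", "3", "4-5", "6-8", ">8")

#' Label trial roles within one modality
#'
#' A trial is a deviant when its intensity differs from the preceding trial
#' of the same modality, a standard when it repeats it; the first trial has
#' no predecessor.
#'
#' @param obs binary intensity vector of one modality (0 = low, 1 = high).
#' @return Character vector: \code{"first"}, \code{"standard"},
#'   \code{"deviant"}.
#' @examples
#' label_roles(c(0, 0, 1))  # first, standard, deviant
#' @export
label_roles <- function(obs) {
  n <- length(obs)
  if (n < 1L) stop("need at least one trial")
  roles <- c("first", ifelse(obs[-1L] != obs[-n], "deviant", "standard"))
  roles
}

#' Train lengths and train-length bins for deviants
#'
#' The train length of a deviant is the number of standard repetitions since
#' the previous deviant in that modality (or since the run start). Deviants
#' ending the run's first train have no preceding deviant; they are included
#' by default and flagged \code{first_train} so they can be excluded.
#' Bins: 1, 2, 3, 4-5, 6-8, >8 repetitions.
#'
#' @param roles role vector from \code{\link{label_roles}}.
#' @param include_first_train bin deviants of the run-initial train
#'   (default \code{TRUE}).
#' @return Data frame, one row per trial: \code{train_length} (NA for
#'   non-deviants and, if excluded, first-train deviants),
#'   \code{train_bin} (factor with the six bin levels), \code{first_train}.
#' @examples
#' r <- label_roles(c(0, 0, 0, 1, 1, 0))
#' compute_train_lengths(r)$train_length  # NA NA NA 2 NA 1
#' @export
compute_train_lengths <- function(roles, include_first_train = TRUE) {
  n <- length(roles)
  train_length <- rep(NA_integer_, n)
  first_train <- rep(FALSE, n)
  run_start <- TRUE        # no deviant seen yet in this modality
  standards <- 0L          # standards since last deviant (or run start)
  for (t in seq_len(n)) {
    role <- roles[t]
    if (role == "deviant") {
      if (!run_start || include_first_train) {
        train_length[t] <- standards
      }
      first_train[t] <- run_start
      run_start <- FALSE
      standards <- 0L
    } else if (role == "standard") {
      standards <- standards + 1L   # the run-initial "first" trial is no standard
    }
  }
  train_bin <- bin_train_length(train_length)
  data.frame(train_length = train_length, train_bin = train_bin,
             first_train = first_train)
}

#' @rdname compute_train_lengths
#' @param train_length integer vector of train lengths (NA allowed).
#' @export
bin_train_length <- function(train_length) {
  idx <- findInterval(train_length, c(1, 2, 3, 4, 6, 9))
  idx[!is.na(train_length) & train_length < 1L] <- NA_integer_
  factor(TRAIN_BIN_LEVELS[idx], levels = TRAIN_BIN_LEVELS)
}

#' Cross-modal predictability of realized transitions
#'
#' A realized transition (change or repetition) of a modality is
#' \emph{predicted} when its conditional probability under the actual
#' cross-modal context exceeds its probability under the opposite context,
#' \emph{mispredicted} when it is lower, and \emph{unpredictable} when the
#' two contexts assign it equal probability (condition C3). In C1 this
#' reduces to: change in congruent context and repetition in incongruent
#' context are predicted, the complementary cells mispredicted; C2 is
#' mirrored.
#'
#' @param states state index sequence of a run.
#' @param condition a \code{condition_setting} or id string.
#' @return Character matrix (trials x modalities); first trial \code{NA}.
#' @export
label_predictability <- function(states, condition) {
  if (is.character(condition)) condition <- condition_setting(condition)
  n <- length(states)
  pcc <- condition$p_change_congruent
  pci <- condition$p_change_incongruent
  out <- matrix(NA_character_, n, 3L, dimnames = list(NULL, MODALITIES))
  if (n < 2L) return(out)
  obs <- state_to_obs(states)
  prev <- states[-n]
  for (mi in seq_along(MODALITIES)) {
    m <- MODALITIES[mi]
    cong <- context_congruency(prev, m) == "congruent"
    chg <- obs[-1L, mi] != obs[-n, mi]
    p_actual <- ifelse(chg, ifelse(cong, pcc, pci),
                       ifelse(cong, 1 - pcc, 1 - pci))
    p_other <- ifelse(chg, ifelse(cong, pci, pcc),
                      ifelse(cong, 1 - pci, 1 - pcc))
    out[-1L, mi] <- ifelse(p_actual > p_other, "predicted",
                           ifelse(p_actual < p_other, "mispredicted",
                                  "unpredictable"))
  }
  out
}

#' Annotate a sampled run trial by trial
#'
#' Derives roles, train lengths/bins and predictability for every trial and
#' modality of a \code{sequence_run}.
#'
#' @param run a \code{sequence_run}.
#' @param include_first_train see \code{\link{compute_train_lengths}}.
#' @return The run with an \code{annotation} element: a list per modality of
#'   data frames (role, context, train_length, train_bin, first_train,
#'   predictability).
#' @export
annotate_run <- function(run, include_first_train = TRUE) {
  stopifnot(inherits(run, "sequence_run"))
  n <- run$n_trials
  pred <- label_predictability(run$states, run$condition)
  ann <- stats::setNames(vector("list", 3L), MODALITIES)
  for (mi in seq_along(MODALITIES)) {
    m <- MODALITIES[mi]
    roles <- label_roles(run$obs[, mi])
    tl <- compute_train_lengths(roles, include_first_train)
    context <- c(NA_character_,
                 context_congruency(run$states[-n], m))
    ann[[m]] <- cbind(data.frame(role = roles, context = context,
                                 predictability = pred[, mi]), tl)
  }
  run$annotation <- ann
  run
}

#' Build the long-format event table of an annotated run
#'
#' One row per trial and modality, BIDS-events-like: onsets at
#' \code{(trial - 1) * isi} seconds, stimulus duration 0.1 s, intensity,
#' role, context, train columns, predictability, catch-trial columns, and
#' the three signed modulator codes used by the GLM:
#' intensity high = +1 / low = -1; mismatch deviant = +1 / standard = -1;
#' predictability mispredicted = +1 / predicted = -1 / unpredictable = 0.
#' First-trial modulators are 0.
#'
#' @param run an annotated \code{sequence_run} (see \code{\link{annotate_run}};
#'   annotation is added on the fly if missing).
#' @param run_index run number recorded in the table.
#' @param isi inter-stimulus interval in seconds (default 1.75).
#' @param predictability_trials code predictability on \code{"all"} trials
#'   (default) or on \code{"deviants"} only (zeros elsewhere).
#' @return Data frame with \code{3 * n_trials} rows.
#' @export
build_event_table <- function(run, run_index = run$run_index %||% 1L,
                              isi = 1.75,
                              predictability_trials = c("all", "deviants")) {
  predictability_trials <- match.arg(predictability_trials)
  if (is.null(run$annotation)) run <- annotate_run(run)
  n <- run$n_trials
  catch <- run$catch_trials
  blocks <- vector("list", 3L)
  for (mi in seq_along(MODALITIES)) {
    m <- MODALITIES[mi]
    a <- run$annotation[[m]]
    mod_int <- ifelse(run$obs[, mi] == 1L, 1, -1)
    mod_mm <- ifelse(a$role == "deviant", 1,
                     ifelse(a$role == "standard", -1, 0))
    mod_pred <- ifelse(is.na(a$predictability), 0,
                       ifelse(a$predictability == "mispredicted", 1,
                              ifelse(a$predictability == "predicted", -1, 0)))
    if (predictability_trials == "deviants") {
      mod_pred[a$role != "deviant"] <- 0
    }
    mod_int[1L] <- 0   # first trial carries no modulators
    is_catch <- rep(FALSE, n)
    catch_query <- rep(NA_character_, n)
    if (!is.null(catch)) {
      is_catch[catch$trial] <- TRUE
      catch_query[catch$trial] <- catch$modality
    }
    blocks[[mi]] <- data.frame(
      trial = seq_len(n),
      onset = (seq_len(n) - 1) * isi,
      duration = 0.1,
      run = run_index,
      condition = run$condition$id,
      modality = m,
      intensity = ifelse(run$obs[, mi] == 1L, "high", "low"),
      role = a$role,
      context = a$context,
      train_length = a$train_length,
      train_bin = as.character(a$train_bin),
      first_train = a$first_train,
      predictability = a$predictability,
      is_catch = is_catch,
      catch_query = catch_query,
      mod_intensity = mod_int,
      mod_mismatch = mod_mm,
      mod_predictability = mod_pred
    )
  }
  events <- do.call(rbind, blocks)
  events <- events[order(events$trial, match(events$modality, MODALITIES)), ]
  rownames(events) <- NULL
  events
}

#' Event tables for every run of a session
#'
#' @param session a \code{session}.
#' @param ... passed to \code{\link{build_event_table}}.
#' @return Single data frame, runs stacked.
#' @export
build_session_events <- function(session, ...) {
  stopifnot(inherits(session, "session"))
  tabs <- lapply(seq_along(session$runs), function(r) {
    build_event_table(session$runs[[r]], run_index = r, ...)
  })
  do.call(rbind, tabs)
}

#' Write / read an events table as TSV
#'
#' @param events event table data frame.
#' @param path file path.
#' @return \code{path} / the table.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
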