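#' Modalities of the tri-modal paradigm
#'
#' The three stimulated senses, in the fixed encoding order used throughout
#' the package: auditory ("A"), somatosensory ("S"), visual ("V").
#'
#' @format Character vector of length 3.
#' @export
MODALITIES <- c("A", "S", "V")

#' Convert a state index to its tri-modal observation triple
#'
#' States 0--7 encode the joint low/high intensity pattern of the three
#' modalities via the bijection \code{index = 4*o_A + 2*o_S + o_V}, with
#' 0 = low and 1 = high in each modality.
#'
#' @param state integer vector of state indices in 0--7.
#' @return Integer matrix with one row per state and columns \code{A, S, V},
#'   entries in \{0, 1\}.
#' @examples
#' state_to_obs(5)          # A = 1, S = 0, V = 1
#' obs_to_state(c(0, 0, 0)) # 0
#' @export
state_to_obs <- function(state) {
  state <- as.integer(state)
  if (any(is.na(state)) || any(state < 0L | state > 7L)) {
    stop("state index must be in 0..7")
  }
  out <- cbind(
    A = bitwAnd(bitwShiftR(state, 2L), 1L),
    S = bitwAnd(bitwShiftR(state, 1L), 1L),
    V = bitwAnd(state, 1L)
  )
  out
}

#' @rdname state_to_obs
#' @param obs integer vector of length 3 (a single observation triple in
#'   A, S, V order) or a 3-column matrix of such triples.
#' @export
obs_to_state <- function(obs) {
  if (is.null(dim(obs))) obs <- matrix(obs, ncol = 3L)
  obs <- matrix(as.integer(obs), ncol = 3L)
  if (any(is.na(obs)) || any(obs != 0L & obs != 1L)) {
    stop("observations must be binary (0 = low, 1 = high)")
  }
  as.integer(4L * obs[, 1L] + 2L * obs[, 2L] + obs[, 3L])
}

#' Cross-modal context congruency
#'
#' For a given modality, the context is the pair of observations carried by
#' the other two modalities: congruent when both are low or both are high,
#' incongruent otherwise.
#'
#' @param state integer vector of state indices 0--7.
#' @param modality one of \code{"A"}, \code{"S"}, \code{"V"}.
#' @return Character vector, \code{"congruent"} or \code{"incongruent"}.
#' @export
context_congruency <- function(state, modality) {
  modality <- match.arg(modality, MODALITIES)
  o <- state_to_obs(state)
  others <- setdiff(MODALITIES, modality)
  unname(ifelse(o[, others[1L]] == o[, others[2L]],
                "congruent", "incongruent"))
}

#' Define a condition's conditional change probabilities
#'
#' A condition setting fixes, for every modality, the per-trial probability of
#' an intensity change conditional on the cross-modal context of the other two
#' modalities. The three default settings are
#' \code{C1 = (0.15, 0.025)} (changes more likely in congruent context),
#' \code{C2 = (0.025, 0.15)} (mirrored), and
#' \code{C3 = (0.0875, 0.0875)} (context-neutral).
#'
#' @param id condition label, one of \code{"C1"}, \code{"C2"}, \code{"C3"},
#'   or any string for custom settings.
#' @param p_change_congruent,p_change_incongruent change probabilities in the
#'   two contexts; when omitted and \code{id} is a default condition, the
#'   default values are used.
#' @return Object of class \code{condition_setting}.
#' @export
condition_setting <- function(id, p_change_congruent = NULL,
                              p_change_incongruent = NULL) {
  defaults <- list(
    C1 = c(0.15, 0.025),
    C2 = c(0.025, 0.15),
    C3 = c(0.0875, 0.0875)
  )
  if (is.null(p_change_congruent) || is.null(p_change_incongruent)) {
    if (!id %in% names(defaults)) {
      stop("no default probabilities for condition '", id,
           "'; supply p_change_congruent and p_change_incongruent")
    }
    p_change_congruent <- defaults[[id]][1L]
    p_change_incongruent <- defaults[[id]][2L]
  }
  pcc <- p_change_congruent
  pci <- p_change_incongruent
  if (!is.numeric(pcc) || !is.numeric(pci) ||
      pcc < 0 || pcc > 1 || pci < 0 || pci > 1) {
    stop("change probabilities must lie in [0, 1]")
  }
  # every row must stay sub-stochastic before the diagonal is filled:
  # a source state exposes either three congruent-context entries (all-equal
  # observation patterns) or one congruent + two incongruent entries
  if (3 * max(pcc, pci) > 1 + 1e-12 || pcc + 2 * pci > 1 + 1e-12) {
    stop("infeasible condition: rows would exceed probability 1 ",
         "(need 3*max(p_cc, p_ci) <= 1 and p_cc + 2*p_ci <= 1)")
  }
  structure(
    list(id = id,
         p_change_congruent = pcc,
         p_change_incongruent = pci),
    class = "condition_setting"
  )
}

#' @export
print.condition_setting <- function(x, ...) {
  cat(sprintf(
    "condition %s: p(change | congruent) = %.4g, p(change | incongruent) = %.4g\n",
    x$id, x$p_change_congruent, x$p_change_incongruent))
  invisible(x)
}

# change probability of each modality out of each source state, 8 x 3
state_change_probs <- function(condition) {
  p <- matrix(NA_real_, 8L, 3L, dimnames = list(0:7, MODALITIES))
  for (s in 0:7) {
    for (m in MODALITIES) {
      p[s + 1L, m] <- if (context_congruency(s, m) == "congruent") {
        condition$p_change_congruent
      } else {
        condition$p_change_incongruent
      }
    }
  }
  p
}

#' Build the 8x8 transition matrix of a condition
#'
#' Entry (s, s') is the probability of moving from joint state s to s' in one
#' trial. Transitions changing two or more modalities have probability exactly
#' zero; a single-modality change carries the condition's conditional change
#' probability given the congruency of the other two modalities in the
#' source state; the diagonal absorbs the remaining mass (tri-modal
#' repetition).
#'
#' @param condition a \code{condition_setting} (or a condition id string).
#' @return Object of class \code{transition_matrix}: the 8x8 matrix with the
#'   condition stored in attribute \code{condition}.
#' @examples
#' P <- build_transition_matrix("C1")
#' P[1, 2]  # state 0 -> 1 flips V in congruent context: 0.15
#' @export
build_transition_matrix <- function(condition) {
  if (is.character(condition)) condition <- condition_setting(condition)
  stopifnot(inherits(condition, "condition_setting"))
  pm <- state_change_probs(condition)
  P <- matrix(0, 8L, 8L, dimnames = list(0:7, 0:7))
  bit <- c(A = 4L, S = 2L, V = 1L)
  for (s in 0:7) {
    for (m in MODALITIES) {
      P[s + 1L, bitwXor(s, bit[[m]]) + 1L] <- pm[s + 1L, m]
    }
    diagmass <- 1 - sum(P[s + 1L, ])
    if (diagmass < -1e-12) {
      stop("infeasible condition: change mass of row for state ", s,
           " exceeds 1")
    }
    P[s + 1L, s + 1L] <- diagmass
  }
  structure(P, class = c("transition_matrix", "matrix"),
            condition = condition)
}

#' @export
print.transition_matrix <- function(x, ...) {
  cond <- attr(x, "condition")
  cat("8-state tri-modal transition matrix (condition ", cond$id, ")\n",
      sep = "")
  print(round(unclass(x)[, ], 4), ...)
  invisible(x)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Solves pi P = pi by the left eigenvector of eigenvalue 1. If the eigenvalue
#' 1 has multiplicity greater than one (reducible chain, e.g. the identity
#' matrix), the stationary distribution is not unique and the function stops
#' unless \code{allow_nonunique} is set, in which case one solution is
#' returned with attribute \code{unique = FALSE}.
#'
#' @param P row-stochastic matrix.
#' @param tol residual tolerance on \code{pi P - pi}.
#' @param allow_nonunique return a (non-unique) solution instead of erroring.
#' @return Probability vector with attribute \code{unique}.
#' @export
stationary_distribution <- function(P, tol = 1e-10, allow_nonunique = FALSE) {
  P <- unclass(P)
  if (any(abs(rowSums(P) - 1) > 1e-8)) stop("matrix is not row-stochastic")
  e <- eigen(t(P))
  ones <- which(abs(e$values - 1) < 1e-8)
  if (length(ones) == 0L) stop("no unit eigenvalue found")
  unique_sol <- length(ones) == 1L
  if (!unique_sol && !allow_nonunique) {
    stop("stationary distribution is not unique (unit eigenvalue has ",
         "multiplicity ", length(ones), ")")
  }
  v <- Re(e$vectors[, ones[1L]])
  pi <- v / sum(v)
  if (any(pi < -tol)) stop("negative stationary component beyond tolerance")
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  if (max(abs(drop(pi %*% P) - pi)) > tol) {
    stop("stationary solve did not reach tolerance ", tol)
  }
  structure(pi, unique = unique_sol, names = rownames(P))
}

# involution swapping low and high in all modalities: state s -> 7 - s
flip_permutation <- function() {
  Pi <- matrix(0, 8L, 8L)
  Pi[cbind(1:8, 8:1)] <- 1
  Pi
}

#' Export / import a transition matrix
#'
#' TSV layout: 8 rows by 8 columns, header = destination state indices,
#' first column = source state index. JSON carries the condition metadata
#' alongside the entries.
#'
#' @param P a \code{transition_matrix}.
#' @param path output file; extension selects the format unless \code{format}
#'   is given.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return \code{write_transition_matrix} returns \code{path} invisibly;
#'   \code{read_transition_matrix} returns a \code{transition_matrix}.
#' @export
write_transition_matrix <- function(P, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  cond <- attr(P, "condition")
  if (format == "tsv") {
    df <- data.frame(state = 0:7, unclass(P)[, ], check.names = FALSE)
    names(df) <- c("state", as.character(0:7))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(condition = list(id = cond$id,
                            p_change_congruent = cond$p_change_congruent,
                            p_change_incongruent = cond$p_change_incongruent),
           entries = unclass(P)[, ]),
      path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_transition_matrix
#' @export
read_transition_matrix <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE)
    P <- as.matrix(df[, as.character(0:7)])
    dimnames(P) <- list(0:7, 0:7)
    cond <- infer_condition_from_matrix(P)
    structure(P, class = c("transition_matrix", "matrix"), condition = cond)
  } else {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    P <- matrix(as.numeric(x$entries), 8L, 8L, dimnames = list(0:7, 0:7))
    cond <- condition_setting(x$condition$id,
                              x$condition$p_change_congruent,
                              x$condition$p_change_incongruent)
    structure(P, class = c("transition_matrix", "matrix"), condition = cond)
  }
}

# recover the two conditionals from a matrix written without metadata
infer_condition_from_matrix <- function(P) {
  pcc <- P[1L, 2L]          # state 0 -> 1: V change, A=S congruent
  pci <- P[2L, 6L]          # state 1 -> 5: A change, S=0 vs V=1 incongruent
  condition_setting("custom", pcc, pci)
}
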