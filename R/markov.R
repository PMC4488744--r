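# Discrete-time homogeneous Markov chains over MSPA classes plus
# non-farmland, estimated from per-cell transitions between two class maps.
# Spectral diagnostics: stationary distribution, convergence rate
# rho = 1/|lambda_2|, and the pi-weighted normalized entropy H(P).

#' Markov chain state space
#'
#' The fixed 8-state ordering used for transition matrices: the seven MSPA
#' classes plus non-farmland (background).
#' @return Character vector of length 8.
#' @export
markov_states <- function() {
  c("core", "perforation", "edge", "islet", "bridge", "loop", "branch",
    "nonfarmland")
}

# map mspa_map label indices (1..8 over mspa_classes()) to state indices
labels_to_states <- function(labels) {
  lut <- match(c("nonfarmland", "core", "islet", "bridge", "loop",
                 "perforation", "edge", "branch"), markov_states())
  matrix(lut[labels], nrow(labels), ncol(labels))
}

#' Estimate a transition model from two class maps
#'
#' Cross-tabulates per-cell states at two dates into an 8x8 count matrix
#' `C` and its row-normalized probability matrix `P`. States absent at the
#' first date get an identity (absorbing) row with a warning, which keeps
#' `P` row-stochastic without inventing flow.
#'
#' @param map_t1,map_t2 `mspa_map` objects (or integer matrices of state
#'   indices into [markov_states()]) of identical shape.
#' @return A `transition_model`: `states`, `C` (counts), `P`
#'   (row-stochastic), `n_pixels`, `absent_states`.
#' @export
estimate_transitions <- function(map_t1, map_t2) {
  as_state <- function(m) {
    if (inherits(m, "mspa_map")) return(labels_to_states(m$labels))
    stopifnot(is.matrix(m))
    if (!all(m %in% seq_len(8L))) stop("unknown state code in grid")
    m
  }
  s1 <- as_state(map_t1); s2 <- as_state(map_t2)
  if (!all(dim(s1) == dim(s2))) {
    stop(sprintf("shape mismatch: %dx%d vs %dx%d",
                 nrow(s1), ncol(s1), nrow(s2), ncol(s2)))
  }
  states <- markov_states()
  C <- table(factor(as.vector(s1), levels = 1:8),
             factor(as.vector(s2), levels = 1:8))
  C <- matrix(as.numeric(C), 8, 8, dimnames = list(states, states))
  transition_model_from_counts(C)
}

# Build a transition_model from a count (or probability) matrix.
transition_model_from_counts <- function(C) {
  states <- rownames(C)
  if (is.null(states)) states <- markov_states()
  rs <- rowSums(C)
  absent <- states[rs == 0]
  if (length(absent) > 0) {
    warning("states absent at t1 set to absorbing rows: ",
            paste(absent, collapse = ", "))
  }
  P <- sweep(C, 1, pmax(rs, 1), "/")
  for (s in absent) {
    P[s, ] <- 0
    P[s, s] <- 1
  }
  structure(
    list(states = states, C = C, P = P, n_pixels = sum(C),
         absent_states = absent),
    class = "transition_model"
  )
}

#' Construct a transition model from a probability matrix
#'
#' For running the diagnostics directly on an externally supplied
#' row-stochastic matrix (e.g. a transcribed published matrix).
#'
#' @param P Square row-stochastic matrix, optionally with state dimnames.
#' @return A `transition_model` with `C = NA`-free zero counts.
#' @export
transition_model <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8)) {
    stop("'P' must be row-stochastic")
  }
  states <- rownames(P)
  if (is.null(states)) states <- paste0("s", seq_len(nrow(P)))
  dimnames(P) <- list(states, states)
  structure(
    list(states = states, C = P * 0, P = P, n_pixels = 0,
         absent_states = character(0)),
    class = "transition_model"
  )
}

#' Read a transition probability matrix from CSV
#'
#' Expects a square numeric matrix with state-labeled header row and first
#' column, rows summing to 1.
#'
#' @param path CSV path.
#' @return A `transition_model`.
#' @export
read_transition_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  transition_model(as.matrix(df))
}

#' Stationary distribution
#'
#' Left eigenvector of `P` for its dominant eigenvalue, normalized to sum 1.
#' Reducible chains (dominant eigenvalue with multiplicity > 1) return one
#' valid solution with a warning.
#'
#' @param model A `transition_model`.
#' @return Named numeric vector `pi` with `pi >= 0`, `sum(pi) = 1`.
#' @export
stationary_distribution <- function(model) {
  P <- model$P
  e <- eigen(t(P))
  mods <- Mod(e$values)
  dom <- which.max(mods)
  if (sum(mods > 1 - 1e-10) > 1L) {
    warning("chain is reducible or periodic; stationary distribution not unique")
  }
  v <- Re(e$vectors[, dom])
  v <- v / sum(v)
  if (any(v < -1e-10)) v <- abs(v) / sum(abs(v))
  v[v < 0] <- 0
  v <- v / sum(v)
  stats::setNames(v, model$states)
}

#' Convergence rate to the stationary distribution
#'
#' `rho = 1 / |lambda_2|`, the reciprocal modulus of the subdominant
#' eigenvalue of `P`. Larger values mean faster convergence; `Inf` when
#' `|lambda_2| = 0` (one-step convergence). When the unit eigenvalue is
#' degenerate (a reducible chain, e.g. several absorbing states), the rate
#' of approach to the absorbing set is still meaningful: the largest
#' eigenvalue modulus strictly below 1 is used, with a warning; if no such
#' eigenvalue exists (identity-like chain) the function warns and
#' returns 1.
#'
#' @param model A `transition_model`.
#' @return Scalar `rho >= 1` (possibly `Inf`).
#' @export
convergence_rate <- function(model) {
  l2 <- subunit_modulus(model$P, warn = TRUE)
  if (is.na(l2)) return(1)
  if (l2 < 1e-12) return(Inf)
  1 / l2
}

# largest eigenvalue modulus strictly below 1 (NA if none); warns when the
# unit eigenvalue is degenerate
subunit_modulus <- function(P, warn = FALSE) {
  mods <- Mod(eigen(P, only.values = TRUE)$values)
  unit <- sum(mods >= 1 - 1e-10)
  sub <- mods[mods < 1 - 1e-10]
  if (warn && unit > 1L) {
    warning("subdominant eigenvalue has modulus 1 (reducible/periodic chain)")
  }
  if (length(sub) == 0L) {
    if (warn && unit <= 1L) warning("no sub-unit eigenvalue")
    return(NA_real_)
  }
  max(sub)
}

#' Normalized entropy of a transition matrix
#'
#' With `weights = "stationary"` (default):
#' `H(P) = -sum_i pi_i sum_j P_ij ln P_ij / ln(s)`, the entropy rate of
#' the chain scaled to `[0, 1]`, with `s` the number of states carrying
#' nonzero stationary mass and `0 ln 0 = 0`. For chains whose stationary
#' mass collapses onto an absorbing state (e.g. estimated from a pure-loss
#' landscape sequence) the entropy rate is legitimately 0; the
#' `weights = "uniform"` variant averages the row entropies equally
#' instead and stays informative there. 0 means fully deterministic
#' transitions; 1 maximally random.
#'
#' @param model A `transition_model`.
#' @param pi Optional stationary distribution (computed if missing).
#' @param weights `"stationary"` (entropy rate) or `"uniform"` (plain row
#'   average).
#' @return Scalar in `[0, 1]`.
#' @export
normalized_entropy <- function(model, pi = NULL,
                               weights = c("stationary", "uniform")) {
  weights <- match.arg(weights)
  P <- model$P
  terms <- P * log(P)
  terms[P == 0] <- 0
  row_h <- -rowSums(terms)
  if (weights == "uniform") {
    return(mean(row_h) / log(nrow(P)))
  }
  if (is.null(pi)) pi <- suppressWarnings(stationary_distribution(model))
  s <- sum(pi > 1e-12)
  if (s < 2) return(0)
  sum(pi * row_h) / log(s)
}

#' Composition of conversion flow into a sink state
#'
#' Shares of the transition counts flowing into `sink` from every other
#' state (persistence `sink -> sink` excluded); shares sum to 1.
#'
#' @param model A `transition_model` with counts.
#' @param sink State name.
#' @return Named numeric vector over the non-sink states.
#' @export
conversion_sources <- function(model, sink) {
  if (!sink %in% model$states) stop("unknown sink state: ", sink)
  flows <- model$C[, sink]
  flows <- flows[names(flows) != sink]
  tot <- sum(flows)
  if (tot == 0) stop("no conversion flow into ", sink)
  flows / tot
}

#' Project a distribution through the chain
#'
#' Iterates `x, xP, xP^2, ...`; for an ergodic chain the distance to the
#' stationary distribution decays geometrically at rate `|lambda_2|`.
#'
#' @param model A `transition_model`.
#' @param initial Non-negative state distribution summing to 1.
#' @param steps Number of steps (>= 0).
#' @return Matrix with `steps + 1` rows, one distribution per row.
#' @export
project_chain <- function(model, initial, steps) {
  if (steps < 0) stop("'steps' must be >= 0")
  stopifnot(length(initial) == length(model$states),
            all(initial >= 0), abs(sum(initial) - 1) < 1e-8)
  out <- matrix(NA_real_, steps + 1L, length(initial),
                dimnames = list(NULL, model$states))
  x <- as.numeric(initial)
  out[1, ] <- x
  if (steps > 0) for (k in seq_len(steps)) {
    x <- as.numeric(x %*% model$P)
    out[k + 1L, ] <- x
  }
  out
}

#' Chain summary diagnostics
#'
#' @param model A `transition_model`.
#' @return List with `stationary`, `rho`, `entropy`, `lambda2`
#'   (subdominant eigenvalue modulus).
#' @export
chain_summary <- function(model) {
  pi <- suppressWarnings(stationary_distribution(model))
  l2 <- subunit_modulus(model$P)
  list(stationary = pi,
       rho = suppressWarnings(convergence_rate(model)),
       entropy = normalized_entropy(model, pi),
       row_entropy = normalized_entropy(model, weights = "uniform"),
       lambda2 = if (is.na(l2)) 1 else l2)
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model> %d states, %g paired cells\n",
              length(x$states), x$n_pixels))
  print(round(x$P, 4))
  invisible(x)
}
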