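# Exact Markov-chain iteration on the 2^n state space.
#
# A PBN induces a Markov chain: at each step every node independently
# selects one of its rules with that rule's probability, and all nodes
# update synchronously from the same source state. The transition
# probability P(s -> t) sums the joint selection probabilities of all
# rule combinations mapping s to t. A deterministic network is the
# degenerate case with a single combination of probability 1.

#' Exact PBN transition matrix
#'
#' @param net A [BooleanNetwork-class] (n <= 16; the matrix is dense
#'   `2^n` x `2^n`).
#' @return Row-stochastic matrix; entry `[i, j]` is the probability of
#'   moving from the state with code `i - 1` to code `j - 1` in one
#'   synchronous step.
#' @examples
#' P <- pbnTransitionMatrix(cdModel("CD-PBN"))
#' range(rowSums(P))  # all rows sum to 1
#' @export
pbnTransitionMatrix <- function(net) {
  .checkStateSpace(net, guard = 16L)
  n <- length(net@nodes)
  N <- 2L^n
  nb <- .nextBitTables(net)
  nFuns <- vapply(net@functions, length, integer(1))
  combos <- expand.grid(lapply(nFuns, seq_len), KEEP.OUT.ATTRS = FALSE)
  P <- matrix(0, N, N)
  rows <- seq_len(N)
  for (r in seq_len(nrow(combos))) {
    prob <- 1
    target <- 0
    for (i in seq_len(n)) {
      k <- combos[[i]][r]
      prob <- prob * net@functions[[i]][[k]]$prob
      target <- target + as.integer(nb[[i]][[k]]) * 2^(n - i)
    }
    idx <- cbind(rows, target + 1L)
    P[idx] <- P[idx] + prob
  }
  P
}

#' Iterate a state distribution under the exact Markov chain
#'
#' Applies the transition law of `net` to a probability distribution
#' over all `2^n` states, exactly (no sampling). Deterministic networks
#' are propagated through the successor map; PBNs through the dense
#' transition matrix.
#'
#' @param net A [BooleanNetwork-class].
#' @param iterations Number of steps (>= 0).
#' @param initial Optional initial distribution: a numeric vector of
#'   length `2^n` summing to 1, a single state string/code (point mass),
#'   or `NULL` for the uniform distribution over all states.
#' @return A [StateDistribution-class].
#' @examples
#' d <- iterateDistribution(cdModel("CD-V1"), 1000)
#' reportAbsorption(d)
#' @export
iterateDistribution <- function(net, iterations = 1000L, initial = NULL) {
  stopifnot(iterations >= 0)
  .checkStateSpace(net, guard = if (isDeterministic(net)) 24L else 16L)
  n <- length(net@nodes)
  N <- 2L^n
  probs <- .initialDistribution(initial, net)
  if (isDeterministic(net)) {
    nxt <- transitionTable(net)
    for (k in seq_len(iterations)) {
      nz <- which(probs > 0)  # 1-based positions; state code = nz - 1
      nextProbs <- numeric(N)
      agg <- rowsum(probs[nz], nxt[nz])
      nextProbs[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
      probs <- nextProbs
    }
  } else {
    P <- pbnTransitionMatrix(net)
    for (k in seq_len(iterations)) probs <- as.vector(probs %*% P)
  }
  new("StateDistribution", nodes = net@nodes, probs = probs,
      iterations = as.integer(iterations))
}

.initialDistribution <- function(initial, net) {
  N <- 2L^length(net@nodes)
  if (is.null(initial)) return(rep(1 / N, N))
  if (length(initial) == 1L) {
    code <- .stateCode(initial, net)
    probs <- numeric(N)
    probs[code + 1L] <- 1
    return(probs)
  }
  probs <- as.numeric(initial)
  if (length(probs) != N || any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
    stop("'initial' must be a distribution over all 2^n states", call. = FALSE)
  }
  probs
}

#' @describeIn iterateDistribution Named probability vector (names are
#'   canonical state strings).
#' @param dist A [StateDistribution-class].
#' @export
stateProbabilities <- function(dist) {
  setNames(dist@probs, stateToString(seq_along(dist@probs) - 1L,
                                     length(dist@nodes)))
}

setMethod("show", "StateDistribution", function(object) {
  cat(sprintf("StateDistribution over %d states after %d iteration(s)\n",
              length(object@probs), object@iterations))
  top <- head(sort(stateProbabilities(object), decreasing = TRUE), 5L)
  for (s in names(top)) cat(sprintf("  %s  %.3f\n", s, top[[s]]))
})

#' Absorption report: states holding probability mass
#'
#' Tabulates the states whose probability exceeds `cutoff`, sorted by
#' state string, with probabilities rounded to 3 decimals for display
#' (the `probability` column keeps full precision; `display` is the
#' rounded value).
#'
#' @param dist A [StateDistribution-class].
#' @param cutoff Minimum probability (exclusive) for a state to appear.
#' @return data.frame with columns `state`, `probability`, `display`.
#' @export
reportAbsorption <- function(dist, cutoff = 0.001) {
  stopifnot(cutoff >= 0)
  p <- stateProbabilities(dist)
  keep <- p > cutoff
  out <- data.frame(state = names(p)[keep], probability = unname(p[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$state), , drop = FALSE]
  rownames(out) <- NULL
  # half-up rounding, the convention of printed absorption tables
  # (0.0625 displays as 0.063, not the half-even 0.062)
  out$display <- floor(out$probability * 1000 + 0.5) / 1000
  out
}
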