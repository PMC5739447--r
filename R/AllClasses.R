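# S4 classes for networks, state-transition graphs, attractors,
# state distributions and robustness reports.

#' BooleanNetwork: a (probabilistic) Boolean network
#'
#' An ordered set of named nodes, each carrying one or more Boolean
#' update rules with selection probabilities. A network with exactly one
#' rule per node is *deterministic*; more than one rule on any node makes
#' it a probabilistic Boolean network (PBN). Node order is significant:
#' it fixes the bit order of every state string and integer code.
#'
#' @slot name Model label.
#' @slot nodes Character vector of unique node names (bit order).
#' @slot functions Named list, parallel to `nodes`; each element is a
#'   list of `list(expr = RuleExpression, prob = numeric)` entries whose
#'   probabilities sum to 1.
#' @seealso [booleanNetwork()], [cdModel()]
#' @export
setClass("BooleanNetwork",
  representation(name = "character", nodes = "character", functions = "list"))

setValidity("BooleanNetwork", function(object) {
  msgs <- character()
  nodes <- object@nodes
  if (length(nodes) == 0L) msgs <- c(msgs, "network has no nodes")
  if (anyDuplicated(nodes)) msgs <- c(msgs, "node names must be unique")
  if (!identical(names(object@functions), nodes)) {
    msgs <- c(msgs, "'functions' must be named by 'nodes' in node order")
  } else {
    for (nd in nodes) {
      fns <- object@functions[[nd]]
      if (length(fns) == 0L) {
        msgs <- c(msgs, sprintf("node '%s' has no update rule", nd))
        next
      }
      probs <- vapply(fns, function(f) f$prob, numeric(1))
      if (any(probs <= 0) || any(probs > 1)) {
        msgs <- c(msgs, sprintf("node '%s': probabilities must lie in (0, 1]", nd))
      }
      if (abs(sum(probs) - 1) > 1e-9) {
        msgs <- c(msgs, sprintf("node '%s': probabilities sum to %.12g, not 1",
                                nd, sum(probs)))
      }
      for (f in fns) {
        bad <- setdiff(ruleInputs(f$expr), nodes)
        if (length(bad)) {
          msgs <- c(msgs, sprintf("node '%s': rule references undeclared node(s) %s",
                                  nd, paste(bad, collapse = ", ")))
        }
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' StateTransitionGraph: all 2^n states under one update semantics
#'
#' @slot mode `"synchronous"`, `"asynchronous"` or `"pbn"`.
#' @slot nodes Node order of the underlying network.
#' @slot edges data.frame with integer columns `from`, `to` (0-based
#'   state codes) and numeric `prob`. Synchronous/PBN graphs include
#'   self-loops; asynchronous graphs record only non-self transitions
#'   (a state with no outgoing edge is fixed under every single-node
#'   update).
#' @seealso [buildSTG()]
#' @export
setClass("StateTransitionGraph",
  representation(mode = "character", nodes = "character", edges = "data.frame"))

setValidity("StateTransitionGraph", function(object) {
  msgs <- character()
  if (!object@mode %in% c("synchronous", "asynchronous", "pbn")) {
    msgs <- c(msgs, "mode must be synchronous, asynchronous or pbn")
  }
  e <- object@edges
  if (!all(c("from", "to", "prob") %in% names(e))) {
    msgs <- c(msgs, "edges need columns from, to, prob")
  } else {
    N <- 2^length(object@nodes)
    if (nrow(e) && (min(e$from, e$to) < 0 || max(e$from, e$to) >= N)) {
      msgs <- c(msgs, "edge endpoints out of state range")
    }
    if (object@mode == "synchronous" &&
        !identical(sort(e$from), 0:(N - 1L))) {
      msgs <- c(msgs, "synchronous graph must have out-degree exactly 1")
    }
    if (object@mode == "pbn") {
      s <- tapply(e$prob, e$from, sum)
      if (any(abs(s - 1) > 1e-9)) {
        msgs <- c(msgs, "pbn outgoing probabilities must sum to 1 per state")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Attractor: a fixed point, limit cycle or complex attractor
#'
#' @slot kind `"fixed_point"`, `"limit_cycle"` or `"complex"`.
#' @slot states 0-based state codes; cycle order for limit cycles
#'   (starting from the smallest code), sorted for complex attractors.
#' @slot nodes Node order, used to render state strings.
#' @slot basinCount Number of states whose forward orbit reaches the
#'   attractor (`NA` for asynchronous attractors, where basins are not
#'   reported).
#' @slot basinPct `100 * basinCount / 2^n`.
#' @slot edges For complex attractors, the internal non-self transitions
#'   as a data.frame `from`/`to`; empty otherwise.
#' @export
setClass("Attractor",
  representation(kind = "character", states = "integer", nodes = "character",
                 basinCount = "integer", basinPct = "numeric",
                 edges = "data.frame"))

setValidity("Attractor", function(object) {
  msgs <- character()
  if (!object@kind %in% c("fixed_point", "limit_cycle", "complex")) {
    msgs <- c(msgs, "unknown attractor kind")
  }
  if (object@kind == "fixed_point" && length(object@states) != 1L) {
    msgs <- c(msgs, "a fixed point has exactly one state")
  }
  if (object@kind != "fixed_point" && length(object@states) < 2L) {
    msgs <- c(msgs, "cycles and complex attractors have at least two states")
  }
  if (length(msgs)) msgs else TRUE
})

#' AttractorSet: all attractors of one network under one semantics
#'
#' @slot model Model label.
#' @slot mode Update semantics the attractors were computed under.
#' @slot nodes Node order.
#' @slot attractors List of [Attractor-class] objects.
#' @export
setClass("AttractorSet",
  representation(model = "character", mode = "character", nodes = "character",
                 attractors = "list"))

#' StateDistribution: a probability vector over all 2^n states
#'
#' @slot nodes Node order.
#' @slot probs Numeric vector of length `2^n`; position `i` is the
#'   probability of the state with integer code `i - 1`.
#' @slot iterations Number of exact Markov-chain steps applied.
#' @export
setClass("StateDistribution",
  representation(nodes = "character", probs = "numeric", iterations = "integer"))

setValidity("StateDistribution", function(object) {
  msgs <- character()
  if (length(object@probs) != 2^length(object@nodes)) {
    msgs <- c(msgs, "probs must have length 2^n")
  }
  if (any(object@probs < -1e-12)) msgs <- c(msgs, "negative probability")
  if (abs(sum(object@probs) - 1) > 1e-9) {
    msgs <- c(msgs, "probabilities must sum to 1 (within 1e-9)")
  }
  if (length(msgs)) msgs else TRUE
})

#' RobustnessReport: Hamming and Gini observables with null statistics
#'
#' @slot model Model label.
#' @slot hammingMean Mean normalized Hamming distance between one-step
#'   images of random states and their single-bit-flipped copies.
#' @slot hammingP Two-sided z-test p-value of `hammingMean` against the
#'   randomized-network null ensemble.
#' @slot gini In-degree Gini index of the synchronous state-transition
#'   graph.
#' @slot giniP Two-sided z-test p-value of `gini` against the null.
#' @slot hammingNull,giniNull Null-ensemble values (one per random
#'   network), kept for audit.
#' @slot nCopies Perturbation sample size per Hamming estimate.
#' @slot nNull Number of randomized networks in the null ensemble.
#' @slot seed Seed the whole report was derived from.
#' @export
setClass("RobustnessReport",
  representation(model = "character", hammingMean = "numeric",
                 hammingP = "numeric", gini = "numeric", giniP = "numeric",
                 hammingNull = "numeric", giniNull = "numeric",
                 nCopies = "integer", nNull = "integer", seed = "integer"))
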