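# Random Boolean network generation: the null ensemble for robustness
# testing and a source of structured fixtures for property tests.

# run code under a temporary seed without disturbing the caller's RNG
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a random Boolean network
#'
#' Each node receives a uniformly drawn input set of the requested size
#' (self-inputs permitted, mirroring the self-loops of the central
#' dogma models) and a random truth table whose rows are i.i.d.
#' Bernoulli(`bias`). Truth tables are rendered as rules in disjunctive
#' normal form, so generated networks flow through the same grammar,
#' file formats and analyses as curated models.
#'
#' @param nNodes Number of nodes.
#' @param inDegree Inputs per node: a scalar or a length-`nNodes`
#'   vector, each value in `0 .. nNodes`.
#' @param bias Probability that a truth-table row outputs 1.
#' @param seed Optional seed; generation is a pure function of
#'   `(nNodes, inDegree, bias, seed)`. The caller's RNG state is left
#'   untouched.
#' @param nodes Optional node names (default `x1 .. xn`).
#' @param name Model label.
#' @return A deterministic [BooleanNetwork-class].
#' @examples
#' net <- randomBooleanNetwork(5, 2, seed = 1)
#' identical(transitionTable(net),
#'           transitionTable(randomBooleanNetwork(5, 2, seed = 1)))
#' @export
randomBooleanNetwork <- function(nNodes, inDegree, bias = 0.5, seed = NULL,
                                 nodes = NULL, name = "random") {
  stopifnot(nNodes >= 1, bias >= 0, bias <= 1)
  if (is.null(nodes)) nodes <- paste0("x", seq_len(nNodes))
  stopifnot(length(nodes) == nNodes)
  inDegree <- as.integer(rep_len(inDegree, nNodes))
  stopifnot(all(inDegree >= 0L), all(inDegree <= nNodes))
  .withSeed(seed, {
    rules <- lapply(seq_len(nNodes), function(i) {
      k <- inDegree[i]
      inputs <- if (k > 0L) sample(nodes, k) else character(0)
      outputs <- stats::rbinom(2L^k, 1L, bias)
      .dnfRule(inputs, outputs, fallbackNode = nodes[1L])
    })
    names(rules) <- nodes
    booleanNetwork(name, nodes, rules)
  })
}

# render a truth table (inputs in MSB-first row order) as a DNF rule string
.dnfRule <- function(inputs, outputs, fallbackNode) {
  k <- length(inputs)
  anchor <- if (k > 0L) inputs[1L] else fallbackNode
  if (all(outputs == 1L)) return(sprintf("%s | !%s", anchor, anchor))
  if (all(outputs == 0L)) return(sprintf("%s & !%s", anchor, anchor))
  terms <- vapply(which(outputs == 1L) - 1L, function(row) {
    bits <- bitwAnd(row %/% 2L^((k - 1L):0L), 1L)
    lits <- ifelse(bits == 1L, inputs, paste0("!", inputs))
    paste(lits, collapse = " & ")
  }, character(1))
  paste(terms, collapse = " | ")
}

#' Randomize a network preserving its wiring-density profile
#'
#' Draws a random network with the same node count, node names and
#' per-node in-degrees (number of distinct inputs of each rule) as
#' `net`, with unbiased random truth tables. This is the null model for
#' [robustnessReport()]: it keeps each node's wiring density while
#' scrambling both the wiring and the logic.
#'
#' @param net A deterministic [BooleanNetwork-class].
#' @param seed Optional seed (see [randomBooleanNetwork()]).
#' @param bias Truth-table bias of the randomized rules.
#' @return A deterministic [BooleanNetwork-class].
#' @export
randomizeLike <- function(net, seed = NULL, bias = 0.5) {
  .requireDeterministic(net)
  k <- vapply(net@functions, function(fns) {
    length(ruleInputs(fns[[1L]]$expr))
  }, integer(1))
  randomBooleanNetwork(length(net@nodes), k, bias = bias, seed = seed,
                       nodes = net@nodes,
                       name = paste0(net@name, "-randomized"))
}
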