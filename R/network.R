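#' Construct a Boolean network
#'
#' @param name Model label.
#' @param nodes Character vector of node names; the order fixes the bit
#'   order of state strings and integer codes (first node leftmost /
#'   most significant).
#' @param rules Named list, one entry per node. A plain string gives a
#'   deterministic rule; a list of `list(rule = , prob = )` entries
#'   defines a probabilistic node whose probabilities must sum to 1.
#' @return A validated [BooleanNetwork-class] object.
#' @examples
#' net <- booleanNetwork("toy", c("A", "B"),
#'   list(A = "A | B", B = "!A"))
#' isDeterministic(net)
#' synchronousStep(net, "10")
#' @export
booleanNetwork <- function(name, nodes, rules) {
  stopifnot(is.character(nodes), length(nodes) >= 1L)
  if (!setequal(names(rules), nodes)) {
    stop("'rules' must have exactly one entry per node", call. = FALSE)
  }
  functions <- lapply(nodes, function(nd) {
    r <- rules[[nd]]
    if (is.character(r) && length(r) == 1L) {
      r <- list(list(rule = r, prob = 1))
    }
    lapply(r, function(f) {
      expr <- if (inherits(f$rule, "RuleExpression")) f$rule
              else parseRule(f$rule, nodes)
      list(expr = expr, prob = as.numeric(f$prob))
    })
  })
  names(functions) <- nodes
  new("BooleanNetwork", name = name, nodes = nodes, functions = functions)
}

#' @describeIn booleanNetwork Model label accessor.
#' @param net A [BooleanNetwork-class].
#' @export
networkName <- function(net) net@name

#' @describeIn booleanNetwork Node names in bit order.
#' @export
networkNodes <- function(net) net@nodes

#' @describeIn booleanNetwork Number of nodes.
#' @export
numNodes <- function(net) length(net@nodes)

#' @describeIn booleanNetwork Update rules of one node (or all nodes):
#'   a list of `list(expr, prob)` entries.
#' @param node Optional node name.
#' @export
nodeFunctions <- function(net, node = NULL) {
  if (is.null(node)) return(net@functions)
  if (!node %in% net@nodes) {
    stop(sprintf("unknown node '%s'", node), call. = FALSE)
  }
  net@functions[[node]]
}

#' @describeIn booleanNetwork `TRUE` iff every node has exactly one rule.
#' @export
isDeterministic <- function(net) {
  all(vapply(net@functions, length, integer(1)) == 1L)
}

setMethod("show", "BooleanNetwork", function(object) {
  kind <- if (isDeterministic(object)) "deterministic" else "probabilistic"
  cat(sprintf("BooleanNetwork '%s': %d nodes (%s)\n",
              object@name, length(object@nodes), kind))
  for (nd in object@nodes) {
    for (f in object@functions[[nd]]) {
      p <- if (f$prob < 1) sprintf("  [p=%g]", f$prob) else ""
      cat(sprintf("  %s <- %s%s\n", nd, ruleToString(f$expr), p))
    }
  }
})

# per node, per function: logical vector of next-bit over all 2^n states
.nextBitTables <- function(net) {
  lapply(net@nodes, function(nd) {
    lapply(net@functions[[nd]], function(f) .evalAllStates(f$expr, net@nodes))
  })
}

.checkStateSpace <- function(net, guard = 24L) {
  if (length(net@nodes) > guard) {
    stop(sprintf("state space 2^%d exceeds the exhaustive-search guard (n <= %d)",
                 length(net@nodes), guard), call. = FALSE)
  }
}

.requireDeterministic <- function(net) {
  if (!isDeterministic(net)) {
    stop("this operation requires a deterministic network (one rule per node)",
         call. = FALSE)
  }
}

#' Synchronous successor map of a deterministic network
#'
#' Enumerates all `2^n` states and returns, for each, its synchronous
#' successor: every node updated simultaneously from the same source
#' state.
#'
#' @param net A deterministic [BooleanNetwork-class] (n <= 24).
#' @return Integer vector of length `2^n`; position `i` holds the
#'   0-based successor code of the state with code `i - 1`.
#' @export
transitionTable <- function(net) {
  .requireDeterministic(net)
  .checkStateSpace(net)
  n <- length(net@nodes)
  nb <- .nextBitTables(net)
  out <- 0
  for (i in seq_len(n)) out <- out + as.integer(nb[[i]][[1L]]) * 2^(n - i)
  as.integer(out)
}

# coerce a user-supplied state (string or 0-based integer) to integer code
.stateCode <- function(state, net) {
  if (is.character(state)) {
    code <- stateFromString(state)
    if (nchar(state) != length(net@nodes)) {
      stop(sprintf("state '%s' has %d bits but the network has %d nodes",
                   state, nchar(state), length(net@nodes)), call. = FALSE)
    }
    code
  } else {
    code <- as.integer(state)
    stopifnot(code >= 0L, code < 2^length(net@nodes))
    code
  }
}

#' One synchronous update step
#'
#' All nodes are updated simultaneously from the same source state.
#'
#' @param net A deterministic [BooleanNetwork-class].
#' @param state A state string (e.g. `"1110"`) or 0-based integer code.
#' @return The successor state, in the same form as the input.
#' @examples
#' v1 <- cdModel("CD1965-V1")
#' synchronousStep(v1, "1110")  # "1101"
#' @export
synchronousStep <- function(net, state) {
  .requireDeterministic(net)
  code <- .stateCode(state, net)
  n <- length(net@nodes)
  bits <- bitwAnd(code %/% 2L^((n - 1L):0L), 1L)
  named <- setNames(bits, net@nodes)
  newBits <- vapply(seq_len(n), function(i) {
    evaluateRule(net@functions[[i]][[1L]]$expr, named)
  }, integer(1))
  out <- sum(newBits * 2L^((n - 1L):0L))
  if (is.character(state)) stateToString(out, n) else as.integer(out)
}

#' Asynchronous single-node successors
#'
#' For each node, the state obtained by updating exactly that node and
#' copying all others. Successors equal to the source state are still
#' reported; the successor count always equals the node count.
#'
#' @inheritParams synchronousStep
#' @return data.frame with columns `node`, `state` (successor, in the
#'   input's form) and `changed` (did the updated bit flip?).
#' @export
asynchronousSuccessors <- function(net, state) {
  .requireDeterministic(net)
  code <- .stateCode(state, net)
  n <- length(net@nodes)
  bits <- bitwAnd(code %/% 2L^((n - 1L):0L), 1L)
  named <- setNames(bits, net@nodes)
  succ <- vapply(seq_len(n), function(i) {
    newBit <- evaluateRule(net@functions[[i]][[1L]]$expr, named)
    code + (newBit - bits[i]) * 2L^(n - i)
  }, numeric(1))
  out <- if (is.character(state)) stateToString(as.integer(succ), n)
         else as.integer(succ)
  data.frame(node = net@nodes, state = out,
             changed = as.integer(succ) != code,
             stringsAsFactors = FALSE)
}
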