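#' Build the complete state-transition graph of a network
#'
#' Enumerates all `2^n` states and records their transitions under the
#' requested update semantics. Synchronous graphs of deterministic
#' networks have out-degree exactly 1 (self-loops kept); asynchronous
#' graphs have one edge per single-node update that changes the state
#' (self-transitions omitted, so a state fixed under every update is an
#' isolated vertex); `pbn` graphs carry the exact Markov transition
#' probabilities of [pbnTransitionMatrix()].
#'
#' @param net A [BooleanNetwork-class] (deterministic for
#'   `"synchronous"`/`"asynchronous"`; n <= 24, and n <= 16 for `"pbn"`).
#' @param mode Update semantics.
#' @return A [StateTransitionGraph-class].
#' @examples
#' stg <- buildSTG(cdModel("CD1965-V1"), "synchronous")
#' nrow(stgEdges(stg))  # 16 edges, one per state
#' @export
buildSTG <- function(net, mode = c("synchronous", "asynchronous", "pbn")) {
  mode <- match.arg(mode)
  .checkStateSpace(net)
  n <- length(net@nodes)
  N <- 2L^n
  edges <- switch(mode,
    synchronous = {
      .requireDeterministic(net)
      data.frame(from = 0:(N - 1L), to = transitionTable(net), prob = 1)
    },
    asynchronous = {
      .requireDeterministic(net)
      .asyncEdges(net)
    },
    pbn = {
      P <- pbnTransitionMatrix(net)
      idx <- which(P > 0, arr.ind = TRUE)
      data.frame(from = idx[, 1L] - 1L, to = idx[, 2L] - 1L,
                 prob = P[idx])
    }
  )
  new("StateTransitionGraph", mode = mode, nodes = net@nodes, edges = edges)
}

# non-self single-node-update edges over all states (vectorized per node)
.asyncEdges <- function(net) {
  n <- length(net@nodes)
  N <- 2L^n
  nb <- .nextBitTables(net)
  states <- 0:(N - 1L)
  from <- integer(0)
  to <- integer(0)
  for (i in seq_len(n)) {
    bit <- bitwAnd(states %/% 2L^(n - i), 1L)
    newBit <- as.integer(nb[[i]][[1L]])
    succ <- states + (newBit - bit) * 2L^(n - i)
    keep <- succ != states
    from <- c(from, states[keep])
    to <- c(to, as.integer(succ[keep]))
  }
  data.frame(from = from, to = to, prob = 1)
}

#' @describeIn buildSTG Edge table accessor (`from`/`to` are 0-based
#'   state codes).
#' @param stg A [StateTransitionGraph-class].
#' @export
stgEdges <- function(stg) stg@edges

#' @describeIn buildSTG Update semantics of the graph.
#' @export
stgMode <- function(stg) stg@mode

#' @describeIn buildSTG Node order underlying the state encoding.
#' @export
stgNodes <- function(stg) stg@nodes

#' @describeIn buildSTG In-degree of every state (self-loops counted
#'   unless `selfLoops = FALSE`).
#' @param selfLoops Count self-loop edges?
#' @export
stgInDegrees <- function(stg, selfLoops = TRUE) {
  N <- 2L^length(stg@nodes)
  e <- stg@edges
  if (!selfLoops) e <- e[e$from != e$to, , drop = FALSE]
  tabulate(e$to + 1L, N)
}

setMethod("show", "StateTransitionGraph", function(object) {
  N <- 2^length(object@nodes)
  cat(sprintf("StateTransitionGraph (%s): %d states, %d edges over nodes %s\n",
              object@mode, N, nrow(object@edges),
              paste(object@nodes, collapse = "/")))
})

#' Convert a state-transition graph (or attractor) to igraph
#'
#' Vertices are all `2^n` states (or the attractor's states), named by
#' their canonical state strings; edge probabilities are kept as the
#' `prob` edge attribute.
#'
#' @param x A [StateTransitionGraph-class] or a complex
#'   [Attractor-class].
#' @return A directed [igraph::igraph] object.
#' @export
asIgraph <- function(x) {
  if (is(x, "StateTransitionGraph")) {
    n <- length(x@nodes)
    verts <- stateToString(0:(2L^n - 1L), n)
    df <- data.frame(from = stateToString(x@edges$from, n),
                     to = stateToString(x@edges$to, n),
                     prob = x@edges$prob)
    igraph::graph_from_data_frame(df, directed = TRUE,
                                  vertices = data.frame(name = verts))
  } else if (is(x, "Attractor")) {
    n <- length(x@nodes)
    verts <- stateToString(x@states, n)
    df <- if (nrow(x@edges)) {
      data.frame(from = stateToString(x@edges$from, n),
                 to = stateToString(x@edges$to, n))
    } else if (x@kind == "limit_cycle") {
      data.frame(from = stateToString(x@states, n),
                 to = stateToString(c(x@states[-1L], x@states[1L]), n))
    } else {
      data.frame(from = character(0), to = character(0))
    }
    igraph::graph_from_data_frame(df, directed = TRUE,
                                  vertices = data.frame(name = verts))
  } else {
    stop("asIgraph() expects a StateTransitionGraph or Attractor", call. = FALSE)
  }
}

#' Export a graph as GraphML
#'
#' Writes a [StateTransitionGraph-class], [Attractor-class] or igraph
#' object as GraphML (readable by Gephi, Cytoscape, yEd, ...).
#'
#' @param x Graph-like object accepted by [asIgraph()], or an igraph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(x, path) {
  g <- if (inherits(x, "igraph")) x else asIgraph(x)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
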