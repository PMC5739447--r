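# Exhaustive attractor and basin analysis.
#
# Synchronous search: the successor map is a functional graph; pointer
# doubling sends every state onto its eventual cycle in O(N log N),
# after which cycles are walked out and basins tallied.

#' Find all synchronous attractors (fixed points and limit cycles)
#'
#' Exhaustively analyzes the synchronous state-transition graph of a
#' deterministic network. Every one of the `2^n` states belongs to the
#' basin of exactly one attractor, so basin counts sum to `2^n`. Limit
#' cycles are reported in forward-trajectory order starting from their
#' smallest state code.
#'
#' @param net A deterministic [BooleanNetwork-class] (n <= 24).
#' @return An [AttractorSet-class]; attractors sorted by smallest member
#'   state.
#' @examples
#' findAttractorsSync(cdModel("CD1965-V1"))  # 8 fixed points
#' @export
findAttractorsSync <- function(net) {
  .requireDeterministic(net)
  .checkStateSpace(net)
  n <- length(net@nodes)
  N <- 2L^n
  nxt <- transitionTable(net)

  # f = nxt composed with itself >= N times: every state lands on its cycle
  f <- nxt
  steps <- 1
  while (steps < N) {
    f <- f[f + 1L]
    steps <- steps * 2
  }

  cycleStates <- sort(unique(f))
  onCycle <- logical(N)
  onCycle[cycleStates + 1L] <- TRUE
  attractors <- list()
  attId <- integer(N)
  visited <- logical(N)
  for (s in cycleStates) {
    if (visited[s + 1L]) next
    cycle <- s
    t <- nxt[s + 1L]
    while (t != s) {
      cycle <- c(cycle, t)
      t <- nxt[t + 1L]
    }
    visited[cycle + 1L] <- TRUE
    m <- which.min(cycle)
    cycle <- c(cycle[m:length(cycle)], cycle[seq_len(m - 1L)])
    attractors[[length(attractors) + 1L]] <- cycle
    attId[cycle + 1L] <- length(attractors)
  }

  basinId <- attId[f + 1L]
  basinCounts <- tabulate(basinId, length(attractors))

  objs <- lapply(seq_along(attractors), function(i) {
    st <- as.integer(attractors[[i]])
    new("Attractor",
        kind = if (length(st) == 1L) "fixed_point" else "limit_cycle",
        states = st, nodes = net@nodes,
        basinCount = basinCounts[i],
        basinPct = 100 * basinCounts[i] / N,
        edges = data.frame(from = integer(0), to = integer(0)))
  })
  ord <- order(vapply(objs, function(a) min(a@states), integer(1)))
  new("AttractorSet", model = net@name, mode = "synchronous",
      nodes = net@nodes, attractors = objs[ord])
}

#' Find all asynchronous attractors (simple and complex)
#'
#' Simple attractors are states fixed under every single-node update
#' (isolated vertices of the asynchronous state-transition graph, which
#' excludes self-transitions); complex ("loose") attractors are terminal
#' strongly connected components with at least two states, reported with
#' their internal non-self edge lists.
#'
#' @param net A deterministic [BooleanNetwork-class] (n <= 24).
#' @return An [AttractorSet-class]. Basin statistics are not defined for
#'   the asynchronous semantics and are reported as `NA`.
#' @examples
#' aset <- findAttractorsAsync(cdModel("CD-V2"))
#' vapply(attractors(aset), attractorKind, character(1))
#' @export
findAttractorsAsync <- function(net) {
  .requireDeterministic(net)
  .checkStateSpace(net)
  n <- length(net@nodes)
  N <- 2L^n
  e <- .asyncEdges(net)

  g <- igraph::graph_from_edgelist(cbind(e$from, e$to) + 1L, directed = TRUE)
  if (igraph::vcount(g) < N) {
    g <- igraph::add_vertices(g, N - igraph::vcount(g))
  }
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  # an SCC is terminal iff no edge leaves it
  leaving <- unique(memb[e$from + 1L][memb[e$from + 1L] != memb[e$to + 1L]])
  terminal <- setdiff(seq_len(comp$no), leaving)

  hasOut <- logical(N)
  hasOut[unique(e$from) + 1L] <- TRUE
  objs <- list()
  for (tc in terminal) {
    st <- which(memb == tc) - 1L
    if (length(st) == 1L) {
      # singleton terminal SCC is an attractor only if truly fixed
      if (!hasOut[st + 1L]) {
        objs[[length(objs) + 1L]] <- new("Attractor",
          kind = "fixed_point", states = as.integer(st), nodes = net@nodes,
          basinCount = NA_integer_, basinPct = NA_real_,
          edges = data.frame(from = integer(0), to = integer(0)))
      }
    } else {
      keep <- e$from %in% st & e$to %in% st
      objs[[length(objs) + 1L]] <- new("Attractor",
        kind = "complex", states = sort(as.integer(st)), nodes = net@nodes,
        basinCount = NA_integer_, basinPct = NA_real_,
        edges = data.frame(from = e$from[keep], to = e$to[keep]))
    }
  }
  ord <- order(vapply(objs, function(a) min(a@states), integer(1)))
  new("AttractorSet", model = net@name, mode = "asynchronous",
      nodes = net@nodes, attractors = objs[ord])
}

#' Basin size of an attractor in a synchronous state-transition graph
#'
#' Counts the states whose forward orbit enters the attractor; attractor
#' states belong to their own basin.
#'
#' @param stg A synchronous [StateTransitionGraph-class].
#' @param attractor An [Attractor-class], a state string vector, or a
#'   vector of 0-based state codes identifying the attractor's states.
#' @return Integer basin size.
#' @examples
#' stg <- buildSTG(cdModel("CD1965-V1"), "synchronous")
#' basinOf(stg, "1111")  # 3
#' @export
basinOf <- function(stg, attractor) {
  if (stg@mode != "synchronous") {
    stop("basinOf() requires a synchronous state-transition graph", call. = FALSE)
  }
  states <- if (is(attractor, "Attractor")) attractor@states
            else if (is.character(attractor)) stateFromString(attractor)
            else as.integer(attractor)
  N <- 2L^length(stg@nodes)
  nxt <- stg@edges$to[order(stg@edges$from)]
  if (!all(states >= 0L & states < N)) {
    stop("attractor states lie outside this graph's state space", call. = FALSE)
  }
  # verify the claimed attractor is closed under the successor map
  if (!all(nxt[states + 1L] %in% states)) {
    stop("supplied states are not a closed attractor of this graph", call. = FALSE)
  }
  f <- nxt
  steps <- 1
  while (steps < N) {
    f <- f[f + 1L]
    steps <- steps * 2
  }
  sum(f %in% states)
}

#' @describeIn findAttractorsSync List of [Attractor-class] objects in a
#'   set.
#' @param aset An [AttractorSet-class].
#' @export
attractors <- function(aset) aset@attractors

#' Attractor accessors
#'
#' @param a An [Attractor-class].
#' @return `attractorKind()`: `"fixed_point"`, `"limit_cycle"` or
#'   `"complex"`. `attractorStates()`: canonical state strings.
#'   `attractorStateCodes()`: 0-based integer codes.
#'   `basinPercentage()`/`basinSize()`: basin statistics (`NA` for
#'   asynchronous attractors). `attractorEdges()`: internal edges of a
#'   complex attractor as a `from`/`to` data.frame of state strings.
#' @export
attractorKind <- function(a) a@kind

#' @rdname attractorKind
#' @export
attractorStates <- function(a) stateToString(a@states, length(a@nodes))

#' @rdname attractorKind
#' @export
attractorStateCodes <- function(a) a@states

#' @rdname attractorKind
#' @export
basinPercentage <- function(a) a@basinPct

#' @rdname attractorKind
#' @export
basinSize <- function(a) a@basinCount

#' @rdname attractorKind
#' @export
attractorEdges <- function(a) {
  n <- length(a@nodes)
  data.frame(from = stateToString(a@edges$from, n),
             to = stateToString(a@edges$to, n),
             stringsAsFactors = FALSE)
}

setMethod("show", "Attractor", function(object) {
  n <- length(object@nodes)
  lab <- switch(object@kind,
    fixed_point = attractorStates(object),
    limit_cycle = paste(attractorStates(object), collapse = " > "),
    complex = sprintf("%d states, %d internal edges",
                      length(object@states), nrow(object@edges)))
  basin <- if (is.na(object@basinCount)) ""
           else sprintf(" basin %d (%.2f%%)", object@basinCount, object@basinPct)
  cat(sprintf("Attractor [%s] %s%s\n", object@kind, lab, basin))
})

setMethod("show", "AttractorSet", function(object) {
  cat(sprintf("AttractorSet '%s' (%s): %d attractor(s)\n",
              object@model, object@mode, length(object@attractors)))
  for (a in object@attractors) show(a)
})

#' Tabulate an attractor set
#'
#' @param aset An [AttractorSet-class].
#' @return data.frame with one row per attractor: `kind`, `states`
#'   (`>`-joined cycle order), `size`, `basinCount`, `basinPct`.
#' @export
attractorTable <- function(aset) {
  rows <- lapply(aset@attractors, function(a) {
    data.frame(model = aset@model, mode = aset@mode, kind = a@kind,
               states = paste(attractorStates(a), collapse = " > "),
               size = length(a@states),
               basinCount = a@basinCount, basinPct = round(a@basinPct, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an attractor report to CSV or JSON
#'
#' @param aset An [AttractorSet-class].
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (defaults from the file extension).
#' @return `path`, invisibly.
#' @export
exportAttractors <- function(aset, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    write.csv(attractorTable(aset), path, row.names = FALSE)
  } else {
    payload <- list(
      model = aset@model, mode = aset@mode, nodes = aset@nodes,
      attractors = lapply(aset@attractors, function(a) {
        list(kind = a@kind, states = attractorStates(a),
             basinCount = a@basinCount, basinPct = a@basinPct,
             edges = if (nrow(a@edges)) attractorEdges(a) else NULL)
      }))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}
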