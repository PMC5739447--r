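# Graph statistics of state-transition graphs and complex attractors:
# betweenness/closeness centralities and the in-degree Gini index.

#' Betweenness and closeness centralities of a directed state graph
#'
#' Computes unweighted shortest-path betweenness (endpoints excluded)
#' and normalized closeness for every vertex of a directed graph,
#' typically a complex attractor. The closeness convention is
#' configurable: `"out"` (default) scores how quickly a state reaches
#' the others along directed paths, `"in"` how quickly it is reached.
#' In the 32-state complex attractor of the present-day
#' mRNA-expression-inhibition model, the all-ON state `1111111`
#' maximizes outgoing closeness and `1001111` (degradation components
#' inactive) maximizes betweenness.
#'
#' @param x A complex [Attractor-class], a [StateTransitionGraph-class],
#'   or a directed igraph object.
#' @param closenessMode Distance direction for closeness: `"out"` or
#'   `"in"`.
#' @return data.frame with columns `state` (vertex name), `betweenness`
#'   and `closeness`, in vertex order.
#' @examples
#' aset <- findAttractorsAsync(cdModel("CD-V2"))
#' cx <- Filter(function(a) attractorKind(a) == "complex", attractors(aset))[[1]]
#' ct <- stateCentralities(cx)
#' ct$state[which.max(ct$closeness)]  # "1111111"
#' @export
stateCentralities <- function(x, closenessMode = c("out", "in")) {
  closenessMode <- match.arg(closenessMode)
  g <- if (inherits(x, "igraph")) x else asIgraph(x)
  if (igraph::vcount(g) == 0L) {
    stop("empty graph: no vertices to score", call. = FALSE)
  }
  btw <- igraph::betweenness(g, directed = TRUE, weights = NA)
  clo <- if (igraph::vcount(g) == 1L) {
    0
  } else {
    suppressWarnings(
      igraph::closeness(g, mode = closenessMode, weights = NA,
                        normalized = TRUE)
    )
  }
  clo[!is.finite(clo)] <- 0
  data.frame(state = igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g))),
             betweenness = unname(btw), closeness = unname(clo),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gini coefficient of a non-negative sequence
#'
#' Mean absolute difference between all pairs, scaled by twice the mean.
#' `corrected = TRUE` (the default used for state-transition graphs)
#' applies the small-sample factor `n / (n - 1)`, the unbiased form most
#' inequality software reports; `corrected = FALSE` gives the population
#' definition `sum_ij |x_i - x_j| / (2 n^2 mean(x))`.
#'
#' @param x Non-negative numeric vector with a positive mean.
#' @param corrected Apply the `n/(n-1)` small-sample correction?
#' @return Gini coefficient; 0 for a constant sequence.
#' @export
giniCoefficient <- function(x, corrected = TRUE) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least two values", call. = FALSE)
  if (any(x < 0)) stop("gini is defined for non-negative values", call. = FALSE)
  if (mean(x) == 0) stop("gini undefined: all values are zero", call. = FALSE)
  n <- length(x)
  xs <- sort(x)
  # sum_ij |xi - xj| = 2 * sum_i (2i - n - 1) x_(i)
  g <- 2 * sum((2 * seq_len(n) - n - 1) * xs) / (2 * n^2 * mean(xs))
  if (corrected) g <- g * n / (n - 1)
  g
}

#' In-degree Gini index of a state-transition graph
#'
#' Measures the inhomogeneity of the in-degree distribution over all
#' `2^n` states. High values mean a few states absorb most transitions
#' (a funnel-shaped landscape); 0 means every state is reached equally
#' often. Defaults (self-loops counted, small-sample corrected
#' estimator) reproduce 0.918 for the present-day activatory model and
#' 0.575 for the 1965 models.
#'
#' @param stg A [StateTransitionGraph-class] (typically synchronous).
#' @param selfLoops Count self-loop edges toward in-degree?
#' @param corrected Passed to [giniCoefficient()].
#' @return Gini index in `[0, 1]`.
#' @examples
#' round(giniIndegree(buildSTG(cdModel("CD-V1"), "synchronous")), 3)
#' @export
giniIndegree <- function(stg, selfLoops = TRUE, corrected = TRUE) {
  indeg <- stgInDegrees(stg, selfLoops = selfLoops)
  giniCoefficient(indeg, corrected = corrected)
}
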