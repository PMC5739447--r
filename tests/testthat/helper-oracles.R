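# Independent oracles used to cross-check the attractor machinery.
# They deliberately avoid the code paths under test: trajectories are
# simulated one synchronousStep()/asynchronousSuccessors() call at a
# time instead of going through transition tables, pointer doubling or
# igraph components.

# Per-initial-state trajectory simulation: follow each state until a
# previously classified state or a fresh cycle is met.
oracleSyncAttractors <- function(net) {
  n <- numNodes(net)
  N <- 2L^n
  basinId <- rep(NA_integer_, N)
  cycles <- list()
  for (s0 in 0:(N - 1L)) {
    if (!is.na(basinId[s0 + 1L])) next
    path <- integer(0)
    s <- s0
    repeat {
      if (!is.na(basinId[s + 1L])) {
        id <- basinId[s + 1L]
        break
      }
      hit <- match(s, path)
      if (!is.na(hit)) {
        cyc <- path[hit:length(path)]
        m <- which.min(cyc)
        cyc <- c(cyc[m:length(cyc)], cyc[seq_len(m - 1L)])
        cycles[[length(cycles) + 1L]] <- cyc
        id <- length(cycles)
        break
      }
      path <- c(path, s)
      s <- synchronousStep(net, s)
    }
    basinId[path + 1L] <- id
    if (is.na(basinId[s + 1L])) basinId[s + 1L] <- id
  }
  list(cycles = cycles, basinCounts = tabulate(basinId, length(cycles)))
}

# Reachability-closure oracle for asynchronous attractors: a state s is
# an attractor member iff every state reachable from s can reach s
# back; attractors are the distinct reachable sets of such states.
oracleAsyncAttractors <- function(net) {
  n <- numNodes(net)
  N <- 2L^n
  succ <- lapply(0:(N - 1L), function(s) {
    out <- asynchronousSuccessors(net, s)
    unique(out$state[out$changed])
  })
  reach <- vector("list", N)
  for (s in 0:(N - 1L)) {
    seen <- logical(N)
    seen[s + 1L] <- TRUE
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      for (w in succ[[v + 1L]]) {
        if (!seen[w + 1L]) {
          seen[w + 1L] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    reach[[s + 1L]] <- which(seen) - 1L
  }
  inAttractor <- vapply(0:(N - 1L), function(s) {
    all(vapply(reach[[s + 1L]], function(t) s %in% reach[[t + 1L]], logical(1)))
  }, logical(1))
  keys <- vapply(which(inAttractor) - 1L, function(s) {
    paste(reach[[s + 1L]], collapse = ",")
  }, character(1))
  lapply(unique(keys), function(k) sort(as.integer(strsplit(k, ",")[[1L]])))
}

# canonical representation for attractor-set comparison
canonicalAttractorSets <- function(listOfStateVectors) {
  keys <- vapply(listOfStateVectors, function(v) {
    paste(sort(v), collapse = ",")
  }, character(1))
  sort(keys)
}

# a small pool of seeded random networks reused by property tests
randomNetworkPool <- function(count, seed = 424242L) {
  lapply(seq_len(count), function(i) {
    nNodes <- 4L + ((seed + i) %% 4L)  # 4..7
    k <- 1L + ((seed + 3L * i) %% 3L)  # 1..3
    bias <- c(0.25, 0.5, 0.75)[1L + (i %% 3L)]
    randomBooleanNetwork(nNodes, k, bias = bias, seed = seed + i,
                         name = sprintf("pool-%d", i))
  })
}
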