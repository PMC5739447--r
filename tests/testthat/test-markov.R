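# Exact Markov-chain iteration and the PBN transition law.

test_that("deterministic transition matrix is the successor map", {
  net <- cdModel("CD-V1")
  P <- pbnTransitionMatrix(net)
  nxt <- transitionTable(net)
  expect_equal(rowSums(P), rep(1, 128))
  for (s in c(0L, 17L, 72L, 127L)) {
    expect_equal(which(P[s + 1L, ] > 0) - 1L, nxt[s + 1L])
    expect_equal(P[s + 1L, nxt[s + 1L] + 1L], 1)
  }
})

test_that("PBN rows aggregate independent per-node rule selections", {
  pbn <- cdModel("CD-PBN")
  P <- pbnTransitionMatrix(pbn)
  expect_equal(rowSums(P), rep(1, 128), tolerance = 1e-12)

  # at 0001000 (DNA on, everything else off) the two miRNA rules and the
  # two mRNA rules disagree while DNA's agree: hand enumeration of the
  # 2x2x2 joint selections gives 4 targets with probs .64/.16/.16/.04
  row <- P["0001000" == stateToString(0:127, 7), ]
  hits <- sort(row[row > 0], decreasing = TRUE)
  expect_equal(unname(hits), c(0.64, 0.16, 0.16, 0.04))
  targets <- stateToString(which(row > 0) - 1L, 7)
  expect_setequal(targets, c("0001000", "0001010", "0001100", "0001110"))
})

test_that("iteration is exact: identity at 0 steps, point masses follow orbits", {
  net <- cdModel("CD-V3")
  d0 <- iterateDistribution(net, 0)
  expect_equal(unname(stateProbabilities(d0)), rep(1 / 128, 128))

  for (start in c(3L, 77L, 120L)) {
    k <- 5L
    d <- iterateDistribution(net, k, initial = start)
    s <- start
    for (i in seq_len(k)) s <- synchronousStep(net, s)
    p <- stateProbabilities(d)
    expect_equal(unname(p[s + 1L]), 1)
  }

  # matrix route and successor-map route implement the same law
  dMap <- stateProbabilities(iterateDistribution(net, 7))
  P <- pbnTransitionMatrix(net)
  v <- rep(1 / 128, 128)
  for (i in 1:7) v <- as.vector(v %*% P)
  expect_equal(unname(dMap), v, tolerance = 1e-12)
})

test_that("probability mass is conserved across 1000 iterations", {
  for (id in c("CD-V2", "CD-PBN")) {
    d <- iterateDistribution(cdModel(id), 1000)
    expect_equal(sum(stateProbabilities(d)), 1, tolerance = 1e-9)
    expect_true(all(stateProbabilities(d) >= 0))
  }
})

test_that("long-run cycle mass equals the synchronous basin fraction", {
  d <- stateProbabilities(iterateDistribution(cdModel("CD-V2"), 1000))
  cyc <- c("1001000", "1001010", "1001111", "1111101")
  expect_equal(sum(d[cyc]), 68 / 128, tolerance = 1e-9)
  expect_equal(round(unname(d[c("1111101", "1001111")]), 3), c(0.234, 0.203))
})

test_that("absorption report applies the cutoff and sorts by state", {
  dV1 <- iterateDistribution(cdModel("CD-V1"), 1000)
  rep1 <- reportAbsorption(dV1, cutoff = 0.001)
  expect_equal(rep1$state, c("0000000", "0001000", "1000000", "1001000"))
  expect_equal(rep1$display, c(0.125, 0.125, 0.219, 0.531))

  expect_equal(nrow(reportAbsorption(dV1, cutoff = 1.0)), 0L)

  repPBN <- reportAbsorption(iterateDistribution(cdModel("CD-PBN"), 1000))
  expect_equal(nrow(repPBN), 16L)
  expect_equal(repPBN$display[repPBN$state == "0001010"], 0.016)
  expect_equal(repPBN$display[repPBN$state == "1111011"], 0.009)
  # states reachable only through the mixture, absent from every
  # deterministic version's absorption set
  detStates <- unlist(lapply(paste0("CD-V", 1:8), function(id) {
    reportAbsorption(iterateDistribution(cdModel(id), 1000))$state
  }))
  expect_true(all(!c("0001010", "1001101", "1111001", "1111011", "1111111")
                  %in% detStates))
})
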