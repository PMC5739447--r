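# Exhaustive attractor search, basins, and the state-transition graph.

test_that("synchronous STGs have one edge per state; guard trips on large n", {
  stg <- buildSTG(cdModel("CD1965-V1"), "synchronous")
  expect_equal(nrow(stgEdges(stg)), 16L)
  expect_equal(sort(stgEdges(stg)$from), 0:15)
  expect_equal(sum(stgInDegrees(stg)), 16L)

  stg7 <- buildSTG(cdModel("CD-V1"), "synchronous")
  expect_equal(nrow(stgEdges(stg7)), 128L)

  astg <- buildSTG(cdModel("CD-V2"), "asynchronous")
  outdeg <- table(stgEdges(astg)$from)
  expect_true(all(outdeg <= 7L))
  expect_true(all(stgEdges(astg)$from != stgEdges(astg)$to))

  big <- booleanNetwork("big", paste0("x", 1:25),
                        setNames(as.list(paste0("x", 1:25)), paste0("x", 1:25)))
  expect_error(buildSTG(big, "synchronous"), "guard")
})

test_that("1965 fixed points and basins match the known synchronous landscape", {
  a1 <- findAttractorsSync(cdModel("CD1965-V1"))
  expect_length(attractors(a1), 8L)
  expect_true(all(vapply(attractors(a1), attractorKind, character(1)) ==
                    "fixed_point"))
  t1 <- attractorTable(a1)
  expect_equal(t1$basinPct[t1$states == "1111"], 18.75)
  expect_equal(t1$basinPct[t1$states == "0000"], 12.5)

  a2 <- findAttractorsSync(cdModel("CD1965-V2"))
  expect_length(attractors(a2), 7L)
  t2 <- attractorTable(a2)
  expect_equal(t2$states[which.max(t2$basinPct)], "1101")
  expect_equal(max(t2$basinPct), 25)

  expect_length(union(t1$states, t2$states), 11L)
})

test_that("present-day synchronous attractors: fixed points, cycles, basins", {
  aV1 <- attractorTable(findAttractorsSync(cdModel("CD-V1")))
  expect_equal(aV1$states,
               c("0000000", "0001000", "1000000", "1001000"))
  expect_equal(aV1$basinPct, c(12.5, 12.5, 21.88, 53.12))

  aV8 <- findAttractorsSync(cdModel("CD-V8"))
  kinds <- vapply(attractors(aV8), attractorKind, character(1))
  expect_equal(sum(kinds == "fixed_point"), 3L)
  expect_equal(sum(kinds == "limit_cycle"), 1L)
  cyc <- attractors(aV8)[[which(kinds == "limit_cycle")]]
  expect_equal(attractorStates(cyc),
               c("1001000", "1001110", "1001111", "1111101"))
  expect_equal(basinPercentage(cyc), 100 * 74 / 128)
})

test_that("basins partition the state space in every deterministic model", {
  for (id in setdiff(cdModelIds(), "CD-PBN")) {
    aset <- findAttractorsSync(cdModel(id))
    counts <- vapply(attractors(aset), basinSize, integer(1))
    expect_equal(sum(counts), 2L^numNodes(cdModel(id)), info = id)
  }
})

test_that("basinOf counts forward orbits into a verified attractor", {
  stg <- buildSTG(cdModel("CD1965-V1"), "synchronous")
  expect_equal(basinOf(stg, "1111"), 3L)
  stg2 <- buildSTG(cdModel("CD1965-V2"), "synchronous")
  expect_equal(basinOf(stg2, "1101"), 4L)
  expect_error(basinOf(stg, "1110"), "not a closed attractor")
  expect_error(basinOf(buildSTG(cdModel("CD-V1"), "asynchronous"), "0000000"),
               "synchronous")
})

test_that("asynchronous analysis separates simple and complex attractors", {
  aV1 <- findAttractorsAsync(cdModel("CD-V1"))
  kinds <- vapply(attractors(aV1), attractorKind, character(1))
  expect_true(all(kinds == "fixed_point"))
  expect_setequal(vapply(attractors(aV1), attractorStates, character(1)),
                  c("0000000", "1000000", "0001000", "1001000"))

  aV2 <- findAttractorsAsync(cdModel("CD-V2"))
  kinds <- vapply(attractors(aV2), attractorKind, character(1))
  expect_setequal(kinds, c("fixed_point", "complex"))
  cx <- attractors(aV2)[[which(kinds == "complex")]]
  expect_length(attractorStateCodes(cx), 32L)
  expect_equal(nrow(attractorEdges(cx)), 84L)
  expect_true(all(c("1111111", "1001000") %in% attractorStates(cx)))

  # closure: no single-node update leaves the complex attractor
  inside <- attractorStates(cx)
  for (s in inside) {
    succ <- asynchronousSuccessors(cdModel("CD-V2"), s)
    expect_true(all(succ$state %in% inside), info = s)
  }
  # strong connectivity via the recorded internal edges
  g <- asIgraph(cx)
  expect_true(igraph::is_connected(g, mode = "strong"))
})

test_that("attractor search agrees with independent oracles on random networks", {
  pool <- randomNetworkPool(25, seed = 90210L)
  for (net in pool) {
    aset <- findAttractorsSync(net)
    got <- canonicalAttractorSets(lapply(attractors(aset),
                                         attractorStateCodes))
    oracle <- oracleSyncAttractors(net)
    expect_equal(got, canonicalAttractorSets(oracle$cycles),
                 info = networkName(net))
    gotBasins <- sort(vapply(attractors(aset), basinSize, integer(1)))
    expect_equal(gotBasins, sort(oracle$basinCounts),
                 info = networkName(net))

    asyncSet <- findAttractorsAsync(net)
    gotAsync <- canonicalAttractorSets(lapply(attractors(asyncSet),
                                              attractorStateCodes))
    expect_equal(gotAsync,
                 canonicalAttractorSets(oracleAsyncAttractors(net)),
                 info = networkName(net))
  }
})

test_that("degenerate generators produce the forced dynamics", {
  allOn <- randomBooleanNetwork(4, 0, bias = 1, seed = 5)
  aset <- findAttractorsSync(allOn)
  expect_length(attractors(aset), 1L)
  expect_equal(attractorStates(attractors(aset)[[1]]), "1111")
  expect_equal(basinPercentage(attractors(aset)[[1]]), 100)
})
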