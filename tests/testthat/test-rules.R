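# Rule grammar, evaluation and one-step update semantics.

cdNodes <- c("Activator", "DegProtein", "DegRNA", "DNA", "miRNA", "mRNA",
             "Protein")

test_that("parser honors precedence, parentheses and the &! idiom", {
  e <- parseRule("(mRNA & Activator) | Protein", cdNodes)
  expect_equal(e$kind, "or")
  expect_equal(e$left$kind, "and")
  expect_equal(e$left$left$name, "mRNA")
  expect_equal(e$left$right$name, "Activator")
  expect_equal(e$right$name, "Protein")

  # `&!` is AND followed by prefix NOT, whatever the spacing
  for (txt in c("DNA &! Protein", "DNA&!Protein", "DNA & !Protein")) {
    e <- parseRule(txt, cdNodes)
    expect_equal(e$kind, "and")
    expect_equal(e$left$name, "DNA")
    expect_equal(e$right$kind, "not")
    expect_equal(e$right$child$name, "Protein")
  }

  # NOT > AND > OR
  e <- parseRule("A | B & C", c("A", "B", "C"))
  expect_equal(e$kind, "or")
  expect_equal(e$left$name, "A")
  expect_equal(e$right$kind, "and")

  e <- parseRule("(DNA & Protein | mRNA) &! DegRNA", cdNodes)
  expect_equal(e$kind, "and")
  expect_equal(e$left$kind, "or")
  expect_equal(e$left$left$kind, "and")
  expect_equal(e$left$right$name, "mRNA")
  expect_equal(e$right$kind, "not")
  expect_equal(e$right$child$name, "DegRNA")
})

test_that("parser rejects undeclared nodes and malformed syntax", {
  expect_error(parseRule("DNA & Rna", cdNodes), "undeclared node 'Rna'")
  expect_error(parseRule("DNA &", cdNodes), "position")
  expect_error(parseRule("(DNA | mRNA", cdNodes), "position")
  expect_error(parseRule("DNA mRNA", cdNodes), "trailing")
  expect_error(parseRule("DNA + mRNA", cdNodes), "illegal character")
})

test_that("serialize/parse round trip is structurally exact for all catalog rules", {
  for (id in cdModelIds()) {
    net <- cdModel(id)
    for (nd in networkNodes(net)) {
      for (f in nodeFunctions(net, nd)) {
        txt <- ruleToString(f$expr)
        expect_identical(unclass(parseRule(txt, networkNodes(net))),
                         unclass(f$expr),
                         info = sprintf("%s / %s / %s", id, nd, txt))
      }
    }
  }
})

test_that("rule evaluation follows standard Boolean semantics", {
  nodes65 <- c("Activator", "DNA", "mRNA", "Protein")
  e <- parseRule("(mRNA & Activator) | Protein", nodes65)
  expect_equal(evaluateRule(e, "1110", nodes65), 1L)
  expect_equal(evaluateRule(e, "1100", nodes65), 0L)
  expect_equal(evaluateRule(parseRule("!DNA", nodes65), "1010", nodes65), 1L)
  expect_equal(evaluateRule(parseRule("DNA", nodes65), "0100", nodes65), 1L)
  expect_equal(evaluateRule(e, c(Activator = 1, DNA = 1, mRNA = 1, Protein = 0)),
               1L)
})

test_that("state string/integer encodings round-trip, first node most significant", {
  expect_equal(stateFromString("1001000"), 72L)
  expect_equal(stateToString(72L, 7), "1001000")
  for (s in c(0L, 1L, 5L, 72L, 127L)) {
    expect_equal(stateFromString(stateToString(s, 7)), s)
  }
  strs <- vapply(0:15, stateToString, character(1), n = 4)
  expect_equal(stateFromString(strs), 0:15)
  expect_error(stateFromString("10a1"), "malformed")
})

test_that("synchronous trajectories of the 1965 models match the known paths", {
  v1 <- cdModel("CD1965-V1")
  expect_equal(synchronousStep(v1, "1110"), "1101")
  expect_equal(synchronousStep(v1, "1101"), "1111")
  expect_equal(synchronousStep(v1, "1111"), "1111")

  v2 <- cdModel("CD1965-V2")
  expect_equal(synchronousStep(v2, "1100"), "1110")
  expect_equal(synchronousStep(v2, "1110"), "1111")
  expect_equal(synchronousStep(v2, "1111"), "1101")
  expect_equal(synchronousStep(v2, "1101"), "1101")

  # no rule has a constant-true term, so the all-OFF state is fixed everywhere
  for (id in setdiff(cdModelIds(), "CD-PBN")) {
    net <- cdModel(id)
    zero <- strrep("0", numNodes(net))
    expect_equal(synchronousStep(net, zero), zero, info = id)
  }
})

test_that("asynchronous successors: one per node, fixed points self-map", {
  v1 <- cdModel("CD-V1")
  atFix <- asynchronousSuccessors(v1, "1001000")
  expect_equal(nrow(atFix), 7L)
  expect_true(all(atFix$state == "1001000"))
  expect_false(any(atFix$changed))

  v2 <- cdModel("CD-V2")
  succ <- asynchronousSuccessors(v2, "1001010")
  expect_equal(succ$state[succ$node == "miRNA"], "1001110")
})

test_that("synchronous step agrees with assembled single-node updates", {
  for (net in randomNetworkPool(12)) {
    n <- numNodes(net)
    for (s in c(0L, 2L^n - 1L, 7L %% 2L^n, 13L %% 2L^n)) {
      sync <- synchronousStep(net, s)
      succ <- asynchronousSuccessors(net, s)
      bits <- vapply(seq_len(n), function(i) {
        bitwAnd(succ$state[i] %/% 2L^(n - i), 1L)  # bit i of node-i update
      }, integer(1))
      expect_equal(sum(bits * 2L^((n - 1L):0L)), sync,
                   info = networkName(net))
    }
  }
})

test_that("update operations demand deterministic networks", {
  pbn <- cdModel("CD-PBN")
  expect_false(isDeterministic(pbn))
  expect_error(synchronousStep(pbn, 0L), "deterministic")
  expect_error(asynchronousSuccessors(pbn, 0L), "deterministic")
  expect_error(transitionTable(pbn), "deterministic")
})
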