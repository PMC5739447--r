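# The model catalog: construction, provenance and self-consistency.

test_that("catalog lists eleven models and rejects unknown ids", {
  ids <- cdModelIds()
  expect_length(ids, 11L)
  expect_error(cdModel("CD-V9"), "valid ids")
  expect_error(cdModelDescription("nope"), "unknown model id")
  expect_match(cdModelDescription("CD-V4"), "silencing")
})

test_that("1965 models have the documented 4-node structure", {
  v1 <- cdModel("CD1965-V1")
  expect_equal(networkNodes(v1), c("Activator", "DNA", "mRNA", "Protein"))
  expect_equal(ruleToString(nodeFunctions(v1, "mRNA")[[1]]$expr),
               "DNA & Protein")
  # serializer emits the minimal-parenthesis form
  expect_equal(ruleToString(nodeFunctions(v1, "Protein")[[1]]$expr),
               "mRNA & Activator | Protein")
  v2 <- cdModel("CD1965-V2")
  expect_equal(ruleToString(nodeFunctions(v2, "mRNA")[[1]]$expr),
               "DNA & !Protein")
})

test_that("present-day models have the documented 7-node structure", {
  v1 <- cdModel("CD-V1")
  expect_equal(networkNodes(v1),
               c("Activator", "DegProtein", "DegRNA", "DNA", "miRNA", "mRNA",
                 "Protein"))
  expect_equal(ruleToString(nodeFunctions(v1, "DegRNA")[[1]]$expr),
               "miRNA & Protein & !DegProtein")
  for (id in paste0("CD-V", 1:8)) {
    expect_true(validObject(cdModel(id)), info = id)
    expect_true(isDeterministic(cdModel(id)), info = id)
  }
})

test_that("PBN mixture carries the catalog probabilities", {
  pbn <- cdModel("CD-PBN")
  probsOf <- function(nd) vapply(nodeFunctions(pbn, nd), `[[`, numeric(1), "prob")
  expect_equal(probsOf("DNA"), c(0.1, 0.9))
  expect_equal(probsOf("miRNA"), c(0.8, 0.2))
  expect_equal(probsOf("mRNA"), c(0.8, 0.2))
  for (nd in c("Activator", "DegProtein", "DegRNA", "Protein")) {
    expect_equal(probsOf(nd), 1)
  }
  expect_equal(ruleToString(nodeFunctions(pbn, "DNA")[[1]]$expr),
               "miRNA & Protein | DNA")
  expect_equal(ruleToString(nodeFunctions(pbn, "DNA")[[2]]$expr),
               "!miRNA & Protein | DNA")
})

test_that("three-switch construction reproduces the catalog versions", {
  expect_identical(transitionTable(buildCDModel(FALSE, FALSE, FALSE)),
                   transitionTable(cdModel("CD-V1")))
  expect_identical(transitionTable(buildCDModel(TRUE, TRUE, TRUE)),
                   transitionTable(cdModel("CD-V8")))
  tables <- lapply(paste0("CD-V", 1:8),
                   function(id) transitionTable(cdModel(id)))
  for (i in 1:7) {
    for (j in (i + 1):8) {
      expect_false(identical(tables[[i]], tables[[j]]),
                   info = sprintf("V%d vs V%d", i, j))
    }
  }
})

test_that("CD-V2 closes its synchronous 4-cycle exactly as documented", {
  v2 <- cdModel("CD-V2")
  s <- "1001000"
  path <- character(0)
  for (k in 1:4) {
    path <- c(path, s)
    s <- synchronousStep(v2, s)
  }
  expect_equal(path, c("1001000", "1001010", "1001111", "1111101"))
  expect_equal(s, "1001000")
})
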