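# SBML-qual (Level 3 qualitative models) import/export for
# deterministic Boolean networks. Rules are encoded as MathML function
# terms over equality tests "node == 1"; PBNs have no qual encoding and
# round-trip through the BoolNet text dialect instead.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.QUAL_NS <- "http://www.sbml.org/sbml/level3/version1/qual/version1"
.MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

#' Write a deterministic Boolean network as SBML-qual
#'
#' @param net A deterministic [BooleanNetwork-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".sbml")
#' writeSBMLQual(cdModel("CD1965-V1"), f)
#' networkNodes(readSBMLQual(f))
#' @export
writeSBMLQual <- function(net, path) {
  .requireDeterministic(net)
  doc <- xml2::xml_new_root("sbml",
    xmlns = .SBML_NS, "xmlns:qual" = .QUAL_NS,
    level = "3", version = "1", "qual:required" = "true")
  model <- xml2::xml_add_child(doc, "model", id = .sbmlId(net@name))
  species <- xml2::xml_add_child(model, "qual:listOfQualitativeSpecies")
  for (nd in net@nodes) {
    xml2::xml_add_child(species, "qual:qualitativeSpecies",
      "qual:id" = nd, "qual:constant" = "false", "qual:maxLevel" = "1")
  }
  transitions <- xml2::xml_add_child(model, "qual:listOfTransitions")
  for (nd in net@nodes) {
    tr <- xml2::xml_add_child(transitions, "qual:transition",
                              "qual:id" = paste0("tr_", nd))
    inputs <- xml2::xml_add_child(tr, "qual:listOfInputs")
    for (inp in ruleInputs(net@functions[[nd]][[1L]]$expr)) {
      xml2::xml_add_child(inputs, "qual:input",
        "qual:qualitativeSpecies" = inp, "qual:transitionEffect" = "none")
    }
    outputs <- xml2::xml_add_child(tr, "qual:listOfOutputs")
    xml2::xml_add_child(outputs, "qual:output",
      "qual:qualitativeSpecies" = nd,
      "qual:transitionEffect" = "assignmentLevel")
    terms <- xml2::xml_add_child(tr, "qual:listOfFunctionTerms")
    xml2::xml_add_child(terms, "qual:defaultTerm", "qual:resultLevel" = "0")
    ft <- xml2::xml_add_child(terms, "qual:functionTerm",
                              "qual:resultLevel" = "1")
    math <- xml2::xml_add_child(ft, "math", xmlns = .MATHML_NS)
    .exprToMathML(math, net@functions[[nd]][[1L]]$expr)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.sbmlId <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

.exprToMathML <- function(parent, expr) {
  switch(expr$kind,
    atom = {
      apply <- xml2::xml_add_child(parent, "apply")
      xml2::xml_add_child(apply, "eq")
      xml2::xml_add_child(apply, "ci", expr$name)
      xml2::xml_add_child(apply, "cn", "1", type = "integer")
    },
    not = {
      apply <- xml2::xml_add_child(parent, "apply")
      xml2::xml_add_child(apply, "not")
      .exprToMathML(apply, expr$child)
    },
    {
      apply <- xml2::xml_add_child(parent, "apply")
      xml2::xml_add_child(apply, expr$kind)  # "and" / "or"
      .exprToMathML(apply, expr$left)
      .exprToMathML(apply, expr$right)
    }
  )
}

#' Read an SBML-qual Boolean model
#'
#' Supports the subset written by [writeSBMLQual()]: binary qualitative
#' species with one transition per species whose level-1 function term
#' is MathML over `and`/`or`/`not` and `eq(species, 0/1)` leaves.
#'
#' @param path SBML file path.
#' @param name Model label (defaults to the SBML model id).
#' @return A deterministic [BooleanNetwork-class].
#' @export
readSBMLQual <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  doc <- xml2::read_xml(path)
  ns <- c(sbml = .SBML_NS, qual = .QUAL_NS, m = .MATHML_NS)
  speciesNodes <- xml2::xml_find_all(doc, ".//qual:qualitativeSpecies", ns)
  nodes <- xml2::xml_attr(speciesNodes, "id", ns)
  if (all(is.na(nodes))) {
    nodes <- vapply(speciesNodes, function(s) {
      a <- xml2::xml_attrs(s)
      a[[grep("(^|:)id$", names(a))[1L]]]
    }, character(1))
  }
  if (!length(nodes)) {
    stop(sprintf("%s: no qualitative species found", path), call. = FALSE)
  }
  rules <- vector("list", length(nodes))
  names(rules) <- nodes
  for (tr in xml2::xml_find_all(doc, ".//qual:transition", ns)) {
    outAttr <- xml2::xml_attrs(
      xml2::xml_find_first(tr, ".//qual:output", ns))
    target <- outAttr[[grep("qualitativeSpecies$", names(outAttr))[1L]]]
    math <- xml2::xml_find_first(
      tr, ".//qual:functionTerm/m:math/*", ns)
    if (inherits(math, "xml_missing")) {
      stop(sprintf("%s: transition for '%s' has no function term math",
                   path, target), call. = FALSE)
    }
    rules[[target]] <- structure(.mathMLToExpr(math, nodes, path),
                                 class = "RuleExpression")
  }
  missing <- nodes[vapply(rules, is.null, logical(1))]
  # species without a transition hold their value (self-rule)
  for (nd in missing) {
    rules[[nd]] <- parseRule(nd, nodes)
  }
  modelId <- xml2::xml_attr(xml2::xml_find_first(doc, ".//sbml:model", ns), "id")
  if (is.na(modelId)) modelId <- basename(path)
  booleanNetwork(name %||% modelId, nodes,
                 lapply(rules, function(e) list(list(rule = e, prob = 1))))
}

.mathMLToExpr <- function(node, nodes, path) {
  nm <- xml2::xml_name(node)
  if (nm != "apply") {
    stop(sprintf("%s: unsupported MathML node <%s>", path, nm), call. = FALSE)
  }
  children <- xml2::xml_children(node)
  op <- xml2::xml_name(children[[1L]])
  args <- children[-1L]
  fold <- function(kind, exprs) {
    Reduce(function(l, r) list(kind = kind, left = l, right = r), exprs)
  }
  switch(op,
    eq = {
      ci <- trimws(xml2::xml_text(args[[1L]]))
      level <- trimws(xml2::xml_text(args[[2L]]))
      if (!ci %in% nodes) {
        stop(sprintf("%s: eq references unknown species '%s'", path, ci),
             call. = FALSE)
      }
      atom <- list(kind = "atom", name = ci)
      if (level == "1") atom else list(kind = "not", child = atom)
    },
    not = list(kind = "not",
               child = .mathMLToExpr(args[[1L]], nodes, path)),
    and = fold("and", lapply(args, .mathMLToExpr, nodes = nodes, path = path)),
    or = fold("or", lapply(args, .mathMLToExpr, nodes = nodes, path = path)),
    stop(sprintf("%s: unsupported MathML operator <%s>", path, op),
         call. = FALSE)
  )
}
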