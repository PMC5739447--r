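# BoolNet-dialect plain-text model files.
#
# Format: a "targets, factors" header (optionally
# "targets, factors, probabilities"), then one "node, rule" line per
# function. Probabilistic nodes repeat the node name with a trailing
# probability column. '#' starts a comment.

#' Read a Boolean network from a BoolNet-style text file
#'
#' @param path File path.
#' @param name Model label (defaults to the file name).
#' @return A validated [BooleanNetwork-class]; PBN probability columns
#'   are honored.
#' @examples
#' f <- tempfile(fileext = ".bn")
#' writeBoolNet(cdModel("CD-V1"), f)
#' net <- readBoolNet(f)
#' @export
readBoolNet <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop(sprintf("%s: empty model file", path), call. = FALSE)
  header <- tolower(gsub("\\s", "", lines[keep[1L]]))
  if (!startsWith(header, "targets,factors")) {
    stop(sprintf("%s:%d: expected 'targets, factors' header, got '%s'",
                 path, keep[1L], trimws(lines[keep[1L]])), call. = FALSE)
  }
  entries <- list()
  for (ln in keep[-1L]) {
    parts <- trimws(strsplit(lines[ln], ",")[[1L]])
    if (length(parts) < 2L || length(parts) > 3L || !nzchar(parts[1L]) ||
        !nzchar(parts[2L])) {
      stop(sprintf("%s:%d: malformed rule line '%s'", path, ln,
                   trimws(lines[ln])), call. = FALSE)
    }
    prob <- if (length(parts) == 3L) suppressWarnings(as.numeric(parts[3L])) else 1
    if (is.na(prob)) {
      stop(sprintf("%s:%d: malformed probability '%s'", path, ln, parts[3L]),
           call. = FALSE)
    }
    entries[[length(entries) + 1L]] <-
      list(node = parts[1L], rule = parts[2L], prob = prob, line = ln)
  }
  nodes <- unique(vapply(entries, `[[`, character(1), "node"))
  rules <- lapply(nodes, function(nd) {
    fns <- Filter(function(e) e$node == nd, entries)
    lapply(fns, function(e) list(rule = e$rule, prob = e$prob))
  })
  names(rules) <- nodes
  net <- tryCatch(
    booleanNetwork(name %||% basename(path), nodes, rules),
    error = function(e) {
      stop(sprintf("%s: %s", path, conditionMessage(e)), call. = FALSE)
    })
  net
}

#' Write a Boolean network as a BoolNet-style text file
#'
#' @param net A [BooleanNetwork-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBoolNet <- function(net, path) {
  pbn <- !isDeterministic(net)
  lines <- if (pbn) "targets, factors, probabilities" else "targets, factors"
  for (nd in net@nodes) {
    for (f in net@functions[[nd]]) {
      lines <- c(lines, if (pbn) {
        sprintf("%s, %s, %g", nd, ruleToString(f$expr), f$prob)
      } else {
        sprintf("%s, %s", nd, ruleToString(f$expr))
      })
    }
  }
  writeLines(lines, path)
  invisible(path)
}
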