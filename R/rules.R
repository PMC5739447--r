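#' Parse a Boolean rule expression
#'
#' Parses rule text in the `&` (AND), `|` (OR), `!` (NOT) grammar used
#' throughout the model catalog into an abstract syntax tree. Operator
#' precedence is NOT > AND > OR with left associativity; parentheses
#' override. `!` is a prefix operator and binds regardless of adjacent
#' spacing, so `DNA &! Protein` reads as `DNA & (!Protein)`.
#'
#' @param text Rule string, e.g. `"(mRNA & Activator) | Protein"`.
#' @param nodes Character vector of declared node names. Identifiers in
#'   `text` are resolved case-sensitively against this set.
#' @return A `RuleExpression`: a nested list with a `kind` field in
#'   `atom`, `not`, `and`, `or`; `atom` carries `name`, `not` carries
#'   `child`, `and`/`or` carry `left` and `right`.
#' @examples
#' e <- parseRule("A | B & C", c("A", "B", "C"))
#' e$kind  # "or": AND binds tighter than OR
#' ruleToString(e)
#' @seealso [ruleToString()], [evaluateRule()]
#' @export
parseRule <- function(text, nodes) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  toks <- .tokenizeRule(text)
  pos <- 1L
  peek <- function() if (pos <= nrow(toks)) toks$type[pos] else "<end>"
  take <- function() {
    t <- toks[pos, ]
    pos <<- pos + 1L
    t
  }
  fail <- function(msg, at = if (pos <= nrow(toks)) toks$pos[pos] else nchar(text) + 1L) {
    stop(sprintf("parse error in rule '%s' at position %d: %s", text, at, msg),
         call. = FALSE)
  }
  pExpr <- function() {
    left <- pTerm()
    while (peek() == "|") {
      take()
      left <- list(kind = "or", left = left, right = pTerm())
    }
    left
  }
  pTerm <- function() {
    left <- pFactor()
    while (peek() == "&") {
      take()
      left <- list(kind = "and", left = left, right = pFactor())
    }
    left
  }
  pFactor <- function() {
    switch(peek(),
      "!" = {
        take()
        list(kind = "not", child = pFactor())
      },
      "(" = {
        take()
        e <- pExpr()
        if (peek() != ")") fail("expected ')'")
        take()
        e
      },
      ident = {
        t <- take()
        if (!(t$value %in% nodes)) {
          stop(sprintf("undeclared node '%s' in rule '%s' (declared: %s)",
                       t$value, text, paste(nodes, collapse = ", ")),
               call. = FALSE)
        }
        list(kind = "atom", name = t$value)
      },
      fail(sprintf("unexpected '%s'", peek()))
    )
  }
  expr <- pExpr()
  if (pos <= nrow(toks)) fail(sprintf("trailing input '%s'", toks$value[pos]))
  structure(expr, class = "RuleExpression")
}

.tokenizeRule <- function(text) {
  types <- character()
  values <- character()
  poss <- integer()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
      next
    }
    if (ch %in% c("&", "|", "!", "(", ")")) {
      types <- c(types, ch)
      values <- c(values, ch)
      poss <- c(poss, i)
      i <- i + 1L
    } else if (grepl("^[A-Za-z_]$", ch)) {
      j <- i + 1L
      while (j <= n && grepl("^[A-Za-z0-9_.]$", substr(text, j, j))) j <- j + 1L
      types <- c(types, "ident")
      values <- c(values, substr(text, i, j - 1L))
      poss <- c(poss, i)
      i <- j
    } else {
      stop(sprintf("parse error in rule '%s' at position %d: illegal character '%s'",
                   text, i, ch), call. = FALSE)
    }
  }
  data.frame(type = types, value = values, pos = poss, stringsAsFactors = FALSE)
}

#' Serialize a rule expression back to text
#'
#' Produces rule text that reparses to a structurally identical tree.
#' Parentheses are inserted only where precedence requires them.
#'
#' @param expr A `RuleExpression` from [parseRule()].
#' @return A single rule string.
#' @export
ruleToString <- function(expr) {
  prec <- function(e) switch(e$kind, or = 1L, and = 2L, not = 3L, atom = 4L)
  render <- function(e, parentPrec) {
    s <- switch(e$kind,
      atom = e$name,
      not = paste0("!", render(e$child, 3L)),
      and = paste(render(e$left, 2L), "&", render(e$right, 3L)),
      or = paste(render(e$left, 1L), "|", render(e$right, 2L))
    )
    if (prec(e) < parentPrec) paste0("(", s, ")") else s
  }
  render(unclass(expr), 0L)
}

#' @export
print.RuleExpression <- function(x, ...) {
  cat("<rule> ", ruleToString(x), "\n", sep = "")
  invisible(x)
}

#' Node names referenced by a rule expression
#'
#' @param expr A `RuleExpression`.
#' @return Character vector of distinct atom names, in first-use order.
#' @export
ruleInputs <- function(expr) {
  out <- character()
  walk <- function(e) {
    switch(e$kind,
      atom = out <<- union(out, e$name),
      not = walk(e$child),
      {
        walk(e$left)
        walk(e$right)
      }
    )
  }
  walk(expr)
  out
}

#' Evaluate a rule expression on a network state
#'
#' @param expr A `RuleExpression`.
#' @param state Named logical/0-1 vector, or an unnamed bit vector in
#'   `nodes` order, or a state string such as `"1001000"` (then `nodes`
#'   is required).
#' @param nodes Node order used to decode unnamed/string states.
#' @return A single bit, 0 or 1.
#' @examples
#' nodes <- c("Activator", "DNA", "mRNA", "Protein")
#' e <- parseRule("(mRNA & Activator) | Protein", nodes)
#' evaluateRule(e, "1110", nodes)
#' @export
evaluateRule <- function(expr, state, nodes = NULL) {
  bits <- .decodeBits(state, nodes)
  ev <- function(e) {
    switch(e$kind,
      atom = {
        v <- bits[[e$name]]
        if (is.null(v) || is.na(v)) {
          stop(sprintf("state does not define node '%s'", e$name), call. = FALSE)
        }
        v
      },
      not = !ev(e$child),
      and = ev(e$left) && ev(e$right),
      or = ev(e$left) || ev(e$right)
    )
  }
  as.integer(ev(expr))
}

# named logical list from the accepted state encodings
.decodeBits <- function(state, nodes) {
  if (is.character(state) && length(state) == 1L) {
    if (is.null(nodes)) stop("'nodes' is required to decode a state string", call. = FALSE)
    bits <- as.integer(strsplit(state, "")[[1]])
    if (length(bits) != length(nodes) || anyNA(bits) || any(!bits %in% 0:1)) {
      stop(sprintf("malformed state string '%s' for %d nodes", state, length(nodes)),
           call. = FALSE)
    }
    return(as.list(setNames(bits == 1L, nodes)))
  }
  v <- as.integer(state)
  if (!is.null(names(state))) {
    return(as.list(setNames(v == 1L, names(state))))
  }
  if (is.null(nodes)) stop("'nodes' is required for an unnamed bit vector", call. = FALSE)
  stopifnot(length(v) == length(nodes))
  as.list(setNames(v == 1L, nodes))
}

# vectorized evaluation of expr over all 2^n states (internal fast path);
# state integers 0..2^n-1, first node = most significant bit
.evalAllStates <- function(expr, nodes) {
  n <- length(nodes)
  states <- 0:(2L^n - 1L)
  ev <- function(e) {
    switch(e$kind,
      atom = {
        i <- match(e$name, nodes)
        bitwAnd(states %/% 2L^(n - i), 1L) == 1L
      },
      not = !ev(e$child),
      and = ev(e$left) & ev(e$right),
      or = ev(e$left) | ev(e$right)
    )
  }
  ev(expr)
}
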