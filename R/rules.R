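#' Rule bases of propositional specification rules
#'
#' A rule base is an ordered list of implications `Ri: antecedent ->
#' consequent` over pathway atoms, with a recorded atom universe.
#'
#' @param rules list of rules, each `list(id, lhs, rhs)` with formula
#'   `lhs`/`rhs` (see [f_atom()]).
#' @return an object of class `rule_base`.
#' @export
rule_base <- function(rules = list()) {
  ids <- vapply(rules, function(r) r$id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate rule id(s): ", paste(unique(ids[duplicated(ids)]),
                                         collapse = ", "))
  }
  atoms <- sort(unique(unlist(lapply(rules, function(r) {
    c(formula_atoms(r$lhs), formula_atoms(r$rhs))
  }))))
  structure(list(rules = rules, atoms = atoms %||% character(0)),
            class = "rule_base")
}

#' @export
print.rule_base <- function(x, ...) {
  cat("rule_base:", length(x$rules), "rules over", length(x$atoms), "atoms\n")
  for (r in x$rules) cat(" ", format_rule(r), "\n")
  invisible(x)
}

#' @export
length.rule_base <- function(x) length(x$rules)

#' Format one rule in the DSL syntax
#' @param r a rule (`list(id, lhs, rhs)`).
#' @return a single string `"Ri: LHS -> RHS"`.
#' @export
format_rule <- function(r) {
  paste0(r$id, ": ", format_formula(r$lhs), " -> ", format_formula(r$rhs))
}

#' Write a rule base in the rule DSL
#' @param rules a [rule_base()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "rule_base"))
  writeLines(vapply(rules$rules, format_rule, ""), path, useBytes = FALSE)
  invisible(path)
}

# ---- DSL parser -----------------------------------------------------------

# one rule per line: `Ri: EXPR -> EXPR`; operators & | ! ( ), standard
# precedence ! > & > |; `#` starts a comment; the unicode operators
# `∧ ∨ ¬ →` are aliases of `& | ! ->`.

tokenize_rule_line <- function(line, line_no) {
  ascii <- line
  for (sub in list(c("∧", " & "), c("∨", " | "),
                   c("¬", " ! "), c("→", " -> "))) {
    ascii <- gsub(sub[1L], sub[2L], ascii, fixed = TRUE)
  }
  perr <- function(col, msg) {
    stop(sprintf("rule syntax error at line %d: %s\n%s\n%s^",
                 line_no, msg, ascii, strrep(" ", col - 1L)), call. = FALSE)
  }
  m <- gregexpr("->|[&|!():]|[A-Za-z_][A-Za-z0-9_]*|[^\\s]", ascii,
                perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(list(tokens = character(0), cols = integer(0),
                                line = ascii, perr = perr))
  toks <- regmatches(ascii, gregexpr("->|[&|!():]|[A-Za-z_][A-Za-z0-9_]*|[^\\s]",
                                     ascii, perl = TRUE))[[1L]]
  cols <- as.integer(m)
  bad <- which(!grepl("^(->|[&|!():]|[A-Za-z_][A-Za-z0-9_]*)$", toks))
  if (length(bad)) perr(cols[bad[1L]], paste0("unexpected character '",
                                              toks[bad[1L]], "'"))
  list(tokens = toks, cols = cols, line = ascii, perr = perr)
}

parse_expr_tokens <- function(tk, from, to) {
  pos <- from
  perr <- tk$perr
  peek <- function() if (pos <= to) tk$tokens[pos] else NA_character_
  col_here <- function() {
    if (pos <= to) tk$cols[pos] else nchar(tk$line) + 1L
  }
  parse_or <- function() {
    f <- parse_and()
    while (!is.na(peek()) && peek() == "|") {
      pos <<- pos + 1L
      f <- f_or(list(f, parse_and()))
    }
    f
  }
  parse_and <- function() {
    f <- parse_unary()
    while (!is.na(peek()) && peek() == "&") {
      pos <<- pos + 1L
      f <- f_and(list(f, parse_unary()))
    }
    f
  }
  parse_unary <- function() {
    t <- peek()
    if (is.na(t)) perr(col_here(), "expected an expression")
    if (t == "!") { pos <<- pos + 1L; return(f_not(parse_unary())) }
    if (t == "(") {
      open_col <- col_here()
      pos <<- pos + 1L
      f <- parse_or()
      if (is.na(peek()) || peek() != ")") perr(open_col, "unclosed '('")
      pos <<- pos + 1L
      return(f)
    }
    if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", t)) {
      pos <<- pos + 1L
      return(f_atom(t))
    }
    perr(col_here(), paste0("unexpected '", t, "'"))
  }
  f <- parse_or()
  if (pos <= to) perr(col_here(), paste0("unexpected '", peek(), "'"))
  f
}

#' Parse a rule base from the rule DSL
#'
#' @param text a character vector of DSL lines, a single string with
#'   newlines, or (with `file = TRUE`) a file path.
#' @param file treat `text` as a path.
#' @return a [rule_base()].
#' @examples
#' parse_rules("R1: MP_SMB & MP_CTM -> MP_TRXN")
#' @export
parse_rules <- function(text, file = FALSE) {
  lines <- if (file) readLines(text, encoding = "UTF-8", warn = FALSE)
           else unlist(strsplit(text, "\n", fixed = TRUE))
  if (is.null(lines)) lines <- character(0)
  rules <- list()
  for (i in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(raw))) next
    tk <- tokenize_rule_line(raw, i)
    n <- length(tk$tokens)
    if (n < 2L || !grepl("^[A-Za-z_][A-Za-z0-9_]*$", tk$tokens[1L]) ||
        tk$tokens[2L] != ":") {
      tk$perr(tk$cols[1L] %||% 1L, "rule must start with 'Ri:'")
    }
    if (n < 3L) tk$perr(tk$cols[n], "missing '->'")
    depth <- 0L; arrow <- NA_integer_
    for (j in 3:n) {
      t <- tk$tokens[j]
      if (t == "(") depth <- depth + 1L
      else if (t == ")") depth <- depth - 1L
      else if (t == "->" && depth == 0L) {
        if (!is.na(arrow)) tk$perr(tk$cols[j], "more than one top-level '->'")
        arrow <- j
      }
    }
    if (is.na(arrow)) tk$perr(tk$cols[n], "missing '->'")
    if (arrow == 3L) tk$perr(tk$cols[arrow], "empty antecedent")
    if (arrow == n) tk$perr(tk$cols[arrow], "empty consequent")
    lhs <- parse_expr_tokens(tk, 3L, arrow - 1L)
    rhs <- parse_expr_tokens(tk, arrow + 1L, n)
    rules[[length(rules) + 1L]] <- list(id = tk$tokens[1L], lhs = lhs,
                                        rhs = rhs)
  }
  rule_base(rules)
}

#' Derive specification rules from an MPIN
#'
#' Converts each hierarchy arrow of the network into a propositional rule.
#' Under the default `"generalize"` policy an arrow from general pathway y
#' to specific pathway x emits `x -> y` (a deficiency in the specific
#' pathway implies one in its more general relative, since their shared
#' molecule belongs to both); `"specialize"` emits `y -> x`;
#' `"conjunctive"` adds, for every pathway x with incoming arrows from
#' y1..yk, the rule `(y1 & ... & yk) -> x`. Undirected edges emit no rule.
#' Rule ids are `R1`, `R2`, ... in the (deterministic) edge order of the
#' MPIN.
#'
#' @param mpin an `mpin`.
#' @param policy `"generalize"`, `"specialize"` or `"conjunctive"`.
#' @return a [rule_base()].
#' @export
rules_from_mpin <- function(mpin,
                            policy = c("generalize", "specialize",
                                       "conjunctive")) {
  policy <- match.arg(policy)
  arrows <- mpin_arrows(mpin)
  rules <- list()
  add <- function(lhs, rhs) {
    rules[[length(rules) + 1L]] <<-
      list(id = paste0("R", length(rules) + 1L), lhs = lhs, rhs = rhs)
  }
  if (policy == "specialize") {
    for (i in seq_len(nrow(arrows))) {
      add(f_atom(arrows$general[i]), f_atom(arrows$specific[i]))
    }
  } else {
    for (i in seq_len(nrow(arrows))) {
      add(f_atom(arrows$specific[i]), f_atom(arrows$general[i]))
    }
    if (policy == "conjunctive") {
      for (x in unique(arrows$specific)) {
        gen <- sort(unique(arrows$general[arrows$specific == x]))
        add(f_and(lapply(gen, f_atom)), f_atom(x))
      }
    }
  }
  rule_base(rules)
}
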