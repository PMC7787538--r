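#' @name logic-inference
#' @title Forward chaining over specification rules
#'
#' @description
#' Given a rule base and the set of pathways detected in an individual (the
#' given premises), the engine derives every pathway atom classically
#' entailed by rules plus premises. Entailment is decided by clause-level
#' resolution saturation with implicit factoring and forward subsumption,
#' which derives every prime implicate of the base — in particular the unit
#' clause of each entailed atom, or the empty clause when the base is
#' contradictory. Saturation proceeds breadth-first over rule applications,
#' and the restricted clause space over the finite atom universe guarantees
#' termination. A replayable proof trace is attached: definite chains are
#' presented with the named natural-deduction rules (modus ponens,
#' conjunction, simplification, addition), everything else with resolution
#' steps whose supports are earlier steps.
NULL

# ---- resolution core ------------------------------------------------------

# clauses: list of list(pos, neg, key, parents = c(i, j) | NULL, origin)
resolution_saturate <- function(init) {
  clauses <- list()
  keys <- character(0)
  add <- function(cl, parents, origin) {
    if (clause_tautology(cl)) return(NA_integer_)
    key <- clause_key(cl)
    if (key %in% keys) return(NA_integer_)
    for (ex in clauses) {
      if (clause_subsumes(ex, cl)) return(NA_integer_)
    }
    clauses[[length(clauses) + 1L]] <<- list(
      pos = cl$pos, neg = cl$neg, key = key, parents = parents,
      origin = origin)
    keys <<- c(keys, key)
    length(clauses)
  }
  new_idx <- integer(0)
  for (c0 in init) {
    i <- add(mk_clause(c0$pos, c0$neg), NULL, c0$origin)
    if (!is.na(i)) new_idx <- c(new_idx, i)
  }
  empty_at <- NA_integer_
  has_empty <- function() {
    any(vapply(clauses, function(cl) {
      !length(cl$pos) && !length(cl$neg)
    }, TRUE))
  }
  while (length(new_idx) && is.na(empty_at)) {
    produced <- integer(0)
    n_before <- length(clauses)
    for (i in new_idx) {
      ci <- clauses[[i]]
      for (j in seq_len(n_before)) {
        if (j == i) next
        cj <- clauses[[j]]
        for (a in intersect(ci$pos, cj$neg)) {
          r <- mk_clause(c(setdiff(ci$pos, a), cj$pos),
                         c(ci$neg, setdiff(cj$neg, a)))
          k <- add(r, c(i, j), NULL)
          if (!is.na(k)) {
            produced <- c(produced, k)
            if (!length(r$pos) && !length(r$neg)) empty_at <- k
          }
        }
        for (a in intersect(ci$neg, cj$pos)) {
          r <- mk_clause(c(ci$pos, setdiff(cj$pos, a)),
                         c(setdiff(ci$neg, a), cj$neg))
          k <- add(r, c(j, i), NULL)
          if (!is.na(k)) {
            produced <- c(produced, k)
            if (!length(r$pos) && !length(r$neg)) empty_at <- k
          }
        }
        if (!is.na(empty_at)) break
      }
      if (!is.na(empty_at)) break
    }
    new_idx <- produced
  }
  list(clauses = clauses, empty_at = empty_at)
}

# ---- forward chaining -----------------------------------------------------

#' Infer undetected pathways from detected ones
#'
#' @param rules a [rule_base()].
#' @param detected character vector of detected pathway atoms (the given
#'   premises). Atoms absent from the rule base are auto-added to the atom
#'   universe and carried through (logged).
#' @return an object of class `inference_result`: list with `detected`,
#'   `inferred` (entailed atoms not among the detected), `combined`
#'   (their union), `inconsistent` flag and `trace` (see
#'   [explain()]/[verify_trace()]). A contradictory rule base entails every
#'   atom; the result is then flagged and a warning raised.
#' @examples
#' rb <- parse_rules("R1: MP_A -> MP_B\nR2: MP_B -> MP_C")
#' forward_chain(rb, "MP_A")$inferred
#' @export
forward_chain <- function(rules, detected) {
  stopifnot(inherits(rules, "rule_base"))
  detected <- unique(as.character(detected))
  extra <- setdiff(detected, rules$atoms)
  if (length(extra) && length(rules$rules)) {
    sddp_log("info", "detected atom(s) not in the rule base, carried through: ",
             paste(extra, collapse = ", "))
  }
  atoms <- sort(union(rules$atoms, detected))
  init <- list()
  for (a in detected) {
    init[[length(init) + 1L]] <-
      list(pos = a, neg = character(0), origin = paste0("premise:", a))
  }
  for (r in rules$rules) {
    for (cl in to_cnf(f_imp(r$lhs, r$rhs))) {
      init[[length(init) + 1L]] <-
        list(pos = cl$pos, neg = cl$neg, origin = paste0("rule:", r$id))
    }
  }
  sat <- resolution_saturate(init)
  inconsistent <- !is.na(sat$empty_at)
  if (inconsistent) {
    warning("contradictory rule base: every atom is entailed")
    inferred <- setdiff(atoms, detected)
  } else {
    units <- vapply(sat$clauses, function(cl) {
      if (length(cl$pos) == 1L && !length(cl$neg)) cl$pos else NA_character_
    }, "")
    inferred <- sort(setdiff(units[!is.na(units)], detected))
  }
  trace <- build_trace(rules, detected, inferred, sat, inconsistent)
  structure(list(detected = sort(detected), inferred = inferred,
                 combined = sort(union(detected, inferred)),
                 inconsistent = inconsistent, trace = trace),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat("inference_result:", length(x$detected), "detected ->",
      length(x$inferred), "inferred",
      if (x$inconsistent) "(INCONSISTENT rule base)" else "", "\n")
  cat("  detected:", paste(x$detected, collapse = ", "), "\n")
  cat("  inferred:", paste(x$inferred, collapse = ", "), "\n")
  invisible(x)
}

# ---- trace construction ---------------------------------------------------

# A trace is a list of steps list(n, formula, justification, supports).
# Justifications: "premise", a rule id, or an inference-rule name among
# modus ponens / conjunction / simplification / addition / resolution.

new_trace <- function() {
  env <- new.env(parent = emptyenv())
  env$steps <- list()
  env$by_canon <- list() # canon(formula) -> step number
  env
}

trace_add <- function(tr, formula, justification, supports = integer(0),
                      memo = TRUE) {
  key <- canon_formula(formula)
  if (memo && !is.null(tr$by_canon[[key]])) return(tr$by_canon[[key]])
  n <- length(tr$steps) + 1L
  tr$steps[[n]] <- list(n = n, formula = formula,
                        justification = justification,
                        supports = as.integer(supports))
  if (memo) tr$by_canon[[key]] <- n
  n
}

build_trace <- function(rules, detected, inferred, sat, inconsistent) {
  tr <- new_trace()
  for (a in sort(detected)) trace_add(tr, f_atom(a), "premise")
  rule_step <- list()
  for (r in rules$rules) {
    rule_step[[r$id]] <- trace_add(tr, f_imp(r$lhs, r$rhs), r$id)
  }
  known <- new.env(parent = emptyenv()) # atom -> step
  for (a in detected) assign(a, tr$by_canon[[canon_formula(f_atom(a))]],
                             envir = known)
  known_atoms <- function() ls(known)

  # step deriving a positive formula from known atoms, or NA
  ensure <- function(f) {
    key <- canon_formula(f)
    if (!is.null(tr$by_canon[[key]])) return(tr$by_canon[[key]])
    switch(f$type,
      atom = get0(f$name, envir = known) %||% NA_integer_,
      and = {
        sup <- vapply(f$args, ensure, 0L)
        if (anyNA(sup)) NA_integer_
        else trace_add(tr, f, "conjunction", sup)
      },
      or = {
        for (arg in f$args) {
          s <- ensure(arg)
          if (!is.na(s)) return(trace_add(tr, f, "addition", s))
        }
        NA_integer_
      },
      NA_integer_)
  }
  assert_atoms <- function(f, step) {
    if (f$type == "atom") {
      if (is.null(get0(f$name, envir = known))) {
        assign(f$name, step, envir = known)
        return(TRUE)
      }
      return(FALSE)
    }
    if (f$type == "and") {
      got <- FALSE
      for (arg in f$args) {
        if (arg$type %in% c("atom", "and")) {
          s <- trace_add(tr, arg, "simplification", step)
          if (assert_atoms(arg, s)) got <- TRUE
        }
      }
      return(got)
    }
    FALSE
  }
  # breadth-first definite-chain pass
  repeat {
    progress <- FALSE
    for (r in rules$rules) {
      if (!formula_positive(r$lhs) || r$rhs$type %in% c("or", "not", "imp")) next
      if (!formula_positive(r$rhs)) next
      if (!eval_formula(r$lhs, known_atoms())) next
      new_atoms <- setdiff(formula_atoms(r$rhs), known_atoms())
      if (!length(new_atoms)) next
      s_l <- ensure(r$lhs)
      if (is.na(s_l)) next
      s <- trace_add(tr, r$rhs, "modus ponens", c(s_l, rule_step[[r$id]]))
      if (assert_atoms(r$rhs, s)) progress <- TRUE
    }
    if (!progress) break
  }

  # resolution fallback for entailed atoms the definite pass missed
  clause_step <- rep(NA_integer_, length(sat$clauses))
  emit_clause <- function(i) {
    if (!is.na(clause_step[[i]])) return(clause_step[[i]])
    cl <- sat$clauses[[i]]
    s <- if (is.null(cl$parents)) {
      if (startsWith(cl$origin, "premise:")) {
        tr$by_canon[[canon_formula(f_atom(sub("^premise:", "", cl$origin)))]]
      } else {
        # clausal restatement of a rule, justified by the rule id
        trace_add(tr, clause_formula(mk_clause(cl$pos, cl$neg)),
                  sub("^rule:", "", cl$origin))
      }
    } else {
      sup <- vapply(cl$parents, emit_clause, 0L)
      trace_add(tr, clause_formula(mk_clause(cl$pos, cl$neg)),
                "resolution", sup)
    }
    clause_step[[i]] <<- s
    s
  }
  if (inconsistent) {
    emit_clause(sat$empty_at)
  } else {
    for (a in inferred) {
      if (!is.null(get0(a, envir = known))) next
      hit <- which(vapply(sat$clauses, function(cl) {
        identical(cl$pos, a) && !length(cl$neg)
      }, TRUE))
      if (length(hit)) emit_clause(hit[[1L]])
    }
  }
  tr$steps
}

#' Explain how an atom was inferred
#'
#' Extracts the minimal sub-derivation of the trace that establishes the
#' atom: the step concluding the atom and the transitive closure of its
#' supports, renumbered consecutively.
#'
#' @param result an `inference_result`.
#' @param atom an atom in `result$inferred`.
#' @return an object of class `derivation` (printable; a data.frame-like
#'   list of steps with `formula`, `justification`, `supports`).
#' @examples
#' res <- forward_chain(parse_rules("R1: MP_P -> MP_Q"), "MP_P")
#' explain(res, "MP_Q")
#' @export
explain <- function(result, atom) {
  stopifnot(inherits(result, "inference_result"))
  if (!atom %in% result$inferred) {
    stop("atom was not inferred: ", atom)
  }
  steps <- result$trace
  goal <- NA_integer_
  key <- canon_formula(f_atom(atom))
  for (s in steps) {
    if (canon_formula(s$formula) == key && s$justification != "premise") {
      goal <- s$n; break
    }
  }
  if (is.na(goal)) stop("no derivation step found for atom: ", atom)
  keep <- integer(0)
  stack <- goal
  while (length(stack)) {
    i <- stack[[1L]]; stack <- stack[-1L]
    if (i %in% keep) next
    keep <- c(keep, i)
    stack <- c(stack, steps[[i]]$supports)
  }
  keep <- sort(keep)
  renum <- setNames(seq_along(keep), keep)
  out <- lapply(seq_along(keep), function(k) {
    s <- steps[[keep[[k]]]]
    list(n = k, formula = s$formula, justification = s$justification,
         supports = unname(renum[as.character(s$supports)]))
  })
  structure(list(atom = atom, steps = out), class = "derivation")
}

#' @export
print.derivation <- function(x, ...) {
  cat("derivation of", x$atom, "\n")
  for (s in x$steps) {
    sup <- if (length(s$supports)) {
      paste0(" (from step", if (length(s$supports) > 1L) "s" else "", " ",
             paste(s$supports, collapse = ", "), ")")
    } else ""
    cat(sprintf("%3d. %s  [%s]%s\n", s$n, format_formula(s$formula),
                s$justification, sup))
  }
  invisible(x)
}

#' Replay-check a proof trace
#'
#' Mechanically re-applies each step's named inference rule to its supports
#' and verifies that it reproduces the step's formula: premises must be
#' detected atoms; rule-id steps must match the rule's implication or one of
#' its clausal forms; named inference-rule steps are recomputed from their
#' supports. Used by the test-suite; returns `TRUE` or stops with the
#' offending step.
#'
#' @param result an `inference_result`.
#' @param rules the [rule_base()] that produced it.
#' @return `TRUE`, invisibly, if every step replays.
#' @export
verify_trace <- function(result, rules) {
  steps <- result$trace
  rule_by_id <- setNames(rules$rules,
                         vapply(rules$rules, function(r) r$id, ""))
  fail <- function(s, why) {
    stop("trace step ", s$n, " (", format_formula(s$formula), " [",
         s$justification, "]) does not replay: ", why)
  }
  cnf_key <- function(f) {
    sort(vapply(to_cnf(f), clause_key, ""))
  }
  for (s in steps) {
    sup <- lapply(s$supports, function(i) steps[[i]]$formula)
    if (any(s$supports >= s$n)) fail(s, "support does not precede the step")
    j <- s$justification
    if (j == "premise") {
      if (!(s$formula$type == "atom" && s$formula$name %in% result$detected)) {
        fail(s, "premise is not a detected atom")
      }
    } else if (j %in% names(rule_by_id)) {
      r <- rule_by_id[[j]]
      full <- f_imp(r$lhs, r$rhs)
      ok <- formula_equal(s$formula, full) ||
        all(cnf_key(s$formula) %in% cnf_key(full))
      if (!ok) fail(s, "formula is not the rule or one of its clauses")
    } else if (j == "modus ponens") {
      imp <- Filter(function(f) f$type == "imp", sup)
      rest <- Filter(function(f) f$type != "imp", sup)
      if (length(imp) != 1L || length(rest) != 1L) fail(s, "needs X and X -> Y")
      if (!formula_equal(rest[[1L]], imp[[1L]]$lhs)) {
        fail(s, "antecedent does not match")
      }
      if (!formula_equal(s$formula, imp[[1L]]$rhs)) {
        fail(s, "consequent does not match")
      }
    } else if (j == "conjunction") {
      if (s$formula$type != "and") fail(s, "conjunction must yield 'and'")
      got <- sort(vapply(sup, canon_formula, ""))
      want <- sort(vapply(s$formula$args, canon_formula, ""))
      if (!identical(got, want)) fail(s, "conjuncts do not match supports")
    } else if (j == "simplification") {
      if (length(sup) != 1L || sup[[1L]]$type != "and") {
        fail(s, "needs one 'and' support")
      }
      keys <- vapply(sup[[1L]]$args, canon_formula, "")
      if (!canon_formula(s$formula) %in% keys) {
        fail(s, "formula is not a conjunct of the support")
      }
    } else if (j == "addition") {
      if (length(sup) != 1L || s$formula$type != "or") {
        fail(s, "needs one support and an 'or' formula")
      }
      keys <- vapply(s$formula$args, canon_formula, "")
      if (!canon_formula(sup[[1L]]) %in% keys) {
        fail(s, "support is not a disjunct of the formula")
      }
    } else if (j == "resolution") {
      if (length(sup) != 2L) fail(s, "needs two supports")
      cl <- lapply(sup, function(f) {
        cs <- to_cnf(f)
        if (length(cs) != 1L) fail(s, "support is not a single clause")
        cs[[1L]]
      })
      want <- to_cnf(s$formula)
      if (s$formula$type == "or" && !length(s$formula$args)) {
        want <- list(mk_clause(character(0), character(0)))
      }
      if (length(want) != 1L) fail(s, "formula is not a single clause")
      ok <- FALSE
      for (a in intersect(cl[[1L]]$pos, cl[[2L]]$neg)) {
        r <- mk_clause(c(setdiff(cl[[1L]]$pos, a), cl[[2L]]$pos),
                       c(cl[[1L]]$neg, setdiff(cl[[2L]]$neg, a)))
        if (identical(clause_key(r), clause_key(want[[1L]]))) ok <- TRUE
      }
      for (a in intersect(cl[[1L]]$neg, cl[[2L]]$pos)) {
        r <- mk_clause(c(cl[[1L]]$pos, setdiff(cl[[2L]]$pos, a)),
                       c(setdiff(cl[[1L]]$neg, a), cl[[2L]]$neg))
        if (identical(clause_key(r), clause_key(want[[1L]]))) ok <- TRUE
      }
      if (!ok) fail(s, "formula is not a resolvent of the supports")
    } else {
      fail(s, paste0("unknown justification '", j, "'"))
    }
  }
  invisible(TRUE)
}

#' Write an inference result as JSON
#'
#' @param result an `inference_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_inference <- function(result, path) {
  obj <- list(
    detected = result$detected,
    inferred = result$inferred,
    combined = result$combined,
    inconsistent = result$inconsistent,
    trace = lapply(result$trace, function(s) {
      list(n = s$n, formula = format_formula(s$formula),
           justification = s$justification, supports = s$supports)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
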