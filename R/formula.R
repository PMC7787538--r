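#' @name prop-formula
#' @title Propositional formulas over pathway atoms
#'
#' @description
#' Specification rules are implications between propositional formulas built
#' from pathway atoms with conjunction (`&`), disjunction (`|`) and negation
#' (`!`). Formulas are plain nested lists with a `type` field in
#' `atom`/`not`/`and`/`or`/`imp`; `f_and()`/`f_or()` flatten nested
#' connectives and a one-element connective collapses to its argument.
NULL

#' @rdname prop-formula
#' @param name atom name.
#' @export
f_atom <- function(name) list(type = "atom", name = as.character(name))

#' @rdname prop-formula
#' @param f a formula.
#' @export
f_not <- function(f) list(type = "not", arg = f)

#' @rdname prop-formula
#' @param args list of formulas.
#' @export
f_and <- function(args) {
  flat <- list()
  for (a in args) {
    if (a$type == "and") flat <- c(flat, a$args) else flat <- c(flat, list(a))
  }
  if (length(flat) == 1L) flat[[1L]] else list(type = "and", args = flat)
}

#' @rdname prop-formula
#' @export
f_or <- function(args) {
  flat <- list()
  for (a in args) {
    if (a$type == "or") flat <- c(flat, a$args) else flat <- c(flat, list(a))
  }
  if (length(flat) == 1L) flat[[1L]] else list(type = "or", args = flat)
}

#' @rdname prop-formula
#' @param lhs,rhs antecedent and consequent formulas.
#' @export
f_imp <- function(lhs, rhs) list(type = "imp", lhs = lhs, rhs = rhs)

#' Format a formula in the rule DSL syntax
#'
#' @param f a formula.
#' @param top internal: suppress outermost parentheses.
#' @return a single string, e.g. `"MP_A & (MP_B | !MP_C)"`.
#' @export
format_formula <- function(f, top = TRUE) {
  wrap <- function(s) if (top) s else paste0("(", s, ")")
  switch(f$type,
    atom = f$name,
    not = paste0("!", format_formula(f$arg, top = FALSE)),
    and = wrap(paste(vapply(f$args, format_formula, "", top = FALSE),
                     collapse = " & ")),
    or = if (!length(f$args)) "FALSE" else
      wrap(paste(vapply(f$args, format_formula, "", top = FALSE),
                 collapse = " | ")),
    imp = wrap(paste(format_formula(f$lhs, top = FALSE), "->",
                     format_formula(f$rhs, top = FALSE))),
    stop("unknown formula type: ", f$type)
  )
}

# canonical string: args of and/or sorted and deduplicated, so formula
# equality is order-insensitive
canon_formula <- function(f) {
  switch(f$type,
    atom = f$name,
    not = paste0("!", canon_formula(f$arg)),
    and = paste0("(&", paste(sort(unique(vapply(f$args, canon_formula, ""))),
                             collapse = " "), ")"),
    or = paste0("(|", paste(sort(unique(vapply(f$args, canon_formula, ""))),
                            collapse = " "), ")"),
    imp = paste0("(-> ", canon_formula(f$lhs), " ", canon_formula(f$rhs), ")")
  )
}

formula_equal <- function(f, g) identical(canon_formula(f), canon_formula(g))

#' Atoms occurring in a formula
#' @param f a formula.
#' @return sorted character vector of atom names.
#' @export
formula_atoms <- function(f) {
  switch(f$type,
    atom = f$name,
    not = formula_atoms(f$arg),
    imp = sort(unique(c(formula_atoms(f$lhs), formula_atoms(f$rhs)))),
    sort(unique(unlist(lapply(f$args, formula_atoms))))
  )
}

#' Evaluate a formula under a set of true atoms
#'
#' @param f a formula.
#' @param true_atoms character vector of atoms assigned `TRUE`; every other
#'   atom is `FALSE`.
#' @return logical scalar.
#' @export
eval_formula <- function(f, true_atoms) {
  switch(f$type,
    atom = f$name %in% true_atoms,
    not = !eval_formula(f$arg, true_atoms),
    and = all(vapply(f$args, eval_formula, TRUE, true_atoms = true_atoms)),
    or = any(vapply(f$args, eval_formula, TRUE, true_atoms = true_atoms)),
    imp = !eval_formula(f$lhs, true_atoms) || eval_formula(f$rhs, true_atoms)
  )
}

# TRUE if the formula contains no negation (and no implication)
formula_positive <- function(f) {
  switch(f$type,
    atom = TRUE,
    not = FALSE,
    imp = FALSE,
    all(vapply(f$args, formula_positive, TRUE))
  )
}

# ---- clausal form ---------------------------------------------------------

# clause: list(pos = sorted chr, neg = sorted chr)
mk_clause <- function(pos, neg) {
  list(pos = sort(unique(pos)), neg = sort(unique(neg)))
}

clause_key <- function(cl) {
  paste0(paste(cl$pos, collapse = ","), "|-", paste(cl$neg, collapse = ","))
}

clause_tautology <- function(cl) length(intersect(cl$pos, cl$neg)) > 0L

# cl1 subsumes cl2
clause_subsumes <- function(cl1, cl2) {
  all(cl1$pos %in% cl2$pos) && all(cl1$neg %in% cl2$neg)
}

# negation-normal form with implications eliminated
to_nnf <- function(f, negate = FALSE) {
  switch(f$type,
    atom = if (negate) f_not(f) else f,
    not = to_nnf(f$arg, !negate),
    imp = to_nnf(f_or(list(f_not(f$lhs), f$rhs)), negate),
    and = if (negate) f_or(lapply(f$args, to_nnf, negate = TRUE))
          else f_and(lapply(f$args, to_nnf, negate = FALSE)),
    or = if (negate) f_and(lapply(f$args, to_nnf, negate = TRUE))
         else f_or(lapply(f$args, to_nnf, negate = FALSE))
  )
}

#' Conjunctive normal form of a formula
#'
#' @param f a formula.
#' @return list of clauses, each `list(pos = , neg = )`, tautologies dropped
#'   and duplicates removed.
#' @export
to_cnf <- function(f) {
  nnf <- to_nnf(f)
  rec <- function(g) {
    switch(g$type,
      atom = list(mk_clause(g$name, character(0))),
      not = list(mk_clause(character(0), g$arg$name)),
      and = do.call(c, lapply(g$args, rec)),
      or = {
        parts <- lapply(g$args, rec)
        acc <- list(mk_clause(character(0), character(0)))
        for (p in parts) {
          acc <- do.call(c, lapply(acc, function(cl1) {
            lapply(p, function(cl2) {
              mk_clause(c(cl1$pos, cl2$pos), c(cl1$neg, cl2$neg))
            })
          }))
        }
        acc
      }
    )
  }
  cls <- rec(nnf)
  cls <- cls[!vapply(cls, clause_tautology, TRUE)]
  cls[!duplicated(vapply(cls, clause_key, ""))]
}

# clause back to a formula (empty clause -> contradiction marker)
clause_formula <- function(cl) {
  lits <- c(lapply(cl$pos, f_atom), lapply(cl$neg, function(a) f_not(f_atom(a))))
  if (!length(lits)) return(list(type = "or", args = list())) # falsum
  f_or(lits)
}
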