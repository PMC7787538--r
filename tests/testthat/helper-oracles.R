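# Independent oracles used across the suite. These deliberately take the
# brute-force route (truth tables, exhaustive scans, igraph distances) so
# they share no code path with the implementations they check.

# --- truth-table entailment oracle (model enumeration over <= 2^n rows) ----

eval_formula_rows <- function(f, mat) {
  switch(f$type,
    atom = if (f$name %in% colnames(mat)) mat[, f$name]
           else rep(FALSE, nrow(mat)),
    not = !eval_formula_rows(f$arg, mat),
    and = Reduce(`&`, lapply(f$args, eval_formula_rows, mat = mat)),
    or = Reduce(`|`, lapply(f$args, eval_formula_rows, mat = mat)),
    imp = !eval_formula_rows(f$lhs, mat) | eval_formula_rows(f$rhs, mat)
  )
}

truth_table_entailed <- function(rules, detected) {
  atoms <- sort(union(rules$atoms, detected))
  mat <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(atoms))))
  colnames(mat) <- atoms
  ok <- rep(TRUE, nrow(mat))
  for (r in rules$rules) {
    ok <- ok & eval_formula_rows(f_imp(r$lhs, r$rhs), mat)
  }
  for (a in detected) ok <- ok & mat[, a]
  if (!any(ok)) {
    return(list(inconsistent = TRUE,
                inferred = sort(setdiff(atoms, detected))))
  }
  models <- mat[ok, , drop = FALSE]
  entailed <- atoms[colSums(models) == nrow(models)]
  list(inconsistent = FALSE, inferred = sort(setdiff(entailed, detected)))
}

# --- naive least-fixpoint oracle for definite-clause bases -----------------

definite_fixpoint <- function(rules, detected) {
  facts <- unique(detected)
  repeat {
    added <- FALSE
    for (r in rules$rules) {
      body <- formula_atoms(r$lhs)
      if (all(body %in% facts)) {
        heads <- formula_atoms(r$rhs)
        new <- setdiff(heads, facts)
        if (length(new)) { facts <- c(facts, new); added <- TRUE }
      }
    }
    if (!added) break
  }
  sort(setdiff(facts, detected))
}

# --- random rule-base generators -------------------------------------------

rand_formula <- function(atoms, k, p_neg = 0.25) {
  picks <- sample(atoms, k, replace = FALSE)
  lits <- lapply(picks, function(a) {
    if (stats::runif(1) < p_neg) f_not(f_atom(a)) else f_atom(a)
  })
  if (length(lits) == 1L) return(lits[[1L]])
  if (stats::runif(1) < 0.5) f_and(lits) else f_or(lits)
}

rand_rulebase <- function(n_atoms, n_rules, p_neg = 0.25) {
  atoms <- paste0("MP_A", seq_len(n_atoms))
  rule_base(lapply(seq_len(n_rules), function(i) {
    list(id = paste0("R", i),
         lhs = rand_formula(atoms, sample(1:3, 1L), p_neg),
         rhs = rand_formula(atoms, sample(1:2, 1L), p_neg))
  }))
}

# definite: conjunctive positive body, single-atom head
rand_definite_rulebase <- function(n_atoms, n_rules) {
  atoms <- paste0("MP_A", seq_len(n_atoms))
  rule_base(lapply(seq_len(n_rules), function(i) {
    body <- sample(atoms, sample(1:3, 1L))
    list(id = paste0("R", i),
         lhs = f_and(lapply(body, f_atom)),
         rhs = f_atom(sample(atoms, 1L)))
  }))
}

# --- small shared fixtures -------------------------------------------------

toy_dict <- function() {
  term_dict(
    c("TP53", "BRCA1", "SARC", "BC"),
    c("marker", "marker", "disease", "disease"),
    list("TP53", "BRCA1", "sarcoma", c("breast cancer", "BC"))
  )
}

table2_matrix <- function() {
  W <- matrix(c(3, 0, 0, 0, 7, 0, 3, 6, 3, 0,
                0, 3, 7, 3, 0, 0, 0, 3, 0, 4,
                3, 3, 5, 0, 0, 6, 0, 0, 4, 0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), paste0("c", 1:10)))
  W
}

# exhaustive per-pair, per-publication dominance oracle
dominance_oracle <- function(W) {
  n <- ncol(W)
  scores <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      wins <- sum(W[, i] > W[, j]); losses <- sum(W[, j] > W[, i])
      if (wins > losses) scores[i] <- scores[i] + 1L
      if (losses > wins) scores[i] <- scores[i] - 1L
    }
  }
  ranks <- vapply(scores, function(s) 1L + sum(scores > s), 1L)
  list(scores = setNames(scores, colnames(W)),
       ranks = setNames(ranks, colnames(W)))
}
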