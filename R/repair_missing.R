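# Phases 3.1-3.4 for missing is-a relations and missing mappings: repair
# spaces (Source x Target), conflict filtering, ranking, informativeness-
# based recommendation, and validated execution of additions.
#
# Informativeness is a preorder on candidate additions of one scope:
# (s, t) is at least as informative as (a, b) when "a is-a s" and "t is-a b"
# already hold, so adding (s, t) entails (a, b). Every validated missing
# relation is provisionally repaired by itself (the least informative
# action); the repair space offers the more informative alternatives.

#' Informativeness comparison of candidate additions
#'
#' @param kb a `knowledge_base`.
#' @param s,t,a,b concept keys; tests whether adding `(s, t)` would entail
#'   `(a, b)` in `kb`, i.e. `(s, t)` is at least as informative as `(a, b)`.
#' @return logical scalar.
#' @export
at_least_as_informative <- function(kb, s, t, a, b) {
  derivable(kb, a, s) && derivable(kb, t, b)
}

missing_defect_row <- function(session, defect) {
  ids <- register_ids(defect)
  if (ids %in% register_ids(session$MI)) {
    list(kind = "CMI", scope = parse_scope(defect$scope))
  } else if (ids %in% register_ids(session$MM)) {
    list(kind = "CMM", scope = parse_scope(defect$scope))
  } else {
    stop("defect (", defect$sub, ", ", defect$sup,
         ") is not an unrepaired validated missing relation")
  }
}

#' Generate the repair space for a missing relation
#'
#' In the scope knowledge base (host ontology for a missing is-a relation;
#' ontology pair for a missing mapping), `Source(a,b)` is the reflexive
#' super-concept cone of `a` minus that of `b`, `Target(a,b)` the reflexive
#' sub-concept cone of `b` minus that of `a`, and the repair space is
#' `Source x Target` minus conflicts with validated wrong relations:
#' elements that are themselves registered wrong or removed, and elements at
#' least as informative as such a pair over validated-correct axioms (adding
#' them would re-derive a known wrong relation). By this set-difference
#' construction no element introduces a non-validated equivalence, every
#' element is a single axiom, and every element makes the defect pair
#' derivable; the defect pair itself is the least informative member.
#'
#' @param session a `repair_session`.
#' @param defect one-row register of an unrepaired validated missing
#'   relation.
#' @param scope_kb,vc_kb optional pre-built scope and validated-correct
#'   knowledge bases.
#' @return object of class `repair_space` with `source`, `target` (concept
#'   keys) and `repair` (data frame `sub`, `sup`).
#' @export
generate_repair_space <- function(session, defect, scope_kb = NULL,
                                  vc_kb = NULL) {
  info <- missing_defect_row(session, defect)
  kb <- if (is.null(scope_kb)) build_kb(session, info$scope) else scope_kb
  a <- defect$sub; b <- defect$sup
  source_set <- setdiff(cone(kb, a, "super"), cone(kb, b, "super"))
  target_set <- setdiff(cone(kb, b, "sub"), cone(kb, a, "sub"))
  rep_grid <- expand.grid(sub = source_set, sup = target_set,
                          stringsAsFactors = FALSE)
  # the defect pair itself (promotion of its provisional axiom) is always
  # offered as the least informative action, subject only to the conflict
  # filters below; the set differences can exclude it when another
  # unrepaired missing relation provisionally asserts the reverse direction
  if (!(pair_id(a, b) %in% pair_id(rep_grid$sub, rep_grid$sup))) {
    rep_grid <- rbind(rep_grid, data.frame(sub = a, sup = b,
                                           stringsAsFactors = FALSE))
  }
  rep_grid <- rep_grid[order(pair_id(rep_grid$sub, rep_grid$sup)), , drop = FALSE]

  conflict <- rbind(session$WI[, c("sub", "sup")], session$WM[, c("sub", "sup")],
                    data.frame(sub = ckey(session$RI_minus$sub_ont, session$RI_minus$sub),
                               sup = ckey(session$RI_minus$sup_ont, session$RI_minus$sup),
                               stringsAsFactors = FALSE),
                    data.frame(sub = ckey(session$RM_minus$sub_ont, session$RM_minus$sub),
                               sup = ckey(session$RM_minus$sup_ont, session$RM_minus$sup),
                               stringsAsFactors = FALSE))
  if (nrow(conflict) > 0L && nrow(rep_grid) > 0L) {
    direct <- pair_id(rep_grid$sub, rep_grid$sup) %in%
      pair_id(conflict$sub, conflict$sup)
    rep_grid <- rep_grid[!direct, , drop = FALSE]
    if (nrow(rep_grid) > 0L) {
      vc <- if (is.null(vc_kb)) validated_correct_kb(session, "network") else vc_kb
      vr <- kb_reach(vc)
      diag(vr) <- TRUE
      entails_wrong <- rep(FALSE, nrow(rep_grid))
      known <- rep_grid$sub %in% vc$concepts & rep_grid$sup %in% vc$concepts
      for (j in seq_len(nrow(conflict))) {
        u <- conflict$sub[j]; v <- conflict$sup[j]
        if (!(u %in% vc$concepts && v %in% vc$concepts)) next
        entails_wrong <- entails_wrong |
          (known & vr[u, ][rep_grid$sub] & vr[, v][rep_grid$sup])
      }
      rep_grid <- rep_grid[!entails_wrong, , drop = FALSE]
    }
  }
  rownames(rep_grid) <- NULL
  structure(list(defect = defect, kind = info$kind,
                 scope = format_scope(info$scope),
                 source = source_set, target = target_set, repair = rep_grid),
            class = "repair_space")
}

#' @export
print.repair_space <- function(x, ...) {
  cat("Repair space for (", x$defect$sub, " is-a ", x$defect$sup, "): ",
      length(x$source), " source x ", length(x$target), " target concepts, ",
      nrow(x$repair), " repairing actions\n", sep = "")
  invisible(x)
}

#' Rank missing relations by number of possible repairing actions
#'
#' Ascending by repair-space size (fewest actions first -- typically the
#' easiest starting points), ties broken lexicographically by pair.
#'
#' @param session a `repair_session`.
#' @param scope an ontology id (missing is-a relations) or pair (missing
#'   mappings).
#' @return ordered defect register with an `n_actions` column.
#' @export
rank_missing <- function(session, scope) {
  sc <- parse_scope(scope)
  reg <- if (sc$type == "ontology") session$MI else session$MM
  reg <- reg[reg$scope == format_scope(sc), , drop = FALSE]
  if (nrow(reg) == 0L) { reg$n_actions <- integer(0); return(reg) }
  scope_kb <- build_kb(session, sc)
  vc_kb <- validated_correct_kb(session, "network")
  reg$n_actions <- vapply(seq_len(nrow(reg)), function(i) {
    nrow(generate_repair_space(session, reg[i, , drop = FALSE],
                               scope_kb = scope_kb, vc_kb = vc_kb)$repair)
  }, integer(1))
  reg <- reg[order(reg$n_actions, pair_id(reg$sub, reg$sup)), , drop = FALSE]
  rownames(reg) <- NULL
  reg
}

maximal_elements <- function(kb, pairs) {
  n <- nrow(pairs)
  if (n <= 1L) return(pairs)
  r <- kb_reach(kb)
  # geq[i, j]: pair i at least as informative as pair j, i.e.
  # derivable(sub_j, sub_i) and derivable(sup_i, sup_j)
  geq <- t(r[pairs$sub, pairs$sub, drop = FALSE]) &
    r[pairs$sup, pairs$sup, drop = FALSE]
  diag(geq) <- TRUE
  keep <- vapply(seq_len(n), function(j) {
    !any(geq[, j] & !geq[j, ] & seq_len(n) != j)
  }, logical(1))
  pairs[keep, , drop = FALSE]
}

#' Recommend repairing actions for a missing relation
#'
#' Among repair-space elements supported by the knowledge oracle (oracle
#' verdict `isa` on normalized labels), returns the maximal elements of the
#' informativeness preorder. When no element is supported, the maximal
#' elements of the whole repair space are returned with `supported = FALSE`
#' so scripted policies can ignore the fallback.
#'
#' @param session a `repair_session`.
#' @param space a `repair_space` with non-empty `repair`.
#' @param oracle a `knowledge_oracle`.
#' @return data frame (`sub`, `sup`, `supported`), best candidates only.
#' @export
recommend_additions <- function(session, space, oracle = null_oracle()) {
  stopifnot(inherits(space, "repair_space"), nrow(space$repair) > 0L)
  kb <- build_kb(session, space$scope)
  net <- session$network
  lab <- function(key) {
    normalize_label(concept_label(net, key_ont(key), key_id(key)))
  }
  supported <- vapply(seq_len(nrow(space$repair)), function(i) {
    tryCatch(identical(oracle(lab(space$repair$sub[i]), lab(space$repair$sup[i])),
                       "isa"),
             error = function(e) FALSE)
  }, logical(1))
  if (any(supported)) {
    best <- maximal_elements(kb, space$repair[supported, , drop = FALSE])
    best$supported <- TRUE
  } else {
    best <- maximal_elements(kb, space$repair)
    best$supported <- FALSE
  }
  rownames(best) <- NULL
  best
}

#' Execute a repairing action for a missing relation
#'
#' The action must be in the defect's repair space, recomputed at call time;
#' otherwise the call is rejected and the session unchanged. An intra-
#' ontology action enters RI+ (the defect pair itself is promoted from its
#' provisional axiom), a cross-ontology action enters RM+; the defect leaves
#' MI/MM and all consequences are propagated.
#'
#' @param session a `repair_session`.
#' @param defect one-row register of an unrepaired validated missing
#'   relation.
#' @param action repairing action `c(sub_key, sup_key)`.
#' @return the updated session; the consequence report is attached as
#'   attribute `"consequences"`.
#' @export
execute_addition <- function(session, defect, action) {
  space <- generate_repair_space(session, defect)
  act_id <- pair_id(action[1], action[2])
  if (!(act_id %in% pair_id(space$repair$sub, space$repair$sup))) {
    stop("repairing action ", act_id, " is not in Repair(",
         defect$sub, ", ", defect$sup, "); the repairing is not allowed")
  }
  is_self <- act_id == pair_id(defect$sub, defect$sup)
  ax <- axioms(sub_ont = key_ont(action[1]), sub = key_id(action[1]),
               sup_ont = key_ont(action[2]), sup = key_id(action[2]),
               status = "repair-added",
               origin = if (is_self) "validated-missing" else "repair")
  if (ax$layer == "intra") {
    session$RI_plus <- bind_axioms(session$RI_plus, ax)
  } else {
    session$RM_plus <- bind_axioms(session$RM_plus, ax)
    key <- pair_key(ax$sub_ont, ax$sup_ont)
    if (is.null(session$network$alignments[[key]])) {
      # a repairing action may create the first mapping between two
      # ontologies; register an (empty) alignment to host it
      al <- alignment(sort(c(ax$sub_ont, ax$sup_ont))[1],
                      sort(c(ax$sub_ont, ax$sup_ont))[2])
      session$network$alignments[[key]] <- al
      session$network$alignments <-
        session$network$alignments[order(names(session$network$alignments))]
    }
  }
  info <- missing_defect_row(session, defect)
  reg <- if (info$kind == "CMI") "MI" else "MM"
  sel <- register_ids(session[[reg]]) == register_ids(defect)
  session[[reg]] <- session[[reg]][!sel, , drop = FALSE]
  session$repaired_missing <- rbind(session$repaired_missing, data.frame(
    scope = defect$scope, sub = defect$sub, sup = defect$sup,
    kind = info$kind, action_sub = action[1], action_sup = action[2],
    via = if (is_self) "promoted" else "action", stringsAsFactors = FALSE))
  session <- log_decision(session, "repair-missing",
                          paste0("added ", act_id, " for ",
                                 register_ids(defect)))
  res <- propagate_consequences(session)
  out <- res$session
  attr(out, "consequences") <- res$report
  out
}
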