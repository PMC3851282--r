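# Phases 3.1-3.4 for wrong is-a relations and wrong mappings: removal
# candidates from justifications, ranking, minimal hitting sets, priority
# recommendation, and transactional execution of removals.
#
# Only original asserted axioms (including equivalence components) are ever
# removable: validated missing relations (provisional axioms) and added
# repairing actions represent validated-correct knowledge and are excluded
# from every removal.

axiom_removable <- function(ax) {
  ax$status == "asserted" & ax$origin %in% c("original", "equivalence-component")
}

#' Removal candidates for one wrong relation
#'
#' Computes all justifications of the defect pair in the current network
#' knowledge base and, for each, the subset of its axioms eligible for
#' removal. A justification with an empty eligible subset cannot be broken
#' by removal and flags the defect as unrepairable-by-removal.
#'
#' @param session a `repair_session`.
#' @param defect one-row register (`scope`, `sub`, `sup`) of a validated
#'   wrong relation whose pair is still derivable from the network.
#' @param net_kb optional pre-built network knowledge base.
#' @return list with `justifications` (list of axiom tables), `eligible`
#'   (list of axiom-key vectors), `unrepairable` flag, and `truncated` flag.
#' @export
removal_candidates <- function(session, defect, net_kb = NULL) {
  kb <- if (is.null(net_kb)) build_kb(session, "network") else net_kb
  if (!derivable(kb, defect$sub, defect$sup)) {
    stop("defect (", defect$sub, ", ", defect$sup,
         ") is already repaired: its pair is not derivable")
  }
  js <- all_justifications(kb, defect$sub, defect$sup,
                           max_paths = session$options$max_paths,
                           max_len = session$options$max_len)
  eligible <- lapply(js, function(j) axiom_keys(j[axiom_removable(j), , drop = FALSE]))
  list(justifications = js, eligible = eligible,
       unrepairable = any(lengths(eligible) == 0L),
       truncated = isTRUE(attr(js, "truncated")))
}

#' Minimal hitting sets of a family of axiom sets
#'
#' Enumerates all subset-minimal sets intersecting every candidate set, up
#' to the caps; removing a hitting set of the justifications of a wrong
#' relation makes that relation underivable.
#'
#' @param candidate_sets list of non-empty character vectors (axiom keys).
#' @param max_size,max_count enumeration caps; hitting them sets the
#'   `truncated` attribute.
#' @return list of sorted character vectors, ordered by size then
#'   lexicographically, with attribute `truncated`.
#' @export
minimal_hitting_sets <- function(candidate_sets, max_size = 5L,
                                 max_count = 10000L) {
  if (length(candidate_sets) == 0L) {
    out <- list(character())
    attr(out, "truncated") <- FALSE
    return(out)
  }
  if (any(lengths(candidate_sets) == 0L)) {
    stop("no hitting set exists: a candidate set is empty")
  }
  sets <- lapply(candidate_sets, function(s) sort(unique(s)))
  found <- list()
  truncated <- FALSE

  extend <- function(current, size_limit) {
    # prune: a found (smaller) hitting set inside `current` would make any
    # completion non-minimal
    for (h in found) {
      if (all(h %in% current)) return(invisible())
    }
    unhit <- Filter(function(s) !any(s %in% current), sets)
    if (length(unhit) == 0L) {
      if (length(current) == size_limit) {
        if (length(found) >= max_count) { truncated <<- TRUE; return(invisible()) }
        found[[length(found) + 1L]] <<- sort(current)
      }
      return(invisible())
    }
    if (length(current) >= size_limit) return(invisible())
    for (e in unhit[[1]]) {
      if (truncated) return(invisible())
      extend(c(current, e), size_limit)
    }
    invisible()
  }

  for (s in seq_len(max_size)) {
    if (truncated) break
    n_before <- length(found)
    extend(character(), s)
    if (length(found) > n_before) {
      found <- unique(found)
    }
  }
  if (any(lengths(sets) > 0L) && length(found) == 0L && !truncated &&
      min(lengths(sets)) > 0L) {
    # every hitting set is larger than max_size
    truncated <- TRUE
  }
  found <- found[order(lengths(found),
                       vapply(found, paste, character(1), collapse = "\r"))]
  attr(found, "truncated") <- truncated
  found
}

#' Rank wrong relations by number of possible repairing actions
#'
#' Ascending by the size of the union of eligible removal axioms over all
#' justifications (fewest first -- the easiest starting points), ties broken
#' lexicographically by pair.
#'
#' @param session a `repair_session`.
#' @param scope an ontology id (wrong is-a relations) or pair (wrong
#'   mappings).
#' @return ordered defect register with an `n_actions` column.
#' @export
rank_wrong <- function(session, scope) {
  sc <- parse_scope(scope)
  reg <- if (sc$type == "ontology") session$WI else session$WM
  reg <- reg[reg$scope == format_scope(sc), , drop = FALSE]
  if (nrow(reg) == 0L) { reg$n_actions <- integer(0); return(reg) }
  net_kb <- build_kb(session, "network")
  reg$n_actions <- vapply(seq_len(nrow(reg)), function(i) {
    rc <- removal_candidates(session, reg[i, , drop = FALSE], net_kb = net_kb)
    length(unique(unlist(rc$eligible)))
  }, integer(1))
  reg <- reg[order(reg$n_actions, pair_id(reg$sub, reg$sup)), , drop = FALSE]
  rownames(reg) <- NULL
  reg
}

#' Priority-ordered removal recommendations for a set of wrong relations
#'
#' For every defect under repair the minimal hitting sets of its own
#' justifications are computed; an axiom's score is the triple (number of
#' those hitting sets containing it across all defects, number of defects
#' having it in some justification, +1 if it was chosen in an earlier
#' executed removal of this session). Priorities P1, P2, ... are assigned in
#' descending lexicographic score order; an axiom hitting several defects at
#' once thereby outranks axioms that repair only one.
#'
#' @param session a `repair_session`.
#' @param defects register of validated wrong relations selected jointly.
#' @return data frame with `axiom`, `hs_count`, `defect_count`, `prior`,
#'   `priority` columns, best first.
#' @export
recommend_removals <- function(session, defects) {
  stopifnot(nrow(defects) > 0L)
  hs_count <- integer(); defect_count <- integer()
  bump <- function(tab, keys) {
    for (k in keys) tab[k] <- (if (k %in% names(tab)) tab[[k]] else 0L) + 1L
    tab
  }
  net_kb <- build_kb(session, "network")
  for (i in seq_len(nrow(defects))) {
    rc <- removal_candidates(session, defects[i, , drop = FALSE], net_kb = net_kb)
    hs <- minimal_hitting_sets(rc$eligible,
                               max_size = session$options$max_hs_size,
                               max_count = session$options$max_hs_count)
    for (h in hs) hs_count <- bump(hs_count, h)
    defect_count <- bump(defect_count, unique(unlist(rc$eligible)))
  }
  keys <- sort(names(defect_count))
  out <- data.frame(axiom = keys,
                    hs_count = as.integer(ifelse(keys %in% names(hs_count),
                                                 hs_count[keys], 0L)),
                    defect_count = as.integer(defect_count[keys]),
                    prior = as.integer(keys %in% session$chosen_removals),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$hs_count, -out$defect_count, -out$prior, out$axiom), ,
             drop = FALSE]
  out$priority <- paste0("P", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Execute removals repairing wrong relations
#'
#' Transactional: the chosen axioms must all be eligible for removal, and
#' after removing them every defect pair and every chosen axiom's own pair
#' must be underivable from the network -- otherwise the call is rejected
#' and the session is unchanged. On success, removed intra axioms enter
#' RI-, removed mappings RM-, the repaired defects leave WI/WM, and all
#' consequences are propagated.
#'
#' @param session a `repair_session`.
#' @param defects register of validated wrong relations under repair.
#' @param chosen axiom keys (or an axiom table) to remove.
#' @return the updated session; the consequence report is attached as
#'   attribute `"consequences"`.
#' @export
execute_removals <- function(session, defects, chosen) {
  if (is.data.frame(chosen)) chosen <- axiom_keys(chosen)
  chosen <- sort(unique(chosen))
  if (length(chosen) == 0L) stop("no removal chosen")
  wrong_ids <- c(register_ids(session$WI), register_ids(session$WM))
  if (!all(register_ids(defects) %in% wrong_ids)) {
    stop("defect(s) not registered as unrepaired wrong relations")
  }
  kb <- build_kb(session, "network")
  rows <- axioms_in(kb$axioms, chosen)
  if (nrow(rows) != length(chosen)) {
    stop("chosen axiom(s) not present in the network: ",
         paste(setdiff(chosen, axiom_keys(rows)), collapse = ", "))
  }
  if (!all(axiom_removable(rows))) {
    stop("chosen axiom(s) not eligible for removal (validated-missing and ",
         "added repairing actions cannot be removed)")
  }
  kb2 <- apply_changes(kb, removals = rows)
  still <- pairs_derivable(kb2, defects$sub, defects$sup)
  if (any(still)) {
    stop("insufficient removal: defect pair(s) still derivable: ",
         paste(pair_id(defects$sub[still], defects$sup[still]), collapse = "; "))
  }
  chosen_pairs_derivable <- pairs_derivable(kb2, ckey(rows$sub_ont, rows$sub),
                                            ckey(rows$sup_ont, rows$sup))
  if (any(chosen_pairs_derivable)) {
    stop("insufficient removal: removed axiom pair(s) still derivable: ",
         paste(axiom_keys(rows)[chosen_pairs_derivable], collapse = "; "))
  }

  removed <- rows
  removed$status <- "removed"
  intra <- removed[removed$layer == "intra", , drop = FALSE]
  maps <- removed[removed$layer == "mapping", , drop = FALSE]
  session$RI_minus <- bind_axioms(session$RI_minus, intra)
  session$RM_minus <- bind_axioms(session$RM_minus, maps)
  session$chosen_removals <- sort(unique(c(session$chosen_removals, chosen)))

  ids <- register_ids(defects)
  for (reg in c("WI", "WM")) {
    sel <- register_ids(session[[reg]]) %in% ids
    if (any(sel)) {
      moved <- session[[reg]][sel, , drop = FALSE]
      moved$kind <- if (reg == "WI") "CMI" else "CMM"
      session$repaired_wrong <- rbind(session$repaired_wrong, moved)
      session[[reg]] <- session[[reg]][!sel, , drop = FALSE]
    }
  }
  session <- log_decision(session, "repair-wrong",
                          paste0("removed ", paste(chosen, collapse = ", "),
                                 " for ", paste(ids, collapse = "; ")))
  res <- propagate_consequences(session)
  out <- res$session
  attr(out, "consequences") <- res$report
  out
}
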