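# Phase 1: detection of candidate missing is-a relations (CMIs, per
# ontology) and candidate missing mappings (CMMs, per ontology pair) over
# pairs of mapped concepts, redundancy removal, and grouping for validation.
#
# A pair (a, b) of mapped concepts is a candidate when "a is-a b" is
# derivable from the network knowledge base but not from the scope-local
# one. Restricting detection to mapped concepts is sound: when the asserted
# structure and mappings are correct, repairing the candidates between
# mapped concepts repairs every derivable-but-local-underivable pair.

# Mapped-concept sets per ontology from a table of mapping axioms.
mapped_from_axioms <- function(ont_ids, ax) {
  ends <- data.frame(ont = c(ax$sub_ont, ax$sup_ont),
                     key = c(ckey(ax$sub_ont, ax$sub), ckey(ax$sup_ont, ax$sup)),
                     stringsAsFactors = FALSE)
  out <- stats::setNames(rep(list(character()), length(ont_ids)), ont_ids)
  if (nrow(ends) > 0L) {
    by_ont <- split(ends$key, ends$ont)
    for (k in names(by_ont)) out[[k]] <- sort(unique(by_ont[[k]]))
  }
  out
}

#' Mapped concepts of every ontology
#'
#' A concept is mapped when it occurs as an endpoint of at least one
#' non-removed mapping axiom.
#'
#' @param network an [ontology_network()].
#' @return named list (by ontology id) of sorted concept-key vectors.
#' @export
mapped_concepts <- function(network) {
  ax <- do.call(bind_axioms, lapply(network$alignments, function(a) {
    a$mappings[a$mappings$status != "removed", , drop = FALSE]
  }))
  mapped_from_axioms(names(network$ontologies), ax)
}

# Mapped concepts in the current session (added mappings count, removed do
# not).
session_mapped_concepts <- function(session) {
  fp <- session_axiom_fingerprint(session)
  hit <- kb_memo_get(fp, "mapped")
  if (!is.null(hit)) return(hit)
  rm_keys <- axiom_keys(session$RM_minus)
  ax <- do.call(bind_axioms, c(
    lapply(session$network$alignments, function(a)
      axioms_not_in(a$mappings, rm_keys)),
    list(session$RM_plus)))
  kb_memo_set(fp, "mapped",
              mapped_from_axioms(names(session$network$ontologies), ax))
}

decided_ids <- function(session) {
  unique(c(register_ids(session$MI), register_ids(session$WI),
           register_ids(session$MM), register_ids(session$WM),
           register_ids(session$repaired_missing),
           register_ids(session$repaired_wrong),
           register_ids(session$CMI[session$CMI$status == "unvalidated", ,
                                    drop = FALSE]),
           register_ids(session$CMM[session$CMM$status == "unvalidated", ,
                                    drop = FALSE])))
}

#' Detect candidate missing is-a relations or mappings in a scope
#'
#' Returns every ordered pair `(a, b)`, `a != b`, of mapped concepts in the
#' scope such that `a` is-a `b` is derivable from the current network
#' knowledge base but not from the scope-local one. Pairs whose status has
#' already been decided in this session (validated, repaired, or currently
#' open) are excluded, making re-detection idempotent.
#'
#' @param session a `repair_session`.
#' @param scope an ontology id (CMI detection) or an ontology pair (CMM
#'   detection).
#' @param net_kb,loc_kb optional pre-built knowledge bases for the network
#'   and the scope (rebuilt from the session when `NULL`).
#' @param mapped optional pre-computed [mapped_concepts()] result.
#' @return candidate register (`scope`, `sub`, `sup`, `status =
#'   "unvalidated"`).
#' @export
detect_candidates <- function(session, scope, net_kb = NULL, loc_kb = NULL,
                              mapped = NULL) {
  sc <- check_scope_exists(session, scope)
  if (sc$type == "network") stop("detection scope must be an ontology or a pair")
  if (is.null(mapped)) mapped <- session_mapped_concepts(session)
  if (is.null(net_kb)) net_kb <- build_kb(session, "network")
  if (is.null(loc_kb)) loc_kb <- build_kb(session, sc)
  reach_net <- kb_reach(net_kb)
  reach_loc <- kb_reach(loc_kb)

  block_hits <- function(rows, cols) {
    # derivable in the network but not locally, over a mapped-concept block
    hit <- reach_net[rows, cols, drop = FALSE] &
      !reach_loc[rows, cols, drop = FALSE]
    idx <- which(hit, arr.ind = TRUE)
    data.frame(sub = rows[idx[, 1]], sup = cols[idx[, 2]],
               stringsAsFactors = FALSE)
  }
  if (sc$type == "ontology") {
    cs <- intersect(mapped[[sc$ids]], loc_kb$concepts)
    if (length(cs) < 2L) return(candidate_register())
    grid <- block_hits(cs, cs)
    grid <- grid[grid$sub != grid$sup, , drop = FALSE]
  } else {
    if (is.null(session$network$alignments[[pair_key(sc$ids[1], sc$ids[2])]])) {
      stop("no alignment declared for pair ", format_scope(sc))
    }
    c1 <- intersect(mapped[[sc$ids[1]]], loc_kb$concepts)
    c2 <- intersect(mapped[[sc$ids[2]]], loc_kb$concepts)
    if (length(c1) == 0L || length(c2) == 0L) return(candidate_register())
    grid <- rbind(block_hits(c1, c2), block_hits(c2, c1))
  }
  out <- candidate_register(rep(format_scope(sc), nrow(grid)),
                            grid$sub, grid$sup,
                            rep("unvalidated", nrow(grid)))
  out <- out[!(register_ids(out) %in% decided_ids(session)), , drop = FALSE]
  canonical_register(out)
}

#' Split candidates into non-redundant and redundant ones
#'
#' A candidate `(a, b)` is redundant when a distinct retained candidate
#' `(c, d)` is at least as informative in the scope-local knowledge base
#' (`a` is-a `c` and `d` is-a `b` locally derivable): repairing `(c, d)`
#' then entails `(a, b)`. Within a set of mutually informative candidates
#' the lexicographically least pair is retained.
#'
#' @param candidates candidate register for one scope.
#' @param local_kb the scope-local `knowledge_base`.
#' @return list with candidate registers `non_redundant` and `redundant`.
#' @export
filter_redundant <- function(candidates, local_kb) {
  n <- nrow(candidates)
  if (n <= 1L) return(list(non_redundant = candidates,
                           redundant = candidates[0, , drop = FALSE]))
  if (length(unique(candidates$scope)) > 1L) {
    stop("redundancy filtering requires candidates of a single scope")
  }
  reach <- kb_reach(local_kb)
  geq <- matrix(FALSE, n, n)  # geq[i, j]: candidate i at least as informative as j
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { geq[i, j] <- TRUE; next }
      a <- candidates$sub[j]; b <- candidates$sup[j]
      c_ <- candidates$sub[i]; d_ <- candidates$sup[i]
      geq[i, j] <- (a == c_ || reach[a, c_]) && (d_ == b || reach[d_, b])
    }
  }
  ids <- register_ids(candidates)
  redundant <- vapply(seq_len(n), function(j) {
    any(vapply(seq_len(n), function(i) {
      i != j && geq[i, j] && (!geq[j, i] || ids[i] < ids[j])
    }, logical(1)))
  }, logical(1))
  list(non_redundant = candidates[!redundant, , drop = FALSE],
       redundant = candidates[redundant, , drop = FALSE])
}

#' First-iteration detection report for a network
#'
#' Runs candidate detection on every ontology and aligned pair of a fresh
#' session and reports, per scope, the total and non-redundant candidate
#' counts and the number of validation groups -- the summary a debugging
#' session prints before any validation. Pointing this at a full-scale
#' network (for instance the OAEI Anatomy ontologies with their reference
#' alignment, loaded via [load_ontology()] and [load_alignment()]) yields
#' the first-iteration detection census for that network.
#'
#' @param network an [ontology_network()].
#' @return data frame with columns `scope`, `kind`, `all`, `non_redundant`,
#'   `groups`.
#' @export
detection_report <- function(network) {
  session <- repair_session(network)
  net_kb <- build_kb(session, "network")
  rows <- lapply(all_scopes(network), function(scope) {
    sc <- parse_scope(scope)
    loc_kb <- build_kb(session, sc)
    cands <- detect_candidates(session, sc, net_kb = net_kb, loc_kb = loc_kb)
    parts <- filter_redundant(cands, loc_kb)
    groups <- group_candidates(parts$non_redundant, net_kb)
    data.frame(scope = format_scope(sc),
               kind = if (sc$type == "ontology") "CMI" else "CMM",
               all = nrow(cands), non_redundant = nrow(parts$non_redundant),
               groups = length(groups), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group candidates for validation
#'
#' Groups are the connected components of the comparability relation between
#' candidates: two candidates are connected when a concept of one subsumes
#' or is subsumed by (derivably, in the network knowledge base) a concept of
#' the other. Groups are ordered largest first, then lexicographically.
#'
#' @param candidates non-redundant candidate register for one scope.
#' @param network_kb the network `knowledge_base`.
#' @return list of candidate registers (one per group).
#' @export
group_candidates <- function(candidates, network_kb) {
  n <- nrow(candidates)
  if (n == 0L) return(list())
  reach <- kb_reach(network_kb)
  comparable <- function(x, y) x == y || reach[x, y] || reach[y, x]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ci <- c(candidates$sub[i], candidates$sup[i])
      cj <- c(candidates$sub[j], candidates$sup[j])
      linked <- any(vapply(ci, function(x)
        any(vapply(cj, function(y) comparable(x, y), logical(1))), logical(1)))
      if (linked) parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- lapply(split(seq_len(n), roots), function(idx) {
    g <- candidates[idx, , drop = FALSE]
    canonical_register(g)
  })
  ord <- order(-vapply(groups, nrow, integer(1)),
               vapply(groups, function(g) register_ids(g)[1], character(1)))
  unname(groups[ord])
}
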