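# Scoped knowledge bases over atomic subsumption axioms.
#
# A knowledge base is an immutable axiom set for one scope (whole network,
# one ontology, or one ontology pair plus its alignment) with a lazily built
# reachability closure. Derivability is reflexive-transitive reachability
# over the directed axiom graph; cycles (mutual subsumption, as created by
# equivalence mappings) are permitted. Everything is recomputed from scratch
# after each executed repair -- sufficient at desk scale and immune to stale
# incremental state.

new_kb <- function(axioms, concepts, scope, concepts_complete = FALSE) {
  axioms <- canonical_axioms(axioms)
  concepts <- if (concepts_complete) sort(unique(concepts)) else {
    sort(unique(c(concepts, ckey(axioms$sub_ont, axioms$sub),
                  ckey(axioms$sup_ont, axioms$sup))))
  }
  structure(list(scope = scope, axioms = axioms, concepts = concepts,
                 cache = new.env(parent = emptyenv())),
            class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("Knowledge base [", format_scope(x$scope), "]: ", length(x$concepts),
      " concepts, ", nrow(x$axioms), " axioms\n", sep = "")
  invisible(x)
}

#' Normalize a scope descriptor
#'
#' A scope is `"network"`, a single ontology id, or a character vector of two
#' ontology ids (an ontology pair). Pair scopes may also be written
#' `"i|j"`.
#' @param scope scope descriptor.
#' @return a list with elements `type` (`"network"`, `"ontology"`, `"pair"`)
#'   and `ids`.
#' @keywords internal
parse_scope <- function(scope) {
  if (is.list(scope) && !is.null(scope$type)) return(scope)
  scope <- as.character(scope)
  if (length(scope) == 1L && scope == "network") {
    return(list(type = "network", ids = character()))
  }
  if (length(scope) == 1L && grepl("|", scope, fixed = TRUE)) {
    scope <- strsplit(scope, "|", fixed = TRUE)[[1]]
  }
  if (length(scope) == 1L) return(list(type = "ontology", ids = scope))
  if (length(scope) == 2L) return(list(type = "pair", ids = sort(scope)))
  stop("invalid scope descriptor")
}

format_scope <- function(scope) {
  scope <- parse_scope(scope)
  switch(scope$type,
         network = "network",
         ontology = scope$ids,
         pair = paste(scope$ids, collapse = "|"))
}

check_scope_exists <- function(session, scope) {
  scope <- parse_scope(scope)
  unknown <- setdiff(scope$ids, names(session$network$ontologies))
  if (length(unknown) > 0L) {
    stop("unknown ontology id(s) in scope: ", paste(unknown, collapse = ", "))
  }
  scope
}

key_ont <- function(key) sub(":.*$", "", key)
key_id <- function(key) sub("^[^:]*:", "", key)

# Axioms for a register of validated-missing pairs (full concept keys).
provisional_axioms <- function(pairs) {
  if (nrow(pairs) == 0L) return(empty_axioms())
  axioms(sub_ont = key_ont(pairs$sub), sub = key_id(pairs$sub),
         sup_ont = key_ont(pairs$sup), sup = key_id(pairs$sup),
         status = "provisional", origin = "validated-missing")
}

# Static canonical axiom tables of the original network, shared across all
# states over the same network (keyed by its content hash).
network_static_tables <- function(network) {
  h <- attr(network, "content_hash")
  if (is.null(h)) h <- network_content_hash(network)
  if (identical(.kb_memo$static_hash, h)) return(.kb_memo$static)
  st <- list(
    intra = lapply(network$ontologies, function(o) canonical_axioms(o$isa)),
    maps = lapply(network$alignments, function(a) canonical_axioms(a$mappings)))
  .kb_memo$static_hash <- h
  .kb_memo$static <- st
  .kb_memo$persist <- new.env(parent = emptyenv())
  st
}

# Current intra axioms of ontology k: asserted minus removals, plus added
# repairs, plus (optionally) provisional axioms for its validated-but-
# unrepaired missing is-a relations.
current_intra_axioms <- function(session, k, include_provisionals = TRUE) {
  base <- network_static_tables(session$network)$intra[[k]]
  ax <- axioms_not_in(base, axiom_keys(session$RI_minus))
  adds <- session$RI_plus[session$RI_plus$sub_ont == k, , drop = FALSE]
  prov <- empty_axioms()
  if (include_provisionals) {
    prov <- provisional_axioms(session$MI[session$MI$scope == k, , drop = FALSE])
  }
  bind_axioms(ax, adds, prov)
}

# Current mapping axioms of pair (i, j), analogous to current_intra_axioms.
current_mapping_axioms <- function(session, i, j, include_provisionals = TRUE) {
  key <- pair_key(i, j)
  base <- network_static_tables(session$network)$maps[[key]]
  ax <- if (is.null(base)) empty_axioms()
        else axioms_not_in(base, axiom_keys(session$RM_minus))
  adds <- session$RM_plus[pair_key_vec(session$RM_plus) == key, , drop = FALSE]
  prov <- empty_axioms()
  if (include_provisionals) {
    prov <- provisional_axioms(session$MM[session$MM$scope == key, , drop = FALSE])
  }
  bind_axioms(ax, adds, prov)
}

pair_key_vec <- function(ax) {
  if (nrow(ax) == 0L) return(character())
  mapply(pair_key, ax$sub_ont, ax$sup_ont, USE.NAMES = FALSE)
}

#' Build the knowledge base for a scope of a session
#'
#' The knowledge base contains exactly the scope-visible non-removed axioms:
#' for an ontology, its asserted is-a axioms plus added repairs plus
#' provisional axioms of its validated-but-unrepaired missing is-a relations;
#' for an ontology pair, the axioms of both ontologies plus their alignment
#' plus the pair's missing-mapping provisionals; for the network, everything.
#'
#' @param session a [repair_session()].
#' @param scope scope descriptor (see [parse_scope]).
#' @param include_provisionals include provisional axioms of unrepaired
#'   validated missing relations (default `TRUE`); status checks against the
#'   "repaired" network set this to `FALSE`.
#' @return a `knowledge_base`.
#' @export
build_kb <- function(session, scope, include_provisionals = TRUE) {
  scope <- check_scope_exists(session, scope)
  if (!include_provisionals && !scope_has_provisionals(session, scope)) {
    include_provisionals <- TRUE  # variants coincide; share the cache entry
  }
  fp <- session_axiom_fingerprint(session)
  key <- paste0(format_scope(scope), "\r", include_provisionals)
  cached <- kb_memo_get(fp, key)
  if (!is.null(cached)) return(cached)
  kb <- build_kb_uncached(session, scope, include_provisionals)
  kb_memo_set(fp, key, kb)
  kb
}

# Memo for knowledge bases, keyed by a fingerprint of everything the scope
# axioms can depend on; entries of a previous state are discarded when the
# state moves on, keeping memory bounded. Purely an acceleration: cached
# bases are immutable and identical to freshly built ones.
.kb_memo <- new.env(parent = emptyenv())

session_axiom_fingerprint <- function(session) {
  h <- attr(session$network, "content_hash")
  if (is.null(h)) h <- network_content_hash(session$network)
  paste(c(h, "|", register_ids(session$MI), "|", register_ids(session$MM),
          "|", axiom_keys(session$RI_plus), "|", axiom_keys(session$RI_minus),
          "|", axiom_keys(session$RM_plus), "|", axiom_keys(session$RM_minus),
          "|", register_ids(session$WI), "|", register_ids(session$WM)),
        collapse = ";")
}

kb_memo_get <- function(fp, key) {
  if (!identical(.kb_memo$fp, fp)) return(NULL)
  .kb_memo$entries[[key]]
}

kb_memo_set <- function(fp, key, kb) {
  if (!identical(.kb_memo$fp, fp)) {
    .kb_memo$fp <- fp
    .kb_memo$entries <- list()
  }
  .kb_memo$entries[[key]] <- kb
  invisible(kb)
}

# Persistent (per-network) memo: entries keyed by a fingerprint of exactly
# the inputs they were built from, so scopes untouched by a repair keep
# their knowledge bases (and closures) across session states. Wiped when a
# different network comes into play (see network_static_tables).
persist_get <- function(key) .kb_memo$persist[[key]]

persist_set <- function(key, value) {
  if (is.null(.kb_memo$persist)) .kb_memo$persist <- new.env(parent = emptyenv())
  .kb_memo$persist[[key]] <- value
  invisible(value)
}

# Fingerprint of everything the intra-axiom table of ontology k depends on.
ontology_fingerprint <- function(session, k, include_provisionals) {
  rip <- session$RI_plus[session$RI_plus$sub_ont == k, , drop = FALSE]
  rim <- session$RI_minus[session$RI_minus$sub_ont == k, , drop = FALSE]
  mi <- if (include_provisionals) {
    register_ids(session$MI[session$MI$scope == k, , drop = FALSE])
  } else character()
  paste(c("ont", k, include_provisionals, "+", axiom_keys(rip),
          "-", axiom_keys(rim), "p", mi), collapse = ";")
}

# Fingerprint of the mapping-axiom table of pair (i, j).
pair_map_fingerprint <- function(session, i, j, include_provisionals) {
  key <- pair_key(i, j)
  rmp <- session$RM_plus[pair_key_vec(session$RM_plus) == key, , drop = FALSE]
  mm <- if (include_provisionals) {
    register_ids(session$MM[session$MM$scope == key, , drop = FALSE])
  } else character()
  paste(c("map", key, include_provisionals, "+", axiom_keys(rmp),
          "-", axiom_keys(session$RM_minus), "p", mm), collapse = ";")
}

build_kb_uncached <- function(session, scope, include_provisionals = TRUE) {
  network_static_tables(session$network)  # wipes stale per-network memos
  ont_fps <- character()
  intra_memo <- function(k) {
    fp <- ontology_fingerprint(session, k, include_provisionals)
    ont_fps[[k]] <<- fp
    hit <- persist_get(fp)
    if (is.null(hit)) {
      hit <- persist_set(fp, current_intra_axioms(session, k,
                                                  include_provisionals))
    }
    hit
  }
  maps_memo <- function(i, j) {
    fp <- pair_map_fingerprint(session, i, j, include_provisionals)
    hit <- persist_get(fp)
    if (is.null(hit)) {
      hit <- persist_set(fp, current_mapping_axioms(session, i, j,
                                                    include_provisionals))
    }
    hit
  }
  onts <- switch(scope$type,
                 network = names(session$network$ontologies),
                 ontology = scope$ids,
                 pair = scope$ids)
  intra <- lapply(onts, intra_memo)
  pairs <- if (scope$type == "ontology" || length(onts) < 2L) list() else {
    combos <- utils::combn(sort(onts), 2L, simplify = FALSE)
    lapply(combos, function(p) maps_memo(p[1], p[2]))
  }
  # an ontology or pair knowledge base is fully determined by its parts;
  # reuse it (with its closure) across session states that left them alone
  if (scope$type %in% c("ontology", "pair")) {
    map_fp <- if (scope$type == "pair") {
      pair_map_fingerprint(session, scope$ids[1], scope$ids[2],
                           include_provisionals)
    } else ""
    kb_key <- paste(c("kb", scope$type, ont_fps[onts], map_fp),
                    collapse = "\n")
    hit <- persist_get(kb_key)
    if (!is.null(hit)) return(hit)
  }
  ax <- do.call(bind_axioms, c(intra, pairs))
  concepts <- unlist(lapply(onts, function(k) {
    ckey(k, session$network$ontologies[[k]]$concepts)
  }), use.names = FALSE)
  kb <- new_kb(ax, concepts, scope, concepts_complete = TRUE)
  if (scope$type %in% c("ontology", "pair")) persist_set(kb_key, kb)
  kb
}

# Validated-correct restriction: the scope axioms minus any axiom whose pair
# is currently registered as a wrong is-a relation or wrong mapping. Used by
# the conflict filters of the missing-relation repair.
scope_has_provisionals <- function(session, scope) {
  if (nrow(session$MI) + nrow(session$MM) == 0L) return(FALSE)
  switch(scope$type,
         network = TRUE,
         ontology = any(session$MI$scope == scope$ids),
         pair = any(session$MI$scope %in% scope$ids) ||
           any(session$MM$scope == paste(scope$ids, collapse = "|")))
}

validated_correct_kb <- function(session, scope) {
  if (nrow(session$WI) + nrow(session$WM) == 0L) {
    return(build_kb(session, scope))
  }
  fp <- session_axiom_fingerprint(session)
  key <- paste0("vc\r", format_scope(scope))
  cached <- kb_memo_get(fp, key)
  if (!is.null(cached)) return(cached)
  kb <- build_kb(session, scope)
  wrong <- c(pair_id(session$WI$sub, session$WI$sup),
             pair_id(session$WM$sub, session$WM$sup))
  keep <- !(axiom_keys(kb$axioms) %in% wrong)
  out <- new_kb(kb$axioms[keep, , drop = FALSE], kb$concepts, kb$scope)
  kb_memo_set(fp, key, out)
  out
}

pair_id <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) return(character())
  paste0(a, "->", b)
}

kb_graph <- function(kb) {
  if (is.null(kb$cache$graph)) {
    g <- igraph::make_empty_graph(n = length(kb$concepts), directed = TRUE)
    g <- igraph::set_vertex_attr(g, "name", value = kb$concepts)
    if (nrow(kb$axioms) > 0L) {
      edges <- rbind(ckey(kb$axioms$sub_ont, kb$axioms$sub),
                     ckey(kb$axioms$sup_ont, kb$axioms$sup))
      g <- igraph::add_edges(g, as.vector(edges))
    }
    kb$cache$graph <- g
  }
  kb$cache$graph
}

kb_reach <- function(kb) {
  if (is.null(kb$cache$reach)) {
    g <- kb_graph(kb)
    d <- igraph::distances(g, mode = "out")
    r <- is.finite(d)
    dimnames(r) <- list(kb$concepts, kb$concepts)
    kb$cache$reach <- r
  }
  kb$cache$reach
}

check_concept <- function(kb, x) {
  cs <- kb$cache$concept_set
  if (is.null(cs)) {
    cs <- new.env(parent = emptyenv(), size = length(kb$concepts))
    for (c_ in kb$concepts) assign(c_, TRUE, envir = cs)
    kb$cache$concept_set <- cs
  }
  if (!exists(x, envir = cs, inherits = FALSE)) {
    stop("concept '", x, "' is not visible in scope ", format_scope(kb$scope))
  }
  x
}

# Vectorized derivability of pairs (no per-call concept validation; callers
# guarantee registered pairs refer to network concepts).
pairs_derivable <- function(kb, sub, sup) {
  if (length(sub) == 0L) return(logical())
  r <- kb_reach(kb)
  out <- r[cbind(sub, sup)]
  out[sub == sup] <- TRUE
  out
}

#' Is `a` is-a `b` derivable in a knowledge base?
#'
#' Reflexive-transitive closure semantics: `TRUE` iff `a == b` or a directed
#' path of axioms leads from `a` to `b`.
#'
#' @param kb a `knowledge_base`.
#' @param a,b concept keys `"ontology:concept"`.
#' @return logical scalar.
#' @export
derivable <- function(kb, a, b) {
  check_concept(kb, a); check_concept(kb, b)
  if (a == b) return(TRUE)
  kb_reach(kb)[a, b]
}

#' Reflexive super- or sub-concept cone of a concept
#'
#' @param kb a `knowledge_base`.
#' @param concept concept key.
#' @param direction `"super"` returns all `d` with `derivable(kb, concept, d)`,
#'   `"sub"` all `d` with `derivable(kb, d, concept)`; both include `concept`.
#' @return sorted character vector of concept keys.
#' @export
cone <- function(kb, concept, direction = "super") {
  if (!direction %in% c("super", "sub")) stop("direction must be 'super' or 'sub'")
  check_concept(kb, concept)
  r <- kb_reach(kb)
  hits <- if (direction == "super") r[concept, ] else r[, concept]
  sort(unique(c(concept, names(hits)[hits])))
}

# Depth-first enumeration of simple directed paths a -> b, capped. `reach`
# prunes branches from which b is unreachable at all (sound: such branches
# contain no path to b).
enumerate_simple_paths <- function(adj, a, b, max_paths, max_len, reach) {
  state <- new.env(parent = emptyenv())
  state$paths <- vector("list", 0L)
  state$truncated <- FALSE
  visit <- function(node, edges, seen) {
    if (state$truncated) return(invisible())
    if (node == b) {
      if (length(state$paths) >= max_paths) { state$truncated <- TRUE; return(invisible()) }
      state$paths[[length(state$paths) + 1L]] <- edges
      return(invisible())
    }
    if (length(edges) >= max_len) { state$truncated <- TRUE; return(invisible()) }
    nxt <- adj[[node]]
    if (is.null(nxt)) return(invisible())
    for (i in seq_along(nxt$to)) {
      to <- nxt$to[i]
      if (!(to %in% seen) && (to == b || reach[to, b])) {
        visit(to, c(edges, nxt$key[i]), c(seen, to))
      }
    }
    invisible()
  }
  visit(a, character(), a)
  state
}

#' All minimal justifications of a derivable subsumption
#'
#' A justification is a subset-minimal axiom set entailing `a` is-a `b`; here
#' the edge sets of simple directed paths from `a` to `b`, filtered to the
#' subset-minimal ones. Enumeration is capped (`max_paths` simple paths,
#' `max_len` axioms per path); hitting a cap sets the `truncated` attribute
#' so callers can surface incompleteness.
#'
#' @param kb a `knowledge_base`.
#' @param a,b concept keys with `derivable(kb, a, b)` and `a != b`.
#' @param max_paths,max_len enumeration caps (both must be positive).
#' @return list of axiom tables, ordered by size then lexicographically by
#'   axiom keys, with attribute `truncated`.
#' @export
all_justifications <- function(kb, a, b, max_paths = 1000L, max_len = 20L) {
  check_concept(kb, a); check_concept(kb, b)
  if (max_paths <= 0L || max_len <= 0L) stop("justification caps must be positive")
  if (a == b) stop("justifications are defined for distinct concepts only")
  if (!derivable(kb, a, b)) {
    stop("(", a, ", ", b, ") is not derivable in scope ", format_scope(kb$scope))
  }
  memo_key <- paste(a, b, max_paths, max_len, sep = "\r")
  if (!is.null(kb$cache$justs[[memo_key]])) return(kb$cache$justs[[memo_key]])
  ax <- kb$axioms
  if (is.null(kb$cache$adj)) {
    keys <- axiom_keys(ax)
    from <- ckey(ax$sub_ont, ax$sub); to <- ckey(ax$sup_ont, ax$sup)
    adj <- split(data.frame(to = to, key = keys, stringsAsFactors = FALSE), from)
    kb$cache$adj <- lapply(adj, function(d) list(to = d$to, key = d$key))
  }
  st <- enumerate_simple_paths(kb$cache$adj, a, b, max_paths, max_len,
                               kb_reach(kb))
  all_keys <- axiom_keys(ax)
  isets <- unique(lapply(st$paths, function(p) sort.int(match(p, all_keys))))
  # retain subset-minimal edge sets: processing in ascending size order,
  # a set is pruned iff some already-retained (hence smaller) set is a
  # proper subset of it
  isets <- isets[order(lengths(isets),
                       vapply(isets, paste, character(1), collapse = "\r"))]
  minimal <- list()
  present <- logical(length(all_keys))
  for (s in isets) {
    present[s] <- TRUE
    dominated <- FALSE
    for (m in minimal) {
      if (length(m) < length(s) && all(present[m])) { dominated <- TRUE; break }
    }
    present[s] <- FALSE
    if (!dominated) minimal[[length(minimal) + 1L]] <- s
  }
  sets <- lapply(minimal, function(s) all_keys[s])
  sets <- sets[order(lengths(sets), vapply(sets, paste, character(1),
                                           collapse = "\r"))]
  out <- lapply(sets, function(s) axioms_in(ax, s))
  attr(out, "truncated") <- st$truncated
  attr(out, "target") <- c(a, b)
  if (is.null(kb$cache$justs)) kb$cache$justs <- list()
  kb$cache$justs[[memo_key]] <- out
  out
}

#' Apply axiom additions and removals to a knowledge base
#'
#' Returns a new knowledge base over the updated axiom set; the original is
#' unchanged. Removals must be present, and addition endpoints must be
#' concepts visible in the scope.
#'
#' @param kb a `knowledge_base`.
#' @param additions,removals axiom tables.
#' @return a new `knowledge_base`.
#' @export
apply_changes <- function(kb, additions = empty_axioms(), removals = empty_axioms()) {
  rk <- axiom_keys(removals)
  missing_rm <- setdiff(rk, axiom_keys(kb$axioms))
  if (length(missing_rm) > 0L) {
    stop("cannot remove axiom(s) not in the knowledge base: ",
         paste(missing_rm, collapse = ", "))
  }
  if (nrow(additions) > 0L) {
    ends <- unique(c(ckey(additions$sub_ont, additions$sub),
                     ckey(additions$sup_ont, additions$sup)))
    bad <- setdiff(ends, kb$concepts)
    if (length(bad) > 0L) {
      stop("addition endpoint(s) outside scope ", format_scope(kb$scope), ": ",
           paste(bad, collapse = ", "))
    }
  }
  new_kb(bind_axioms(axioms_not_in(kb$axioms, rk), additions),
         kb$concepts, kb$scope)
}
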