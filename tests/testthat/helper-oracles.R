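# Brute-force oracles (independent of the package's reasoning code) and
# small network builders used across the tests.

# Reflexive-transitive closure by naive boolean matrix iteration.
bf_closure <- function(edges, concepts) {
  n <- length(concepts)
  m <- matrix(FALSE, n, n, dimnames = list(concepts, concepts))
  if (nrow(edges) > 0L) m[cbind(edges$from, edges$to)] <- TRUE
  diag(m) <- TRUE
  repeat {
    nxt <- m | ((m %*% m) > 0)
    if (all(nxt == m)) return(m)
    m <- nxt
  }
}

kb_edges <- function(kb) {
  data.frame(from = paste0(kb$axioms$sub_ont, ":", kb$axioms$sub),
             to = paste0(kb$axioms$sup_ont, ":", kb$axioms$sup),
             key = axiom_keys(kb$axioms), stringsAsFactors = FALSE)
}

# All subset-minimal axiom sets entailing a -> b, by exhaustive subset
# enumeration (use only for <= 12 axioms).
bf_justifications <- function(kb, a, b) {
  e <- kb_edges(kb)
  n <- nrow(e)
  stopifnot(n <= 12L)
  entails <- function(idx) {
    cl <- bf_closure(e[idx, , drop = FALSE], kb$concepts)
    cl[a, b]
  }
  hits <- Filter(function(idx) entails(idx),
                 unlist(lapply(seq_len(n), function(k) {
                   utils::combn(n, k, simplify = FALSE)
                 }), recursive = FALSE))
  key_sets <- lapply(hits, function(idx) sort(e$key[idx]))
  minimal <- Filter(function(s) {
    !any(vapply(key_sets, function(t) length(t) < length(s) && all(t %in% s),
                logical(1)))
  }, key_sets)
  unique(minimal)
}

# All subset-minimal hitting sets by exhaustive enumeration over the union
# (use only for <= 12 distinct elements).
bf_hitting_sets <- function(sets) {
  u <- sort(unique(unlist(sets)))
  stopifnot(length(u) <= 12L)
  hits <- Filter(function(s) all(vapply(sets, function(x) any(x %in% s),
                                        logical(1))),
                 unlist(lapply(seq_along(u), function(k) {
                   lapply(utils::combn(length(u), k, simplify = FALSE),
                          function(idx) u[idx])
                 }), recursive = FALSE))
  Filter(function(s) {
    !any(vapply(hits, function(t) length(t) < length(s) && all(t %in% s),
                logical(1)))
  }, hits)
}

# Single-ontology network from an edge list.
mk_net <- function(edges, concepts = NULL, id = "o1", partof = NULL) {
  if (is.null(concepts)) concepts <- unique(c(edges$sub, edges$sup))
  ontology_network(list(taxonomy(id, concepts, isa = edges, partof = partof)))
}

# Random directed graph (cycles allowed) wrapped in one ontology; returns
# the session-backed knowledge base for its scope.
random_kb <- function(n, p, seed, id = "o1") {
  set.seed(seed)
  concepts <- sprintf("c%03d", seq_len(n))
  pairs <- expand.grid(sub = concepts, sup = concepts,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$sub != pairs$sup, , drop = FALSE]
  pairs <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  net <- mk_net(pairs, concepts, id = id)
  build_kb(repair_session(net), id)
}

# Two-ontology network with an equivalence alignment over shared ids.
mk_pair_net <- function(edges1, edges2, shared, id1 = "o1", id2 = "o2") {
  c1 <- unique(c(edges1$sub, edges1$sup, shared))
  c2 <- unique(c(edges2$sub, edges2$sup, shared))
  al <- alignment(id1, id2, data.frame(concept_1 = shared, concept_2 = shared,
                                       rel = "="))
  ontology_network(list(taxonomy(id1, c1, isa = edges1),
                        taxonomy(id2, c2, isa = edges2)), list(al))
}

edges <- function(sub, sup) data.frame(sub = sub, sup = sup,
                                       stringsAsFactors = FALSE)

# Verdicts for a candidate register, all with one decision.
verdicts_for <- function(cands, decision, kind = "CMI") {
  lapply(seq_len(nrow(cands)), function(i) {
    list(kind = kind, scope = cands$scope[i], sub = cands$sub[i],
         sup = cands$sup[i], decision = decision)
  })
}

# Residual scan: pairs derivable in the network KB but not in their scope
# KB, over *all* concepts (not just mapped ones).
residual_pairs <- function(session) {
  net <- build_kb(session, "network")
  rn <- taxodebug:::kb_reach(net)
  bad <- 0L
  for (scope in taxodebug:::all_scopes(session$network)) {
    sc <- taxodebug:::parse_scope(scope)
    kb <- build_kb(session, sc)
    rl <- taxodebug:::kb_reach(kb)
    cs <- kb$concepts
    if (sc$type == "ontology") {
      bad <- bad + sum(rn[cs, cs] & !rl[cs, cs])
    } else {
      o1 <- cs[startsWith(cs, paste0(sc$ids[1], ":"))]
      o2 <- cs[startsWith(cs, paste0(sc$ids[2], ":"))]
      bad <- bad + sum(rn[o1, o2] & !rl[o1, o2]) +
        sum(rn[o2, o1] & !rl[o2, o1])
    }
  }
  bad
}

# Planted-defect recovery check for a finished scripted session.
planted_recovered <- function(session, truth) {
  pm <- truth$planted_missing
  ok_missing <- all(vapply(seq_len(nrow(pm)), function(i) {
    kb <- build_kb(session, pm$scope[i], include_provisionals = FALSE)
    derivable(kb, pm$sub[i], pm$sup[i])
  }, logical(1)))
  net_kb <- build_kb(session, "network")
  pw <- rbind(truth$planted_wrong[, c("sub", "sup")],
              truth$planted_wrong_map[, c("sub", "sup")])
  ok_wrong <- all(!taxodebug:::pairs_derivable(net_kb, pw$sub, pw$sup))
  list(missing = ok_missing, wrong = ok_wrong)
}
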