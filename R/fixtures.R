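# Worked anatomy fragments, a seeded synthetic-network generator with
# planted defects and ground truth, and the ground-truth decision policy
# driving scripted sessions.

#' Worked anatomy fragments
#'
#' Small ontology networks reconstructing the published worked fragments of
#' mouse/NCI anatomy debugging, together with machine-checkable expected
#' facts:
#'
#' * `"colon"`: two two-concept ontologies linked by two equivalence
#'   mappings; the ascending-colon/colon subsumption (actually a part-of
#'   relation, recorded as such in the second ontology) induces one wrong
#'   candidate is-a relation whose justification holds two equivalence
#'   mapping components and one asserted is-a axiom.
#' * `"white_matter"`: the grey/white-matter fragment. Three wrong candidate
#'   is-a relations arise in the first ontology, each with a unique
#'   three-axiom justification; the two justifications of the white-matter
#'   sub-concepts share the reverse component of the grey-matter/white-matter
#'   equivalence, so removing that equivalence pair repairs all three at
#'   once. The unprinted connecting edges are reconstructed minimally so
#'   that exactly these three candidates appear.
#' * `"laryngeal"`: one ontology with four cartilage concepts under
#'   laryngeal cartilage and four validated missing is-a relations to
#'   laryngeal connective tissue; the informative action (laryngeal
#'   cartilage, laryngeal connective tissue) repairs the three others as a
#'   side effect.
#' * `"bone"`: the viscerocranium-bone fragment with three validated missing
#'   is-a relations to bone; (viscerocranium bone, bone) is the informative
#'   repair for (nasal bone, bone) and also repairs the maxilla and lacrimal
#'   defects.
#'
#' @param name fragment name.
#' @return list with elements `network` (an [ontology_network()]),
#'   `missing_isa` (pre-validated missing is-a register, possibly empty) and
#'   `expected` (named list of expected facts used by the tests).
#' @export
paper_fixture <- function(name = c("colon", "white_matter", "laryngeal", "bone")) {
  name <- match.arg(name)
  switch(name,
    colon = {
      ama <- taxonomy("ama", c("ascending colon", "colon"),
                      isa = data.frame(sub = "ascending colon", sup = "colon"))
      ncia <- taxonomy("ncia", c("Ascending_Colon", "Colon"),
                       partof = data.frame(part = "Ascending_Colon",
                                           whole = "Colon"))
      al <- alignment("ama", "ncia", data.frame(
        concept_1 = c("ascending colon", "colon"),
        concept_2 = c("Ascending_Colon", "Colon"),
        rel = c("=", "=")))
      list(network = ontology_network(list(ama, ncia), list(al)),
           missing_isa = pair_register(),
           expected = list(
             n_induced = 5L,
             cmi_scope = "ncia",
             cmi = c("ncia:Ascending_Colon", "ncia:Colon"),
             wrong_removal = "ama:ascending colon->ama:colon"))
    },
    white_matter = {
      ama <- taxonomy("ama",
        c("brain grey matter", "white matter",
          "cerebellum white matter", "cerebral white matter"),
        isa = data.frame(sub = c("cerebellum white matter",
                                 "cerebral white matter"),
                         sup = c("white matter", "white matter")))
      ncia <- taxonomy("ncia",
        c("Brain_White_Matter", "White_Matter",
          "Cerebellum_White_Matter", "Cerebral_White_Matter"),
        isa = data.frame(sub = c("Brain_White_Matter",
                                 "Cerebellum_White_Matter",
                                 "Cerebral_White_Matter"),
                         sup = c("White_Matter", "Brain_White_Matter",
                                 "Brain_White_Matter")))
      al <- alignment("ama", "ncia", data.frame(
        concept_1 = c("brain grey matter", "white matter",
                      "cerebellum white matter", "cerebral white matter"),
        concept_2 = c("Brain_White_Matter", "White_Matter",
                      "Cerebellum_White_Matter", "Cerebral_White_Matter"),
        rel = "="))
      list(network = ontology_network(list(ama, ncia), list(al)),
           missing_isa = pair_register(),
           expected = list(
             cmi_scope = "ama",
             cmis = pair_register(
               scope = "ama",
               sub = c("ama:brain grey matter", "ama:cerebellum white matter",
                       "ama:cerebral white matter"),
               sup = c("ama:white matter", "ama:brain grey matter",
                       "ama:brain grey matter")),
             quoted_defect = c("ama:brain grey matter", "ama:white matter"),
             top_priority = "ncia:Brain_White_Matter->ama:brain grey matter",
             equivalence_pair = c(
               "ama:brain grey matter->ncia:Brain_White_Matter",
               "ncia:Brain_White_Matter->ama:brain grey matter")))
    },
    laryngeal = {
      carts <- c("Epiglottic_Cartilage", "Cricoid_Cartilage",
                 "Arytenoid_Cartilage", "Thyroid_Cartilage")
      ncia <- taxonomy("ncia",
        c(carts, "Laryngeal_Cartilage", "Laryngeal_Connective_Tissue"),
        isa = data.frame(sub = carts, sup = "Laryngeal_Cartilage"))
      list(network = ontology_network(list(ncia)),
           missing_isa = pair_register(
             scope = "ncia", sub = ckey("ncia", carts),
             sup = "ncia:Laryngeal_Connective_Tissue"),
           expected = list(
             defect = c("ncia:Epiglottic_Cartilage",
                        "ncia:Laryngeal_Connective_Tissue"),
             informative_action = c("ncia:Laryngeal_Cartilage",
                                    "ncia:Laryngeal_Connective_Tissue"),
             n_side_repaired = 3L))
    },
    bone = {
      ama <- taxonomy("ama",
        c("bone", "viscerocranium bone", "nasal bone", "maxilla",
          "lacrimal bone"),
        isa = data.frame(sub = c("nasal bone", "maxilla", "lacrimal bone"),
                         sup = "viscerocranium bone"))
      list(network = ontology_network(list(ama)),
           missing_isa = pair_register(
             scope = "ama",
             sub = ckey("ama", c("nasal bone", "maxilla", "lacrimal bone")),
             sup = "ama:bone"),
           expected = list(
             defect = c("ama:nasal bone", "ama:bone"),
             source = c("ama:nasal bone", "ama:viscerocranium bone"),
             target = c("ama:bone", "ama:lacrimal bone", "ama:maxilla"),
             informative_action = c("ama:viscerocranium bone", "ama:bone"),
             side_repaired = pair_register(
               scope = "ama", sub = ckey("ama", c("maxilla", "lacrimal bone")),
               sup = "ama:bone")))
    })
}

#' Specification of a synthetic ontology network
#'
#' The generator emulates the study setting: several overlapping taxonomies
#' of one domain linked by equivalence alignments over their shared
#' concepts, corrupted by hiding true is-a axioms (planted missing
#' relations), adding false ones (planted wrong relations), and rewiring
#' mappings to non-corresponding concepts (planted wrong mappings).
#' Corruption is restricted to concepts shared with other ontologies so
#' that every planted defect remains recoverable and detectable from
#' knowledge intrinsic to the network.
#'
#' @param n_ontologies number of taxonomies (>= 2).
#' @param concepts_per_ontology concepts per taxonomy.
#' @param true_edge_density probability of a direct true subsumption between
#'   two concepts (in topological order) of the global domain.
#' @param overlap_fraction fraction of each taxonomy's concepts drawn from
#'   the pool shared by all taxonomies.
#' @param p_omit probability that an assertable true axiom between shared
#'   concepts is hidden (planted missing is-a relation).
#' @param p_spurious expected spurious axioms per asserted axiom (planted
#'   wrong is-a relations).
#' @param p_wrong_mapping probability that a shared concept's mapping in one
#'   alignment is rewired to a non-corresponding concept (planted wrong
#'   mapping); applied only when a third ontology carries the concept.
#' @param seed integer seed; generation is deterministic per seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_ontologies = 3L, concepts_per_ontology = 60L,
                           true_edge_density = 0.04, overlap_fraction = 0.4,
                           p_omit = 0.1, p_spurious = 0.03,
                           p_wrong_mapping = 0.02, seed = 1L) {
  stopifnot(n_ontologies >= 2L, concepts_per_ontology >= 2L,
            true_edge_density >= 0, true_edge_density <= 1,
            overlap_fraction >= 0, overlap_fraction <= 1,
            p_omit >= 0, p_omit <= 1, p_spurious >= 0, p_spurious <= 1,
            p_wrong_mapping >= 0, p_wrong_mapping <= 1)
  n_shared <- round(overlap_fraction * concepts_per_ontology)
  if (n_shared > concepts_per_ontology) stop("overlap larger than ontology size")
  structure(list(n_ontologies = as.integer(n_ontologies),
                 concepts_per_ontology = as.integer(concepts_per_ontology),
                 true_edge_density = true_edge_density,
                 overlap_fraction = overlap_fraction,
                 p_omit = p_omit, p_spurious = p_spurious,
                 p_wrong_mapping = p_wrong_mapping,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

bool_closure <- function(adj) {
  # reflexive-transitive closure of a logical adjacency matrix
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- reach | ((reach %*% reach) > 0)
    if (all(nxt == reach)) break
    reach <- nxt
  }
  reach
}

transitive_reduction <- function(reach) {
  # unique minimal edge set of a finite partial order (reach must be a
  # reflexive closure of a DAG restricted to its row/col names)
  n <- nrow(reach)
  strict <- reach & !diag(TRUE, n)
  via <- (strict %*% strict) > 0
  strict & !via
}

#' Generate a synthetic ontology network with ground truth
#'
#' Builds a random true subsumption DAG over a global concept universe,
#' assigns each ontology the shared pool plus a private block, asserts the
#' transitive reduction of the true order restricted to each ontology's
#' concepts, links shared concepts by equivalence mappings, and then plants
#' defects per the spec probabilities. Deterministic for a fixed spec.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `network` (an [ontology_network()]) and `truth` (class
#'   `ground_truth`: global concept map, true reachability, planted defect
#'   registers and the set of corrupted axiom keys).
#' @export
synthesize_network <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_ontologies
    m <- spec$concepts_per_ontology
    n_shared <- round(spec$overlap_fraction * m)
    n_priv <- m - n_shared
    n_global <- n_shared + n * n_priv
    gids <- sprintf("c%03d", seq_len(n_global))
    # the shared pool is spread through the topological order so that true
    # paths between shared concepts can run through private concepts of a
    # single ontology -- the situation intrinsic detection exists for
    shared <- sort(sample(gids, n_shared))
    rest <- setdiff(gids, shared)
    priv <- split(rest, rep(seq_len(n), each = n_priv))
    ont_ids <- sprintf("ont%d", seq_len(n))

    # true DAG in index order (i -> j only for i < j)
    adj <- matrix(FALSE, n_global, n_global, dimnames = list(gids, gids))
    for (i in seq_len(n_global - 1L)) {
      adj[i, (i + 1L):n_global] <-
        stats::runif(n_global - i) < spec$true_edge_density
    }
    true_reach <- bool_closure(adj)

    concepts_of <- lapply(seq_len(n), function(k) {
      sort(c(shared, if (n_priv > 0L) priv[[k]] else character()))
    })
    # each ontology asserts the transitive reduction of the closure of the
    # true *direct* edges among its own concepts: knowledge carried by
    # concepts it does not contain stays derivable only via the network,
    # exactly the setting in which intrinsic detection has work to do
    reductions <- lapply(seq_len(n), function(k) {
      cs <- concepts_of[[k]]
      transitive_reduction(bool_closure(adj[cs, cs, drop = FALSE]))
    })
    edge_df <- function(red) {
      idx <- which(red, arr.ind = TRUE)
      data.frame(sub = rownames(red)[idx[, 1]], sup = colnames(red)[idx[, 2]],
                 stringsAsFactors = FALSE)
    }
    intra <- lapply(reductions, edge_df)
    for (k in seq_len(n)) {
      intra[[k]] <- intra[[k]][order(intra[[k]]$sub, intra[[k]]$sup), ,
                               drop = FALSE]
    }

    # planted missing: hide shared-endpoint reduction edges, at most one
    # ontology per pair, keeping local derivability in some other ontology
    planted_missing <- pair_register()
    omitted <- lapply(seq_len(n), function(k) rep(FALSE, nrow(intra[[k]])))
    taken_pairs <- character()
    for (k in seq_len(n)) {
      e <- intra[[k]]
      cand <- which(e$sub %in% shared & e$sup %in% shared)
      for (i in cand) {
        pid <- paste0(e$sub[i], "->", e$sup[i])
        if (pid %in% taken_pairs) next
        if (stats::runif(1) < spec$p_omit) {
          omitted[[k]][i] <- TRUE
          taken_pairs <- c(taken_pairs, pid)
        }
      }
    }
    # cancel omissions whose pair would lose local derivability everywhere
    repeat {
      changed <- FALSE
      reach_after <- lapply(seq_len(n), function(k) {
        e <- intra[[k]][!omitted[[k]], , drop = FALSE]
        cs <- concepts_of[[k]]
        a2 <- matrix(FALSE, length(cs), length(cs), dimnames = list(cs, cs))
        a2[cbind(e$sub, e$sup)] <- TRUE
        bool_closure(a2)
      })
      for (k in seq_len(n)) {
        for (i in which(omitted[[k]])) {
          a <- intra[[k]]$sub[i]; b <- intra[[k]]$sup[i]
          supported <- any(vapply(setdiff(seq_len(n), k), function(j) {
            reach_after[[j]][a, b]
          }, logical(1)))
          if (!supported) { omitted[[k]][i] <- FALSE; changed <- TRUE }
        }
      }
      if (!changed) break
    }
    for (k in seq_len(n)) {
      e <- intra[[k]][omitted[[k]], , drop = FALSE]
      if (nrow(e) > 0L) {
        planted_missing <- rbind(planted_missing, pair_register(
          scope = ont_ids[k], sub = ckey(ont_ids[k], e$sub),
          sup = ckey(ont_ids[k], e$sup)))
      }
      intra[[k]] <- intra[[k]][!omitted[[k]], , drop = FALSE]
    }
    touched <- unique(c(key_id(planted_missing$sub), key_id(planted_missing$sup)))

    # planted wrong is-a: spurious edges between shared concepts with no
    # true relation in either direction
    planted_wrong <- pair_register()
    corrupted <- character()
    for (k in seq_len(n)) {
      n_sp <- stats::rbinom(1L, max(nrow(intra[[k]]), 1L), spec$p_spurious)
      pool <- setdiff(shared, touched)
      tries <- 0L
      while (n_sp > 0L && tries < 200L && length(pool) >= 2L) {
        tries <- tries + 1L
        ab <- sample(pool, 2L)
        if (!true_reach[ab[1], ab[2]] && !true_reach[ab[2], ab[1]] &&
            !any(intra[[k]]$sub == ab[1] & intra[[k]]$sup == ab[2])) {
          intra[[k]] <- rbind(intra[[k]],
                              data.frame(sub = ab[1], sup = ab[2],
                                         stringsAsFactors = FALSE))
          planted_wrong <- rbind(planted_wrong, pair_register(
            scope = ont_ids[k], sub = ckey(ont_ids[k], ab[1]),
            sup = ckey(ont_ids[k], ab[2])))
          corrupted <- c(corrupted,
                         paste0(ckey(ont_ids[k], ab[1]), "->",
                                ckey(ont_ids[k], ab[2])))
          touched <- unique(c(touched, ab))
          pool <- setdiff(pool, ab)
          n_sp <- n_sp - 1L
        }
      }
    }

    # alignments: equivalence per shared concept; optionally rewired
    planted_wrong_map <- pair_register()
    used_for_maps <- character()
    alignments <- list()
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          rows <- data.frame(concept_1 = shared, concept_2 = shared,
                             rel = "=", stringsAsFactors = FALSE)
          if (n >= 3L && spec$p_wrong_mapping > 0) {
            for (r in seq_len(nrow(rows))) {
              c_ <- rows$concept_1[r]
              if (c_ %in% c(touched, used_for_maps)) next
              if (stats::runif(1) < spec$p_wrong_mapping) {
                pool <- setdiff(concepts_of[[j]], c(touched, used_for_maps, c_))
                pool <- pool[!true_reach[c_, pool] & !true_reach[pool, c_]]
                if (length(pool) == 0L) next
                d <- sample(pool, 1L)
                rows$concept_2[r] <- d
                used_for_maps <- c(used_for_maps, c_, d)
                planted_wrong_map <- rbind(planted_wrong_map, pair_register(
                  scope = rep(pair_key(ont_ids[i], ont_ids[j]), 2L),
                  sub = c(ckey(ont_ids[i], c_), ckey(ont_ids[j], d)),
                  sup = c(ckey(ont_ids[j], d), ckey(ont_ids[i], c_))))
                corrupted <- c(corrupted,
                               paste0(ckey(ont_ids[i], c_), "->", ckey(ont_ids[j], d)),
                               paste0(ckey(ont_ids[j], d), "->", ckey(ont_ids[i], c_)))
              }
            }
          }
          alignments[[length(alignments) + 1L]] <-
            alignment(ont_ids[i], ont_ids[j], rows)
        }
      }
    }

    onts <- lapply(seq_len(n), function(k) {
      taxonomy(ont_ids[k], concepts_of[[k]], isa = intra[[k]])
    })
    network <- ontology_network(onts, alignments)

    global_map <- stats::setNames(
      unlist(lapply(seq_len(n), function(k) concepts_of[[k]])),
      unlist(lapply(seq_len(n), function(k) ckey(ont_ids[k], concepts_of[[k]]))))

    truth <- structure(list(global = global_map, reach = true_reach,
                            planted_missing = planted_missing,
                            planted_wrong = planted_wrong,
                            planted_wrong_map = planted_wrong_map,
                            corrupted_axioms = sort(unique(corrupted))),
                       class = "ground_truth")
    list(network = network, truth = truth)
  })
}

truth_reachable <- function(truth, key_a, key_b) {
  ga <- truth$global[[key_a]]; gb <- truth$global[[key_b]]
  if (is.null(ga) || is.null(gb)) return(FALSE)
  truth$reach[ga, gb]
}

#' Ground-truth decision policy for scripted sessions
#'
#' Stands in for the domain expert on synthetic networks: candidates are
#' validated missing when their pair is reachable in the true order and
#' wrong otherwise; wrong defects are repaired by removing the corrupted
#' (planted) axioms occurring in their justifications (expanded to a
#' fixpoint so every removed axiom's own pair also becomes underivable);
#' missing defects are repaired with the informativeness-maximal
#' truth-consistent repairing action, falling back to the defect pair
#' itself.
#'
#' @param truth a `ground_truth`.
#' @return a policy list usable with [run_scripted_session()].
#' @export
truth_policy <- function(truth) {
  list(
    verdict = function(session, defect) {
      if (truth_reachable(truth, defect$sub, defect$sup)) "missing" else "wrong"
    },
    repair_wrong = function(session, defects) {
      # every derivation path of a pair that is not true-reachable contains
      # at least one corrupted axiom (correct axioms are truth-sound), so
      # cutting the corrupted axioms found on any path, to a fixpoint over
      # the defects and the already-chosen pairs, makes them all underivable
      kb <- build_kb(session, "network")
      chosen <- character()
      repeat {
        kb2 <- apply_changes(kb, removals = axioms_in(kb$axioms, chosen))
        g2 <- kb_graph(kb2)
        keys2 <- axiom_keys(kb2$axioms)
        targets <- rbind(defects[, c("sub", "sup")],
                         data.frame(sub = ckey(kb$axioms$sub_ont, kb$axioms$sub),
                                    sup = ckey(kb$axioms$sup_ont, kb$axioms$sup),
                                    stringsAsFactors = FALSE)[
                                      axiom_keys(kb$axioms) %in% chosen, ,
                                      drop = FALSE])
        new_found <- character()
        live <- which(pairs_derivable(kb2, targets$sub, targets$sup))
        for (i in live) {
          sp <- suppressWarnings(igraph::shortest_paths(
            g2, from = targets$sub[i], to = targets$sup[i],
            mode = "out", output = "epath"))
          path_keys <- keys2[as.integer(sp$epath[[1]])]
          new_found <- c(new_found,
                         setdiff(intersect(path_keys, truth$corrupted_axioms),
                                 chosen))
        }
        new_found <- unique(new_found)
        if (length(new_found) == 0L) {
          if (length(live) > 0L) {
            stop("ground-truth policy found no corrupted axiom on a live path")
          }
          break
        }
        chosen <- sort(unique(c(chosen, new_found)))
      }
      if (length(chosen) == 0L) {
        stop("ground-truth policy found no corrupted axiom to remove")
      }
      chosen
    },
    repair_missing = function(session, defect, space) {
      ok <- vapply(seq_len(nrow(space$repair)), function(i) {
        truth_reachable(truth, space$repair$sub[i], space$repair$sup[i])
      }, logical(1))
      cands <- space$repair[ok, , drop = FALSE]
      if (nrow(cands) == 0L) return(c(defect$sub, defect$sup))
      kb <- build_kb(session, space$scope)
      best <- maximal_elements(kb, cands)
      best <- best[order(pair_id(best$sub, best$sup)), , drop = FALSE]
      c(best$sub[1], best$sup[1])
    })
}
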