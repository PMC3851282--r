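test_that("mapped concepts are the endpoints of live mappings", {
  fx <- paper_fixture("colon")
  m <- mapped_concepts(fx$network)
  expect_equal(lengths(m), c(ama = 2L, ncia = 2L))

  lone <- ontology_network(list(taxonomy("o1", c("a", "b"))))
  expect_true(all(lengths(mapped_concepts(lone)) == 0L))

  # an alignment of 7 equivalences yields >= 7 mapped concepts per side
  shared <- paste0("t", 1:7)
  net <- mk_pair_net(edges(character(), character()),
                     edges(character(), character()), shared)
  expect_true(all(lengths(mapped_concepts(net)) >= 7L))
})

test_that("candidates are network-derivable, locally underivable mapped pairs", {
  fx <- paper_fixture("colon")
  s <- repair_session(fx$network)
  got <- detect_candidates(s, "ncia")
  expect_equal(nrow(got), 1L)
  expect_equal(c(got$sub, got$sup), fx$expected$cmi)
  expect_equal(nrow(detect_candidates(s, "ama")), 0L)
  # in a 2-ontology network the pair scope equals the network scope
  expect_equal(nrow(detect_candidates(s, c("ama", "ncia"))), 0L)
})

test_that("detection agrees with brute force over all mapped pairs", {
  for (seed in 1:8) {
    gen <- synthesize_network(synthetic_spec(
      n_ontologies = 3, concepts_per_ontology = 25, seed = 300 + seed))
    s <- repair_session(gen$network)
    mapped <- taxodebug:::session_mapped_concepts(s)
    net_kb <- build_kb(s, "network")
    for (scope in taxodebug:::all_scopes(gen$network)) {
      sc <- taxodebug:::parse_scope(scope)
      loc_kb <- build_kb(s, sc)
      got <- detect_candidates(s, sc)
      cs <- if (sc$type == "ontology") list(mapped[[sc$ids]], mapped[[sc$ids]])
            else list(mapped[[sc$ids[1]]], mapped[[sc$ids[2]]])
      brute <- character()
      for (a in union(cs[[1]], cs[[2]])) for (b in union(cs[[1]], cs[[2]])) {
        if (a == b || (sc$type == "pair" && sub(":.*", "", a) == sub(":.*", "", b))) next
        if (derivable(net_kb, a, b) && !derivable(loc_kb, a, b)) {
          brute <- c(brute, paste0(a, "->", b))
        }
      }
      expect_setequal(taxodebug:::pair_id(got$sub, got$sup), brute)
      # soundness re-check on the emitted candidates
      for (i in seq_len(nrow(got))) {
        expect_true(derivable(net_kb, got$sub[i], got$sup[i]))
        expect_false(derivable(loc_kb, got$sub[i], got$sup[i]))
      }
    }
  }
})

test_that("redundancy keeps the most informative candidates", {
  # (a,b) redundant when retained (c,b) repairs it via asserted a -> c
  net <- mk_pair_net(edges("a", "c"), edges("b2", "d2"),
                     shared = c("a", "b", "c"))
  s <- repair_session(net)
  kb <- build_kb(s, "o1")
  cands <- data.frame(scope = "o1", sub = c("o1:a", "o1:c"),
                      sup = c("o1:b", "o1:b"), status = "unvalidated",
                      stringsAsFactors = FALSE)
  parts <- filter_redundant(cands, kb)
  expect_equal(parts$non_redundant$sub, "o1:c")
  expect_equal(parts$redundant$sub, "o1:a")

  single <- cands[1, , drop = FALSE]
  expect_equal(nrow(filter_redundant(single, kb)$non_redundant), 1L)

  # the two directions of an equivalence are both retained
  cands2 <- data.frame(scope = "o1", sub = c("o1:a", "o1:b"),
                       sup = c("o1:b", "o1:a"), status = "unvalidated",
                       stringsAsFactors = FALSE)
  parts2 <- filter_redundant(cands2, kb)
  expect_equal(nrow(parts2$non_redundant), 2L)

  # adding every retained candidate makes every redundant one derivable
  kb2 <- apply_changes(kb, additions = axioms(
    sub_ont = "o1", sub = sub("^o1:", "", parts$non_redundant$sub),
    sup_ont = "o1", sup = sub("^o1:", "", parts$non_redundant$sup)))
  for (i in seq_len(nrow(parts$redundant))) {
    expect_true(derivable(kb2, parts$redundant$sub[i], parts$redundant$sup[i]))
  }
})

test_that("groups are comparability components, largest first", {
  fw <- paper_fixture("white_matter")
  s <- repair_session(fw$network)
  cm <- detect_candidates(s, "ama")
  g <- group_candidates(cm, build_kb(s, "network"))
  expect_length(g, 1L)
  expect_equal(nrow(g[[1]]), 3L)

  # disjoint components give singleton groups
  net <- mk_pair_net(edges("a", "b"), edges("c2", "d2"), shared = c("a", "x"))
  s2 <- repair_session(net)
  kb2 <- build_kb(s2, "network")
  cands <- data.frame(scope = "o1", sub = c("o1:a", "o1:x"),
                      sup = c("o1:b", "o1:y"), status = "unvalidated",
                      stringsAsFactors = FALSE)
  net3 <- mk_net(edges(c("a", "x"), c("b", "y")))
  s3 <- repair_session(net3)
  g2 <- group_candidates(cands, build_kb(s3, "o1"))
  expect_length(g2, 2L)
  expect_true(all(vapply(g2, nrow, integer(1)) == 1L))

  expect_length(group_candidates(cands[0, ], kb2), 0L)
})
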