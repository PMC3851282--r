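test_that("scope knowledge bases contain exactly the scope-visible axioms", {
  fx <- paper_fixture("colon")
  s <- repair_session(fx$network)
  expect_equal(nrow(build_kb(s, "ncia")$axioms), 0L)  # part-of never enters
  expect_equal(nrow(build_kb(s, "network")$axioms), 5L)

  lx <- paper_fixture("laryngeal")
  sl <- initialize_repair_state(lx$network, missing_isa = lx$missing_isa)
  kb <- build_kb(sl, "ncia")
  expect_equal(sum(kb$axioms$status == "asserted"), 4L)
  expect_equal(sum(kb$axioms$status == "provisional"), 4L)
  expect_error(build_kb(s, "nope"), "unknown ontology")
})

test_that("derivability is reflexive-transitive reachability", {
  fx <- paper_fixture("colon")
  s <- repair_session(fx$network)
  net <- build_kb(s, "network")
  expect_true(derivable(net, "ncia:Ascending_Colon", "ncia:Colon"))
  expect_true(derivable(net, "ncia:Colon", "ncia:Colon"))
  expect_false(derivable(build_kb(s, "ncia"),
                         "ncia:Ascending_Colon", "ncia:Colon"))
  expect_error(derivable(net, "ncia:Nope", "ncia:Colon"), "not visible")
})

test_that("derivable agrees with a brute-force closure oracle on random graphs", {
  for (seed in 1:20) {
    n <- sample(5:60, 1)
    kb <- random_kb(n, p = runif(1, 0.01, 0.1), seed = seed)
    cl <- bf_closure(kb_edges(kb), kb$concepts)
    expect_identical(unname(taxodebug:::kb_reach(kb)[kb$concepts, kb$concepts]),
                     unname(cl[kb$concepts, kb$concepts]),
                     info = paste("seed", seed))
  }
})

test_that("cones are reflexive and match derivable exactly", {
  bx <- paper_fixture("bone")
  sb <- initialize_repair_state(bx$network, missing_isa = bx$missing_isa)
  kb <- build_kb(sb, "ama")
  expect_setequal(cone(kb, "ama:nasal bone", "super"),
                  c("ama:nasal bone", "ama:viscerocranium bone", "ama:bone"))

  iso <- build_kb(repair_session(mk_net(edges(character(), character()),
                                        concepts = "solo")), "o1")
  expect_equal(cone(iso, "o1:solo", "super"), "o1:solo")

  lx <- paper_fixture("laryngeal")
  sl <- initialize_repair_state(lx$network, missing_isa = lx$missing_isa)
  klb <- build_kb(sl, "ncia")
  expect_setequal(cone(klb, "ncia:Laryngeal_Connective_Tissue", "sub"),
                  c("ncia:Laryngeal_Connective_Tissue",
                    ckey("ncia", c("Epiglottic_Cartilage", "Cricoid_Cartilage",
                                   "Arytenoid_Cartilage", "Thyroid_Cartilage"))))

  kb2 <- random_kb(30, 0.08, seed = 99)
  for (c_ in sample(kb2$concepts, 5)) {
    expect_setequal(cone(kb2, c_, "super"),
                    kb2$concepts[vapply(kb2$concepts, function(d)
                      derivable(kb2, c_, d), logical(1))])
  }
})

test_that("justifications are the minimal edge sets of simple paths", {
  fw <- paper_fixture("white_matter")
  kb <- build_kb(repair_session(fw$network), "network")
  js <- all_justifications(kb, "ama:brain grey matter", "ama:white matter")
  expect_length(js, 1L)
  expect_equal(nrow(js[[1]]), 3L)

  # direct asserted edge with no other path
  kbd <- build_kb(repair_session(mk_net(edges("a", "b"))), "o1")
  jd <- all_justifications(kbd, "o1:a", "o1:b")
  expect_length(jd, 1L)
  expect_equal(axiom_keys(jd[[1]]), "o1:a->o1:b")

  # diamond: two justifications
  kdd <- build_kb(repair_session(mk_net(edges(c("a", "x", "a", "y"),
                                              c("x", "b", "y", "b")))), "o1")
  expect_length(all_justifications(kdd, "o1:a", "o1:b"), 2L)

  expect_error(all_justifications(kbd, "o1:b", "o1:a"), "not derivable")
  expect_error(all_justifications(kbd, "o1:a", "o1:b", max_paths = 0),
               "caps")
})

test_that("justifications match exhaustive subset enumeration on small graphs", {
  for (seed in 1:15) {
    kb <- random_kb(6, 0.25, seed = 100 + seed)
    if (nrow(kb$axioms) > 12L || nrow(kb$axioms) == 0L) next
    reach <- taxodebug:::kb_reach(kb)
    pairs <- which(reach & !diag(TRUE, length(kb$concepts)), arr.ind = TRUE)
    if (nrow(pairs) == 0L) next
    i <- pairs[1, ]
    a <- kb$concepts[i[1]]; b <- kb$concepts[i[2]]
    got <- lapply(all_justifications(kb, a, b), axiom_keys)
    expect_setequal(vapply(got, paste, character(1), collapse = "|"),
                    vapply(bf_justifications(kb, a, b), paste, character(1),
                           collapse = "|"))
    # replay: each justification entails its target, no proper subset does
    for (j in got) {
      sub_kb <- taxodebug:::new_kb(
        taxodebug:::axioms_in(kb$axioms, j), kb$concepts, kb$scope)
      expect_true(derivable(sub_kb, a, b))
      for (drop in seq_along(j)) {
        smaller <- taxodebug:::new_kb(
          taxodebug:::axioms_in(kb$axioms, j[-drop]), kb$concepts, kb$scope)
        expect_false(derivable(smaller, a, b))
      }
    }
  }
})

test_that("applying changes updates derivability and is invertible", {
  kb <- build_kb(repair_session(mk_net(edges("a", "b"))), "o1")
  kb2 <- apply_changes(kb, removals = kb$axioms)
  expect_false(derivable(kb2, "o1:a", "o1:b"))

  add <- axioms(sub_ont = "o1", sub = "b", sup_ont = "o1", sup = "a")
  kb3 <- apply_changes(kb, additions = add)
  kb4 <- apply_changes(kb3, removals = add)
  expect_equal(kb4$axioms, kb$axioms)
  expect_error(apply_changes(kb, removals = add), "cannot remove")

  # removing the equivalence pair breaks all three wrong derivations
  fw <- paper_fixture("white_matter")
  kbw <- build_kb(repair_session(fw$network), "network")
  eq <- taxodebug:::axioms_in(kbw$axioms, fw$expected$equivalence_pair)
  kbw2 <- apply_changes(kbw, removals = eq)
  for (i in seq_len(nrow(fw$expected$cmis))) {
    expect_false(derivable(kbw2, fw$expected$cmis$sub[i],
                           fw$expected$cmis$sup[i]))
  }
})
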