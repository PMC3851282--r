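# Builds the white-matter session with all three candidates validated wrong.
wm_session <- function() {
  fw <- paper_fixture("white_matter")
  s <- repair_session(fw$network)
  s$CMI <- detect_candidates(s, "ama")
  record_verdicts(s, verdicts_for(s$CMI, "wrong"))
}

test_that("removal candidates are the eligible axioms of each justification", {
  s <- wm_session()
  d <- s$WI[s$WI$sub == "ama:brain grey matter", , drop = FALSE]
  rc <- removal_candidates(s, d)
  expect_length(rc$justifications, 1L)
  expect_length(rc$eligible[[1]], 3L)
  expect_false(rc$unrepairable)

  fx <- paper_fixture("colon")
  sc <- repair_session(fx$network)
  sc$CMI <- detect_candidates(sc, "ncia")
  sc <- record_verdicts(sc, verdicts_for(sc$CMI, "wrong"))
  rcc <- removal_candidates(sc, sc$WI)
  expect_length(rcc$justifications, 1L)
  expect_setequal(rcc$eligible[[1]],
                  c("ama:ascending colon->ama:colon",
                    "ncia:Ascending_Colon->ama:ascending colon",
                    "ama:colon->ncia:Colon"))

  # a justification consisting solely of provisional axioms is flagged
  net <- mk_net(edges(character(), character()), concepts = c("a", "b", "c"))
  sp <- repair_session(net)
  sp$MI <- data.frame(scope = "o1", sub = c("o1:a", "o1:c"),
                      sup = c("o1:c", "o1:b"), stringsAsFactors = FALSE)
  sp$WI <- data.frame(scope = "o1", sub = "o1:a", sup = "o1:b",
                      stringsAsFactors = FALSE)
  rcl <- removal_candidates(sp, sp$WI)
  expect_true(rcl$unrepairable)
  expect_length(rcl$eligible[[1]], 0L)
})

test_that("minimal hitting sets match exhaustive enumeration", {
  got <- minimal_hitting_sets(list(c("x", "y"), c("y", "z")))
  expect_setequal(vapply(got, paste, character(1), collapse = "|"),
                  c("y", "x|z"))
  expect_equal(minimal_hitting_sets(list("x"))[[1]], "x")
  expect_error(minimal_hitting_sets(list(c("x"), character())), "empty")

  set.seed(42)
  for (rep in 1:20) {
    u <- paste0("e", 1:sample(4:9, 1))
    sets <- replicate(sample(2:4, 1),
                      sample(u, sample(1:3, 1)), simplify = FALSE)
    got <- minimal_hitting_sets(sets, max_size = 9L)
    want <- bf_hitting_sets(sets)
    expect_setequal(vapply(got, paste, character(1), collapse = "|"),
                    vapply(want, paste, character(1), collapse = "|"))
  }
})

test_that("joint hitting sets of the white-matter defects pivot on the shared mapping", {
  s <- wm_session()
  sets <- unlist(lapply(seq_len(nrow(s$WI)), function(i) {
    removal_candidates(s, s$WI[i, , drop = FALSE])$eligible
  }), recursive = FALSE)
  hs <- minimal_hitting_sets(sets)
  rev_comp <- paper_fixture("white_matter")$expected$top_priority
  size2 <- hs[lengths(hs) == 2L]
  expect_gt(length(size2), 0L)
  expect_true(all(vapply(size2, function(h) rev_comp %in% h, logical(1))))
  # agreement with the exhaustive oracle on the full 9-axiom instance
  want <- bf_hitting_sets(sets)
  expect_setequal(vapply(hs, paste, character(1), collapse = "|"),
                  vapply(want, paste, character(1), collapse = "|"))
})

test_that("removal priorities favour axioms that repair several defects", {
  s <- wm_session()
  rec <- recommend_removals(s, s$WI)
  expect_equal(rec$axiom[1],
               paper_fixture("white_matter")$expected$top_priority)
  expect_equal(rec$priority[1], "P1")
  expect_equal(rec$defect_count[1], 2L)

  # single defect, single-axiom justification
  net <- mk_net(edges("a", "b"))
  s1 <- repair_session(net)
  s1$WI <- data.frame(scope = "o1", sub = "o1:a", sup = "o1:b",
                      stringsAsFactors = FALSE)
  rec1 <- recommend_removals(s1, s1$WI)
  expect_equal(rec1$axiom, "o1:a->o1:b")
  expect_equal(rec1$priority, "P1")

  # disjoint defects tie on defect count; ids break the tie
  net2 <- mk_net(edges(c("a", "c"), c("b", "d")))
  s2 <- repair_session(net2)
  s2$WI <- data.frame(scope = "o1", sub = c("o1:a", "o1:c"),
                      sup = c("o1:b", "o1:d"), stringsAsFactors = FALSE)
  rec2 <- recommend_removals(s2, s2$WI)
  expect_equal(rec2$defect_count, c(1L, 1L))
  expect_equal(rec2$axiom, sort(rec2$axiom))
})

test_that("wrong relations rank ascending by number of repairing actions", {
  s <- wm_session()
  r <- rank_wrong(s, "ama")
  expect_equal(r$n_actions, c(3L, 3L, 3L))
  expect_equal(taxodebug:::pair_id(r$sub, r$sup),
               sort(taxodebug:::pair_id(r$sub, r$sup)))
})

test_that("executed removals are transactional and effective", {
  fx <- paper_fixture("colon")
  s <- repair_session(fx$network)
  s$CMI <- detect_candidates(s, "ncia")
  s <- record_verdicts(s, verdicts_for(s$CMI, "wrong"))
  s2 <- execute_removals(s, s$WI, fx$expected$wrong_removal)
  expect_equal(axiom_keys(s2$RI_minus), fx$expected$wrong_removal)
  expect_equal(nrow(s2$WI), 0L)
  expect_false(derivable(build_kb(s2, "network"),
                         "ncia:Ascending_Colon", "ncia:Colon"))

  # insufficient removals are rejected bit-identically
  sw <- wm_session()
  d <- sw$WI[sw$WI$sub == "ama:brain grey matter", , drop = FALSE]
  expect_error(execute_removals(sw, d,
                                "ama:cerebellum white matter->ama:white matter"),
               "insufficient removal")
  before <- sw
  try(execute_removals(sw, d, "ama:cerebellum white matter->ama:white matter"),
      silent = TRUE)
  expect_equal(sw, before)

  # the equivalence pair repairs all three wrong defects in one execution
  eq <- paper_fixture("white_matter")$expected$equivalence_pair
  s3 <- execute_removals(sw, sw$WI, eq)
  expect_equal(nrow(s3$WI), 0L)
  expect_equal(nrow(s3$repaired_wrong), 3L)
  expect_equal(nrow(s3$RM_minus), 2L)
})

test_that("validated-missing and added axioms are never removable", {
  lx <- paper_fixture("laryngeal")
  sl <- initialize_repair_state(lx$network, missing_isa = lx$missing_isa)
  sl$WI <- data.frame(scope = "ncia", sub = "ncia:Epiglottic_Cartilage",
                      sup = "ncia:Laryngeal_Connective_Tissue",
                      stringsAsFactors = FALSE)
  sl$MI <- sl$MI[-1, , drop = FALSE]
  expect_error(
    execute_removals(sl, sl$WI,
                     "ncia:Cricoid_Cartilage->ncia:Laryngeal_Connective_Tissue"),
    "not eligible")

  # fuzz: on corrupted synthetic sessions no executed removal ever touches
  # a provisional or repair-added axiom
  for (seed in 1:3) {
    gen <- synthesize_network(synthetic_spec(
      n_ontologies = 3, concepts_per_ontology = 25, seed = 400 + seed))
    res <- run_scripted_session(gen$network, truth_policy(gen$truth),
                                seed = seed)
    removed <- bind_axioms(res$session$RI_minus, res$session$RM_minus)
    expect_true(all(removed$origin %in% c("original", "equivalence-component")))
  }
})
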