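test_that("repair-state initialization installs provisional axioms everywhere due", {
  lx <- paper_fixture("laryngeal")
  s <- initialize_repair_state(lx$network, missing_isa = lx$missing_isa)
  for (scope in list("ncia", "network")) {
    kb <- build_kb(s, scope)
    expect_equal(sum(kb$axioms$status == "provisional"), 4L)
  }

  # empty validated sets give back the original network
  fx <- paper_fixture("colon")
  s0 <- initialize_repair_state(fx$network)
  expect_equal(nrow(build_kb(s0, "network")$axioms),
               nrow(induced_axioms(fx$network)))
  expect_equal(nrow(s0$RI_plus) + nrow(s0$RI_minus), 0L)

  bx <- paper_fixture("bone")
  sb <- initialize_repair_state(bx$network, missing_isa = bx$missing_isa)
  expect_setequal(cone(build_kb(sb, "ama"), "ama:bone", "sub"),
                  ckey("ama", c("bone", "nasal bone", "maxilla",
                                "lacrimal bone")))

  # a pair knowledge base carries the provisional missing is-a axioms of
  # both member ontologies
  net <- mk_pair_net(edges("a", "b"), edges("a", "c"), shared = c("a", "b"))
  sp <- initialize_repair_state(net, missing_isa = data.frame(
    scope = "o1", sub = "o1:b", sup = "o1:a", stringsAsFactors = FALSE))
  kbp <- build_kb(sp, c("o1", "o2"))
  expect_true("o1:b->o1:a" %in% axiom_keys(kbp$axioms))

  expect_error(initialize_repair_state(
    lx$network, missing_isa = lx$missing_isa,
    wrong_isa = lx$missing_isa), "invariant")
})

test_that("repair spaces are source x target minus wrong-relation conflicts", {
  bx <- paper_fixture("bone")
  s <- initialize_repair_state(bx$network, missing_isa = bx$missing_isa)
  d <- bx$missing_isa[bx$missing_isa$sub == "ama:nasal bone", , drop = FALSE]
  sp <- generate_repair_space(s, d)
  expect_setequal(sp$source, bx$expected$source)
  expect_setequal(sp$target, bx$expected$target)
  expect_true(paste0(bx$expected$informative_action, collapse = "->") %in%
                taxodebug:::pair_id(sp$repair$sub, sp$repair$sup))
  # the defect pair itself is the least informative member
  expect_true("ama:nasal bone->ama:bone" %in%
                taxodebug:::pair_id(sp$repair$sub, sp$repair$sup))

  lx <- paper_fixture("laryngeal")
  sl <- initialize_repair_state(lx$network, missing_isa = lx$missing_isa)
  dl <- lx$missing_isa[1, , drop = FALSE]
  spl <- generate_repair_space(sl, dl)
  expect_true("ncia:Laryngeal_Cartilage" %in% spl$source)
  expect_true(paste0(lx$expected$informative_action, collapse = "->") %in%
                taxodebug:::pair_id(spl$repair$sub, spl$repair$sup))

  # a pair recorded as removed never reappears as a repairing action
  net <- mk_net(edges(character(), character()), concepts = c("a", "b"))
  s1 <- repair_session(net)
  s1$MI <- data.frame(scope = "o1", sub = "o1:a", sup = "o1:b",
                      stringsAsFactors = FALSE)
  s1$RI_minus <- axioms(sub_ont = "o1", sub = "a", sup_ont = "o1", sup = "b",
                        status = "removed")
  sp1 <- generate_repair_space(s1, s1$MI)
  expect_equal(nrow(sp1$repair), 0L)
})

test_that("repair-space elements satisfy the contribution and no-equivalence properties", {
  # pref1: every element, added to the scope KB, derives the defect pair
  # pref3: no element introduces a non-validated equivalence
  # pref4: every element is a single axiom by construction
  fixtures <- list(paper_fixture("bone"), paper_fixture("laryngeal"))
  for (fx in fixtures) {
    s <- initialize_repair_state(fx$network, missing_isa = fx$missing_isa)
    for (i in seq_len(nrow(fx$missing_isa))) {
      d <- fx$missing_isa[i, , drop = FALSE]
      sp <- generate_repair_space(s, d)
      kb <- build_kb(s, d$scope)
      expect_length(intersect(sp$source, cone(kb, d$sup, "super")), 0L)
      expect_length(intersect(sp$target, cone(kb, d$sub, "sub")), 0L)
      for (j in seq_len(nrow(sp$repair))) {
        kb2 <- apply_changes(kb, additions = axioms(
          sub_ont = taxodebug:::key_ont(sp$repair$sub[j]),
          sub = taxodebug:::key_id(sp$repair$sub[j]),
          sup_ont = taxodebug:::key_ont(sp$repair$sup[j]),
          sup = taxodebug:::key_id(sp$repair$sup[j])))
        expect_true(derivable(kb2, d$sub, d$sup))
      }
    }
  }
})

test_that("missing relations rank ascending by repair-space size", {
  net <- mk_net(edges(c("s1", "t1", "t2"), c("a", "b", "b")),
                concepts = c("a", "b", "s1", "t1", "t2"))
  s <- repair_session(net)
  s$MI <- data.frame(scope = "o1", sub = c("o1:a", "o1:t1"),
                     sup = c("o1:b", "o1:s1"), stringsAsFactors = FALSE)
  r <- rank_missing(s, "o1")
  expect_equal(r$n_actions, sort(r$n_actions))
  expect_equal(nrow(rank_missing(repair_session(net), "o1")), 0L)
})

test_that("recommended additions are informativeness-maximal, oracle first", {
  bx <- paper_fixture("bone")
  s <- initialize_repair_state(bx$network, missing_isa = bx$missing_isa)
  d <- bx$missing_isa[bx$missing_isa$sub == "ama:nasal bone", , drop = FALSE]
  sp <- generate_repair_space(s, d)

  oracle <- table_oracle(data.frame(term_a = "viscerocranium bone",
                                    term_b = "bone", rel = "isa"))
  rec <- recommend_additions(s, sp, oracle)
  expect_equal(nrow(rec), 1L)
  expect_equal(c(rec$sub, rec$sup), bx$expected$informative_action)
  expect_true(rec$supported)

  rec0 <- recommend_additions(s, sp, null_oracle())
  expect_false(any(rec0$supported))
  expect_gt(nrow(rec0), 0L)

  self_only <- table_oracle(data.frame(term_a = "nasal bone", term_b = "bone",
                                       rel = "isa"))
  rec1 <- recommend_additions(s, sp, self_only)
  expect_equal(c(rec1$sub, rec1$sup), c("ama:nasal bone", "ama:bone"))
})

test_that("executing additions enforces the repair space and propagates", {
  lx <- paper_fixture("laryngeal")
  s <- initialize_repair_state(lx$network, missing_isa = lx$missing_isa)
  d <- lx$missing_isa[lx$missing_isa$sub == "ncia:Epiglottic_Cartilage", ,
                      drop = FALSE]
  s2 <- execute_addition(s, d, lx$expected$informative_action)
  rep <- attr(s2, "consequences")
  expect_equal(nrow(rep$newly_repaired), 3L)
  expect_equal(nrow(s2$MI), 0L)
  expect_equal(nrow(s2$RI_plus), 1L)

  # self-repair promotes the provisional axiom
  s3 <- initialize_repair_state(lx$network, missing_isa = lx$missing_isa)
  s4 <- execute_addition(s3, d, c(d$sub, d$sup))
  expect_equal(s4$RI_plus$origin, "validated-missing")
  expect_equal(nrow(s4$MI), 3L)  # the other three stay unrepaired

  # actions outside the repair space are rejected, session unchanged
  before <- s3
  expect_error(execute_addition(s3, d, c("ncia:Laryngeal_Connective_Tissue",
                                         "ncia:Thyroid_Cartilage")),
               "not allowed")
  expect_equal(s3, before)
})
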