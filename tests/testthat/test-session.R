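test_that("consequence propagation repairs, reinstates and re-detects", {
  # removing the grey/white-matter equivalence pair repairs the two other
  # wrong defects by side effect
  fw <- paper_fixture("white_matter")
  s <- repair_session(fw$network)
  s$CMI <- detect_candidates(s, "ama")
  s <- record_verdicts(s, verdicts_for(s$CMI, "wrong"))
  d <- s$WI[s$WI$sub == "ama:brain grey matter", , drop = FALSE]
  s2 <- execute_removals(s, d, fw$expected$equivalence_pair)
  rep <- attr(s2, "consequences")
  expect_equal(nrow(rep$newly_repaired), 2L)
  expect_equal(nrow(s2$WI), 0L)

  # a no-op propagation reports nothing
  res <- propagate_consequences(s2)
  expect_equal(nrow(res$report$newly_repaired), 0L)
  expect_equal(nrow(res$report$reinstated), 0L)
  expect_equal(nrow(res$report$new_candidates), 0L)

  # a removal that severs a repaired missing derivation reinstates it
  net <- mk_net(edges(c("a", "m"), c("m", "b")),
                concepts = c("a", "m", "b"))
  sr <- initialize_repair_state(net, missing_isa = data.frame(
    scope = "o1", sub = "o1:a", sup = "o1:b", stringsAsFactors = FALSE))
  sr <- execute_addition(sr, sr$MI, c("o1:a", "o1:b"))
  expect_equal(nrow(sr$MI), 0L)
  # drop the added axiom behind the session's back and re-propagate
  sr$RI_plus <- sr$RI_plus[0, , drop = FALSE]
  res2 <- propagate_consequences(sr)
  expect_equal(nrow(res2$report$reinstated), 0L)  # (a,b) still via m
  sr$network$ontologies$o1$isa <- sr$network$ontologies$o1$isa[0, , drop = FALSE]
  attr(sr$network, "content_hash") <- taxodebug:::network_content_hash(sr$network)
  res3 <- propagate_consequences(sr)
  expect_equal(nrow(res3$report$reinstated), 1L)
  expect_equal(nrow(res3$session$MI), 1L)
})

test_that("network status reports the four repair requirements and done", {
  fx <- paper_fixture("colon")
  s <- repair_session(fx$network)
  s$CMI <- detect_candidates(s, "ncia")
  st0 <- network_status(s)
  expect_false(st0$done)
  expect_equal(st0$open_candidates, 1L)

  s <- record_verdicts(s, verdicts_for(s$CMI, "wrong"))
  s <- execute_removals(s, s$WI, fx$expected$wrong_removal)
  st1 <- network_status(s)
  expect_true(st1$done)
  expect_true(all(vapply(st1$violations, nrow, integer(1)) == 0L))

  # an unrepaired validated missing relation violates requirement (i)
  lx <- paper_fixture("laryngeal")
  sl <- initialize_repair_state(lx$network, missing_isa = lx$missing_isa)
  stl <- network_status(sl)
  expect_false(stl$done)
  expect_equal(nrow(stl$violations$missing_isa), 4L)
})

test_that("scripted sessions drive the colon fragment to done", {
  fx <- paper_fixture("colon")
  policy <- list(
    verdict = function(session, defect) "wrong",
    repair_wrong = function(session, defects) fx$expected$wrong_removal,
    repair_missing = function(session, defect, space) c(defect$sub, defect$sup))
  res <- run_scripted_session(fx$network, policy, seed = 1)
  expect_true(network_status(res$session)$done)
  expect_equal(axiom_keys(res$session$RI_minus), fx$expected$wrong_removal)
  expect_lte(sum(grepl("^iteration", res$transcript)), 2L)
})

test_that("defect-free synthetic networks finish with full local coverage", {
  gen <- synthesize_network(synthetic_spec(
    n_ontologies = 3, concepts_per_ontology = 25,
    p_omit = 0, p_spurious = 0, p_wrong_mapping = 0, seed = 11))
  res <- run_scripted_session(gen$network, truth_policy(gen$truth), seed = 11)
  expect_true(network_status(res$session)$done)
  expect_equal(residual_pairs(res$session), 0L)
})

test_that("ground-truth sessions recover planted defects on small networks", {
  for (seed in c(21, 22, 23)) {
    gen <- synthesize_network(synthetic_spec(
      n_ontologies = 3, concepts_per_ontology = 25, seed = seed))
    res <- run_scripted_session(gen$network, truth_policy(gen$truth),
                                seed = seed)
    expect_true(network_status(res$session)$done)
    rec <- planted_recovered(res$session, gen$truth)
    expect_true(rec$missing)
    expect_true(rec$wrong)
  }
})

test_that("open work never grows across iterations under a ground-truth policy", {
  # monotone progress: unvalidated candidates + unrepaired defects do not
  # increase between consecutive iterations
  for (seed in c(31, 32, 33, 34, 35, 36)) {
    gen <- synthesize_network(synthetic_spec(
      n_ontologies = 3, concepts_per_ontology = 20, seed = seed))
    res <- run_scripted_session(gen$network, truth_policy(gen$truth),
                                seed = seed)
    prog <- as.integer(sub(".*: ", "",
                           grep("progress:", res$transcript, value = TRUE)))
    expect_true(all(diff(prog) <= 0L), info = paste("seed", seed))
    # and the finished session is a fixpoint
    again <- propagate_consequences(res$session)
    expect_equal(nrow(again$report$new_candidates), 0L)
    st <- network_status(res$session)
    expect_equal(st$open_candidates + st$unrepaired, 0L)
  }
})
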