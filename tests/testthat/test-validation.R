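test_that("verdict recommendations use part-of and oracle knowledge", {
  fx <- paper_fixture("colon")
  host <- fx$network$ontologies$ncia
  defect <- data.frame(scope = "ncia", sub = "ncia:Ascending_Colon",
                       sup = "ncia:Colon", stringsAsFactors = FALSE)
  expect_equal(recommend_verdict(defect, host), "wrong?")

  other <- data.frame(scope = "ncia", sub = "ncia:Colon",
                      sup = "ncia:Ascending_Colon", stringsAsFactors = FALSE)
  expect_equal(recommend_verdict(other, host, null_oracle()), "none")

  joints <- table_oracle(data.frame(term_a = "elbow joint", term_b = "joint",
                                    rel = "isa"))
  host2 <- taxonomy("o1", c("elbow_joint", "joint"))
  d2 <- data.frame(scope = "o1", sub = "o1:elbow_joint", sup = "o1:joint",
                   stringsAsFactors = FALSE)
  expect_equal(recommend_verdict(d2, host2, joints), "missing?")

  # oracle part-of suggests wrong, but host part-of takes precedence anyway
  po_oracle <- table_oracle(data.frame(term_a = "elbow joint",
                                       term_b = "joint", rel = "partof"))
  expect_equal(recommend_verdict(d2, host2, po_oracle), "wrong?")

  broken <- structure(function(a, b) stop("boom"),
                      class = c("knowledge_oracle", "function"))
  expect_message(res <- recommend_verdict(d2, host2, broken), "failed")
  expect_equal(res, "none")
})

test_that("accepted verdict batches partition candidates into registers", {
  fw <- paper_fixture("white_matter")
  s <- repair_session(fw$network)
  s$CMI <- detect_candidates(s, "ama")
  s2 <- record_verdicts(s, verdicts_for(s$CMI, "wrong"))
  expect_equal(nrow(s2$WI), 3L)
  expect_equal(nrow(s2$MI), 0L)
  expect_equal(nrow(s2$CMI), 0L)
})

test_that("contradictory batches are rejected atomically", {
  net <- mk_pair_net(edges("a", "b"), edges(c("a", "b"), c("c", "c")),
                     shared = c("a", "b", "c"))
  s <- repair_session(net)
  # synthesize open candidates so the rules can be exercised directly
  s$CMI <- data.frame(scope = "o1",
                      sub = c("o1:a", "o1:b", "o1:a", "o1:c"),
                      sup = c("o1:b", "o1:c", "o1:c", "o1:a"),
                      status = "unvalidated", stringsAsFactors = FALSE)
  before <- s

  # rule 1: same pair decided both ways across batches
  s1 <- record_verdicts(s, list(list(kind = "CMI", scope = "o1", sub = "o1:a",
                                     sup = "o1:b", decision = "missing")))
  s1$CMI <- rbind(s1$CMI, data.frame(scope = "o1", sub = "o1:a", sup = "o1:b",
                                     status = "unvalidated",
                                     stringsAsFactors = FALSE))
  expect_error(record_verdicts(s1, list(list(kind = "CMI", scope = "o1",
                                             sub = "o1:a", sup = "o1:b",
                                             decision = "wrong"))),
               "contradiction")

  # rule 2: wrong pair derivable from the missing pairs alone
  bad_batch <- list(
    list(kind = "CMI", scope = "o1", sub = "o1:a", sup = "o1:b",
         decision = "missing"),
    list(kind = "CMI", scope = "o1", sub = "o1:b", sup = "o1:c",
         decision = "missing"),
    list(kind = "CMI", scope = "o1", sub = "o1:a", sup = "o1:c",
         decision = "wrong"))
  expect_error(record_verdicts(s, bad_batch), "contradiction")
  expect_equal(s, before)  # rejection leaves the session untouched

  # (a,b) missing with (b,a) wrong is not a contradiction
  ok_batch <- list(
    list(kind = "CMI", scope = "o1", sub = "o1:a", sup = "o1:b",
         decision = "missing"),
    list(kind = "CMI", scope = "o1", sub = "o1:c", sup = "o1:a",
         decision = "wrong"))
  expect_silent(s3 <- record_verdicts(s, ok_batch))
  expect_equal(nrow(s3$MI), 1L)
  expect_equal(nrow(s3$WI), 1L)

  # after any accepted batch the registers are disjoint and rule 2 holds
  expect_length(intersect(taxodebug:::register_ids(s3$MI),
                          taxodebug:::register_ids(s3$WI)), 0L)
  expect_length(taxodebug:::wrong_derivable_from_missing(s3), 0L)
})

test_that("verdicts for pairs that are not open candidates are refused", {
  s <- repair_session(paper_fixture("colon")$network)
  expect_error(record_verdicts(s, list(list(kind = "CMI", scope = "ama",
                                            sub = "ama:colon",
                                            sup = "ama:ascending colon",
                                            decision = "wrong"))),
               "not an open candidate")
})
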