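# Phase 2: expert validation of candidates into missing and wrong
# relations, contradiction checks, and verdict recommendations from part-of
# knowledge and a pluggable external-knowledge oracle.

#' Knowledge oracles
#'
#' An oracle is a function `oracle(term_a, term_b)` returning `"isa"`,
#' `"partof"` or `"unknown"` for two normalized labels; it must be
#' deterministic. Shipped implementations are a dictionary-backed oracle and
#' a file-backed table; live lexical resources are intentionally out of
#' scope.
#'
#' @param table data frame with columns `term_a`, `term_b`, `rel`
#'   (`isa`/`partof`); labels are normalized with [normalize_label()].
#' @return a function of class `knowledge_oracle`.
#' @export
table_oracle <- function(table) {
  stopifnot(all(c("term_a", "term_b", "rel") %in% names(table)))
  key <- paste(normalize_label(table$term_a), normalize_label(table$term_b),
               sep = "\r")
  rel <- as.character(table$rel)
  stopifnot(all(rel %in% c("isa", "partof")))
  lookup <- stats::setNames(rel, key)
  structure(function(term_a, term_b) {
    k <- paste(normalize_label(term_a), normalize_label(term_b), sep = "\r")
    if (k %in% names(lookup)) unname(lookup[[k]]) else "unknown"
  }, class = c("knowledge_oracle", "function"))
}

#' @rdname table_oracle
#' @export
null_oracle <- function() {
  structure(function(term_a, term_b) "unknown",
            class = c("knowledge_oracle", "function"))
}

#' @rdname table_oracle
#' @param path TSV file with columns `term_a`, `term_b`, `rel`.
#' @export
load_oracle <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  table_oracle(tab)
}

#' Recommend a validation verdict for a candidate
#'
#' Is-a and part-of are often confused: a part-of relation between the two
#' concepts (asserted in the host ontology, or known to the oracle) suggests
#' the candidate is a wrong is-a relation; an is-a relation in external
#' knowledge suggests it is a missing one. Host part-of knowledge takes
#' precedence over the oracle; oracle failures degrade to `"none"`.
#'
#' @param defect one-row candidate register (`scope`, `sub`, `sup`).
#' @param host the host [taxonomy()] of the candidate's sub-concept.
#' @param oracle a `knowledge_oracle`.
#' @return `"wrong?"`, `"missing?"` or `"none"` (recommendations never
#'   auto-decide).
#' @export
recommend_verdict <- function(defect, host, oracle = null_oracle()) {
  sub_id <- key_id(defect$sub); sup_id <- key_id(defect$sup)
  hit <- host$partof$part == sub_id & host$partof$whole == sup_id
  if (any(hit)) return("wrong?")
  la <- normalize_label(if (sub_id %in% names(host$labels) &&
                            nzchar(host$labels[[sub_id]]))
                          host$labels[[sub_id]] else sub_id)
  lb <- normalize_label(if (sup_id %in% names(host$labels) &&
                            nzchar(host$labels[[sup_id]]))
                          host$labels[[sup_id]] else sup_id)
  ans <- tryCatch(oracle(la, lb), error = function(e) {
    message("oracle failed for (", la, ", ", lb, "): ", conditionMessage(e))
    "unknown"
  })
  switch(ans, partof = "wrong?", isa = "missing?", "none")
}

as_verdict_list <- function(verdicts) {
  if (is.data.frame(verdicts)) {
    verdicts <- lapply(seq_len(nrow(verdicts)), function(i) as.list(verdicts[i, ]))
  }
  lapply(verdicts, function(v) {
    stopifnot(all(c("kind", "scope", "sub", "sup", "decision") %in% names(v)))
    v$decision <- match.arg(v$decision, c("missing", "wrong"))
    v
  })
}

#' Record a batch of validation verdicts
#'
#' Partitions the validated candidates into missing and wrong relations. The
#' whole batch is checked for contradictions before anything is committed:
#' (1) no pair may receive both decisions across the batch and all previous
#' decisions; (2) no wrong-validated pair may be derivable from the
#' missing-validated pairs plus executed additions alone. A rejected batch
#' leaves the session unchanged.
#'
#' On success, missing pairs enter the MI/MM registers (gaining provisional
#' axioms in their scope and network knowledge bases), wrong pairs enter
#' WI/WM, and the decision log is appended.
#'
#' @param session a `repair_session`.
#' @param verdicts list (or data frame) of verdicts with fields `kind`
#'   (`"CMI"`/`"CMM"`), `scope`, `sub`, `sup`, `decision`
#'   (`"missing"`/`"wrong"`), and optional `provenance`.
#' @return the updated session.
#' @export
record_verdicts <- function(session, verdicts) {
  verdicts <- as_verdict_list(verdicts)
  if (length(verdicts) == 0L) return(session)

  open_ids <- c(register_ids(session$CMI), register_ids(session$CMM))
  for (v in verdicts) {
    vid <- paste(v$scope, pair_id(v$sub, v$sup))
    if (!(vid %in% open_ids)) {
      stop("verdict for a pair that is not an open candidate: ", vid)
    }
  }
  vids <- vapply(verdicts, function(v) paste(v$scope, pair_id(v$sub, v$sup)),
                 character(1))
  if (anyDuplicated(vids)) {
    dups <- vids[duplicated(vids)]
    decs <- split(vapply(verdicts, `[[`, character(1), "decision"), vids)
    if (any(vapply(decs, function(d) length(unique(d)) > 1L, logical(1)))) {
      stop("contradiction: a pair receives both decisions within the batch")
    }
  }

  trial <- session
  for (v in verdicts) {
    row <- pair_register(v$scope, v$sub, v$sup)
    if (v$decision == "missing") {
      if (v$kind == "CMI") trial$MI <- rbind(trial$MI, row)
      else trial$MM <- rbind(trial$MM, row)
    } else {
      if (v$kind == "CMI") trial$WI <- rbind(trial$WI, row)
      else trial$WM <- rbind(trial$WM, row)
    }
    reg <- if (v$kind == "CMI") "CMI" else "CMM"
    trial[[reg]] <- trial[[reg]][register_ids(trial[[reg]]) !=
                                   paste(v$scope, pair_id(v$sub, v$sup)), ,
                                 drop = FALSE]
  }
  trial$MI <- canonical_register(trial$MI); trial$WI <- canonical_register(trial$WI)
  trial$MM <- canonical_register(trial$MM); trial$WM <- canonical_register(trial$WM)

  # rule 1 across all decisions ever made
  decided_missing <- c(register_ids(trial$MI), register_ids(trial$MM),
                       register_ids(trial$repaired_missing))
  decided_wrong <- c(register_ids(trial$WI), register_ids(trial$WM),
                     register_ids(trial$repaired_wrong))
  clash <- intersect(decided_missing, decided_wrong)
  if (length(clash) > 0L) {
    stop("contradiction: pair(s) validated both missing and wrong: ",
         paste(clash, collapse = "; "))
  }
  # rule 2: wrong pairs must not follow from missing pairs + additions alone
  conflicts <- wrong_derivable_from_missing(trial)
  if (length(conflicts) > 0L) {
    stop("contradiction: wrong-validated pair(s) derivable from the ",
         "missing-validated pairs and executed additions alone: ",
         paste(conflicts, collapse = "; "))
  }
  n_miss <- sum(vapply(verdicts, function(v) v$decision == "missing", logical(1)))
  trial <- log_decision(trial, "validate",
                        paste0(length(verdicts), " verdicts (", n_miss,
                               " missing, ", length(verdicts) - n_miss,
                               " wrong)"))
  normalize_session(trial)
}
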