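# Session state: the current network with its defect registers, and the
# orchestration of the debugging workflow (consequence propagation, global
# status, scripted sessions).
#
# Registers follow the workflow bookkeeping: MI/WI hold validated missing /
# wrong is-a relations per ontology, MM/WM the validated missing / wrong
# mappings per ontology pair, RI+/RI- and RM+/RM- the executed additions and
# removals, CMI/CMM the open candidates. All concept endpoints are stored as
# global keys "ontology:concept".

pair_register <- function(scope = character(), sub = character(), sup = character()) {
  data.frame(scope = as.character(scope), sub = as.character(sub),
             sup = as.character(sup), stringsAsFactors = FALSE)
}

candidate_register <- function(scope = character(), sub = character(),
                               sup = character(), status = character()) {
  data.frame(scope = as.character(scope), sub = as.character(sub),
             sup = as.character(sup), status = as.character(status),
             stringsAsFactors = FALSE)
}

repaired_register <- function() {
  data.frame(scope = character(), sub = character(), sup = character(),
             kind = character(), action_sub = character(),
             action_sup = character(), via = character(),
             stringsAsFactors = FALSE)
}

empty_log <- function() {
  data.frame(seq = integer(), time = character(), phase = character(),
             detail = character(), stringsAsFactors = FALSE)
}

#' Start a debugging session over an ontology network
#'
#' @param network an [ontology_network()].
#' @param max_paths,max_len caps for justification enumeration.
#' @param max_hs_size,max_hs_count caps for minimal hitting set enumeration.
#' @param seed optional integer recorded in the decision log and used by any
#'   seeded step of a scripted session.
#' @return an object of class `repair_session`.
#' @export
repair_session <- function(network, max_paths = 1000L, max_len = 20L,
                           max_hs_size = 5L, max_hs_count = 10000L,
                           seed = NULL) {
  stopifnot(inherits(network, "ontology_network"))
  s <- structure(list(
    network = network,
    MI = pair_register(), WI = pair_register(),
    MM = pair_register(), WM = pair_register(),
    RI_plus = empty_axioms(), RI_minus = empty_axioms(),
    RM_plus = empty_axioms(), RM_minus = empty_axioms(),
    CMI = candidate_register(), CMM = candidate_register(),
    repaired_missing = repaired_register(),
    repaired_wrong = pair_register()[, c("scope", "sub", "sup"), drop = FALSE],
    chosen_removals = character(),
    decision_log = empty_log(),
    options = list(max_paths = as.integer(max_paths),
                   max_len = as.integer(max_len),
                   max_hs_size = as.integer(max_hs_size),
                   max_hs_count = as.integer(max_hs_count),
                   seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  ), class = "repair_session")
  s$repaired_wrong$kind <- character(0)
  log_decision(s, "init", paste0("session started (seed=", s$options$seed, ")"))
}

log_decision <- function(session, phase, detail) {
  session$decision_log <- rbind(session$decision_log, data.frame(
    seq = nrow(session$decision_log) + 1L,
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    phase = phase, detail = detail, stringsAsFactors = FALSE))
  session
}

#' @export
print.repair_session <- function(x, ...) {
  cat("Debugging session over ", length(x$network$ontologies), " ontologies\n",
      "  open candidates: ", sum(x$CMI$status == "unvalidated"), " CMI, ",
      sum(x$CMM$status == "unvalidated"), " CMM\n",
      "  unrepaired: ", nrow(x$MI), " missing is-a, ", nrow(x$WI),
      " wrong is-a, ", nrow(x$MM), " missing mappings, ", nrow(x$WM),
      " wrong mappings\n",
      "  repairs: +", nrow(x$RI_plus), " is-a, -", nrow(x$RI_minus),
      " is-a, +", nrow(x$RM_plus), " mappings, -", nrow(x$RM_minus),
      " mappings\n", sep = "")
  invisible(x)
}

defect_scope <- function(kind, scope) {
  if (kind == "CMI") parse_scope(scope) else parse_scope(strsplit(scope, "|", fixed = TRUE)[[1]])
}

#' Initialize the repairing phase from validated defect sets
#'
#' Builds a session whose knowledge bases (constructed on demand by
#' [build_kb()]) contain a provisional axiom for every validated missing is-a
#' relation in its host ontology, every ontology-pair knowledge base
#' involving that ontology, and the network; and for every validated missing
#' mapping in its pair knowledge base and the network. All repair registers
#' start empty.
#'
#' @param network an [ontology_network()].
#' @param missing_isa,wrong_isa registers (`scope`, `sub`, `sup`) of validated
#'   missing / wrong is-a relations; `scope` is an ontology id, endpoints are
#'   concept keys.
#' @param missing_map,wrong_map registers of validated missing / wrong
#'   mappings; `scope` is a pair key `"i|j"`.
#' @param ... passed to [repair_session()].
#' @return a `repair_session`.
#' @export
initialize_repair_state <- function(network,
                                    missing_isa = pair_register(),
                                    wrong_isa = pair_register(),
                                    missing_map = pair_register(),
                                    wrong_map = pair_register(), ...) {
  s <- repair_session(network, ...)
  s$MI <- pair_register(missing_isa$scope, missing_isa$sub, missing_isa$sup)
  s$WI <- pair_register(wrong_isa$scope, wrong_isa$sub, wrong_isa$sup)
  s$MM <- pair_register(missing_map$scope, missing_map$sub, missing_map$sup)
  s$WM <- pair_register(wrong_map$scope, wrong_map$sub, wrong_map$sup)
  check_register_invariants(s)
  log_decision(s, "init-repair",
               paste0("validated sets: ", nrow(s$MI), " MI, ", nrow(s$WI),
                      " WI, ", nrow(s$MM), " MM, ", nrow(s$WM), " WM"))
}

register_ids <- function(reg) {
  if (nrow(reg) == 0L) return(character())
  paste(reg$scope, pair_id(reg$sub, reg$sup))
}

check_register_invariants <- function(session) {
  clash_i <- intersect(register_ids(session$MI), register_ids(session$WI))
  clash_m <- intersect(register_ids(session$MM), register_ids(session$WM))
  if (length(clash_i) + length(clash_m) > 0L) {
    stop("validation invariant violated: pair(s) registered both missing and wrong: ",
         paste(c(clash_i, clash_m), collapse = "; "))
  }
  conflicts <- wrong_derivable_from_missing(session)
  if (length(conflicts) > 0L) {
    stop("validation invariant violated: wrong pair(s) derivable from the ",
         "validated missing relations and executed additions alone: ",
         paste(conflicts, collapse = "; "))
  }
  invisible(TRUE)
}

# Wrong pairs derivable from the validated missing pairs plus executed
# additions alone (contradiction rule 2).
wrong_derivable_from_missing <- function(session) {
  missing_ax <- bind_axioms(provisional_axioms(session$MI),
                            provisional_axioms(session$MM),
                            provisional_axioms(session$repaired_missing),
                            session$RI_plus, session$RM_plus)
  wrong <- rbind(session$WI[, c("scope", "sub", "sup")],
                 session$WM[, c("scope", "sub", "sup")])
  if (nrow(wrong) == 0L) return(character())
  kb <- new_kb(missing_ax, network_concepts(session$network),
               list(type = "network", ids = character()))
  hit <- vapply(seq_len(nrow(wrong)), function(i) {
    derivable(kb, wrong$sub[i], wrong$sup[i])
  }, logical(1))
  register_ids(wrong)[hit]
}

all_scopes <- function(network) {
  onts <- sort(names(network$ontologies))
  pairs <- lapply(network$alignments, function(a) sort(a$onts))
  c(as.list(onts), unname(pairs))
}

#' Compute all consequences of executed repairing actions
#'
#' Rebuilds the scope knowledge bases and reconciles the registers: wrong
#' defects whose pair is no longer derivable from the network are marked
#' repaired; unrepaired missing defects whose pair is derivable from their
#' scope without any provisional axiom are marked repaired by others;
#' previously repaired missing defects whose pair lost that derivability are
#' reinstated (provisional restored); previously repaired wrong defects whose
#' pair is derivable again regress to open; finally detection is re-run on
#' every scope and fresh candidates are registered.
#'
#' @param session a `repair_session`.
#' @return list with elements `session` (updated) and `report` (a
#'   `consequence_report`: `newly_repaired`, `reinstated`, `new_candidates`,
#'   `invalidated_caches`).
#' @export
propagate_consequences <- function(session) {
  newly <- pair_register(); newly$kind <- character(0)
  reinst <- pair_register(); reinst$kind <- character(0)
  touched_scopes <- character()

  repeat {
    changed <- FALSE
    net_kb <- build_kb(session, "network")

    # wrong defects repaired as a side effect
    for (reg in c("WI", "WM")) {
      w <- session[[reg]]
      if (nrow(w) == 0L) next
      gone <- !pairs_derivable(net_kb, w$sub, w$sup)
      if (any(gone)) {
        moved <- w[gone, , drop = FALSE]
        moved$kind <- if (reg == "WI") "CMI" else "CMM"
        newly <- rbind(newly, moved)
        session$repaired_wrong <- rbind(session$repaired_wrong, moved)
        session[[reg]] <- w[!gone, , drop = FALSE]
        changed <- TRUE
      }
    }

    # unrepaired missing defects now derivable without any provisional axiom
    noprov_kbs <- new.env(parent = emptyenv())
    noprov_kb <- function(scope) {
      if (is.null(noprov_kbs[[scope]])) {
        noprov_kbs[[scope]] <- build_kb(session, scope,
                                        include_provisionals = FALSE)
      }
      noprov_kbs[[scope]]
    }
    by_scope_derivable <- function(m) {
      out <- logical(nrow(m))
      for (sc in unique(m$scope)) {
        sel <- m$scope == sc
        out[sel] <- pairs_derivable(noprov_kb(sc), m$sub[sel], m$sup[sel])
      }
      out
    }
    for (reg in c("MI", "MM")) {
      m <- session[[reg]]
      if (nrow(m) == 0L) next
      done_idx <- by_scope_derivable(m)
      if (any(done_idx)) {
        moved <- m[done_idx, , drop = FALSE]
        moved$kind <- if (reg == "MI") "CMI" else "CMM"
        newly <- rbind(newly, moved)
        add <- moved
        add$action_sub <- NA_character_; add$action_sup <- NA_character_
        add$via <- "others"
        session$repaired_missing <- rbind(session$repaired_missing,
                                          add[, names(repaired_register())])
        session[[reg]] <- m[!done_idx, , drop = FALSE]
        changed <- TRUE
      }
    }

    # repaired missing defects that regressed
    rm_reg <- session$repaired_missing
    if (nrow(rm_reg) > 0L) {
      lost <- !by_scope_derivable(rm_reg)
      if (any(lost)) {
        back <- rm_reg[lost, , drop = FALSE]
        reinst <- rbind(reinst, back[, c("scope", "sub", "sup", "kind")])
        for (i in seq_len(nrow(back))) {
          reg <- if (back$kind[i] == "CMI") "MI" else "MM"
          session[[reg]] <- rbind(session[[reg]],
                                  pair_register(back$scope[i], back$sub[i], back$sup[i]))
        }
        session$repaired_missing <- rm_reg[!lost, , drop = FALSE]
        changed <- TRUE
      }
    }

    # repaired wrong defects that became derivable again (the network KB is
    # rebuilt first: register moves above change the provisional axioms)
    if (changed) net_kb <- build_kb(session, "network")
    rw_reg <- session$repaired_wrong
    if (nrow(rw_reg) > 0L) {
      backd <- pairs_derivable(net_kb, rw_reg$sub, rw_reg$sup)
      if (any(backd)) {
        back <- rw_reg[backd, , drop = FALSE]
        reinst <- rbind(reinst, back[, c("scope", "sub", "sup", "kind")])
        for (i in seq_len(nrow(back))) {
          reg <- if (back$kind[i] == "CMI") "WI" else "WM"
          session[[reg]] <- rbind(session[[reg]],
                                  pair_register(back$scope[i], back$sub[i], back$sup[i]))
        }
        session$repaired_wrong <- rw_reg[!backd, , drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  # re-run detection on every scope; candidates whose pair stopped being a
  # CMI/CMM (including previously redundant ones) are dropped, fresh ones
  # registered
  new_cands <- candidate_register()
  session$CMI <- session$CMI[session$CMI$status == "unvalidated", , drop = FALSE]
  session$CMM <- session$CMM[session$CMM$status == "unvalidated", , drop = FALSE]
  det_net_kb <- NULL
  det_mapped <- session_mapped_concepts(session)
  for (scope in all_scopes(session$network)) {
    sc <- parse_scope(scope)
    reg <- if (sc$type == "ontology") "CMI" else "CMM"
    scope_str <- format_scope(sc)
    open_prev <- session[[reg]][session[[reg]]$scope == scope_str, , drop = FALSE]
    if (is.null(det_net_kb)) det_net_kb <- build_kb(session, "network")
    kb_net <- det_net_kb
    kb_loc <- build_kb(session, scope)
    cands <- detect_candidates(session, scope, net_kb = kb_net, loc_kb = kb_loc,
                               mapped = det_mapped)
    # keep only open candidates that are still CMIs/CMMs
    valid_prev <- pairs_derivable(kb_net, open_prev$sub, open_prev$sup) &
      !pairs_derivable(kb_loc, open_prev$sub, open_prev$sup)
    session[[reg]] <- rbind(
      session[[reg]][session[[reg]]$scope != scope_str, , drop = FALSE],
      open_prev[valid_prev, , drop = FALSE])
    if (nrow(cands) > 0L) {
      fresh <- cands[!(register_ids(cands) %in% register_ids(open_prev)), , drop = FALSE]
      if (nrow(fresh) > 0L) {
        split_res <- filter_redundant(fresh, kb_loc)
        fresh$status <- ifelse(register_ids(fresh) %in% register_ids(split_res$redundant),
                               "redundant", "unvalidated")
        session[[reg]] <- rbind(session[[reg]], fresh)
        new_cands <- rbind(new_cands, fresh)
      }
    }
  }
  session$CMI <- canonical_register(session$CMI)
  session$CMM <- canonical_register(session$CMM)

  report <- structure(list(newly_repaired = newly, reinstated = reinst,
                           new_candidates = new_cands,
                           invalidated_caches = unique(c(
                             register_ids(session$WI), register_ids(session$WM),
                             register_ids(session$MI), register_ids(session$MM)))),
                      class = "consequence_report")
  session <- log_decision(session, "propagate",
                          paste0(nrow(newly), " newly repaired, ", nrow(reinst),
                                 " reinstated, ", nrow(new_cands), " new candidates"))
  list(session = normalize_session(session), report = report)
}

canonical_register <- function(reg) {
  reg <- reg[!duplicated(register_ids(reg)), , drop = FALSE]
  reg <- reg[order(register_ids(reg)), , drop = FALSE]
  rownames(reg) <- NULL
  reg
}

# Row names carry no information in the registers; normalizing them keeps
# sessions comparable (and save/load an identity) after subsetting.
normalize_session <- function(session) {
  for (nm in c("MI", "WI", "MM", "WM", "CMI", "CMM",
               "repaired_missing", "repaired_wrong", "decision_log")) {
    rownames(session[[nm]]) <- NULL
  }
  session
}

#' @export
print.consequence_report <- function(x, ...) {
  cat("Consequences: ", nrow(x$newly_repaired), " newly repaired, ",
      nrow(x$reinstated), " reinstated, ", nrow(x$new_candidates),
      " new candidates\n", sep = "")
  invisible(x)
}

#' Global status of a debugging session
#'
#' Reports the four structural-repair requirements: (i) every validated
#' missing is-a relation is derivable from its repaired host ontology
#' (asserted non-removed axioms plus added repairs, no provisionals);
#' (ii) every validated wrong is-a relation is underivable from the repaired
#' network; (iii) every validated missing mapping is derivable from its
#' repaired ontology pair; (iv) every validated wrong mapping is underivable
#' from the repaired network. The session is done when all four hold and no
#' open candidates or unrepaired defects remain.
#'
#' @param session a `repair_session`.
#' @return list of class `network_status` with per-requirement violation
#'   registers, open counts and a `done` flag.
#' @export
network_status <- function(session) {
  viol <- list()
  net_kb <- build_kb(session, "network")
  noprov_kbs <- new.env(parent = emptyenv())
  noprov_kb <- function(scope) {
    if (is.null(noprov_kbs[[scope]])) {
      noprov_kbs[[scope]] <- build_kb(session, scope,
                                      include_provisionals = FALSE)
    }
    noprov_kbs[[scope]]
  }

  check_missing <- function(reg, kind) {
    all_m <- rbind(reg[, c("scope", "sub", "sup")],
                   session$repaired_missing[session$repaired_missing$kind == kind,
                                            c("scope", "sub", "sup")])
    if (nrow(all_m) == 0L) return(all_m)
    bad <- logical(nrow(all_m))
    for (sc in unique(all_m$scope)) {
      sel <- all_m$scope == sc
      bad[sel] <- !pairs_derivable(noprov_kb(sc), all_m$sub[sel], all_m$sup[sel])
    }
    all_m[bad, , drop = FALSE]
  }
  check_wrong <- function(reg, kind) {
    all_w <- rbind(reg[, c("scope", "sub", "sup")],
                   session$repaired_wrong[session$repaired_wrong$kind == kind,
                                          c("scope", "sub", "sup")])
    if (nrow(all_w) == 0L) return(all_w)
    bad <- pairs_derivable(net_kb, all_w$sub, all_w$sup)
    all_w[bad, , drop = FALSE]
  }

  viol$missing_isa <- check_missing(session$MI, "CMI")
  viol$wrong_isa <- check_wrong(session$WI, "CMI")
  viol$missing_map <- check_missing(session$MM, "CMM")
  viol$wrong_map <- check_wrong(session$WM, "CMM")

  open_candidates <- sum(session$CMI$status == "unvalidated") +
    sum(session$CMM$status == "unvalidated")
  unrepaired <- nrow(session$MI) + nrow(session$WI) +
    nrow(session$MM) + nrow(session$WM)
  done <- open_candidates == 0L && unrepaired == 0L &&
    all(vapply(viol, nrow, integer(1)) == 0L)
  structure(list(violations = viol, open_candidates = open_candidates,
                 unrepaired = unrepaired, done = done),
            class = "network_status")
}

#' @export
print.network_status <- function(x, ...) {
  cat("Network status: ", if (x$done) "done" else "in progress", "\n",
      "  open candidates: ", x$open_candidates,
      "; unrepaired defects: ", x$unrepaired, "\n", sep = "")
  for (nm in names(x$violations)) {
    v <- x$violations[[nm]]
    if (nrow(v) > 0L) {
      cat("  violated (", nm, "): ",
          paste(register_ids(v), collapse = "; "), "\n", sep = "")
    }
  }
  invisible(x)
}

session_state_hash <- function(session) {
  paste(c(register_ids(session$MI), "|", register_ids(session$WI), "|",
          register_ids(session$MM), "|", register_ids(session$WM), "|",
          axiom_keys(session$RI_plus), "|", axiom_keys(session$RI_minus), "|",
          axiom_keys(session$RM_plus), "|", axiom_keys(session$RM_minus), "|",
          register_ids(session$CMI[session$CMI$status == "unvalidated", ]), "|",
          register_ids(session$CMM[session$CMM$status == "unvalidated", ])),
        collapse = ";")
}

#' Run a non-interactive debugging session under a decision policy
#'
#' Loops detect -> validate -> repair-wrong -> repair-missing until
#' [network_status()] reports done or an iteration cap trips. The policy
#' supplies a verdict for every open candidate and a repair choice for every
#' defect; see [truth_policy()] for the ground-truth policy used with
#' synthetic networks.
#'
#' @param network an [ontology_network()].
#' @param policy list of functions `verdict(session, defect)` returning
#'   `"missing"` or `"wrong"`; `repair_wrong(session, defects)` returning
#'   axiom keys to remove for the wrong defects of one scope (lexicographic
#'   order); and `repair_missing(session, defect, space)` returning a single
#'   repairing action `c(sub_key, sup_key)`.
#' @param max_iterations iteration cap (default 50).
#' @param seed optional integer seed recorded in the transcript.
#' @return list with elements `session` and `transcript` (character vector).
#' @export
run_scripted_session <- function(network, policy, max_iterations = 50L,
                                 seed = NULL) {
  session <- repair_session(network, seed = seed)
  transcript <- paste0("session start: ", length(network$ontologies),
                       " ontologies, seed=",
                       if (is.null(seed)) "NA" else seed)
  seen <- character()

  for (iter in seq_len(max_iterations)) {
    transcript <- c(transcript, paste0("iteration ", iter))

    # phase 1: detection over all scopes
    res <- propagate_consequences(session)
    session <- res$session
    transcript <- c(transcript, paste0("  detected ",
                                       nrow(res$report$new_candidates),
                                       " new candidates"))

    # phase 2: validation of open candidates
    open <- rbind(cbind(session$CMI[session$CMI$status == "unvalidated", ],
                        kind = rep("CMI", sum(session$CMI$status == "unvalidated"))),
                  cbind(session$CMM[session$CMM$status == "unvalidated", ],
                        kind = rep("CMM", sum(session$CMM$status == "unvalidated"))))
    if (nrow(open) > 0L) {
      verdicts <- lapply(seq_len(nrow(open)), function(i) {
        d <- open[i, , drop = FALSE]
        list(kind = d$kind, scope = d$scope, sub = d$sub, sup = d$sup,
             decision = policy$verdict(session, d))
      })
      session <- record_verdicts(session, verdicts)
      transcript <- c(transcript, paste0("  validated ", nrow(open),
                                         " candidates"))
    }
    open_now <- sum(session$CMI$status == "unvalidated") +
      sum(session$CMM$status == "unvalidated")
    unrep_now <- nrow(session$MI) + nrow(session$WI) +
      nrow(session$MM) + nrow(session$WM)
    transcript <- c(transcript, paste0("  progress: ", open_now + unrep_now))

    # phase 3: wrong-defect repairs, scope family by scope family; defects
    # are presented in deterministic lexicographic order (ranking by number
    # of repairing actions is an interactive aid, not needed by policies
    # that repair a scope jointly)
    repeat {
      wrong_scopes <- unique(c(session$WI$scope, session$WM$scope))
      if (length(wrong_scopes) == 0L) break
      scope <- sort(wrong_scopes)[1]
      sc <- parse_scope(scope)
      reg <- if (sc$type == "ontology") session$WI else session$WM
      defects <- reg[reg$scope == format_scope(sc), , drop = FALSE]
      defects <- defects[order(pair_id(defects$sub, defects$sup)), ,
                         drop = FALSE]
      chosen <- policy$repair_wrong(session, defects)
      session <- execute_removals(session, defects, chosen)
      transcript <- c(transcript, paste0("  removed ", length(chosen),
                                         " axiom(s) for scope ", scope))
    }

    # phase 4: missing-defect repairs; each scope pass is ranked once
    # (fewest repairing actions first) and worked through in that order,
    # skipping defects that consequence propagation repaired meanwhile
    repeat {
      if (nrow(session$MI) + nrow(session$MM) == 0L) break
      scopes <- sort(unique(c(session$MI$scope, session$MM$scope)))
      ranked <- rank_missing(session, scopes[1])
      for (i in seq_len(nrow(ranked))) {
        defect <- ranked[i, c("scope", "sub", "sup"), drop = FALSE]
        if (!(register_ids(defect) %in% c(register_ids(session$MI),
                                          register_ids(session$MM)))) next
        space <- generate_repair_space(session, defect)
        action <- policy$repair_missing(session, defect, space)
        session <- execute_addition(session, defect, action)
        transcript <- c(transcript, paste0("  added (", action[1], " -> ",
                                           action[2], ") for ", defect$sub,
                                           " is-a ", defect$sup))
      }
    }

    st <- network_status(session)
    if (st$done) {
      transcript <- c(transcript, "done")
      return(list(session = session, transcript = transcript))
    }
    h <- session_state_hash(session)
    if (h %in% seen) {
      stop("scripted session entered a cycle without reaching done")
    }
    seen <- c(seen, h)
  }
  stop("scripted session exceeded ", max_iterations,
       " iterations without reaching done")
}
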