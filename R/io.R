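# Readers and writers: taxonomy TSV dialect, OBO 1.2 subset, alignment TSV,
# network configuration (YAML), verdict files, session state (JSON) and
# export of repaired ontologies and alignments.
#
# TSV dialects are tab-separated, UTF-8, '#' comments; exports use a
# bit-exact canonical ordering (concepts then axioms, lexicographic) so that
# load -> export -> load is a fixpoint.

read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Load a taxonomy from a file
#'
#' Two dialects are supported. The TSV dialect has one record per line:
#' `C <TAB> id <TAB> label` declares a concept, `I <TAB> sub <TAB> sup` an
#' asserted is-a axiom, `P <TAB> part <TAB> whole` a part-of pair. The OBO
#' dialect reads the OBO 1.2 subset: `[Term]` stanzas with `id`, `name`,
#' `is_a`, `relationship: part_of` and `is_obsolete` (obsolete terms are
#' skipped). Axioms with undeclared endpoints reject the whole file.
#'
#' @param path file path.
#' @param id ontology identifier (defaults to the file base name).
#' @param format `"tsv"` or `"obo"`.
#' @return a [taxonomy()].
#' @export
load_ontology <- function(path, id = tools::file_path_sans_ext(basename(path)),
                          format = c("tsv", "obo")) {
  format <- match.arg(format)
  ont <- if (format == "tsv") load_ontology_tsv(path, id) else load_ontology_obo(path, id)
  message("loaded ontology '", id, "': ", length(ont$concepts), " concepts, ",
          nrow(ont$isa), " is-a axioms, ", nrow(ont$partof), " part-of pairs")
  ont
}

load_ontology_tsv <- function(path, id) {
  tl <- read_tsv_lines(path)
  concepts <- character(); labels <- character()
  isa_sub <- character(); isa_sup <- character()
  po_part <- character(); po_whole <- character()
  for (i in seq_along(tl$lines)) {
    f <- strsplit(tl$lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop(path, ":", tl$lineno[i], ": expected 3 tab-separated fields")
    }
    switch(f[1],
           C = { concepts <- c(concepts, f[2]); labels <- c(labels, f[3]) },
           I = { isa_sub <- c(isa_sub, f[2]); isa_sup <- c(isa_sup, f[3]) },
           P = { po_part <- c(po_part, f[2]); po_whole <- c(po_whole, f[3]) },
           stop(path, ":", tl$lineno[i], ": unknown record type '", f[1], "'"))
  }
  dangling <- setdiff(c(isa_sub, isa_sup), concepts)
  if (length(dangling) > 0L) {
    stop(path, ": is-a axiom endpoint(s) not declared: ",
         paste(dangling, collapse = ", "))
  }
  taxonomy(id, concepts,
           isa = data.frame(sub = isa_sub, sup = isa_sup,
                            stringsAsFactors = FALSE),
           labels = stats::setNames(labels, concepts),
           partof = data.frame(part = po_part, whole = po_whole,
                               stringsAsFactors = FALSE))
}

load_ontology_obo <- function(path, id) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  terms <- list(); cur <- NULL; in_term <- FALSE
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id) && !isTRUE(cur$obsolete)) {
      terms[[cur$id]] <- cur
    }
    terms
  }
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms); cur <- list(); in_term <- TRUE; next
    }
    if (grepl("^\\[", ln)) { terms <- flush(cur, terms); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    strip_comment <- function(v) trimws(sub("\\s*!.*$", "", v))
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^is_a:", ln)) {
      cur$is_a <- c(cur$is_a, strip_comment(sub("^is_a:", "", ln)))
    } else if (grepl("^relationship:\\s*part_of\\s", ln)) {
      cur$part_of <- c(cur$part_of,
                       strip_comment(sub("^relationship:\\s*part_of\\s+", "", ln)))
    } else if (grepl("^is_obsolete:\\s*true", ln)) cur$obsolete <- TRUE
  }
  terms <- flush(cur, terms)
  ids <- names(terms)
  isa <- do.call(rbind, c(list(data.frame(sub = character(), sup = character(),
                                          stringsAsFactors = FALSE)),
                          lapply(terms, function(t) {
                            if (is.null(t$is_a)) NULL
                            else data.frame(sub = t$id, sup = t$is_a,
                                            stringsAsFactors = FALSE)
                          })))
  # is_a targets pointing at obsolete/undeclared terms reject the file
  dangling <- setdiff(isa$sup, ids)
  if (length(dangling) > 0L) {
    stop(path, ": is_a target(s) not declared as (non-obsolete) terms: ",
         paste(dangling, collapse = ", "))
  }
  partof <- do.call(rbind, c(list(data.frame(part = character(), whole = character(),
                                             stringsAsFactors = FALSE)),
                             lapply(terms, function(t) {
                               if (is.null(t$part_of)) NULL
                               else data.frame(part = t$id,
                                               whole = intersect(t$part_of, ids),
                                               stringsAsFactors = FALSE)
                             })))
  labels <- stats::setNames(vapply(terms, function(t) {
    if (is.null(t$name)) "" else t$name
  }, character(1)), ids)
  taxonomy(id, ids, isa = isa, labels = labels, partof = partof)
}

#' Write a taxonomy in the TSV dialect
#' @param ontology a [taxonomy()].
#' @param path output path.
#' @export
write_ontology <- function(ontology, path) {
  cs <- sort(ontology$concepts)
  lab <- vapply(cs, function(c) {
    if (c %in% names(ontology$labels) && nzchar(ontology$labels[[c]]))
      ontology$labels[[c]] else c
  }, character(1))
  isa <- ontology$isa[order(axiom_keys(ontology$isa)), , drop = FALSE]
  po <- ontology$partof[order(ontology$partof$part, ontology$partof$whole), ,
                        drop = FALSE]
  lines <- c(paste("C", cs, lab, sep = "\t"),
             if (nrow(isa) > 0L) paste("I", isa$sub, isa$sup, sep = "\t"),
             if (nrow(po) > 0L) paste("P", po$part, po$whole, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Load an alignment from a TSV file
#'
#' Columns `concept_1`, `concept_2`, `rel` and optional `conf`; `rel` is one
#' of `=` (equivalence, expanded into two directed components), `<`
#' (`concept_1` subsumed by `concept_2`) or `>` (the reverse). Any other
#' symbol (e.g. related-terms mappings, which cannot participate in logical
#' derivation) rejects the file. Confidence is kept as metadata only.
#'
#' @param path file path.
#' @param ont1,ont2 ontology ids of the two sides.
#' @return an [alignment()].
#' @export
load_alignment <- function(path, ont1, ont2) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("concept_1", "concept_2", "rel")
  if (!all(need %in% names(tab))) {
    stop(path, ": alignment file must have columns ",
         paste(need, collapse = ", "))
  }
  al <- alignment(ont1, ont2, tab)
  message("loaded alignment ", ont1, "|", ont2, ": ", nrow(al$mappings),
          " directed mapping axioms from ", nrow(tab), " rows")
  al
}

#' Write an alignment in the TSV dialect
#' @param al an [alignment()].
#' @param path output path.
#' @export
write_alignment <- function(al, path) {
  m <- al$mappings[al$mappings$status != "removed", , drop = FALSE]
  rows <- data.frame(concept_1 = character(), concept_2 = character(),
                     rel = character(), conf = numeric(),
                     stringsAsFactors = FALSE)
  tags <- unique(stats::na.omit(m$pair_tag))
  for (tg in tags) {
    comp <- m[!is.na(m$pair_tag) & m$pair_tag == tg, , drop = FALSE]
    if (nrow(comp) == 2L) {
      fwd <- comp[comp$sub_ont == al$onts[1], , drop = FALSE]
      rows <- rbind(rows, data.frame(concept_1 = fwd$sub, concept_2 = fwd$sup,
                                     rel = "=", conf = fwd$conf,
                                     stringsAsFactors = FALSE))
      m <- axioms_not_in(m, axiom_keys(comp))
    }
  }
  # surviving single components and plain subsumption mappings
  for (i in seq_len(nrow(m))) {
    if (m$sub_ont[i] == al$onts[1]) {
      rows <- rbind(rows, data.frame(concept_1 = m$sub[i], concept_2 = m$sup[i],
                                     rel = "<", conf = m$conf[i],
                                     stringsAsFactors = FALSE))
    } else {
      rows <- rbind(rows, data.frame(concept_1 = m$sup[i], concept_2 = m$sub[i],
                                     rel = ">", conf = m$conf[i],
                                     stringsAsFactors = FALSE))
    }
  }
  rows <- rows[order(rows$concept_1, rows$concept_2, rows$rel), , drop = FALSE]
  lines <- c("concept_1\tconcept_2\trel\tconf",
             if (nrow(rows) > 0L)
               paste(rows$concept_1, rows$concept_2, rows$rel,
                     ifelse(is.na(rows$conf), "", format(rows$conf)), sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Load an ontology network from a YAML configuration
#'
#' The configuration lists ontologies (`id`, `path`, optional `format`) and
#' alignments (`ontologies: [i, j]`, `path`); paths are resolved relative to
#' the configuration file. An `options` block may set enumeration caps, a
#' seed and an oracle file.
#'
#' @param path YAML file.
#' @return list with `network` and `options`.
#' @export
load_network <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  onts <- lapply(cfg$ontologies, function(o) {
    load_ontology(resolve(o$path), id = o$id,
                  format = if (is.null(o$format)) "tsv" else o$format)
  })
  ids <- vapply(onts, function(o) o$id, character(1))
  als <- lapply(cfg$alignments, function(a) {
    pair <- unlist(a$ontologies)
    if (!all(pair %in% ids)) {
      stop("alignment references undeclared ontology id(s): ",
           paste(setdiff(pair, ids), collapse = ", "))
    }
    load_alignment(resolve(a$path), pair[1], pair[2])
  })
  list(network = ontology_network(onts, als),
       options = if (is.null(cfg$options)) list() else cfg$options)
}

#' Read a verdict file
#'
#' TSV with columns `scope`, `sub`, `sup`, `decision` (`missing`/`wrong`);
#' endpoints are concept keys `"ontology:concept"`, `scope` an ontology id
#' or pair key `"i|j"`.
#'
#' @param path file path.
#' @return verdict data frame suitable for [record_verdicts()].
#' @export
load_verdicts <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("scope", "sub", "sup", "decision")
  if (!all(need %in% names(tab))) {
    stop(path, ": verdict file must have columns ", paste(need, collapse = ", "))
  }
  tab$kind <- ifelse(grepl("|", tab$scope, fixed = TRUE), "CMM", "CMI")
  tab
}

## ---- session state (JSON) ----------------------------------------------

df_cols <- function(df) lapply(df, function(col) col)

rebuild_df <- function(template, cols) {
  n <- if (length(cols) == 0L) 0L else max(c(0L, vapply(cols, length, integer(1))))
  out <- template[0, , drop = FALSE]
  if (n == 0L) return(out)
  built <- lapply(names(template), function(nm) {
    v <- cols[[nm]]
    if (is.null(v)) v <- rep(NA, n)
    v <- unlist(lapply(v, function(x) if (is.null(x)) NA else x),
                use.names = FALSE)
    mode_fun <- switch(class(template[[nm]])[1],
                       character = as.character, integer = as.integer,
                       numeric = as.numeric, logical = as.logical,
                       as.character)
    mode_fun(v)
  })
  names(built) <- names(template)
  out <- as.data.frame(built, stringsAsFactors = FALSE)
  out
}

network_to_list <- function(network) {
  list(
    ontologies = lapply(unname(network$ontologies), function(o) {
      list(id = o$id, concepts = as.list(o$concepts),
           labels = as.list(o$labels),
           isa = df_cols(o$isa), partof = df_cols(o$partof))
    }),
    alignments = lapply(unname(network$alignments), function(a) {
      list(onts = as.list(a$onts), mappings = df_cols(a$mappings))
    }))
}

network_from_list <- function(x) {
  onts <- lapply(x$ontologies, function(o) {
    labs <- unlist(o$labels, use.names = FALSE)
    taxonomy(as.character(unlist(o$id)), unlist(o$concepts, use.names = FALSE),
             isa = rebuild_df(empty_axioms(), o$isa),
             labels = stats::setNames(
               if (is.null(labs)) character() else as.character(labs),
               names(o$labels)),
             partof = rebuild_df(data.frame(part = character(),
                                            whole = character(),
                                            stringsAsFactors = FALSE),
                                 o$partof))
  })
  als <- lapply(x$alignments, function(a) {
    onts_pair <- unlist(a$onts, use.names = FALSE)
    alignment(onts_pair[1], onts_pair[2],
              rebuild_df(empty_axioms(), a$mappings))
  })
  ontology_network(onts, als)
}

STATE_SCHEMA_VERSION <- 1L

#' Save and load session state
#'
#' The full session (network with statuses, defect registers, repair
#' registers, open candidates, decision log, options) round-trips through a
#' JSON file: `load_state(save_state(s, path))` equals `s` by deep
#' comparison. A schema-version mismatch or truncated file is rejected.
#'
#' @param session a `repair_session`.
#' @param path file path.
#' @return `save_state` returns `path` invisibly; `load_state` the session.
#' @export
save_state <- function(session, path) {
  x <- list(
    schema_version = STATE_SCHEMA_VERSION,
    network = network_to_list(session$network),
    registers = lapply(session[c("MI", "WI", "MM", "WM")], df_cols),
    repairs = lapply(session[c("RI_plus", "RI_minus", "RM_plus", "RM_minus")],
                     df_cols),
    candidates = lapply(session[c("CMI", "CMM")], df_cols),
    repaired_missing = df_cols(session$repaired_missing),
    repaired_wrong = df_cols(session$repaired_wrong),
    chosen_removals = as.list(session$chosen_removals),
    decision_log = df_cols(session$decision_log),
    options = session$options)
  json <- jsonlite::toJSON(x, auto_unbox = FALSE, digits = NA, null = "null",
                           na = "null", pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) stop("cannot parse session state file: ",
                                         conditionMessage(e)))
  if (is.null(x$schema_version) ||
      unlist(x$schema_version) != STATE_SCHEMA_VERSION) {
    stop("session state schema version mismatch")
  }
  opt <- lapply(x$options, function(v) {
    v <- unlist(v)
    if (is.null(v)) NA_integer_ else v
  })
  s <- repair_session(network_from_list(x$network),
                      max_paths = opt$max_paths, max_len = opt$max_len,
                      max_hs_size = opt$max_hs_size,
                      max_hs_count = opt$max_hs_count,
                      seed = if (is.na(opt$seed)) NULL else opt$seed)
  for (nm in c("MI", "WI", "MM", "WM")) {
    s[[nm]] <- rebuild_df(pair_register(), x$registers[[nm]])
  }
  for (nm in c("RI_plus", "RI_minus", "RM_plus", "RM_minus")) {
    s[[nm]] <- canonical_axioms(rebuild_df(empty_axioms(), x$repairs[[nm]]))
  }
  for (nm in c("CMI", "CMM")) {
    s[[nm]] <- rebuild_df(candidate_register(), x$candidates[[nm]])
  }
  s$repaired_missing <- rebuild_df(repaired_register(), x$repaired_missing)
  rw_template <- pair_register(); rw_template$kind <- character(0)
  s$repaired_wrong <- rebuild_df(rw_template, x$repaired_wrong)
  s$chosen_removals <- as.character(unlist(x$chosen_removals))
  if (is.null(s$chosen_removals)) s$chosen_removals <- character()
  s$decision_log <- rebuild_df(empty_log(), x$decision_log)
  s
}

#' Export the repaired ontologies and alignments
#'
#' Writes one TSV ontology file per ontology (asserted axioms minus
#' removals, plus added and promoted repairing actions) and one alignment
#' file per pair (minus removed mappings, plus added ones), together with a
#' change report listing every addition and removal. Partial repairs are
#' exportable.
#'
#' @param session a `repair_session`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of written file paths, invisibly.
#' @export
export_repaired <- function(session, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (o in session$network$ontologies) {
    cur <- axioms_not_in(o$isa, axiom_keys(session$RI_minus))
    adds <- session$RI_plus[session$RI_plus$sub_ont == o$id, , drop = FALSE]
    if (nrow(adds) > 0L) { adds$status <- "asserted"; adds$origin <- "original" }
    repaired <- taxonomy(o$id, o$concepts, isa = bind_axioms(cur, adds),
                         labels = o$labels, partof = o$partof)
    p <- file.path(out_dir, paste0(o$id, ".tsv"))
    write_ontology(repaired, p)
    files[paste0("ontology:", o$id)] <- p
  }
  for (a in session$network$alignments) {
    key <- pair_key(a$onts[1], a$onts[2])
    cur <- axioms_not_in(a$mappings, axiom_keys(session$RM_minus))
    adds <- session$RM_plus[pair_key_vec(session$RM_plus) == key, , drop = FALSE]
    if (nrow(adds) > 0L) { adds$status <- "asserted" }
    al2 <- alignment(a$onts[1], a$onts[2], bind_axioms(cur, adds))
    p <- file.path(out_dir, paste0(gsub("\\|", "_", key), ".alignment.tsv"))
    write_alignment(al2, p)
    files[paste0("alignment:", key)] <- p
  }
  changes <- rbind(
    data.frame(change = rep("added", nrow(session$RI_plus) + nrow(session$RM_plus)),
               axiom = c(axiom_keys(session$RI_plus), axiom_keys(session$RM_plus)),
               stringsAsFactors = FALSE),
    data.frame(change = rep("removed", nrow(session$RI_minus) + nrow(session$RM_minus)),
               axiom = c(axiom_keys(session$RI_minus), axiom_keys(session$RM_minus)),
               stringsAsFactors = FALSE))
  p <- file.path(out_dir, "changes.tsv")
  writeLines(c("change\taxiom",
               if (nrow(changes) > 0L)
                 paste(changes$change, changes$axiom, sep = "\t")), p,
             useBytes = TRUE)
  files["changes"] <- p
  invisible(files)
}
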