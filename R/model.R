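# Domain types: taxonomies, alignments, ontology networks and axiom tables.
#
# Axioms are kept in plain data frames (one row per directed subsumption
# axiom) rather than per-axiom objects: every downstream step (reachability,
# justification enumeration, set algebra on removals/additions) is a set
# operation over axioms, and data frames make those operations vectorised and
# deterministic.

#' Columns of an axiom table
#'
#' An axiom table is a data frame with one row per directed subsumption axiom
#' `sub -> sup` ("sub is-a sup"). `layer` is `"intra"` for axioms inside one
#' ontology and `"mapping"` for cross-ontology axioms. An equivalence mapping
#' is stored as two directed mapping axioms sharing a `pair_tag`, each
#' independently removable. `conf` carries optional alignment confidence and
#' is never used in reasoning.
#'
#' @keywords internal
#' @name axiom-table
NULL

AXIOM_COLS <- c("sub_ont", "sub", "sup_ont", "sup",
                "layer", "status", "origin", "pair_tag", "conf")

AXIOM_STATUS <- c("asserted", "provisional", "repair-added", "removed")
AXIOM_ORIGIN <- c("original", "validated-missing", "repair", "equivalence-component")

#' Build an axiom table
#'
#' @param sub_ont,sub,sup_ont,sup character vectors (recycled to common
#'   length) identifying the sub- and super-concept endpoints.
#' @param layer `"intra"` or `"mapping"`; inferred from the ontology ids when
#'   `NULL`.
#' @param status,origin axiom lifecycle fields; see [axiom-table].
#' @param pair_tag shared tag linking the two directed components of an
#'   equivalence mapping (`NA` otherwise).
#' @param conf optional confidence metadata.
#' @return a canonically ordered axiom data frame.
#' @export
axioms <- function(sub_ont = character(), sub = character(),
                   sup_ont = sub_ont, sup = character(),
                   layer = NULL, status = "asserted", origin = "original",
                   pair_tag = NA_character_, conf = NA_real_) {
  n <- max(length(sub), length(sup))
  if (n == 0L) return(empty_axioms())
  df <- data.frame(sub_ont = rep_len(as.character(sub_ont), n),
                   sub = rep_len(as.character(sub), n),
                   sup_ont = rep_len(as.character(sup_ont), n),
                   sup = rep_len(as.character(sup), n),
                   stringsAsFactors = FALSE)
  df$layer <- if (is.null(layer)) ifelse(df$sub_ont == df$sup_ont, "intra", "mapping")
              else rep_len(layer, n)
  df$status <- rep_len(status, n)
  df$origin <- rep_len(origin, n)
  df$pair_tag <- rep_len(as.character(pair_tag), n)
  df$conf <- rep_len(as.numeric(conf), n)
  bad <- df$sub_ont == df$sup_ont & df$sub == df$sup
  if (any(bad)) {
    stop("self-subsumption axioms are not allowed: ",
         paste(axiom_keys(df[bad, , drop = FALSE]), collapse = ", "))
  }
  mism <- (df$layer == "intra") != (df$sub_ont == df$sup_ont)
  if (any(mism)) stop("axiom layer inconsistent with endpoint ontologies")
  canonical_axioms(df)
}

empty_axioms <- function() {
  out <- data.frame(sub_ont = character(), sub = character(),
                    sup_ont = character(), sup = character(),
                    layer = character(), status = character(),
                    origin = character(), pair_tag = character(),
                    conf = numeric(), stringsAsFactors = FALSE)
  attr(out, "axiom_keys") <- character()
  out
}

#' Global concept key `"ontology:concept"`
#' @param ont,id character vectors.
#' @keywords internal
ckey <- function(ont, id) {
  if (length(ont) == 0L && length(id) == 0L) return(character())
  paste0(ont, ":", id)
}

#' Axiom identity keys `"ont:sub->ont:sup"`
#'
#' Canonical tables carry their keys as an attribute (row subsetting drops
#' it, forcing recomputation); keys depend on the endpoint columns only.
#'
#' @param ax axiom table.
#' @export
axiom_keys <- function(ax) {
  k <- attr(ax, "axiom_keys")
  if (!is.null(k) && length(k) == nrow(ax)) return(k)
  if (nrow(ax) == 0L) return(character())
  paste0(ax$sub_ont, ":", ax$sub, "->", ax$sup_ont, ":", ax$sup)
}

canonical_axioms <- function(ax) {
  keys <- axiom_keys(ax)
  dup <- duplicated(keys)
  if (any(dup)) { ax <- ax[!dup, , drop = FALSE]; keys <- keys[!dup] }
  ord <- order(keys)
  if (is.unsorted(keys)) { ax <- ax[ord, , drop = FALSE]; keys <- keys[ord] }
  rownames(ax) <- NULL
  attr(ax, "axiom_keys") <- keys
  ax
}

# Union of axiom tables; duplicate definitions (same endpoints) collapse to
# the first occurrence, with a message when collapsing actually happened.
# Column-wise binding: axiom tables have a fixed schema.
bind_axioms <- function(..., warn_dups = FALSE) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0L, list(...))
  if (length(parts) == 0L) return(empty_axioms())
  if (length(parts) == 1L) return(canonical_axioms(parts[[1]]))
  cols <- lapply(AXIOM_COLS, function(nm) {
    unlist(lapply(parts, function(p) p[[nm]]), use.names = FALSE)
  })
  names(cols) <- AXIOM_COLS
  ax <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  if (warn_dups) {
    dup <- duplicated(axiom_keys(ax))
    if (any(dup)) {
      message("collapsing ", sum(dup), " duplicate axiom definition(s)")
    }
  }
  canonical_axioms(ax)
}

# Row filter: axioms of `ax` whose identity key is in `keys`.
axioms_in <- function(ax, keys) ax[axiom_keys(ax) %in% keys, , drop = FALSE]
axioms_not_in <- function(ax, keys) ax[!(axiom_keys(ax) %in% keys), , drop = FALSE]

#' Expand one equivalence correspondence into its two directed components
#'
#' @param ont1,c1,ont2,c2 endpoint ontologies and concepts.
#' @param tag shared pair tag; defaults to a canonical tag built from the
#'   endpoints.
#' @param conf optional confidence.
#' @return axiom table with two `mapping` rows carrying
#'   `origin = "equivalence-component"`.
#' @export
equivalence_axioms <- function(ont1, c1, ont2, c2, tag = NULL, conf = NA_real_) {
  if (is.null(tag)) tag <- paste0(ckey(ont1, c1), "<->", ckey(ont2, c2))
  axioms(sub_ont = c(ont1, ont2), sub = c(c1, c2),
         sup_ont = c(ont2, ont1), sup = c(c2, c1),
         layer = "mapping", origin = "equivalence-component",
         pair_tag = tag, conf = conf)
}

#' Construct a taxonomy
#'
#' A taxonomy is an ontology restricted to named concepts and asserted is-a
#' axioms, with optional part-of pairs used only for validation
#' recommendations (they never enter any knowledge base).
#'
#' @param id ontology identifier.
#' @param concepts character vector of concept ids.
#' @param isa two-column data frame (`sub`, `sup`) of asserted is-a pairs, or
#'   an axiom table restricted to this ontology.
#' @param labels optional named character vector mapping concept id to a
#'   display label.
#' @param partof optional two-column data frame (`part`, `whole`).
#' @return an object of class `taxonomy`.
#' @export
taxonomy <- function(id, concepts = character(), isa = NULL,
                     labels = NULL, partof = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  concepts <- unique(as.character(concepts))
  if (is.null(isa)) {
    isa <- empty_axioms()
  } else if (!all(AXIOM_COLS %in% names(isa))) {
    isa <- axioms(sub_ont = id, sub = as.character(isa[[1]]),
                  sup_ont = id, sup = as.character(isa[[2]]))
  } else {
    isa <- canonical_axioms(isa)
  }
  if (nrow(isa) > 0L && !all(isa$layer == "intra" & isa$sub_ont == id)) {
    stop("taxonomy '", id, "': isa axioms must be intra-ontology axioms of ", id)
  }
  ends <- unique(c(isa$sub, isa$sup))
  dangling <- setdiff(ends, concepts)
  if (length(dangling) > 0L) {
    stop("taxonomy '", id, "': axiom endpoint(s) not declared as concepts: ",
         paste(dangling, collapse = ", "))
  }
  if (is.null(partof)) {
    partof <- data.frame(part = character(), whole = character(),
                         stringsAsFactors = FALSE)
  } else {
    partof <- data.frame(part = as.character(partof[[1]]),
                         whole = as.character(partof[[2]]),
                         stringsAsFactors = FALSE)
  }
  lab <- if (is.null(labels)) character(0) else labels
  lab <- lab[names(lab) %in% concepts]
  lab <- stats::setNames(as.character(lab), names(lab))
  structure(list(id = id, concepts = sort(concepts), isa = isa,
                 labels = lab, partof = partof),
            class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("Taxonomy '", x$id, "': ", length(x$concepts), " concepts, ",
      nrow(x$isa), " asserted is-a axioms, ", nrow(x$partof),
      " part-of pairs\n", sep = "")
  invisible(x)
}

#' Construct an alignment between two ontologies
#'
#' @param ont1,ont2 ontology ids (stored in the given order).
#' @param mappings either an axiom table of mapping axioms, or a data frame
#'   with columns `concept_1`, `concept_2`, `rel` (one of `=`, `<`, `>`) and
#'   optional `conf`; `=` expands into two directed components sharing a pair
#'   tag, `<` into `concept_1 -> concept_2`, `>` into the reverse.
#' @return an object of class `alignment`.
#' @export
alignment <- function(ont1, ont2, mappings = NULL) {
  if (is.null(mappings)) {
    ax <- empty_axioms()
  } else if (all(AXIOM_COLS %in% names(mappings))) {
    ax <- canonical_axioms(mappings)
  } else {
    rel <- as.character(mappings$rel)
    bad <- setdiff(unique(rel), c("=", "<", ">"))
    if (length(bad) > 0L) {
      stop("unknown mapping relation symbol(s): ", paste(bad, collapse = ", "),
           " (only '=', '<', '>' participate in logical derivation)")
    }
    conf <- if ("conf" %in% names(mappings)) as.numeric(mappings$conf) else NA_real_
    conf <- rep_len(conf, nrow(mappings))
    parts <- lapply(seq_len(nrow(mappings)), function(i) {
      a <- as.character(mappings$concept_1[i]); b <- as.character(mappings$concept_2[i])
      switch(rel[i],
        "=" = equivalence_axioms(ont1, a, ont2, b, conf = conf[i]),
        "<" = axioms(sub_ont = ont1, sub = a, sup_ont = ont2, sup = b,
                     layer = "mapping", conf = conf[i]),
        ">" = axioms(sub_ont = ont2, sub = b, sup_ont = ont1, sup = a,
                     layer = "mapping", conf = conf[i]))
    })
    ax <- do.call(bind_axioms, parts)
  }
  if (nrow(ax) > 0L) {
    ok <- (ax$sub_ont %in% c(ont1, ont2)) & (ax$sup_ont %in% c(ont1, ont2)) &
      ax$sub_ont != ax$sup_ont
    if (!all(ok)) stop("alignment axioms must connect '", ont1, "' and '", ont2, "'")
  }
  structure(list(onts = c(ont1, ont2), mappings = ax), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  n_eq <- length(unique(stats::na.omit(x$mappings$pair_tag)))
  cat("Alignment ", x$onts[1], " - ", x$onts[2], ": ", nrow(x$mappings),
      " directed mapping axioms (", n_eq, " equivalence pairs)\n", sep = "")
  invisible(x)
}

pair_key <- function(i, j) paste(sort(c(i, j)), collapse = "|")

#' Assemble an ontology network
#'
#' @param ontologies list of [taxonomy()] objects.
#' @param alignments list of [alignment()] objects, at most one per unordered
#'   ontology pair.
#' @return an object of class `ontology_network`.
#' @export
ontology_network <- function(ontologies, alignments = list()) {
  if (inherits(ontologies, "taxonomy")) ontologies <- list(ontologies)
  ids <- vapply(ontologies, function(o) o$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate ontology ids in network")
  names(ontologies) <- ids
  if (inherits(alignments, "alignment")) alignments <- list(alignments)
  keys <- vapply(alignments, function(a) pair_key(a$onts[1], a$onts[2]), character(1))
  if (anyDuplicated(keys)) stop("more than one alignment for an ontology pair")
  names(alignments) <- keys
  for (al in alignments) {
    miss <- setdiff(al$onts, ids)
    if (length(miss) > 0L) {
      stop("alignment references undeclared ontolog", if (length(miss) > 1) "ies: " else "y: ",
           paste(miss, collapse = ", "))
    }
    m <- al$mappings
    for (side in c("sub", "sup")) {
      onts <- m[[paste0(side, "_ont")]]; cs <- m[[side]]
      for (k in seq_along(cs)) {
        if (!(cs[k] %in% ontologies[[onts[k]]]$concepts)) {
          stop("alignment concept '", cs[k], "' not found in ontology '", onts[k], "'")
        }
      }
    }
  }
  net <- structure(list(ontologies = ontologies,
                        alignments = alignments[order(names(alignments))]),
                   class = "ontology_network")
  attr(net, "content_hash") <- network_content_hash(net)
  net
}

# Deterministic content fingerprint (axioms + concepts); computed once at
# construction and used to key the knowledge-base memo.
network_content_hash <- function(net) {
  paste(c(unlist(lapply(net$ontologies, function(o) {
    c(o$id, o$concepts, axiom_keys(o$isa))
  }), use.names = FALSE),
  unlist(lapply(net$alignments, function(a) axiom_keys(a$mappings)),
         use.names = FALSE)), collapse = ";")
}

#' @export
print.ontology_network <- function(x, ...) {
  cat("Ontology network: ", length(x$ontologies), " ontologies, ",
      length(x$alignments), " alignments\n", sep = "")
  for (o in x$ontologies) cat("  - ", format(o$id), ": ", length(o$concepts),
                              " concepts, ", nrow(o$isa), " is-a axioms\n", sep = "")
  for (a in x$alignments) cat("  - alignment ", a$onts[1], "|", a$onts[2], ": ",
                              nrow(a$mappings), " mapping axioms\n", sep = "")
  invisible(x)
}

#' Asserted axioms of the induced ontology
#'
#' The induced ontology of a network has the union of all concepts, and its
#' asserted is-a axioms are the union of the intra-ontology axioms of every
#' member taxonomy with the directed axioms representing every mapping
#' (equivalences expanded into both directions). Removed axioms are excluded;
#' duplicate definitions collapse silently to one.
#'
#' @param network an [ontology_network()].
#' @return an axiom table.
#' @export
induced_axioms <- function(network) {
  parts <- c(lapply(network$ontologies, function(o) o$isa),
             lapply(network$alignments, function(a) a$mappings))
  ax <- do.call(bind_axioms, parts)
  ax[ax$status != "removed", , drop = FALSE]
}

#' All concept keys of a network
#' @param network an [ontology_network()].
#' @keywords internal
network_concepts <- function(network) {
  unlist(lapply(network$ontologies, function(o) ckey(o$id, o$concepts)),
         use.names = FALSE)
}

#' Display label of a concept, falling back to its id
#' @keywords internal
concept_label <- function(network, ont, id) {
  lab <- network$ontologies[[ont]]$labels
  if (!is.null(lab) && id %in% names(lab) && nzchar(lab[[id]])) lab[[id]] else id
}

#' Normalize a label for lexical matching (lowercase, underscores to spaces)
#' @param x character vector.
#' @export
normalize_label <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("_", " ", x, fixed = TRUE)
  trimws(gsub("[[:space:]]+", " ", x))
}
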