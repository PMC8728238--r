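# GO ontology: OBO parsing into a typed DAG, ancestor queries, annotation
# closure (the true-path rule) and inter-ontology-link inference.

.aspect_letter <- c(molecular_function = "F",
                    biological_process = "P",
                    cellular_component = "C")

#' Parse a go.obo-style ontology file into a DAG
#'
#' Supports the OBO 1.2 flat-file dialect used by go.obo: `[Term]` stanzas
#' with `id`, `name`, `namespace`, `alt_id`, `is_a`, `relationship` and
#' `is_obsolete` tags. Other stanza types (`[Typedef]`, ...) are ignored.
#' Obsolete terms are recorded but carry no edges. `relationship` tags become
#' typed edges, so inter-ontology links (e.g. a molecular function `part_of`
#' a biological process) are preserved with their relation label.
#'
#' @param file Path to an OBO file (ignored when `text` is given).
#' @param text Optional character vector of OBO lines, for in-memory parsing.
#' @param closure_relations Relation labels treated as "parent" semantics for
#'   closure; the graph restricted to these must be acyclic.
#' @return An object of class `go_ontology`: a list with `terms` (data.frame:
#'   id, name, aspect, obsolete), `edges` (data.frame: child, relation,
#'   parent), `alt_ids` (named vector alt id -> primary id), `parents`
#'   (adjacency list) and `closure_relations`.
#' @export
parse_obo <- function(file = NULL, text = NULL,
                      closure_relations = c("is_a", "part_of")) {
  lines <- if (is.null(text)) readLines(file, warn = FALSE) else text
  # locate [Term] stanzas
  stanza_at <- grep("^\\[", lines)
  is_term <- lines[stanza_at] == "[Term]"
  ends <- c(stanza_at[-1] - 1L, length(lines))

  ids <- names <- aspects <- character(0)
  obsolete <- logical(0)
  alt_from <- alt_to <- character(0)
  e_child <- e_rel <- e_parent <- character(0)

  strip_comment <- function(x) sub("\\s*!.*$", "", x)

  for (k in which(is_term)) {
    from <- stanza_at[k]
    to <- ends[k]
    body <- lines[(from + 1L):to]
    tags <- regmatches(body, regexec("^([A-Za-z_]+):\\s*(.*)$", body))
    id <- NA_character_; nm <- ""; ns <- NA_character_; obs <- FALSE
    alts <- character(0); rels <- list()
    for (tg in tags) {
      if (length(tg) == 0L) next
      key <- tg[2]; val <- strip_comment(tg[3])
      if (key == "id") id <- trimws(val)
      else if (key == "name") nm <- trimws(val)
      else if (key == "namespace") ns <- trimws(val)
      else if (key == "is_obsolete") obs <- identical(trimws(val), "true")
      else if (key == "alt_id") alts <- c(alts, trimws(val))
      else if (key == "is_a") rels <- c(rels, list(c("is_a", trimws(val))))
      else if (key == "relationship") {
        parts <- strsplit(trimws(val), "\\s+")[[1]]
        if (length(parts) >= 2L)
          rels <- c(rels, list(c(parts[1], parts[2])))
      }
    }
    if (is.na(id) || !nzchar(id))
      stop("OBO parse error: [Term] stanza starting at line ", from,
           " has no id tag")
    ids <- c(ids, id); names <- c(names, nm)
    aspects <- c(aspects, if (is.na(ns)) NA_character_ else ns)
    obsolete <- c(obsolete, obs)
    if (length(alts)) { alt_from <- c(alt_from, alts)
                        alt_to <- c(alt_to, rep(id, length(alts))) }
    if (!obs) for (r in rels) {
      e_child <- c(e_child, id); e_rel <- c(e_rel, r[1])
      e_parent <- c(e_parent, r[2])
    }
  }

  terms <- data.frame(id = ids, name = names, aspect = aspects,
                      obsolete = obsolete, stringsAsFactors = FALSE)
  if (anyDuplicated(terms$id))
    stop("OBO parse error: duplicate term id ",
         terms$id[duplicated(terms$id)][1])
  alt_ids <- stats::setNames(alt_to, alt_from)

  # resolve edge endpoints through alt_ids; all endpoints must be known terms
  resolve <- function(x) ifelse(x %in% terms$id, x,
                                unname(alt_ids[x]))
  e_parent2 <- resolve(e_parent)
  bad <- is.na(e_parent2) | !(e_parent2 %in% terms$id)
  if (any(bad))
    stop("OBO parse error: edge references unknown term ", e_parent[bad][1])
  edges <- data.frame(child = e_child, relation = e_rel, parent = e_parent2,
                      stringsAsFactors = FALSE)
  # edges out of obsolete terms were skipped at parse; also drop edges into
  # obsolete terms so obsolete ids never take part in traversal
  if (nrow(edges)) {
    obs_ids <- terms$id[terms$obsolete]
    edges <- edges[!(edges$parent %in% obs_ids), , drop = FALSE]
  }

  g <- structure(list(terms = terms, edges = edges, alt_ids = alt_ids,
                      parents = .adjacency(edges, terms$id),
                      closure_relations = closure_relations),
                 class = "go_ontology")
  cyc <- .find_cycle(g, closure_relations)
  if (!is.null(cyc))
    stop("ontology validation error: cycle among closure relations: ",
         paste(cyc, collapse = " -> "))
  g
}

.adjacency <- function(edges, ids) {
  adj <- split(seq_len(nrow(edges)), factor(edges$child, levels = ids))
  lapply(adj, function(i) edges[i, c("relation", "parent"), drop = FALSE])
}

# Kahn-style check; returns one cycle (as an id path) or NULL
.find_cycle <- function(graph, relations) {
  e <- graph$edges[graph$edges$relation %in% relations, , drop = FALSE]
  if (nrow(e) == 0L) return(NULL)
  ids <- graph$terms$id
  # edges child -> parent; Kahn over that direction
  out <- split(e$parent, factor(e$child, levels = ids))
  indeg <- stats::setNames(rep(0L, length(ids)), ids)
  tab <- table(e$parent)
  indeg[names(tab)] <- as.integer(tab)
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (w in out[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (seen == length(ids)) return(NULL)
  # prune nodes without an outgoing edge inside the remainder, leaving only
  # cycle nodes, then walk until a node repeats to exhibit one cycle
  rem <- ids[indeg > 0L]
  repeat {
    keep <- vapply(rem, function(v) any(out[[v]] %in% rem), logical(1))
    if (all(keep)) break
    rem <- rem[keep]
  }
  path <- rem[1]
  repeat {
    nxt <- out[[path[length(path)]]]
    nxt <- nxt[nxt %in% rem][1]
    if (nxt %in% path)
      return(c(path[which(path == nxt)[1]:length(path)], nxt))
    path <- c(path, nxt)
  }
}

#' Resolve a GO identifier to its primary id
#'
#' Looks `id` up in the term table, falling back to the `alt_id` table.
#'
#' @param graph A `go_ontology`.
#' @param id GO identifier(s).
#' @return Primary GO id(s); errors on any id that is neither a primary nor
#'   an alternate id.
#' @export
resolve_term <- function(graph, id) {
  out <- ifelse(id %in% graph$terms$id, id, unname(graph$alt_ids[id]))
  if (anyNA(out))
    stop("unknown GO term id: ", paste(unique(id[is.na(out)]), collapse = ", "))
  out
}

#' Ancestors of a term in the ontology DAG
#'
#' All terms reachable from `term` by repeatedly following edges whose
#' relation label is in `relations`, excluding `term` itself.
#'
#' @param graph A `go_ontology`.
#' @param term A GO identifier (alternate ids are resolved).
#' @param relations Relation labels to traverse; defaults to the graph's
#'   closure relations (`is_a`, `part_of`).
#' @return Character vector of ancestor GO ids (sorted).
#' @export
ancestors <- function(graph, term, relations = graph$closure_relations) {
  term <- resolve_term(graph, term)
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    nxt <- character(0)
    for (t in frontier) {
      p <- graph$parents[[t]]
      if (is.null(p) || nrow(p) == 0L) next
      nxt <- c(nxt, p$parent[p$relation %in% relations])
    }
    nxt <- setdiff(unique(nxt), c(seen, term))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

.term_aspect_letter <- function(graph, ids) {
  ns <- graph$terms$aspect[match(ids, graph$terms$id)]
  unname(.aspect_letter[ns])
}

#' Propagate annotations to all ancestors (true-path closure)
#'
#' For every input record (gene, term), adds one record (gene, ancestor) for
#' each ancestor of the term under `relations`, carrying the child record's
#' evidence code, provenance `source = "closure"` and the child term id in
#' `with_from`. Records whose term is obsolete are dropped with a warning and
#' counted; alternate ids are silently resolved (and counted). Output is
#' deduplicated on (subject, term, evidence, source); the input records are
#' always retained, so the closure is idempotent.
#'
#' @param graph A `go_ontology`.
#' @param records Annotation records.
#' @param relations Relations to traverse (default: the graph's closure
#'   relations).
#' @return Deduplicated records, a superset of the (non-obsolete) input, with
#'   attribute `counts`: named integer vector with `dropped_obsolete` and
#'   `alt_resolved`.
#' @export
close_annotations <- function(graph, records,
                              relations = graph$closure_relations) {
  counts <- c(dropped_obsolete = 0L, alt_resolved = 0L)
  if (nrow(records) == 0L) {
    out <- dedup_records(records)
    attr(out, "counts") <- counts
    return(out)
  }
  resolved <- resolve_term(graph, records$term)
  counts["alt_resolved"] <- sum(resolved != records$term)
  records$term <- resolved
  obs <- graph$terms$obsolete[match(records$term, graph$terms$id)]
  if (any(obs)) {
    counts["dropped_obsolete"] <- sum(obs)
    warning(sum(obs), " annotation(s) to obsolete terms dropped")
    records <- records[!obs, , drop = FALSE]
  }
  anc_of <- lapply(stats::setNames(nm = unique(records$term)),
                   function(t) ancestors(graph, t, relations))
  expandable <- !grepl("\\bNOT\\b", records$qualifier)
  new <- lapply(which(expandable), function(i) {
    a <- anc_of[[records$term[i]]]
    if (length(a) == 0L) return(NULL)
    r <- records[rep(i, length(a)), , drop = FALSE]
    r$with_from <- r$term
    r$term <- a
    r$aspect <- .term_aspect_letter(graph, a)
    r$source <- "closure"
    r
  })
  out <- dedup_records(bind_records(c(list(records), new)))
  attr(out, "counts") <- counts
  out
}

#' Default inter-ontology inference channels
#'
#' Each channel names a relation and the source/target aspects it links:
#' a molecular-function term `part_of` a biological process implies a BP
#' annotation, and a biological-process term `occurs_in` a cellular
#' component implies a CC annotation.
#'
#' @return A list of channels, each `list(relation, from, to)` with aspects
#'   given as namespace names.
#' @export
default_link_channels <- function() {
  list(list(relation = "part_of", from = "molecular_function",
            to = "biological_process"),
       list(relation = "occurs_in", from = "biological_process",
            to = "cellular_component"))
}

#' Infer annotations across aspects via inter-ontology links
#'
#' For every positive input record annotated to a term with a direct edge
#' matching one of the configured channels (relation label, source aspect,
#' target aspect), emits one inferred record to the edge's parent term, with
#' the target term's aspect, evidence `IEA`, provenance `"inter-ontology"`,
#' and the originating term in `with_from`. Only the newly inferred records
#' are returned.
#'
#' @param graph A `go_ontology`.
#' @param records Annotation records.
#' @param channels Inference channels as in [default_link_channels()].
#' @return Deduplicated inferred records (possibly zero rows).
#' @export
infer_cross_aspect <- function(graph, records,
                               channels = default_link_channels()) {
  if (nrow(records) == 0L) return(empty_records())
  records <- drop_not_qualified(records)
  if (nrow(records) == 0L) return(empty_records())
  records$term <- resolve_term(graph, records$term)
  ns <- graph$terms$aspect
  names(ns) <- graph$terms$id
  out <- list()
  for (ch in channels) {
    e <- graph$edges
    e <- e[e$relation == ch$relation &
             ns[e$child] == ch$from & ns[e$parent] == ch$to, , drop = FALSE]
    if (nrow(e) == 0L) next
    hit <- records$term %in% e$child
    if (!any(hit)) next
    for (i in which(hit)) {
      targets <- e$parent[e$child == records$term[i]]
      r <- records[rep(i, length(targets)), , drop = FALSE]
      r$with_from <- r$term
      r$term <- targets
      r$aspect <- .term_aspect_letter(graph, targets)
      r$evidence <- "IEA"
      r$source <- "inter-ontology"
      r$db_ref <- "GO_REF:0000108"
      out <- c(out, list(r))
    }
  }
  dedup_records(bind_records(out))
}

#' Fill in record aspects from the ontology
#'
#' Sets each record's aspect letter (F/P/C) from its term's namespace.
#' Useful for records built from sources that do not carry an aspect column
#' (e.g. InterProScan GO lookups).
#'
#' @param graph A `go_ontology`.
#' @param records Annotation records; terms must resolve in the graph.
#' @return The records with `aspect` consistent with the ontology.
#' @export
assign_aspects <- function(graph, records) {
  if (nrow(records) == 0L) return(records)
  records$term <- resolve_term(graph, records$term)
  asp <- .term_aspect_letter(graph, records$term)
  records$aspect <- ifelse(is.na(asp), records$aspect, asp)
  records
}

#' Export the ontology edge list as TSV (child, relation, parent)
#'
#' @param graph A `go_ontology`.
#' @param file Output path.
#' @export
write_ontology_edges <- function(graph, file) {
  e <- graph$edges[order(graph$edges$child, graph$edges$relation,
                         graph$edges$parent), , drop = FALSE]
  utils::write.table(e, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
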