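# Orchestration: merge the three sources, apply inter-ontology inference and
# ancestor closure, compute summary statistics, write GAF / GeneMerge /
# summary JSON. Stage order is fixed: sources -> merge -> inference ->
# closure, so inferred terms also receive their ancestors.

#' Merge gene-level annotation sets from several sources
#'
#' Union of the inputs, deduplicated on (subject_id, term, evidence, source)
#' so the same assertion from two sources keeps both provenance records,
#' while duplicates within a source collapse (with `with_from` values
#' `|`-joined). `NOT`-qualified records are excluded.
#'
#' @param sets List of gene-level annotation record data.frames.
#' @return Deduplicated merged records.
#' @export
merge_sources <- function(sets) {
  dedup_records(drop_not_qualified(bind_records(sets)))
}

#' Summarize an annotation set
#'
#' @param records Merged (and usually closed) gene-level records.
#' @param discards Optional named integer vector of discard counters
#'   accumulated by the pipeline stages.
#' @return An `annotation_summary`: list with `n_genes` (distinct annotated
#'   genes), `n_records`, `genes_per_source`, `records_per_aspect` and
#'   `discards`.
#' @export
summarize_annotations <- function(records, discards = NULL) {
  per_source <- vapply(split(records$subject_id, records$source),
                       function(g) length(unique(g)), integer(1))
  per_aspect <- vapply(split(seq_len(nrow(records)), records$aspect),
                       length, integer(1))
  structure(list(
    n_genes = length(unique(records$subject_id)),
    n_records = nrow(records),
    genes_per_source = as.list(per_source[order(names(per_source))]),
    records_per_aspect = as.list(per_aspect[order(names(per_aspect))]),
    discards = as.list(discards)
  ), class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat("Annotation summary:", x$n_genes, "annotated genes,",
      x$n_records, "records\n")
  if (length(x$genes_per_source)) {
    cat("  genes per source:\n")
    for (s in names(x$genes_per_source))
      cat(sprintf("    %-24s %d\n", s, x$genes_per_source[[s]]))
  }
  if (length(x$records_per_aspect))
    cat("  records per aspect:",
        paste(names(x$records_per_aspect),
              unlist(x$records_per_aspect), sep = "=", collapse = " "), "\n")
  if (length(x$discards))
    cat("  discards:",
        paste(names(x$discards), unlist(x$discards), sep = "=",
              collapse = " "), "\n")
  invisible(x)
}

#' Aggregate per-species summaries
#'
#' @param summaries Named list of `annotation_summary` objects, one per
#'   species.
#' @return List with per-species annotated-gene counts and their mean.
#' @export
aggregate_summaries <- function(summaries) {
  n <- vapply(summaries, function(s) s$n_genes, integer(1))
  list(genes_per_species = as.list(n), mean_annotated_genes = mean(n))
}

#' Read a pipeline configuration file
#'
#' YAML with keys: `species`, `taxon`, `assigned_by`, `ontology`,
#' `uniprot_gaf`, `idmapping` (+ optional `idmapping_protein_col`,
#' `idmapping_gene_col`), `protein_to_gene`, `interproscan`, `evalue`,
#' `analyses`, and `references`, a list of blocks with `name`, `is_human`,
#' `gaf`, `interproscan`, `hits_fwd`, `hits_rev`. Relative paths are
#' resolved against the config file's directory.
#'
#' @param path Path to a YAML config file.
#' @return Config list with absolute paths.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  absol <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  for (k in c("ontology", "uniprot_gaf", "idmapping", "protein_to_gene",
              "interproscan"))
    cfg[[k]] <- absol(cfg[[k]])
  cfg$references <- lapply(cfg$references, function(r) {
    for (k in c("gaf", "interproscan", "hits_fwd", "hits_rev"))
      r[[k]] <- absol(r[[k]])
    if (is.null(r$is_human)) r$is_human <- FALSE
    r
  })
  n_human <- sum(vapply(cfg$references, function(r) isTRUE(r$is_human),
                        logical(1)))
  if (n_human > 1L)
    stop("config error: at most one reference may be flagged is_human")
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full annotation pipeline for one species
#'
#' Executes, in fixed order: UniProt-GOA ingestion (protein-to-gene
#' conversion with the multi-gene exclusion rule), InterPro domain-to-GO
#' extraction, homology transfer per reference (reciprocal best hits, then
#' non-reciprocal best hits with identical domain profiles; no
#' biological-process transfer from a human reference), source merging,
#' inter-ontology-link inference, ancestor closure, and output emission.
#'
#' @param config Config list (see [read_pipeline_config()]) or path to a
#'   YAML config file.
#' @param out_dir Output directory; created if missing. Receives
#'   `<species>.gaf`, `<species>.genemerge.txt`, `<species>.summary.json`.
#' @return Invisibly, a list with `records` (the closed annotation set),
#'   `summary`, `graph`, `rbh` (per-reference reciprocal pair tables) and
#'   `paths` to the written files.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  species <- config$species %||% "species"
  evalue <- config$evalue %||% 1e-5
  analyses <- config$analyses %||% .default_analyses
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, paste0(species, c(".gaf", ".genemerge.txt",
                                                ".summary.json")))
  names(paths) <- c("gaf", "genemerge", "summary")
  on_error_cleanup <- function() unlink(paths[file.exists(paths)])

  graph <- .stage("ontology", parse_obo(config$ontology))
  discards <- integer(0)
  add_discards <- function(prefix, d)
    stats::setNames(as.integer(d), paste0(prefix, "_", names(d)))

  sources <- list()
  if (!is.null(config$uniprot_gaf)) {
    uni <- .stage("uniprot", {
      prot <- read_gaf(config$uniprot_gaf, source = "uniprot")
      idmap <- read_idmapping(config$idmapping,
                              protein_col = config$idmapping_protein_col %||% 1L,
                              gene_col = config$idmapping_gene_col %||% 3L)
      ingest_uniprot(prot, idmap)
    })
    discards <- c(discards, add_discards("uniprot", attr(uni, "discards")))
    sources$uniprot <- uni
  }

  p2g <- .stage("protein_to_gene",
                read_idmapping(config$protein_to_gene, protein_col = 1L,
                               gene_col = 2L))
  qprofiles <- list()
  if (!is.null(config$interproscan)) {
    ipr <- .stage("interproscan", read_interproscan(config$interproscan))
    dom <- .stage("domain_go",
                  assign_aspects(graph, extract_domain_go(ipr, p2g)))
    discards <- c(discards, add_discards("interpro", attr(dom, "discards")))
    sources$interpro <- dom
    qprofiles <- build_profiles(ipr, analyses)
  }

  rbh_tables <- list()
  n_over <- 0L
  for (r in config$references) {
    st <- .stage(paste0("homology:", r$name), {
      ref_ann <- read_gaf(r$gaf, source = "reference")
      rprofiles <- build_profiles(read_interproscan(r$interproscan),
                                  analyses)
      fwd <- best_hits(read_hits(r$hits_fwd), evalue,
                       direction = c(species, r$name))
      rev <- best_hits(read_hits(r$hits_rev), evalue,
                       direction = c(r$name, species))
      rbh <- reciprocal_best_hits(fwd, rev)
      ref <- reference_set(r$name, ref_ann, is_human = isTRUE(r$is_human))
      list(records = transfer_homology(rbh, fwd, qprofiles, rprofiles, ref,
                                       p2g),
           rbh = rbh, n_excluded = fwd$n_excluded + rev$n_excluded)
    })
    n_over <- n_over + st$n_excluded
    rbh_tables[[r$name]] <- st$rbh
    discards <- c(discards,
                  add_discards(paste0("homology_", r$name),
                               attr(st$records, "discards")))
    sources[[paste0("homology:", r$name)]] <- st$records
  }
  discards <- c(discards, over_threshold_hits = n_over)

  closed <- .stage("merge_infer_close", {
    merged <- merge_sources(sources)
    inferred <- infer_cross_aspect(graph, merged)
    merged <- merge_sources(list(merged, inferred))
    withCallingHandlers(
      close_annotations(graph, merged),
      warning = function(w) invokeRestart("muffleWarning"))
  })
  cc <- attr(closed, "counts")
  discards <- c(discards, obsolete_terms = unname(cc["dropped_obsolete"]),
                alt_id_resolved = unname(cc["alt_resolved"]))

  # stamp configured taxon / assigned_by for GAF emission
  if (nrow(closed) > 0L) {
    if (!is.null(config$taxon)) closed$taxon <- as.integer(config$taxon)
    if (!is.null(config$assigned_by)) closed$assigned_by <- config$assigned_by
  }

  summary <- summarize_annotations(closed, discards)
  ok <- FALSE
  tryCatch({
    .stage("write_gaf", write_gaf(closed, paths[["gaf"]]))
    .stage("write_genemerge", write_genemerge(closed, paths[["genemerge"]]))
    .stage("write_summary",
           jsonlite::write_json(unclass(summary), paths[["summary"]],
                                auto_unbox = TRUE, digits = NA))
    ok <- TRUE
  }, finally = if (!ok) on_error_cleanup())

  invisible(list(records = closed, summary = summary, graph = graph,
                 rbh = rbh_tables, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
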