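# The three annotation sources: UniProt-GOA ingestion (with the multi-gene
# exclusion rule), InterPro domain -> GO extraction with domain profiles, and
# homology-based transfer from reciprocal / domain-identical best hits.

.default_analyses <- c("SMART", "SUPERFAMILY", "PANTHER", "Pfam")

#' Convert protein-level UniProt-GOA records to gene level
#'
#' Each record whose protein maps to exactly one gene is re-subjected to that
#' gene with `source = "uniprot"` and its evidence code preserved.
#' Annotations on proteins that map to more than one gene are excluded
#' entirely, as are annotations on proteins absent from the mapping and
#' `NOT`-qualified records; each discard class is counted, not raised.
#'
#' @param records Protein-level annotation records.
#' @param mapping Named list protein -> gene id vector, from
#'   [read_idmapping()].
#' @return Deduplicated gene-level records with attribute `discards`: named
#'   counts of distinct proteins discarded (`multi_gene`, `unmapped`) and of
#'   `not_qualifier` records excluded.
#' @export
ingest_uniprot <- function(records, mapping) {
  n_not <- sum(grepl("\\bNOT\\b", records$qualifier))
  records <- drop_not_qualified(records)
  genes <- mapping[records$subject_id]
  n_genes <- lengths(genes)
  unmapped <- vapply(genes, is.null, logical(1)) | n_genes == 0L
  multi <- !unmapped & n_genes > 1L
  keep <- !unmapped & !multi
  discards <- c(
    multi_gene = length(unique(records$subject_id[multi])),
    unmapped = length(unique(records$subject_id[unmapped])),
    not_qualifier = n_not
  )
  out <- records[keep, , drop = FALSE]
  if (nrow(out) > 0L) {
    out$with_from <- ifelse(nzchar(out$with_from), out$with_from,
                            out$subject_id)
    out$subject_id <- vapply(genes[keep], `[[`, character(1), 1L)
    out$symbol <- out$subject_id
    out$subject_kind <- "gene"
    out$object_type <- "gene"
    out$source <- "uniprot"
  }
  out <- dedup_records(out)
  attr(out, "discards") <- discards
  out
}

#' Extract gene-level GO annotations from InterProScan rows
#'
#' Every (protein, GO id) pair observed in the rows yields one record per
#' mapped gene with evidence `IEA`, the matching signature accession in
#' `with_from` and `source = "interpro"`. Duplicate pairs collapse; a pair
#' supported by several signatures keeps them `|`-joined in `with_from`.
#'
#' @param rows Data.frame from [read_interproscan()].
#' @param mapping Named list protein -> gene id vector.
#' @return Deduplicated gene-level records with attribute `discards`
#'   (`unmapped`: distinct proteins with GO terms but no gene mapping).
#' @export
extract_domain_go <- function(rows, mapping) {
  ngo <- lengths(rows$go_terms)
  rows <- rows[ngo > 0L, , drop = FALSE]
  if (nrow(rows) == 0L) {
    out <- empty_records()
    attr(out, "discards") <- c(unmapped = 0L)
    return(out)
  }
  prot <- rep(rows$protein, lengths(rows$go_terms))
  sig <- rep(rows$signature, lengths(rows$go_terms))
  term <- unlist(rows$go_terms, use.names = FALSE)
  genes <- mapping[prot]
  unmapped <- vapply(genes, function(g) is.null(g) || length(g) == 0L,
                     logical(1))
  discards <- c(unmapped = length(unique(prot[unmapped])))
  prot <- prot[!unmapped]; sig <- sig[!unmapped]; term <- term[!unmapped]
  genes <- genes[!unmapped]
  ng <- lengths(genes)
  out <- annotation_records(
    subject_id = unlist(genes, use.names = FALSE),
    term = rep(term, ng), aspect = "",
    evidence = "IEA", source = "interpro", subject_kind = "gene",
    with_from = rep(sig, ng), db_ref = "GO_REF:0000002"
  )
  out <- dedup_records(out)
  attr(out, "discards") <- discards
  out
}

#' Build per-protein domain profiles
#'
#' A protein's domain profile is the set of signature accessions it matched,
#' restricted to the configured analyses (SMART, SUPERFAMILY, PANTHER and
#' Pfam by default; analysis names compared case-insensitively). Proteins
#' present in `rows` but with no qualifying rows get an empty profile.
#'
#' @param rows Data.frame from [read_interproscan()].
#' @param analyses Analysis (member database) names to include.
#' @return Named list protein -> sorted character vector of signatures.
#' @export
build_profiles <- function(rows, analyses = .default_analyses) {
  stopifnot(length(analyses) > 0L)
  prots <- unique(rows$protein)
  keep <- toupper(rows$analysis) %in% toupper(analyses)
  sigs <- split(rows$signature[keep],
                factor(rows$protein[keep], levels = prots))
  lapply(sigs, function(s) sort(unique(s)))
}

#' Select the best hit per query
#'
#' Hits with E-value above `min_evalue` are excluded first; among the rest,
#' each query's best hit is the one with maximal bit score, ties broken by
#' minimal E-value, then by lexicographically smallest subject id, so the
#' result is deterministic.
#'
#' @param hits Data.frame from [read_hits()], all in one (query species,
#'   reference species) direction.
#' @param min_evalue E-value cutoff applied before selection (default 1e-5).
#' @param direction Optional length-2 character vector `c(query species,
#'   subject species)`, used by [reciprocal_best_hits()] to verify that two
#'   maps are opposite directions.
#' @return A `best_hit_map`: list with `best` (named vector query ->
#'   subject), `direction`, and `n_excluded` (hits over the cutoff).
#' @export
best_hits <- function(hits, min_evalue = 1e-5, direction = NULL) {
  n_excluded <- sum(hits$evalue > min_evalue)
  hits <- hits[hits$evalue <= min_evalue, , drop = FALSE]
  best <- stats::setNames(character(0), character(0))
  if (nrow(hits) > 0L) {
    o <- order(hits$query, -hits$bitscore, hits$evalue, hits$subject)
    hits <- hits[o, , drop = FALSE]
    first <- !duplicated(hits$query)
    best <- stats::setNames(hits$subject[first], hits$query[first])
  }
  structure(list(best = best, direction = direction,
                 n_excluded = n_excluded),
            class = "best_hit_map")
}

#' Reciprocal best hits between two search directions
#'
#' A pair (q, r) is reciprocal iff r is q's best hit in the forward
#' direction and q is r's best hit in the reverse direction.
#'
#' @param fwd,rev `best_hit_map`s for the two directions of one species
#'   pair. When both carry a `direction`, they must be opposite or an error
#'   is raised.
#' @return Data.frame with columns `query`, `ref`, sorted by `query`.
#' @export
reciprocal_best_hits <- function(fwd, rev) {
  if (!is.null(fwd$direction) && !is.null(rev$direction) &&
      !identical(unname(fwd$direction), unname(rev$direction[c(2, 1)])))
    stop("direction mismatch: forward is ",
         paste(fwd$direction, collapse = "->"), ", reverse is ",
         paste(rev$direction, collapse = "->"))
  q <- names(fwd$best)
  r <- unname(fwd$best)
  back <- unname(rev$best[r])
  keep <- !is.na(back) & back == q
  out <- data.frame(query = q[keep], ref = r[keep], stringsAsFactors = FALSE)
  out <- out[order(out$query), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Declare a reference annotation set
#'
#' @param name Reference species label (used in the provenance tag
#'   `homology:<name>`).
#' @param annotations Annotation records for the reference, protein-level or
#'   gene-level.
#' @param is_human TRUE for the human reference: its biological-process (P)
#'   annotations are never transferred.
#' @param protein_to_gene Optional named list protein -> genes; required to
#'   resolve gene-level reference annotations to searched proteins.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(name, annotations, is_human = FALSE,
                          protein_to_gene = NULL) {
  structure(list(name = name, annotations = annotations,
                 is_human = is_human, protein_to_gene = protein_to_gene),
            class = "reference_set")
}

# terms annotated to each reference protein, as a data.frame
# (protein, term, aspect); gene-level reference annotations are pushed down
# to proteins via the reference's protein_to_gene map
.ref_protein_terms <- function(ref) {
  ann <- drop_not_qualified(ref$annotations)
  if (nrow(ann) == 0L)
    return(data.frame(protein = character(0), term = character(0),
                      aspect = character(0), stringsAsFactors = FALSE))
  if (all(ann$subject_kind == "protein") || is.null(ref$protein_to_gene)) {
    return(data.frame(protein = ann$subject_id, term = ann$term,
                      aspect = ann$aspect, stringsAsFactors = FALSE))
  }
  # gene-level: invert protein -> gene
  genes <- unlist(ref$protein_to_gene, use.names = FALSE)
  prots <- rep(names(ref$protein_to_gene), lengths(ref$protein_to_gene))
  idx <- split(prots, genes)
  hit <- idx[ann$subject_id]
  n <- lengths(hit)
  data.frame(protein = unlist(hit, use.names = FALSE),
             term = rep(ann$term, n), aspect = rep(ann$aspect, n),
             stringsAsFactors = FALSE)
}

#' Transfer GO terms from reference proteins by homology
#'
#' For each query protein q with forward best hit r: if (q, r) is a
#' reciprocal best-hit pair, all of r's GO terms are transferred; otherwise,
#' if q's and r's domain profiles (signature sets) are identical, all of r's
#' terms are transferred; otherwise nothing. When the reference is human,
#' biological-process (aspect P) terms are never transferred. Transferred
#' records get evidence `IEA`, the reference protein id in `with_from`,
#' `source = "homology:<ref name>"`, and are re-subjected to the query genes
#' through `mapping_query`; a gene with several isoforms receives the union
#' over its proteins.
#'
#' @param rbh Data.frame of reciprocal pairs from [reciprocal_best_hits()].
#' @param fwd Forward `best_hit_map` (query -> reference).
#' @param profiles_query,profiles_ref Domain profile maps from
#'   [build_profiles()]; a protein absent from a map has an empty profile.
#' @param ref A [reference_set()].
#' @param mapping_query Named list query protein -> gene ids.
#' @return Deduplicated gene-level records with attribute `discards`
#'   (`unmapped`: query proteins with transfers but no gene mapping).
#' @export
transfer_homology <- function(rbh, fwd, profiles_query, profiles_ref, ref,
                              mapping_query) {
  ref_terms <- .ref_protein_terms(ref)
  rbh_key <- paste(rbh$query, rbh$ref, sep = "\r")
  out <- list()
  n_unmapped <- 0L
  for (q in names(fwd$best)) {
    r <- fwd$best[[q]]
    eligible <- paste(q, r, sep = "\r") %in% rbh_key
    if (!eligible) {
      pq <- profiles_query[[q]]; pr <- profiles_ref[[r]]
      if (is.null(pq)) pq <- character(0)
      if (is.null(pr)) pr <- character(0)
      eligible <- setequal(pq, pr)
    }
    if (!eligible) next
    tt <- ref_terms[ref_terms$protein == r, , drop = FALSE]
    if (ref$is_human) tt <- tt[tt$aspect != "P", , drop = FALSE]
    if (nrow(tt) == 0L) next
    genes <- mapping_query[[q]]
    if (is.null(genes) || length(genes) == 0L) {
      n_unmapped <- n_unmapped + 1L
      next
    }
    for (g in genes) {
      out <- c(out, list(annotation_records(
        subject_id = g, term = tt$term, aspect = tt$aspect,
        evidence = "IEA", source = paste0("homology:", ref$name),
        subject_kind = "gene", with_from = r, db_ref = "GO_REF:0000024"
      )))
    }
  }
  res <- dedup_records(bind_records(out))
  attr(res, "discards") <- c(unmapped = n_unmapped)
  res
}
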