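# Readers and writers for the tabular formats the pipeline touches:
# GAF 2.1, UniProt idmapping_selected.tab, InterProScan TSV, 12-column
# BLAST/FASTA tabular hits, and the GeneMerge association file.

.split_lines <- function(file, text = NULL) {
  if (is.null(text)) readLines(file, warn = FALSE) else text
}

#' Read a GAF 2.1 annotation file
#'
#' Lines starting with `!` are header/comment lines. Every record line must
#' have exactly 17 tab-separated columns (GAF 2.1). Column 13 (`taxon:NNNN`)
#' is parsed to an integer; an unparseable taxon field keeps the record with
#' taxon unset and increments a warning counter (attribute `taxon_warnings`).
#'
#' @param file Path to a GAF file (ignored when `text` is given).
#' @param text Optional character vector of GAF lines.
#' @param source Provenance tag attached to the records (default
#'   `"uniprot"`).
#' @param subject_kind Fallback subject kind when column 12 is neither
#'   `"gene"` nor `"protein"`.
#' @return Annotation records; attribute `taxon_warnings` counts malformed
#'   taxon fields.
#' @export
read_gaf <- function(file = NULL, text = NULL, source = "uniprot",
                     subject_kind = "protein") {
  lines <- .split_lines(file, text)
  idx <- which(!startsWith(lines, "!") & nzchar(lines))
  if (length(idx) == 0L) {
    out <- empty_records()
    attr(out, "taxon_warnings") <- 0L
    return(out)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  # a trailing empty column 17 is dropped by strsplit; restore it
  short <- nf == 16L & endsWith(lines[idx], "\t")
  fields[short] <- lapply(fields[short], function(f) c(f, ""))
  nf <- lengths(fields)
  if (any(nf != 17L)) {
    bad <- which(nf != 17L)[1]
    stop("GAF line ", idx[bad], ": expected 17 columns, got ", nf[bad])
  }
  m <- do.call(rbind, fields)
  taxon_raw <- sub("^taxon:", "", m[, 13])
  taxon <- suppressWarnings(as.integer(taxon_raw))
  n_warn <- sum(is.na(taxon) & nzchar(m[, 13]))
  kind <- ifelse(m[, 12] %in% c("gene", "protein"), m[, 12], subject_kind)
  out <- annotation_records(
    subject_id = m[, 2], term = m[, 5], aspect = m[, 9],
    evidence = m[, 7], source = source, subject_kind = kind,
    qualifier = m[, 4], with_from = m[, 8], db = m[, 1], symbol = m[, 3],
    db_ref = m[, 6], name = m[, 10], synonym = m[, 11],
    object_type = m[, 12], taxon = taxon, date = m[, 14],
    assigned_by = m[, 15], extension = m[, 16], form_id = m[, 17]
  )
  attr(out, "taxon_warnings") <- n_warn
  out
}

#' Write annotation records as GAF 2.1
#'
#' Emits the `!gaf-version: 2.1` header followed by one 17-column line per
#' record, sorted by (subject_id, term, evidence) so output is deterministic
#' and diffable. The internal `subject_kind` and `source` columns are not
#' part of GAF and are not written.
#'
#' @param records Annotation records.
#' @param file Output path or connection.
#' @export
write_gaf <- function(records, file) {
  if (nrow(records) > 0L) {
    bad <- !nzchar(records$subject_id) | !nzchar(records$term)
    if (any(bad))
      stop("record ", which(bad)[1], " is missing its subject id or GO term")
  }
  records <- records[order(records$subject_id, records$term,
                           records$evidence, records$source), , drop = FALSE]
  taxon <- ifelse(is.na(records$taxon), "",
                  paste0("taxon:", records$taxon))
  body <- do.call(paste, c(unname(as.list(
    cbind(records[, c("db", "subject_id", "symbol", "qualifier", "term",
                      "db_ref", "evidence", "with_from", "aspect", "name",
                      "synonym", "object_type")],
          taxon = taxon,
          records[, c("date", "assigned_by", "extension", "form_id")])
  )), list(sep = "\t")))
  writeLines(c("!gaf-version: 2.1", body), file)
}

#' Read a UniProt idmapping_selected.tab-style protein-to-gene table
#'
#' Tab-separated; one protein accession per line. The gene column may hold a
#' single id, several ids separated by `;`, or be empty. Proteins with an
#' empty gene field are omitted. Multi-valued fields yield multi-element gene
#' sets (the multi-gene exclusion rule is applied downstream, in
#' [ingest_uniprot()], not here).
#'
#' @param file Path (ignored when `text` given).
#' @param text Optional character vector of lines.
#' @param protein_col,gene_col 1-based column indices; defaults match
#'   idmapping_selected.tab (UniProtKB-AC in column 1, GeneID in column 3).
#' @return A named list: protein id -> character vector of gene ids.
#' @export
read_idmapping <- function(file = NULL, text = NULL, protein_col = 1L,
                           gene_col = 3L) {
  lines <- .split_lines(file, text)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(stats::setNames(list(), character(0)))
  # keep trailing empty fields (a line may end in an empty gene column)
  fields <- strsplit(paste0(lines, "\x01"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) {
    f[length(f)] <- sub("\x01$", "", f[length(f)])
    f
  })
  need <- max(protein_col, gene_col)
  nf <- lengths(fields)
  if (any(nf < need)) {
    bad <- which(nf < need)[1]
    stop("idmapping line ", bad, ": column index ", need,
         " out of range (line has ", nf[bad], " columns)")
  }
  prot <- vapply(fields, `[[`, character(1), protein_col)
  gene_raw <- vapply(fields, `[[`, character(1), gene_col)
  genes <- lapply(strsplit(gene_raw, ";", fixed = TRUE),
                  function(g) { g <- trimws(g); g[nzchar(g)] })
  keep <- lengths(genes) > 0L
  stats::setNames(genes[keep], prot[keep])
}

#' Read InterProScan TSV output
#'
#' Standard InterProScan tab-separated output with at least 11 columns:
#' protein accession (1), analysis/database (4), signature accession (5),
#' InterPro entry accession (12, optional) and pipe-separated GO ids
#' (14, optional; `-` or absent means none).
#'
#' @param file Path (ignored when `text` given).
#' @param text Optional character vector of lines.
#' @return A data.frame with columns `protein`, `analysis`, `signature`,
#'   `interpro` and a list-column `go_terms`.
#' @export
read_interproscan <- function(file = NULL, text = NULL) {
  lines <- .split_lines(file, text)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(protein = character(0), analysis = character(0),
                      signature = character(0), interpro = character(0),
                      go_terms = I(list()), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1]
    stop("InterProScan line ", bad, ": expected at least 11 columns, got ",
         nf[bad])
  }
  pick <- function(f, i) if (length(f) >= i) f[[i]] else ""
  go_raw <- vapply(fields, pick, character(1), 14L)
  go <- lapply(go_raw, function(x) {
    if (x %in% c("", "-")) character(0)
    else unlist(strsplit(x, "|", fixed = TRUE))
  })
  data.frame(
    protein = vapply(fields, `[[`, character(1), 1L),
    analysis = vapply(fields, `[[`, character(1), 4L),
    signature = vapply(fields, `[[`, character(1), 5L),
    interpro = vapply(fields, pick, character(1), 12L),
    go_terms = I(go), stringsAsFactors = FALSE
  )
}

#' Read 12-column tabular pairwise search results
#'
#' The BLAST `-outfmt 6` / FASTA `-m 8` layout: query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, E-value, bit score.
#'
#' @param file Path (ignored when `text` given).
#' @param text Optional character vector of lines.
#' @return A data.frame with one row per hit and numeric score fields.
#' @export
read_hits <- function(file = NULL, text = NULL) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- .split_lines(file, text)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 10)), cols),
      stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1]
    stop("hit table line ", bad, ": expected 12 columns, got ", nf[bad])
  }
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10)
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0L)[1]
    stop("hit table line ", bad, ": non-numeric score field")
  }
  out <- data.frame(query = m[, 1], subject = m[, 2],
                    stringsAsFactors = FALSE)
  for (i in seq_len(10)) out[[cols[i + 2]]] <- num[, i]
  out
}

#' Write a GeneMerge association file
#'
#' One line per gene: gene id, a tab, then the gene's GO terms sorted and
#' joined with `;`. Genes are emitted in lexicographic order. Records with
#' the `NOT` qualifier are excluded.
#'
#' @param records Gene-level annotation records.
#' @param file Output path or connection.
#' @export
write_genemerge <- function(records, file) {
  records <- drop_not_qualified(records)
  if (nrow(records) == 0L) {
    writeLines(character(0), file)
    return(invisible(NULL))
  }
  terms <- split(records$term, records$subject_id)
  genes <- sort(names(terms))
  body <- vapply(genes, function(g)
    paste0(g, "\t", paste(sort(unique(terms[[g]])), collapse = ";")),
    character(1))
  writeLines(unname(body), file)
}
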