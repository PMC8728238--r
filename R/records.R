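# Annotation records are plain data.frames with a fixed column set: the 17
# GAF 2.1 columns under stable internal names, plus two bookkeeping columns
# (subject_kind, source) that are never written to GAF.

.gaf_cols <- c("db", "subject_id", "symbol", "qualifier", "term", "db_ref",
               "evidence", "with_from", "aspect", "name", "synonym",
               "object_type", "taxon", "date", "assigned_by", "extension",
               "form_id")
.record_cols <- c(.gaf_cols, "subject_kind", "source")

#' Construct a set of annotation records
#'
#' An annotation record is one subject (gene or protein) x GO term assertion
#' with its aspect, evidence code and provenance. Records are held as a
#' data.frame whose columns cover all 17 GAF 2.1 fields plus two internal
#' columns: `subject_kind` ("gene" or "protein") and `source`, the provenance
#' tag (`"uniprot"`, `"interpro"`, `"homology:<ref>"`, `"inter-ontology"` or
#' `"closure"`).
#'
#' @param subject_id Gene or protein identifiers.
#' @param term GO identifiers (`GO:` + 7 digits).
#' @param aspect Aspect letters: `"F"`, `"P"` or `"C"`.
#' @param evidence GO evidence codes (default `"IEA"`).
#' @param source Provenance tag.
#' @param subject_kind `"gene"` or `"protein"`.
#' @param qualifier Optional qualifier, e.g. `"NOT"`.
#' @param with_from Supporting identifier(s), `|`-joined.
#' @param db,symbol,db_ref,name,synonym,object_type,taxon,date,assigned_by,extension,form_id
#'   Remaining GAF 2.1 fields; sensible defaults are supplied.
#' @return A data.frame of annotation records (zero rows if `subject_id` is
#'   empty). All columns are character except `taxon` (integer).
#' @export
annotation_records <- function(subject_id = character(), term = character(),
                               aspect = character(), evidence = "IEA",
                               source = "uniprot", subject_kind = "gene",
                               qualifier = "", with_from = "",
                               db = "HGD", symbol = NULL,
                               db_ref = "GO_REF:0000002",
                               name = "", synonym = "", object_type = NULL,
                               taxon = NA_integer_, date = "20200101",
                               assigned_by = "goxfer", extension = "",
                               form_id = "") {
  n <- max(length(subject_id), length(term))
  if (n == 0L) return(empty_records())
  if (is.null(symbol)) symbol <- subject_id
  if (is.null(object_type)) object_type <- subject_kind
  df <- data.frame(
    db = rep_len(as.character(db), n),
    subject_id = rep_len(as.character(subject_id), n),
    symbol = rep_len(as.character(symbol), n),
    qualifier = rep_len(as.character(qualifier), n),
    term = rep_len(as.character(term), n),
    db_ref = rep_len(as.character(db_ref), n),
    evidence = rep_len(as.character(evidence), n),
    with_from = rep_len(as.character(with_from), n),
    aspect = rep_len(as.character(aspect), n),
    name = rep_len(as.character(name), n),
    synonym = rep_len(as.character(synonym), n),
    object_type = rep_len(as.character(object_type), n),
    taxon = rep_len(as.integer(taxon), n),
    date = rep_len(as.character(date), n),
    assigned_by = rep_len(as.character(assigned_by), n),
    extension = rep_len(as.character(extension), n),
    form_id = rep_len(as.character(form_id), n),
    subject_kind = rep_len(as.character(subject_kind), n),
    source = rep_len(as.character(source), n),
    stringsAsFactors = FALSE
  )
  df
}

#' @rdname annotation_records
#' @export
empty_records <- function() {
  df <- as.data.frame(
    c(lapply(stats::setNames(.gaf_cols, .gaf_cols),
             function(x) character(0)),
      list(subject_kind = character(0), source = character(0))),
    stringsAsFactors = FALSE
  )
  df$taxon <- integer(0)
  df[, .record_cols]
}

# rbind records, tolerating empty/NULL members
bind_records <- function(sets) {
  sets <- Filter(function(x) !is.null(x) && nrow(x) > 0L, sets)
  if (length(sets) == 0L) return(empty_records())
  do.call(rbind, c(sets, list(make.row.names = FALSE)))
}

#' Deduplicate annotation records
#'
#' Collapses records on the key (subject_id, term, evidence, source). Records
#' that differ only in `with_from` merge into one record whose `with_from` is
#' the sorted, `|`-joined union of the supporting identifiers. Output rows are
#' sorted by the key, giving a canonical order.
#'
#' @param records Annotation record data.frame.
#' @return Deduplicated, sorted records.
#' @export
dedup_records <- function(records) {
  if (nrow(records) == 0L) return(empty_records())
  key <- paste(records$subject_id, records$term, records$evidence,
               records$source, sep = "\r")
  wf <- vapply(split(records$with_from, key), function(w) {
    parts <- unlist(strsplit(w[nzchar(w)], "|", fixed = TRUE))
    paste(sort(unique(parts)), collapse = "|")
  }, character(1))
  keep <- !duplicated(key)
  out <- records[keep, , drop = FALSE]
  out$with_from <- unname(wf[match(key[keep], names(wf))])
  out <- out[order(out$subject_id, out$term, out$evidence, out$source), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# positive annotations only (NOT-qualified records are never merged or
# transferred)
drop_not_qualified <- function(records) {
  records[!grepl("\\bNOT\\b", records$qualifier), , drop = FALSE]
}
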