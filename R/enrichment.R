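# GO term over-representation analysis: exact hypergeometric test of a
# study gene list against a background, over ancestor-closed annotations.

#' Multiple-testing correction
#'
#' `bonferroni` returns `min(1, p * m)` with `m` the number of tests;
#' `bh` returns Benjamini-Hochberg step-up adjusted values.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @param method `"bonferroni"` (default) or `"bh"`.
#' @return Corrected p-values, same length and order as the input.
#' @export
correct_pvalues <- function(p_values, method = c("bonferroni", "bh")) {
  if (!is.character(method) || !all(method %in% c("bonferroni", "bh")))
    stop("unknown correction method: ", paste(method, collapse = ", "))
  method <- match.arg(method)
  stats::p.adjust(p_values, method = if (method == "bh") "BH" else
    "bonferroni")
}

#' GO term enrichment by the exact hypergeometric test
#'
#' For every term annotated to at least one study gene (k >= 1) and one
#' background gene (K >= 1), computes the upper-tail hypergeometric
#' probability of observing at least k annotated genes in a study list of
#' size n drawn from a background of size N containing K annotated genes.
#' Unannotated background genes count in N (the GeneMerge population
#' convention). Annotations should be ancestor-closed so counts are
#' monotone along the ontology.
#'
#' @param study Character vector of study gene ids; must be a non-empty
#'   subset of `background`.
#' @param background Character vector of background (population) gene ids.
#' @param records Gene-level annotation records (closed); `NOT`-qualified
#'   records are ignored.
#' @param graph Optional `go_ontology` used to attach term names/aspects.
#' @param method Correction method passed to [correct_pvalues()].
#' @param alternative `"greater"` (over-representation, default) or
#'   `"less"` (under-representation).
#' @return Data.frame with one row per tested term: `term`, `name`,
#'   `aspect`, `N`, `K`, `n`, `k`, `p_raw`, `p_corrected`, `method`, sorted
#'   by `p_corrected` then term id.
#' @export
enrich <- function(study, background, records, graph = NULL,
                   method = c("bonferroni", "bh"),
                   alternative = c("greater", "less")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  study <- unique(study)
  background <- unique(background)
  if (length(study) == 0L) stop("empty study set")
  extra <- setdiff(study, background)
  if (length(extra))
    stop("study genes missing from background: ",
         paste(extra, collapse = ", "))
  records <- drop_not_qualified(records)
  records <- records[records$subject_id %in% background, , drop = FALSE]
  records <- records[!duplicated(paste(records$subject_id, records$term)), ,
                     drop = FALSE]
  N <- length(background)
  n <- length(study)
  genes_by_term <- split(records$subject_id, records$term)
  K <- lengths(genes_by_term)
  k <- vapply(genes_by_term, function(g) sum(g %in% study), integer(1))
  keep <- K >= 1L & k >= 1L
  terms <- names(genes_by_term)[keep]
  K <- unname(K[keep]); k <- unname(k[keep])
  if (length(terms) == 0L) {
    out <- data.frame(term = character(0), name = character(0),
                      aspect = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p_raw = numeric(0),
                      p_corrected = numeric(0), method = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  p_raw <- if (alternative == "greater") {
    stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  }
  p_corr <- correct_pvalues(p_raw, method)
  nm <- rep("", length(terms)); asp <- rep("", length(terms))
  if (!is.null(graph)) {
    i <- match(terms, graph$terms$id)
    nm <- ifelse(is.na(i), "", graph$terms$name[i])
    asp <- ifelse(is.na(i), "", unname(.aspect_letter[graph$terms$aspect[i]]))
  }
  out <- data.frame(term = terms, name = nm, aspect = asp, N = N, K = K,
                    n = n, k = k, p_raw = p_raw, p_corrected = p_corr,
                    method = method, stringsAsFactors = FALSE)
  out <- out[order(out$p_corrected, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a plain-text gene list (one id per line)
#'
#' @param file Path; blank lines and `#` comments are skipped.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(file) {
  x <- trimws(readLines(file, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
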