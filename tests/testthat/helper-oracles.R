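# Independent oracles and small fixture builders used across the suite.

# OBO text for a term list; each term: list(id, ns, is_a = chr(), rel =
# named chr (relation -> parent), obsolete = FALSE, alt = chr())
make_obo <- function(terms) {
  out <- c("format-version: 1.2", "")
  for (t in terms) {
    out <- c(out, "[Term]", paste0("id: ", t$id),
             paste0("name: ", t$id),
             paste0("namespace: ", t$ns %||% "molecular_function"))
    for (a in t$alt %||% character(0)) out <- c(out, paste0("alt_id: ", a))
    for (p in t$is_a %||% character(0)) out <- c(out, paste0("is_a: ", p))
    rel <- t$rel %||% character(0)
    for (i in seq_along(rel))
      out <- c(out, paste0("relationship: ", names(rel)[i], " ", rel[i]))
    if (isTRUE(t$obsolete)) out <- c(out, "is_obsolete: true")
    out <- c(out, "")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random single-aspect DAG as OBO text; forward edges only, so acyclic
random_obo <- function(n, p = 0.15, seed = 1) {
  set.seed(seed)
  ids <- sprintf("GO:%07d", seq_len(n))
  edges <- data.frame(child = character(0), relation = character(0),
                      parent = character(0), stringsAsFactors = FALSE)
  terms <- list()
  for (i in seq_len(n)) {
    is_a <- character(0); rel <- character(0)
    if (i > 1L) for (j in seq_len(i - 1L)) if (stats::runif(1) < p) {
      lab <- sample(c("is_a", "part_of"), 1L)
      if (lab == "is_a") is_a <- c(is_a, ids[j])
      else rel <- c(rel, stats::setNames(ids[j], "part_of"))
      edges <- rbind(edges, data.frame(child = ids[i], relation = lab,
                                       parent = ids[j],
                                       stringsAsFactors = FALSE))
    }
    terms[[i]] <- list(id = ids[i], is_a = is_a, rel = rel)
  }
  list(text = make_obo(terms), ids = ids, edges = edges)
}

# transitive reachability by repeated boolean matrix products — an oracle
# independent of the package's graph traversal
reach_matrix <- function(ids, edges, relations) {
  A <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  e <- edges[edges$relation %in% relations, , drop = FALSE]
  if (nrow(e)) A[cbind(match(e$child, ids), match(e$parent, ids))] <- TRUE
  R <- A
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

oracle_ancestors <- function(R, term) sort(colnames(R)[R[term, ]])

# complete-enumeration hypergeometric oracle: probability that a uniformly
# random study subset of size n has at least k_obs genes annotated to the
# term, enumerated over every subset of the background
enum_upper_tail <- function(background, annotated, n, k_obs) {
  subs <- utils::combn(background, n, simplify = FALSE)
  mean(vapply(subs, function(S) sum(S %in% annotated) >= k_obs, logical(1)))
}

# one tab-separated hit line
hit_line <- function(q, s, bits, ev = signif(10^(-bits / 10), 3)) {
  paste(q, s, "50.0", "200", "10", "2", "1", "200", "1", "200",
        format(ev, scientific = TRUE), bits, sep = "\t")
}

# one GAF 2.1 record line
gaf_line <- function(id = "P00001", term = "GO:0000001", ev = "IDA",
                     aspect = "F", qual = "", with = "",
                     taxon = "taxon:7460") {
  paste("UniProtKB", id, id, qual, term, "GO_REF:0000033", ev, with,
        aspect, "", "", "protein", taxon, "20200101", "SynthGOA", "", "",
        sep = "\t")
}

# one InterProScan TSV line
ipr_line <- function(p = "P1", db = "Pfam", sig = "PF00001", go = "-") {
  paste(p, "-", "300", db, sig, "-", "1", "100", "1e-10", "T", "-", "-",
        "-", go, sep = "\t")
}
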