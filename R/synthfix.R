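# Synthetic fixture bundles: a self-consistent ontology, reference and query
# annotation inputs, bidirectional hit tables and InterProScan output with
# planted ground truth (orthologue pairs, expected transfers, expected
# discard counts), so every pipeline stage is testable without downloads.

#' Specify a synthetic fixture bundle
#'
#' @param seed Master seed; one derived pseudo-random stream is used per
#'   file type, so a fixed seed yields a byte-identical bundle.
#' @param n_terms Terms per GO aspect in the generated ontology.
#' @param dag_density Probability of each optional extra parent edge.
#' @param n_ref_genes,n_query_genes Genes (one searched protein each) on the
#'   reference and query sides.
#' @param orthologue_fraction Fraction of query genes given a planted
#'   one-to-one reference orthologue (mutual best hits with dominant
#'   scores).
#' @param domain_vocab_size Size of the domain signature vocabulary.
#' @param profile_match_fraction Fraction of non-orthologous best-hit pairs
#'   given identical domain profiles (hence eligible for transfer).
#' @param n_multi_gene UniProt accessions mapped to more than one gene
#'   (their annotations must be discarded).
#' @param n_unmapped UniProt accessions annotated in the GAF but absent
#'   from the idmapping table.
#' @param human_mode If TRUE the reference is flagged human, so
#'   biological-process terms must not be transferred.
#' @return A validated `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_terms = 40L, dag_density = 0.08,
                         n_ref_genes = 60L, n_query_genes = 80L,
                         orthologue_fraction = 0.4,
                         domain_vocab_size = 40L,
                         profile_match_fraction = 0.5,
                         n_multi_gene = 3L, n_unmapped = 2L,
                         human_mode = FALSE) {
  spec <- list(seed = as.integer(seed), n_terms = as.integer(n_terms),
               dag_density = dag_density, n_ref_genes = as.integer(n_ref_genes),
               n_query_genes = as.integer(n_query_genes),
               orthologue_fraction = orthologue_fraction,
               domain_vocab_size = as.integer(domain_vocab_size),
               profile_match_fraction = profile_match_fraction,
               n_multi_gene = as.integer(n_multi_gene),
               n_unmapped = as.integer(n_unmapped),
               human_mode = isTRUE(human_mode))
  fr <- c(spec$dag_density, spec$orthologue_fraction,
          spec$profile_match_fraction)
  if (any(fr < 0 | fr > 1)) stop("fixture spec: fractions must be in [0, 1]")
  n_orth <- round(spec$orthologue_fraction * spec$n_query_genes)
  if (n_orth > 0L && spec$n_ref_genes == 0L)
    stop("infeasible fixture spec: orthologue_fraction > 0 with zero ",
         "reference genes")
  if (n_orth > spec$n_ref_genes)
    stop("infeasible fixture spec: more planted orthologues than reference ",
         "genes")
  structure(spec, class = "fixture_spec")
}

.substream <- function(seed, offset)
  set.seed((as.numeric(seed) * 1009 + offset) %% 2147483647)

.go_id <- function(i) sprintf("GO:%07d", i)

# random DAG ontology: ranked terms with forward edges only (acyclic by
# construction); per-aspect blocks plus cross-aspect link edges
.gen_ontology <- function(spec) {
  n <- spec$n_terms
  aspects <- c("molecular_function", "biological_process",
               "cellular_component")
  block <- function(a) ((match(a, aspects) - 1L) * n + 1L):(match(a, aspects) * n)
  stanzas <- character(0)
  edges <- list()
  for (a in aspects) {
    ids <- block(a)
    for (j in seq_along(ids)) {
      i <- ids[j]
      lines <- c("[Term]", paste0("id: ", .go_id(i)),
                 paste0("name: synthetic term ", i),
                 paste0("namespace: ", a))
      if (j > 1L) {
        mand <- ids[sample.int(j - 1L, 1L)]
        rel <- c(is_a = .go_id(mand))
        for (p in setdiff(ids[seq_len(j - 1L)], mand))
          if (stats::runif(1) < spec$dag_density) {
            lab <- sample(c("is_a", "part_of"), 1L, prob = c(0.7, 0.3))
            rel <- c(rel, stats::setNames(.go_id(p), lab))
          }
        for (x in seq_along(rel)) {
          lines <- c(lines, if (names(rel)[x] == "is_a")
            paste0("is_a: ", rel[x])
            else paste0("relationship: ", names(rel)[x], " ", rel[x]))
        }
      }
      stanzas <- c(stanzas, lines, "")
    }
  }
  # cross-aspect link edges: MF --part_of--> BP, BP --occurs_in--> CC
  n_cross <- min(3L, n - 1L)
  mf_src <- sort(sample(block("molecular_function")[-1], n_cross))
  bp_tgt <- sample(block("biological_process"), n_cross)
  bp_src <- sort(sample(block("biological_process")[-1], n_cross))
  cc_tgt <- sample(block("cellular_component"), n_cross)
  inject <- function(stanzas, src, tgt, rel) {
    for (x in seq_along(src)) {
      at <- which(stanzas == paste0("id: ", .go_id(src[x])))
      stanzas <- append(stanzas,
                        paste0("relationship: ", rel, " ", .go_id(tgt[x])),
                        after = at + 2L)
    }
    stanzas
  }
  stanzas <- inject(stanzas, mf_src, bp_tgt, "part_of")
  stanzas <- inject(stanzas, bp_src, cc_tgt, "occurs_in")
  # one obsolete term and one alt_id
  obs_id <- 3L * n + 1L
  stanzas <- c(stanzas,
               "[Term]", paste0("id: ", .go_id(obs_id)),
               "name: synthetic obsolete term",
               "namespace: molecular_function",
               "is_obsolete: true", "")
  alt_host <- .go_id(n + 2L)  # a biological-process term
  at <- which(stanzas == paste0("id: ", alt_host))
  stanzas <- append(stanzas, "alt_id: GO:0900001", after = at)
  list(text = c("format-version: 1.2",
                "ontology: go-synthetic", "", stanzas),
       obsolete = .go_id(obs_id),
       usable = .go_id(setdiff(seq_len(3L * n),
                               c(1L, n + 1L, 2L * n + 1L))),  # non-roots
       aspect_of = stats::setNames(
         rep(c("F", "P", "C"), each = n), .go_id(seq_len(3L * n))))
}

.ipr_line <- function(protein, analysis, signature, go = "-") {
  paste(protein, "-", "300", analysis, signature, "-", "1", "100",
        "1.0E-10", "T", "-", "-", "-", go, sep = "\t")
}

.hit_line <- function(q, s, bitscore, ev = signif(10^(-bitscore / 10), 3)) {
  paste(q, s, format(round(stats::runif(1, 30, 95), 1), nsmall = 1),
        "200", "10", "2", "1", "200", "1", "200",
        format(ev, scientific = TRUE), format(bitscore, nsmall = 1),
        sep = "\t")
}

#' Generate a synthetic fixture bundle with planted ground truth
#'
#' Writes, under `dir`: a `go.obo` ontology (random DAG per aspect plus
#' cross-aspect links, one obsolete term, one alt_id), a protein-level
#' reference GAF, reference and query InterProScan TSVs realizing the
#' planted profile (in)equalities, hit tables in both directions in which
#' planted orthologues are mutual best hits with dominant bit scores and
#' decoys are strictly one-directional, a UniProt-style GAF + idmapping
#' with planted multi-gene and unmapped accessions, a query
#' protein-to-gene table, and a ready-to-run `config.yaml`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created).
#' @return List with `dir`, `config` (path), `files` (named paths) and
#'   `truth`: the planted ground truth (`pairs`, `expected_transfer` per
#'   query gene pre-closure, `discards`, `human_mode`).
#' @export
make_bundle <- function(spec = fixture_spec(), dir = tempfile("bundle")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)

  ## ontology ----------------------------------------------------------
  .substream(spec$seed, 11)
  ont <- .gen_ontology(spec)
  writeLines(ont$text, fp("go.obo"))

  ref_name <- if (spec$human_mode) "human" else "refA"
  n_ref <- spec$n_ref_genes
  n_query <- spec$n_query_genes
  rp <- sprintf("RP%04d", seq_len(n_ref))
  rg <- sprintf("RG%04d", seq_len(n_ref))
  qp <- sprintf("QP%04d", seq_len(n_query))
  qg <- sprintf("QG%04d", seq_len(n_query))

  ## reference annotations ---------------------------------------------
  .substream(spec$seed, 23)
  ref_terms <- lapply(seq_len(n_ref), function(i)
    sort(sample(ont$usable, sample.int(3L, 1L))))
  names(ref_terms) <- rp
  ref_rec <- bind_records(lapply(seq_len(n_ref), function(i)
    annotation_records(
      subject_id = rp[i], term = ref_terms[[i]],
      aspect = unname(ont$aspect_of[ref_terms[[i]]]),
      evidence = sample(c("IDA", "ISS", "IEA"), length(ref_terms[[i]]),
                        replace = TRUE),
      source = "reference", subject_kind = "protein", db = "UniProtKB",
      taxon = if (spec$human_mode) 9606L else 7227L,
      assigned_by = "SynthGOA")))
  write_gaf(dedup_records(ref_rec), fp(paste0("ref_", ref_name, ".gaf")))

  ## planted orthology + hit tables ------------------------------------
  .substream(spec$seed, 37)
  n_orth <- round(spec$orthologue_fraction * n_query)
  planted_q <- if (n_orth > 0L) sort(sample.int(n_query, n_orth)) else integer(0)
  planted_r <- if (n_orth > 0L) sample.int(n_ref, n_orth) else integer(0)
  decoy_q <- setdiff(seq_len(n_query), planted_q)

  fwd <- character(0); rev <- character(0)
  # planted pairs: dominant, mutual
  for (x in seq_along(planted_q)) {
    i <- planted_q[x]; j <- planted_r[x]
    fwd <- c(fwd, .hit_line(qp[i], rp[j], round(stats::runif(1, 300, 400), 1)))
    rev <- c(rev, .hit_line(rp[j], qp[i], round(stats::runif(1, 300, 400), 1)))
    if (n_ref > 1L) {
      other <- sample(setdiff(seq_len(n_ref), j), 1L)
      fwd <- c(fwd, .hit_line(qp[i], rp[other],
                              round(stats::runif(1, 50, 150), 1)))
    }
  }
  # decoy queries: one-directional hits only; record each decoy's best
  decoy_best <- stats::setNames(character(0), character(0))
  if (length(decoy_q) > 0L && n_ref > 0L) {
    for (i in decoy_q) {
      tgt <- sample.int(n_ref, min(2L, n_ref))
      bs <- round(stats::runif(length(tgt), 50, 150), 1)
      for (x in seq_along(tgt))
        fwd <- c(fwd, .hit_line(qp[i], rp[tgt[x]], bs[x]))
      ev <- signif(10^(-bs / 10), 3)
      pick <- order(-bs, ev, rp[tgt])[1]   # same rule as best_hits()
      decoy_best[qp[i]] <- rp[tgt[pick]]
    }
  }
  # reverse anchors keep decoy best hits non-reciprocal: each unpaired
  # reference that is somebody's best points back to a query OUTSIDE the
  # set of queries whose best it is
  for (r in unique(unname(decoy_best))) {
    q_r <- names(decoy_best)[decoy_best == r]
    anchor <- setdiff(qp, q_r)[1]
    if (!is.na(anchor))
      rev <- c(rev, .hit_line(r, anchor, 200.0))
  }
  # two over-threshold hits, excluded before best-hit selection
  n_over <- if (n_ref > 0L) min(2L, n_query) else 0L
  for (i in seq_len(n_over))
    fwd <- c(fwd, .hit_line(qp[i], rp[((i - 1L) %% n_ref) + 1L], 20.0,
                            ev = 0.5))
  writeLines(fwd, fp(paste0("hits_query_to_", ref_name, ".tsv")))
  writeLines(rev, fp(paste0("hits_", ref_name, "_to_query.tsv")))

  ## domain profiles + InterProScan TSVs -------------------------------
  .substream(spec$seed, 53)
  analyses4 <- c("Pfam", "SMART", "SUPERFAMILY", "PANTHER")
  vocab <- sprintf("SIG%05d", seq_len(spec$domain_vocab_size))
  vocab_db <- analyses4[((seq_along(vocab) - 1L) %% 4L) + 1L]
  rand_profile <- function()
    sort(sample(seq_along(vocab), sample.int(4L, 1L)))
  ref_prof <- lapply(seq_len(n_ref), function(i) rand_profile())
  names(ref_prof) <- rp
  q_prof <- list(); q_extra <- list()
  matched_decoys <- character(0)
  for (i in seq_len(n_query)) {
    p <- qp[i]
    if (p %in% names(decoy_best)) {
      r <- decoy_best[[p]]
      if (stats::runif(1) < spec$profile_match_fraction) {
        q_prof[[p]] <- ref_prof[[r]]          # identical domain content
        matched_decoys <- c(matched_decoys, p)
      } else {
        q_prof[[p]] <- rand_profile()
        q_extra[[p]] <- sprintf("QX%04d", i)  # guarantees inequality
      }
    } else {
      q_prof[[p]] <- rand_profile()
    }
  }
  # domain-derived GO terms on ~30% of query proteins
  dom_go <- lapply(seq_len(n_query), function(i)
    if (stats::runif(1) < 0.3)
      sort(sample(ont$usable, sample.int(2L, 1L))) else character(0))
  names(dom_go) <- qp

  ipr_rows <- function(p, prof_idx, extra = NULL, go = character(0)) {
    sigs <- c(vocab[prof_idx], extra)
    dbs <- c(vocab_db[prof_idx], rep("Pfam", length(extra)))
    out <- character(0)
    for (x in seq_along(sigs))
      out <- c(out, .ipr_line(p, dbs[x], sigs[x],
                              if (x == 1L && length(go))
                                paste(go, collapse = "|") else "-"))
    out
  }
  q_tsv <- unlist(lapply(seq_len(n_query), function(i)
    ipr_rows(qp[i], q_prof[[qp[i]]], q_extra[[qp[i]]], dom_go[[qp[i]]])))
  # non-domain analyses are ignored by profile construction
  q_tsv <- c(q_tsv, vapply(qp[seq_len(min(3L, n_query))], function(p)
    .ipr_line(p, "Coils", "Coil"), character(1)))
  writeLines(q_tsv, fp("query.interproscan.tsv"))
  r_tsv <- unlist(lapply(seq_len(n_ref), function(i)
    ipr_rows(rp[i], ref_prof[[rp[i]]])))
  writeLines(r_tsv, fp(paste0("ref_", ref_name, ".interproscan.tsv")))

  ## UniProt GAF + idmapping -------------------------------------------
  .substream(spec$seed, 89)
  n_uni <- max(1L, round(0.25 * n_query))
  uni_genes <- sort(sample.int(n_query, min(n_uni, n_query)))
  up <- sprintf("UP%04d", seq_along(uni_genes))
  uni_rec <- bind_records(lapply(seq_along(up), function(x) {
    tt <- sort(sample(ont$usable, sample.int(3L, 1L)))
    annotation_records(subject_id = up[x], term = tt,
                       aspect = unname(ont$aspect_of[tt]),
                       evidence = sample(c("IDA", "IMP", "IEA"), length(tt),
                                         replace = TRUE),
                       subject_kind = "protein", db = "UniProtKB",
                       taxon = 7460L, assigned_by = "SynthGOA")
  }))
  idmap_lines <- sprintf("%s\t%s_SYN\t%s", up, up, qg[uni_genes])
  # one annotation to the obsolete term (dropped at closure)
  obs_acc <- "UPOBS1"
  uni_rec <- bind_records(list(uni_rec, annotation_records(
    subject_id = obs_acc, term = ont$obsolete, aspect = "F",
    evidence = "IEA", subject_kind = "protein", db = "UniProtKB",
    taxon = 7460L, assigned_by = "SynthGOA")))
  idmap_lines <- c(idmap_lines,
                   sprintf("%s\t%s_SYN\t%s", obs_acc, obs_acc, qg[1]))
  # multi-gene accessions: annotated, but must be excluded
  if (spec$n_multi_gene > 0L) {
    upm <- sprintf("UPM%04d", seq_len(spec$n_multi_gene))
    g2 <- vapply(seq_along(upm), function(x) paste(
      qg[((2L * x - 2L) %% n_query) + 1L],
      qg[((2L * x - 1L) %% n_query) + 1L], sep = "; "), character(1))
    idmap_lines <- c(idmap_lines, sprintf("%s\t%s_SYN\t%s", upm, upm, g2))
    uni_rec <- bind_records(c(list(uni_rec), lapply(upm, function(p) {
      t1 <- sample(ont$usable, 1L)
      annotation_records(subject_id = p, term = t1,
                         aspect = unname(ont$aspect_of[t1]),
                         evidence = "IDA", subject_kind = "protein",
                         db = "UniProtKB", taxon = 7460L,
                         assigned_by = "SynthGOA")
    })))
  }
  # annotated accessions missing from the idmapping table
  if (spec$n_unmapped > 0L) {
    upx <- sprintf("UPX%04d", seq_len(spec$n_unmapped))
    uni_rec <- bind_records(c(list(uni_rec), lapply(upx, function(p) {
      t1 <- sample(ont$usable, 1L)
      annotation_records(subject_id = p, term = t1,
                         aspect = unname(ont$aspect_of[t1]),
                         evidence = "IDA", subject_kind = "protein",
                         db = "UniProtKB", taxon = 7460L,
                         assigned_by = "SynthGOA")
    })))
  }
  write_gaf(dedup_records(uni_rec), fp("query.uniprot.gaf"))
  writeLines(idmap_lines, fp("idmapping.tsv"))
  writeLines(sprintf("%s\t%s", qp, qg), fp("query.protein_to_gene.tsv"))

  ## ground truth -------------------------------------------------------
  gene_of <- stats::setNames(qg, qp)
  expected <- list()
  add_expected <- function(q, r) {
    tt <- ref_terms[[r]]
    if (spec$human_mode) tt <- tt[ont$aspect_of[tt] != "P"]
    g <- gene_of[[q]]
    expected[[g]] <<- sort(unique(c(expected[[g]], tt)))
  }
  for (x in seq_along(planted_q)) add_expected(qp[planted_q[x]],
                                               rp[planted_r[x]])
  for (p in matched_decoys) add_expected(p, decoy_best[[p]])
  truth <- list(
    pairs = data.frame(query = qp[planted_q], ref = rp[planted_r],
                       stringsAsFactors = FALSE)[
                         order(qp[planted_q]), , drop = FALSE],
    expected_transfer = expected,
    discards = list(uniprot_multi_gene = spec$n_multi_gene,
                    uniprot_unmapped = spec$n_unmapped,
                    obsolete_terms = 1L,
                    over_threshold_hits = n_over),
    human_mode = spec$human_mode,
    ref_name = ref_name
  )
  rownames(truth$pairs) <- NULL

  ## config --------------------------------------------------------------
  cfg <- list(
    species = "querysp", taxon = 7460L, assigned_by = "goxfer",
    ontology = "go.obo",
    uniprot_gaf = "query.uniprot.gaf",
    idmapping = "idmapping.tsv",
    idmapping_protein_col = 1L, idmapping_gene_col = 3L,
    protein_to_gene = "query.protein_to_gene.tsv",
    interproscan = "query.interproscan.tsv",
    evalue = 1e-5,
    analyses = analyses4,
    references = list(list(
      name = ref_name, is_human = spec$human_mode,
      gaf = paste0("ref_", ref_name, ".gaf"),
      interproscan = paste0("ref_", ref_name, ".interproscan.tsv"),
      hits_fwd = paste0("hits_query_to_", ref_name, ".tsv"),
      hits_rev = paste0("hits_", ref_name, "_to_query.tsv")
    ))
  )
  yaml::write_yaml(cfg, fp("config.yaml"))

  files <- list.files(dir, full.names = TRUE)
  list(dir = dir, config = fp("config.yaml"),
       files = stats::setNames(files, basename(files)), truth = truth)
}

#' Check pipeline output against a bundle's planted ground truth
#'
#' Verifies that (a) the recovered reciprocal best-hit pairs equal the
#' planted pairs, (b) every planted query gene carries exactly its expected
#' transferred terms (homology provenance) and all their ancestors, (c) a
#' human-mode bundle yields zero transferred biological-process records,
#' and (d) the pipeline's discard counters match the planted counts.
#'
#' @param truth Ground truth from [make_bundle()].
#' @param result Return value of [run_pipeline()] on the bundle.
#' @return A `recovery_report`: list with `pass` (logical) and `failures`
#'   (character vector describing each failed check).
#' @export
verify_recovery <- function(truth, result) {
  failures <- character(0)
  fail <- function(msg) failures <<- c(failures, msg)

  # (a) reciprocal best hits
  rbh <- result$rbh[[truth$ref_name]]
  got <- paste(rbh$query, rbh$ref, sep = "->")
  want <- paste(truth$pairs$query, truth$pairs$ref, sep = "->")
  if (!setequal(got, want)) {
    miss <- setdiff(want, got); extra <- setdiff(got, want)
    fail(paste0("RBH mismatch: missing [",
                paste(miss, collapse = ", "), "] extra [",
                paste(extra, collapse = ", "), "]"))
  }

  # (b) transferred term sets and their ancestors
  rec <- result$records
  hom <- rec[startsWith(rec$source, "homology:"), , drop = FALSE]
  hom_by_gene <- lapply(split(hom$term, hom$subject_id),
                        function(x) sort(unique(x)))
  all_by_gene <- lapply(split(rec$term, rec$subject_id), unique)
  genes <- union(names(truth$expected_transfer), names(hom_by_gene))
  for (g in genes) {
    exp_t <- truth$expected_transfer[[g]]
    if (is.null(exp_t)) exp_t <- character(0)
    got_t <- hom_by_gene[[g]]
    if (is.null(got_t)) got_t <- character(0)
    if (!setequal(exp_t, got_t))
      fail(paste0("gene ", g, ": transferred terms {",
                  paste(got_t, collapse = ","), "} != expected {",
                  paste(exp_t, collapse = ","), "}"))
    if (length(exp_t)) {
      anc <- unique(unlist(lapply(exp_t, function(t)
        ancestors(result$graph, t))))
      missing <- setdiff(anc, all_by_gene[[g]])
      if (length(missing))
        fail(paste0("gene ", g, ": missing ancestors ",
                    paste(missing, collapse = ",")))
    }
  }

  # (c) no biological-process transfer from a human reference
  if (truth$human_mode && any(hom$aspect == "P"))
    fail("human-mode bundle contains transferred aspect-P records")

  # (d) discard counters
  d <- result$summary$discards
  for (nm in names(truth$discards)) {
    got_d <- d[[nm]]
    if (is.null(got_d)) got_d <- NA_integer_
    if (!identical(as.integer(got_d), as.integer(truth$discards[[nm]])))
      fail(paste0("discard counter ", nm, ": got ", got_d, ", expected ",
                  truth$discards[[nm]]))
  }

  structure(list(pass = length(failures) == 0L, failures = failures),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  if (x$pass) cat("recovery report: all checks passed\n")
  else cat("recovery report:", length(x$failures), "failure(s)\n -",
           paste(x$failures, collapse = "\n - "), "\n")
  invisible(x)
}
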