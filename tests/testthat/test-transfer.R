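test_that("ingest_uniprot applies the multi-gene exclusion rule", {
  rec <- annotation_records(
    subject_id = c("P1", "P1", "P2", "P3"),
    term = sprintf("GO:%07d", 1:4), aspect = "F",
    evidence = c("IDA", "IEA", "IDA", "IDA"), subject_kind = "protein")
  mapping <- list(P1 = "G1", P2 = c("G1", "G2"))

  out <- ingest_uniprot(rec, mapping)
  expect_equal(nrow(out), 2L)               # P1's two terms on G1
  expect_setequal(out$subject_id, "G1")
  expect_setequal(out$evidence, c("IDA", "IEA"))  # evidence preserved
  expect_equal(unique(out$source), "uniprot")
  expect_equal(unique(out$subject_kind), "gene")
  d <- attr(out, "discards")
  expect_equal(d[["multi_gene"]], 1L)       # P2 contributes nothing
  expect_equal(d[["unmapped"]], 1L)         # P3 contributes nothing
})

test_that("NOT-qualified records never enter the gene-level set", {
  rec <- annotation_records("P1", "GO:0000001", "F", qualifier = "NOT",
                            subject_kind = "protein")
  out <- ingest_uniprot(rec, list(P1 = "G1"))
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "discards")[["not_qualifier"]], 1L)
})

test_that("extract_domain_go yields one record per gene-term pair", {
  rows <- read_interproscan(text = c(
    paste("P1", "-", "1", "Pfam", "PF00001", "-", "1", "9", "1", "T", "-",
          "-", "-", "GO:0000001|GO:0000002", sep = "\t"),
    paste("P1", "-", "1", "SMART", "SM00001", "-", "1", "9", "1", "T", "-",
          "-", "-", "GO:0000001", sep = "\t"),
    paste("P2", "-", "1", "Pfam", "PF00002", "-", "1", "9", "1", "T", "-",
          "-", "-", "-", sep = "\t"),
    paste("P3", "-", "1", "Pfam", "PF00003", "-", "1", "9", "1", "T", "-",
          "-", "-", "GO:0000009", sep = "\t")))
  out <- extract_domain_go(rows, list(P1 = "G1", P2 = "G2"))
  expect_equal(nrow(out), 2L)  # two distinct (G1, term) pairs
  expect_setequal(out$term, c("GO:0000001", "GO:0000002"))
  # the shared GO id keeps both supporting signatures
  expect_equal(out$with_from[out$term == "GO:0000001"], "PF00001|SM00001")
  expect_equal(unique(out$evidence), "IEA")
  expect_equal(attr(out, "discards")[["unmapped"]], 1L)  # P3 has no gene
})

test_that("build_profiles restricts to the configured analyses", {
  rows <- read_interproscan(text = c(
    paste("P1", "-", "1", "Pfam", "PF00001", "-", "1", "9", "1", "T", "-",
          sep = "\t"),
    paste("P1", "-", "1", "Pfam", "PF00002", "-", "1", "9", "1", "T", "-",
          sep = "\t"),
    paste("P1", "-", "1", "Pfam", "PF00001", "-", "20", "30", "1", "T", "-",
          sep = "\t"),   # repeated signature occurrence
    paste("P1", "-", "1", "Coils", "Coil", "-", "1", "9", "1", "T", "-",
          sep = "\t"),   # analysis outside the configured set
    paste("P2", "-", "1", "Coils", "Coil", "-", "1", "9", "1", "T", "-",
          sep = "\t")))
  prof <- build_profiles(rows)
  expect_equal(prof[["P1"]], c("PF00001", "PF00002"))
  expect_equal(prof[["P2"]], character(0))
})

test_that("best_hits picks maximal bit score with deterministic ties", {
  one <- read_hits(text = hit_line("Q1", "S1", 100))
  expect_equal(best_hits(one)$best, c(Q1 = "S1"))

  two <- read_hits(text = c(hit_line("Q1", "S1", 100),
                            hit_line("Q1", "S2", 90)))
  expect_equal(best_hits(two)$best, c(Q1 = "S1"))

  tie <- read_hits(text = c(hit_line("Q1", "B", 100, ev = 1e-20),
                            hit_line("Q1", "A", 100, ev = 1e-20)))
  expect_equal(best_hits(tie)$best, c(Q1 = "A"))

  # E-value filter precedes selection; excluded hits are counted
  filt <- read_hits(text = c(hit_line("Q1", "S1", 500, ev = 1e-3),
                             hit_line("Q1", "S2", 60)))
  bh <- best_hits(filt, min_evalue = 1e-5)
  expect_equal(bh$best, c(Q1 = "S2"))
  expect_equal(bh$n_excluded, 1L)

  # determinism: identical input, identical map
  set.seed(42)
  txt <- unlist(lapply(1:20, function(i)
    hit_line(sprintf("Q%d", sample(5, 1)), sprintf("S%d", sample(5, 1)),
             round(runif(1, 50, 100), 1))))
  h <- read_hits(text = txt)
  expect_identical(best_hits(h), best_hits(h))
})

test_that("reciprocal_best_hits requires mutual best hits", {
  fwd <- best_hits(read_hits(text = hit_line("q", "r", 100)),
                   direction = c("qs", "rs"))
  rev_ok <- best_hits(read_hits(text = hit_line("r", "q", 100)),
                      direction = c("rs", "qs"))
  expect_equal(reciprocal_best_hits(fwd, rev_ok),
               data.frame(query = "q", ref = "r",
                          stringsAsFactors = FALSE))

  rev_other <- best_hits(read_hits(text = hit_line("r", "q2", 100)),
                         direction = c("rs", "qs"))
  expect_equal(nrow(reciprocal_best_hits(fwd, rev_other)), 0L)

  bad_dir <- best_hits(read_hits(text = hit_line("r", "q", 100)),
                       direction = c("qs", "other"))
  expect_error(reciprocal_best_hits(fwd, bad_dir), "direction mismatch")
})

test_that("reciprocal best hits are symmetric in the two directions", {
  for (s in 1:10) {
    set.seed(s)
    fwd_txt <- unlist(lapply(1:12, function(i)
      hit_line(sprintf("Q%d", sample(6, 1)), sprintf("R%d", sample(6, 1)),
               round(runif(1, 50, 300), 1))))
    rev_txt <- unlist(lapply(1:12, function(i)
      hit_line(sprintf("R%d", sample(6, 1)), sprintf("Q%d", sample(6, 1)),
               round(runif(1, 50, 300), 1))))
    f <- best_hits(read_hits(text = fwd_txt))
    r <- best_hits(read_hits(text = rev_txt))
    ab <- reciprocal_best_hits(f, r)
    ba <- reciprocal_best_hits(r, f)
    expect_setequal(paste(ab$query, ab$ref), paste(ba$ref, ba$query))
  }
})

# a small fixed transfer scenario used by several tests
transfer_fixture <- function(is_human = FALSE) {
  ref_ann <- annotation_records(
    subject_id = "R1", term = sprintf("GO:%07d", 1:3),
    aspect = c("F", "P", "C"), subject_kind = "protein",
    source = "reference")
  ref <- reference_set(if (is_human) "human" else "fly", ref_ann,
                       is_human = is_human)
  fwd <- best_hits(read_hits(text = c(hit_line("Q1", "R1", 100),
                                      hit_line("Q2", "R1", 90))))
  rev <- best_hits(read_hits(text = hit_line("R1", "Q1", 100)))
  list(ref = ref, fwd = fwd, rbh = reciprocal_best_hits(fwd, rev))
}

test_that("RBH transfer carries all reference terms to the query genes", {
  fx <- transfer_fixture()
  out <- transfer_homology(fx$rbh, fx$fwd, list(), list(), fx$ref,
                           list(Q1 = "G1"))
  got <- out[out$subject_id == "G1", ]
  expect_setequal(got$term, sprintf("GO:%07d", 1:3))
  expect_setequal(got$aspect, c("F", "P", "C"))
  expect_equal(unique(got$evidence), "IEA")
  expect_equal(unique(got$source), "homology:fly")
  expect_equal(unique(got$with_from), "R1")
})

test_that("non-reciprocal best hits transfer only with identical domains", {
  fx <- transfer_fixture()
  prof_same <- list(Q2 = c("PF1", "PF2"))
  prof_ref <- list(R1 = c("PF2", "PF1"))   # same set, different order
  out <- transfer_homology(fx$rbh, fx$fwd, prof_same, prof_ref, fx$ref,
                           list(Q1 = "G1", Q2 = "G2"))
  expect_setequal(out$subject_id, c("G1", "G2"))

  prof_diff <- list(Q2 = c("PF1", "PF3"))
  out2 <- transfer_homology(fx$rbh, fx$fwd, prof_diff, prof_ref, fx$ref,
                            list(Q1 = "G1", Q2 = "G2"))
  expect_setequal(out2$subject_id, "G1")   # Q2 transfers nothing

  # two empty profiles count as identical domain content
  out3 <- transfer_homology(fx$rbh, fx$fwd, list(), list(), fx$ref,
                            list(Q1 = "G1", Q2 = "G2"))
  expect_true("G2" %in% out3$subject_id)
})

test_that("human references never transfer biological-process terms", {
  fx <- transfer_fixture(is_human = TRUE)
  out <- transfer_homology(fx$rbh, fx$fwd, list(), list(), fx$ref,
                           list(Q1 = "G1"))
  expect_setequal(out$aspect, c("F", "C"))
  expect_false(any(out$aspect == "P"))
})

test_that("transfers collapse to genes as the union across isoforms", {
  ref_ann <- annotation_records("R1", "GO:0000001", "F",
                                subject_kind = "protein")
  ref_ann2 <- annotation_records("R2", "GO:0000002", "P",
                                 subject_kind = "protein")
  ref <- reference_set("fly", rbind(ref_ann, ref_ann2))
  fwd <- best_hits(read_hits(text = c(hit_line("Q1a", "R1", 100),
                                      hit_line("Q1b", "R2", 100))))
  rev <- best_hits(read_hits(text = c(hit_line("R1", "Q1a", 100),
                                      hit_line("R2", "Q1b", 100))))
  rbh <- reciprocal_best_hits(fwd, rev)
  out <- transfer_homology(rbh, fwd, list(), list(), ref,
                           list(Q1a = "G1", Q1b = "G1"))
  expect_setequal(out$term[out$subject_id == "G1"],
                  c("GO:0000001", "GO:0000002"))
  # unmapped query proteins are counted, not raised
  out2 <- transfer_homology(rbh, fwd, list(), list(), ref,
                            list(Q1a = "G1"))
  expect_equal(attr(out2, "discards")[["unmapped"]], 1L)
})

test_that("transferred terms always come from the reference set", {
  for (s in 1:10) {
    set.seed(s)
    terms <- sprintf("GO:%07d", 1:8)
    ref_ann <- annotation_records(
      subject_id = sprintf("R%d", sample(4, 6, replace = TRUE)),
      term = sample(terms, 6, replace = TRUE),
      aspect = sample(c("F", "P", "C"), 6, replace = TRUE),
      subject_kind = "protein")
    ref <- reference_set("fly", ref_ann)
    fwd_txt <- unlist(lapply(1:8, function(i)
      hit_line(sprintf("Q%d", sample(4, 1)), sprintf("R%d", sample(4, 1)),
               round(runif(1, 50, 300), 1))))
    rev_txt <- unlist(lapply(1:8, function(i)
      hit_line(sprintf("R%d", sample(4, 1)), sprintf("Q%d", sample(4, 1)),
               round(runif(1, 50, 300), 1))))
    fwd <- best_hits(read_hits(text = fwd_txt))
    rev <- best_hits(read_hits(text = rev_txt))
    rbh <- reciprocal_best_hits(fwd, rev)
    mapping <- as.list(stats::setNames(sprintf("G%d", 1:4),
                                       sprintf("Q%d", 1:4)))
    out <- transfer_homology(rbh, fwd, list(), list(), ref, mapping)
    expect_true(all(out$term %in% ref_ann$term))
  }
})
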