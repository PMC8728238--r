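chain_obo <- make_obo(list(
  list(id = "GO:0000001"),
  list(id = "GO:0000002", is_a = "GO:0000001"),
  list(id = "GO:0000003", is_a = "GO:0000002")
))

test_that("parse_obo builds terms and typed edges from OBO stanzas", {
  g <- parse_obo(text = chain_obo)
  expect_s3_class(g, "go_ontology")
  expect_equal(nrow(g$terms), 3L)
  expect_equal(nrow(g$edges), 2L)
  expect_true(all(g$edges$relation == "is_a"))

  g2 <- parse_obo(text = make_obo(list(
    list(id = "GO:0000001"),
    list(id = "GO:0000002", rel = c(part_of = "GO:0000001"))
  )))
  expect_equal(g2$edges$relation, "part_of")

  # obsolete terms are present but carry no edges
  g3 <- parse_obo(text = make_obo(list(
    list(id = "GO:0000001"),
    list(id = "GO:0000002", is_a = "GO:0000001", obsolete = TRUE)
  )))
  expect_true("GO:0000002" %in% g3$terms$id)
  expect_equal(nrow(g3$edges), 0L)
})

test_that("parse_obo rejects malformed stanzas and is_a cycles", {
  bad <- c("format-version: 1.2", "", "[Term]", "name: no id here", "")
  expect_error(parse_obo(text = bad), "line 3")

  cyc <- make_obo(list(
    list(id = "GO:0000001", is_a = "GO:0000003"),
    list(id = "GO:0000002", is_a = "GO:0000001"),
    list(id = "GO:0000003", is_a = "GO:0000002")
  ))
  expect_error(parse_obo(text = cyc), "cycle")
})

test_that("alt_ids resolve to the primary id", {
  g <- parse_obo(text = make_obo(list(
    list(id = "GO:0000001", alt = "GO:0900001"),
    list(id = "GO:0000002", is_a = "GO:0000001")
  )))
  expect_equal(resolve_term(g, "GO:0900001"), "GO:0000001")
  expect_error(resolve_term(g, "GO:0999999"), "unknown GO term")
  expect_equal(ancestors(g, "GO:0000002"), "GO:0000001")
})

test_that("ancestors walks the requested relations, excluding the term", {
  g <- parse_obo(text = chain_obo)
  expect_equal(ancestors(g, "GO:0000001"), character(0))  # root
  expect_equal(ancestors(g, "GO:0000003"), c("GO:0000001", "GO:0000002"))

  gm <- parse_obo(text = make_obo(list(
    list(id = "GO:0000001"),
    list(id = "GO:0000002", rel = c(part_of = "GO:0000001")),
    list(id = "GO:0000003", is_a = "GO:0000002")
  )))
  expect_equal(ancestors(gm, "GO:0000003", relations = "is_a"),
               "GO:0000002")
  expect_equal(ancestors(gm, "GO:0000003"),
               c("GO:0000001", "GO:0000002"))
})

test_that("ancestors agrees with matrix-reachability on random DAGs", {
  for (s in 1:25) {
    ro <- random_obo(n = sample(5:50, 1), p = 0.15, seed = s)
    g <- parse_obo(text = ro$text)
    R <- reach_matrix(ro$ids, ro$edges, c("is_a", "part_of"))
    for (t in sample(ro$ids, 5))
      expect_equal(ancestors(g, t), oracle_ancestors(R, t))
    # restricting relations can only shrink the ancestor set
    t <- sample(ro$ids, 1)
    expect_true(all(ancestors(g, t, "is_a") %in% ancestors(g, t)))
  }
})

test_that("close_annotations adds every ancestor and is idempotent", {
  g <- parse_obo(text = chain_obo)
  root_only <- annotation_records("G1", "GO:0000001", "F")
  closed <- close_annotations(g, root_only)
  expect_equal(closed$term, "GO:0000001")  # root: output = input

  rec <- annotation_records("G1", "GO:0000003", "F", evidence = "IDA")
  closed <- close_annotations(g, rec)
  expect_setequal(closed$term, c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_true(all(closed$evidence == "IDA"))
  expect_setequal(closed$source[closed$term != "GO:0000003"], "closure")

  # idempotence and monotonicity on random inputs
  for (s in 1:5) {
    ro <- random_obo(20, 0.2, seed = 100 + s)
    gg <- parse_obo(text = ro$text)
    set.seed(s)
    rec <- annotation_records(
      subject_id = sample(sprintf("G%d", 1:4), 8, replace = TRUE),
      term = sample(ro$ids, 8, replace = TRUE), aspect = "F",
      evidence = sample(c("IEA", "IDA"), 8, replace = TRUE))
    c1 <- close_annotations(gg, rec)
    c2 <- close_annotations(gg, c1)
    expect_identical(c1$term, c2$term)
    expect_identical(c1$subject_id, c2$subject_id)
    expect_gte(nrow(c1), nrow(dedup_records(rec)))  # never removes input
    # is_a-only closure is a subset of {is_a, part_of} closure
    key <- function(x) paste(x$subject_id, x$term)
    expect_true(all(key(close_annotations(gg, rec, "is_a")) %in% key(c1)))
  }
})

test_that("close_annotations drops obsolete-term records with a count", {
  g <- parse_obo(text = make_obo(list(
    list(id = "GO:0000001"),
    list(id = "GO:0000002", obsolete = TRUE)
  )))
  rec <- annotation_records(c("G1", "G2"),
                            c("GO:0000001", "GO:0000002"), "F")
  expect_warning(out <- close_annotations(g, rec), "obsolete")
  expect_equal(out$subject_id, "G1")
  expect_equal(attr(out, "counts")[["dropped_obsolete"]], 1L)
  expect_false(any(out$term == "GO:0000002"))
})

cross_obo <- make_obo(list(
  list(id = "GO:0000001", ns = "molecular_function"),
  list(id = "GO:0000002", ns = "biological_process"),
  list(id = "GO:0000003", ns = "biological_process",
       is_a = "GO:0000002"),
  list(id = "GO:0000004", ns = "molecular_function",
       is_a = "GO:0000001", rel = c(part_of = "GO:0000003")),
  list(id = "GO:0000005", ns = "cellular_component")
))

test_that("inter-ontology links infer annotations across aspects", {
  g <- parse_obo(text = cross_obo)
  rec <- annotation_records("G1", "GO:0000004", "F", evidence = "IDA")
  inf <- infer_cross_aspect(g, rec)
  expect_equal(nrow(inf), 1L)
  expect_equal(inf$term, "GO:0000003")
  expect_equal(inf$aspect, "P")
  expect_equal(inf$evidence, "IEA")
  expect_equal(inf$source, "inter-ontology")

  # no cross-aspect edges -> nothing inferred
  g2 <- parse_obo(text = chain_obo)
  expect_equal(nrow(infer_cross_aspect(
    g2, annotation_records("G1", "GO:0000003", "F"))), 0L)

  # closure after inference includes the inferred terms' parents
  both <- merge_sources(list(rec, inf))
  closed <- close_annotations(g, both)
  expect_true("GO:0000002" %in% closed$term[closed$subject_id == "G1"])
})

test_that("edge-list export writes (child, relation, parent) TSV", {
  g <- parse_obo(text = chain_obo)
  f <- tempfile()
  write_ontology_edges(g, f)
  got <- read.table(f, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(got$V1, c("GO:0000002", "GO:0000003"))
  expect_equal(got$V3, c("GO:0000001", "GO:0000002"))
})
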