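---
title: "Building GO annotation sets by transfer, inference and closure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building GO annotation sets by transfer, inference and closure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goxfer)
```

## The problem

Gene Ontology (GO) enrichment analysis needs a reasonably complete
annotation set, but for most non-model genomes the curated UniProt-GOA
annotations cover only a small fraction of genes. `goxfer` builds a
usable annotation set for such a species by combining three sources —
curated GAF annotations, GO terms attached to InterProScan domain
matches, and terms transferred by protein homology from well-annotated
reference species — and then making the result logically consistent with
the ontology. This vignette explains the procedure, its assumptions, the
parameters that matter, and the choices made where conventions differ.

## The procedure and its assumptions

The pipeline runs in a fixed order: **sources → merge → inter-ontology
inference → ancestor closure**. Inference precedes closure deliberately,
so that inferred annotations also receive their ancestors; closure last
guarantees the emitted set satisfies the true-path rule (every record's
ancestors along `is_a`/`part_of` are present).

### Source 1: curated annotations

Protein-level GAF records are re-subjected to gene ids through a
UniProt `idmapping_selected.tab`-style table (defaults: protein
accession in column 1, GeneID in column 3; both configurable, since
mapping via RefSeq protein accessions instead is equally defensible).
A protein mapping to **more than one gene contributes nothing** — the
annotation's gene-level target is ambiguous and guessing would plant
errors that closure then amplifies. Unmapped proteins likewise
contribute nothing. Both classes are counted, not raised: partial input
coverage is the expected situation, not an error.

### Source 2: domain-derived annotations

InterProScan rows carry an optional column of GO ids looked up for the
matching signature. Every observed (protein, GO id) pair becomes one
gene-level record with evidence `IEA` and the signature accession kept
as supporting evidence in `with_from`. The assumption is the usual
InterPro2GO one: the presence of a domain is sufficient evidence for
the (deliberately general) terms mapped to it.

### Source 3: homology transfer

For each reference species, tabular search results in both directions
are reduced to best-hit maps: hits with E-value above the cutoff
(default `1e-5`, a conventional protein-homology threshold; the
procedure is not sensitive to it because decoy and orthologue scores
are well separated in realistic data) are discarded, then each query
keeps the hit with **maximal bit score**, ties broken by minimal
E-value, then lexicographically smallest subject id. Bit score is the
standard criterion and the two extra tie-breaks make the selection
fully deterministic. Terms are transferred from

* reciprocal best hits — the classical orthologue proxy; or
* non-reciprocal best hits whose **domain content is identical** to the
  query's.

Domain content is compared as the *set of signature accessions* over
the four member databases (SMART, SUPERFAMILY, PANTHER, Pfam) — not
InterPro entry accessions, and without copy numbers. Signature sets are
what InterProScan reports per database, so equality at that granularity
is the most direct reading of "identical domain content"; the
granularity is configurable via the `analyses` argument. Note that two
proteins with *no* qualifying domains also compare equal; the rule is
set equality, and callers who consider empty profiles uninformative can
require non-empty ones upstream.

From a **human** reference only molecular-function and
cellular-component terms are transferred; biological-process terms are
excluded because process annotations generalize poorly across that
evolutionary distance. Queries are searched per protein; transferred
records are collapsed to genes as the union over a gene's isoforms —
the only monotone choice when different isoforms hit different
reference proteins.

All computed transfers carry evidence `IEA`, the GO convention for
unreviewed computational assignments, with the supporting reference
protein in `with_from` and a `homology:<reference>` provenance tag.

### Inference and closure

Inter-ontology inference uses two documented link classes by default: a
molecular function `part_of` a biological process implies the BP
annotation, and a process `occurs_in` a component implies the CC
annotation. The channel set is configurable
(`default_link_channels()`), since further link classes exist and an
ontology release may or may not assert them. Inference reads *direct*
edges only; combined with closure afterwards this yields the same
record set as inferring over ancestors would, up to provenance tags.

Closure propagates every record to all ancestors of its term along
`is_a` and `part_of` ("true-path" propagation; `part_of` is included
because annotation to a part implies annotation to the whole in both GO
practice and the generated ontologies here, and the relation set is an
argument for users who want `is_a` only). Records to obsolete terms are
dropped and counted rather than remapped through `replaced_by`:
remapping requires curatorial judgement the pipeline cannot supply.
Alternate ids resolve silently to their primary id, with a counter.

### Merging and provenance

The deduplication key is (gene, term, evidence, source): the same
assertion arriving from two sources keeps both records, so provenance
stays auditable; within a source, duplicates collapse and their
supporting identifiers are `|`-joined in `with_from`. `NOT`-qualified
records are parsed but excluded from every transfer and merge —
propagating negative annotations by homology is unsound. All writers
sort deterministically and the GAF writer stamps a fixed default date,
so identical inputs produce byte-identical outputs.

## Enrichment

`enrich()` tests over-representation of each term in a study list
against a background with the exact upper-tail hypergeometric
probability; under-representation sits behind `alternative = "less"`.
Unannotated background genes count in the population size N (the
GeneMerge convention; conventions differ, which is why it is stated
here). Only terms with K ≥ 1 and k ≥ 1 are tested, and the correction
denominator is the number of tested terms. Bonferroni is the default
correction, matching GeneMerge; Benjamini–Hochberg is available. On
closed annotations the counts are monotone along the DAG (an ancestor's
K and k bound its descendants'), which the tests verify.

## What the synthetic fixtures emulate — and what they do not

`make_bundle()` generates, from a single seed, a mutually consistent
input bundle with planted ground truth: a random DAG per aspect built
by ranking terms and adding forward edges only (acyclic by
construction), cross-aspect link edges, an obsolete term and an
alternate id; a reference proteome with protein-level annotations;
bidirectional hit tables in which planted orthologue pairs are mutual
best hits whose bit scores (300–400) lie strictly above the decoy range
(50–150), so best-hit recovery is deterministic and test failures
isolate logic errors rather than sampling noise; InterProScan output
realizing planted profile equalities (a configurable fraction of
non-orthologous best-hit pairs get identical signature sets, the rest
get provably unequal ones); and a UniProt GAF plus idmapping with
planted multi-gene, unmapped and obsolete-term annotations driving
known discard counts. One pseudo-random stream is derived from the
master seed per file type, so adding a file type never perturbs the
others.

Defaults are sized for a small study: 40 terms per aspect, 60 reference
and 80 query genes, orthologue fraction 0.4, profile-match fraction
0.5, three multi-gene and two unmapped accessions. These are the
problem sizes used throughout the test suite and the acceptance script
(three bundles per run); generation takes well under a second.

The fixtures contain **no sequence content**: hit tables are
synthesized directly, with E-values derived monotonically from bit
scores. They therefore validate the selection, transfer, inference and
closure logic and the format fidelity — not alignment quality, score
calibration, or the biological error rate of domain-based transfer on
real proteomes. Passing recovery on fixtures shows the pipeline applies
its stated rules exactly; it cannot show that those rules yield
biologically correct annotations for a real genome.

## Numerical and degenerate-input behaviour

* Best-hit ties are resolved bit score → E-value → subject id; two
  identical runs give identical maps.
* Empty inputs are legal everywhere: an empty GAF yields a header-only
  output, empty hit tables yield no transfers, and every counter is 0.
* A failing stage aborts with the stage name and removes partial
  outputs.
* Cyclic `is_a` structures are rejected at parse time with one witness
  cycle; edges referencing unknown terms are a parse error.
* Enrichment p-values come from `phyper`; the suite cross-checks them
  against complete enumeration of all study subsets on small instances.

## Limitations

* One-to-many orthology is not resolved beyond best hits; co-orthologs
  other than the best hit contribute nothing.
* GAF 2.1 only (17 columns); GAF 2.2 qualifiers and GPAD are out of
  scope.
* OBO support covers the go.obo dialect (`id`, `name`, `namespace`,
  `alt_id`, `is_a`, `relationship`, `is_obsolete`); `intersection_of`
  and imports are not parsed.
* The pipeline is single-species per run; multi-species aggregation is
  a thin loop left to the caller (`aggregate_summaries()` computes the
  cross-species mean).
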