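---
title: "Curating COI barcode reference collections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating COI barcode reference collections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Taxonomic assignment in animal DNA barcoding and metabarcoding depends
on a reference collection of COI sequences whose sequences are really
COI, whose taxonomy follows one backbone, and whose metadata are
machine-readable. The two archives that matter — ENA's EMBL flat files
and BOLD's TSV dumps — overlap heavily, disagree on taxonomy, and carry
annotation of very uneven quality. `coiref` implements the curation,
integration and harmonization workflow as a reusable package: every
filter is an exported, unit-tested predicate, and the whole pipeline runs
on synthetic corpora with known ground truth.

## The curation model

A record is kept iff it passes all of the fixed stage sequence
`length → hmm → tc → annotation → contamination → n_filter → stop_codon`.
Each gate is a pure predicate, so the *outcome* is order-independent;
only the audit trail (`curate_records()$trail`) reflects the order, and
stages after the first failure are recorded as skipped rather than
evaluated.

### Six-frame mitochondrial translation

Sequences are translated in all six frames under the record's
mitochondrial genetic code, resolved by nearest-ancestor lookup of the
taxdump's mitochondrial-code field. Unresolved records use table 5
(invertebrate mitochondrial) because arthropods dominate animal barcode
collections. Translation runs *through* stop codons: no ORF calling is
attempted, because the profile search localizes the coding region and
the stop-codon gate then inspects only the accepted envelope. Codons
containing any non-ACGT symbol translate to `X`.

### Plan7-lite profile scoring

The built-in scorer is a local Viterbi over the plan7 state set
(match/insert/delete per node, begin/end) with two deliberate
simplifications relative to full HMMER:

* uniform, zero-bit local entry and exit (begin connects to every match
  state; every match state connects to end), rather than HMMER's
  occupancy-weighted entries;
* no MSV/bias/forward stages, no length-dependent null correction and no
  E-values: the gate in this workflow is a bit-score threshold, so the
  Viterbi bit score is sufficient and exactly reproducible.

Emissions are converted to log-odds bits against the profile file's null
model (taken, as in HMMER3 files, from the node-0 insert emission line);
transitions contribute `log2` of their probabilities; residues outside
the 20-letter alphabet (`X`, `*`) emit background, i.e. 0 bits, in both
match and insert states — the background-neutral convention. Ties in the
dynamic program resolve toward the earliest end position, then the
earliest model state, then entry/M/I/D predecessors in that order; ties
can affect only the reported envelope, never the score. The
implementation is validated against an independent exhaustive
enumeration of all alignment paths on ~1000 random instances (model
length ≤ 3, peptide ≤ 4) per test run.

Scores from an external `hmmsearch` run (`--domtblout`) can be
substituted through `read_domtbl()`. Absolute bit scores differ between
backends because HMMER applies null2 bias corrections and a
length-dependent null term that plan7-lite omits; the integration test
therefore asserts classification and ranking agreement, not score
equality.

### The trusted cutoff

`passes_tc()` accepts a hit iff its bit score is ≥ the profile's TC
(trusted cutoff — the lowest score of any known true family member),
matching HMMER's inclusive `--cut_tc` semantics. The cutoff applies to
the best single frame's best alignment, not to summed domains. Profiles
without a TC line (e.g. fresh `hmmbuild` output) require an explicit
`tc_override`.

### Annotation consistency and synonyms (ENA only)

For ENA records the annotated CDS is compared positionally with the
profile's nucleotide footprint. The denominator is the number of CDS
sites (multi-span `join` locations contribute the union of their spans),
so the fraction measures how much of the *annotation* the profile match
covers; the threshold is ≥ 0.80, inclusive. Among several CDS features
the maximal-overlap one decides, and a pseudogene tag on the decisive
CDS rejects regardless of overlap. Strand is ignored: the comparison is
purely positional. Gene/product labels of all threshold-passing,
non-pseudogene CDS on kept records are collected as COI name synonyms.

Records with no CDS annotation at all are governed by `no_cds_policy`.
The default, `keep_on_hmm`, trusts the profile evidence; this is a
genuine design choice (archives contain COI records annotated only as
`rRNA`-adjacent or not at all), exposed as configuration rather than
hard-coded.

### Quality and contamination gates

* Length window: 100–60 000 nt, both bounds inclusive, applied to both
  sources by default (`apply_length_to = "ENA_only"` restores a
  ENA-only reading).
* Terminal `N` runs are trimmed and the *trimmed* sequence is what is
  counted, written out and measured (`seq_length` metadata and the
  length histogram refer to it).
* At most five internal `N`s pass; six fail. Non-N IUPAC ambiguity
  codes are not counted.
* The stop-codon check is restricted to the accepted envelope by
  default (`stop_check_scope = "full_frame"` widens it); stops outside
  the matched region are common alignment artefacts of frame
  read-through and do not indicate a pseudogene.
* The contamination stage consumes an externally produced BLAST tabular
  file (BLAST itself is not re-implemented); the rule is an
  ancestor-or-self test of the top-bitscore hit against the Bacteria,
  Archaea and Viridiplantae roots. Queries with no hit, and hits whose
  taxid the taxonomy cannot place, pass — absence of evidence is not
  treated as contamination.

### Integration and taxonomy harmonization

Kept records are dereplicated by versionless accession; ENA data take
precedence for shared records (theirs is the annotation the pipeline
validated) while BOLD fills missing metadata. BOLD-only records are
keyed by process ID. Lineages use exactly the seven canonical NCBI ranks;
intermediate ranks (subfamily etc.) never fill canonical slots, and
"kingdom" means the rank literally labelled kingdom (Metazoa for
animals). Accessioned records resolve through accession2taxid; BOLD-only
records through the lowest-ranked raw name present in the backbone.
Homonyms are resolved by requiring a candidate's ancestry to contain one
of the record's *other* raw rank names (the queried name itself is
excluded, since every candidate trivially carries it); an ambiguous
homonym stays unresolved rather than guessed. Names absent from the
backbone are kept verbatim with `"NA"` taxids, and every BOLD record
whose raw name differs from the backbone name at a resolved rank is
counted and itemized in the update report.

### Metadata

Nine fields per record: final sequence length, mitochondrial code id,
country, sub-country region (the EMBL `country` qualifier splits at its
first colon, per INSDC convention), host, collection year, complete
ISO-8601 date, decimal-degree coordinates and the source permalink.
Coordinates accept the EMBL `lat_lon` dialect, DMS strings and numeric
pairs; south/west are negative, out-of-range values become `NA`, and
formatting is fixed at four decimals (≈ 11 m, below specimen-level
georeferencing precision), which makes parse–format a fixed point.
Two-digit years are rejected as ambiguous rather than guessed.

### Summaries

Published provenance/composition tables mix rounding conventions, so
`pct_of()` takes an explicit mode: `half_up` (0.5 away from zero, unlike
base R's banker's rounding) or `truncate`. Composition counts distinct
names per phylum at each lower rank, excluding `"NA"`; histogram mode
ties break toward the smaller length.

## The synthetic corpus

`generate_corpus()` emulates the *structure* of the real inputs, not
their biology. Clean records are 658 nt (the standard animal barcode
length) reverse-translations of a fixed 219-residue consensus; a third
of the clean BOLD-only records are 400 nt mini-barcodes. The toy profile
emits the consensus residue with probability 0.6 (≈ 3.585 bits per
matched position) over a uniform null and carries TC = 34, so a run of
10 consensus codons passes the cutoff and 9 fail — each violation class
is therefore decided by construction, not by chance: the low-score class
carries exactly 9 consensus codons; the overlap class plants a footprint
sharing 479 of 600 CDS sites (79.8%); the ambiguity class carries
exactly six internal `N`s; spacer DNA is a `CCT` repeat whose
translations (P/L/S forward, R/G/E reverse) are excluded from the
consensus alphabet and thus can never extend a match. The manifest
(verdicts, provenance counts, synonyms, update counts) is computed from
the construction, and the test suite requires the pipeline to reproduce
it exactly across seeds.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: sequencing error, indels relative to
the profile, heterogeneous codon usage, chimeras, incomplete taxonomies
beyond the planted cases, and the scale of the real archives (millions
of records). Validation runs use 40-record corpora in unit tests and
five 200-record corpora plus ~1000 scorer-oracle instances in the
acceptance suite — sizes chosen to keep the whole suite in the
one-minute range while exercising every code path.

## Known limitations

* The plan7-lite score is not a HMMER bit score for real Pfam profiles;
  with the external backend the TC gate is exact, with the built-in
  scorer it is faithful to the gate's *semantics* (bit threshold) but
  not to HMMER's numeric scale.
* BOLD exports vary by vintage; `bold_column_map()` covers the classic
  combined export and must be remapped for others.
* Homonym resolution uses only the record's own raw lineage as context;
  records naming a homonym with no other ranks stay unresolved.
* gzip-compressed inputs are supported only where R's `readLines`
  transparently handles them; archive payloads (XML/JSON API dumps) are
  out of scope.
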