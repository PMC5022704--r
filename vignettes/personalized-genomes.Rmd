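---
title: "Personalized genomes with genolite: model, defaults, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized genomes with genolite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genolite)
```

genolite turns a reference genome plus a subject's polymorphisms into
subject-specific transcript and protein sequences. This vignette is the
package's account of how that computation is defined, which knobs matter,
and where the design was genuinely open — so that results can be
interpreted (and distrusted) for the right reasons.

## The procedure

A personalized genome binds three things: an imported reference genome, an
ordered list of imported polymorphism sets, and an *allele filter*. The
handle itself is cheap — no sequence is touched at construction. When a
personalized sequence is first requested, the pipeline runs once per
transcript and is cached:

1. **Collect.** For each exon (or CDS interval), polymorphisms from all
   sets overlapping the interval are found through an interval index and
   grouped by locus (position). The filter is called once per locus with
   all candidates together, so it can weigh, say, a dbSNP record against a
   patient-specific call at the same site.
2. **Decide.** The filter returns one decision per locus: keep the
   reference, substitute one base, insert a sequence after the position,
   or delete a number of bases. `keep_reference` decisions are dropped.
3. **Insert.** Retained decisions are applied to the reference slice in
   descending genomic position, so coordinate shifts from indels stay
   strictly downstream of every remaining edit. Substitutions are checked
   against the recorded reference allele; a mismatch (stale variant set,
   wrong genome build) is an error, not a silent skip.
4. **Assemble.** Edited slices are concatenated in genomic order; for
   minus-strand genes the concatenation is reverse-complemented. For CDS
   assembly, a nonzero frame on the transcription-first CDS interval trims
   that many leading bases.
5. **Translate.** Standard genetic code, codon by codon; translation
   truncates at the first stop codon. A codon containing IUPAC ambiguity
   codes translates to the unique amino acid when every expansion agrees,
   otherwise `X`.

Assumptions worth stating: transcripts are single-strand and
single-chromosome (mixed-strand transcripts are rejected at import); the
caller's GTF frames are trusted; variants are unphased (see "Open
choices"); and personalization is deterministic — identical store, sets
and filter give byte-identical output.

## Allele filters and their defaults

The filter is the scientific control surface: it is where sequencing
quality, validation status and heterozygosity policy live. Filters are
plain R functions, so any rule is expressible; four are built in.

`filter_het_iupac()` (the default) preserves heterozygosity rather than
calling a winner: a substitution locus becomes the minimal IUPAC code
covering the reference allele and every observed alternate (A reference
with a G alternate becomes `R`). This is information-preserving — the
downstream translation rule turns genuinely ambiguous codons into `X`
rather than asserting an amino acid the data cannot support. Indels
cannot be encoded ambiguously in a single sequence, so they are applied
only when *trusted*: the record's metadata marks it validated (VCF INFO
flag `VLD`/`VALIDATED`), or its quality is at least 30 (a conventional
"almost certainly real" Phred threshold; there is no universal number in
the literature, and the cutoff is a named constant of the default filter,
not of the engine). A trusted indel takes precedence over substitutions
at the same locus, since it explains the site's sequence change more
specifically.

`filter_qual_ge(n)` keeps candidates with quality ≥ *n* and applies
survivors directly (single surviving substitution → its alternate
allele); `filter_validated_only()` does the same keyed on the validation
flag; `filter_ref_only()` ignores all variants. The CLI exposes these as
`het-iupac`, `qual-ge:<N>`, `validated-only`, `ref-only`.

Two decisions whose edited spans overlap — a SNP inside a retained
deletion, say — are a **conflict error**. The engine refuses to guess
because any tie-break (deletion wins? SNP wins?) is a scientific claim
the filter author should make explicitly. An insertion point is
considered in conflict with a deletion only when it falls strictly inside
the deleted span; an insertion at the span's edge is unambiguous.

## Coordinates and edge rules

Internally everything is 0-based, half-open; GTF (1-based inclusive) and
VCF (1-based, anchor-based alleles) are converted at parse time and
back-converted on export. The rules for the awkward edges:

- VCF alleles are trimmed (shared leading, then trailing bases) to a
  minimal representation before classification. Trimming is idempotent.
- An insertion "after position *p*" is anchored as `[p, p+1)` in the
  interval index, so an insertion whose anchor is an exon's last base is
  part of that exon, while one anchored exactly on the half-open end
  coordinate belongs to the downstream interval.
- A retained deletion running past an exon/CDS boundary is clipped to the
  overlapping part with a warning (`clip_policy = "clip"`, the default) or
  rejected (`"strict"`). Splice-site-destroying deletions are outside the
  modeling scope; clipping keeps the pipeline total while the warning
  flags the transcript for inspection.
- A point interval query (`start == end`) returns nothing under half-open
  overlap; use `[p, p+1)` for point lookups.
- A transcript with no CDS yields an empty protein with a warning rather
  than an error.

## The store

The store is one file: a fixed header, a JSON index holding every light
field, and a payload section holding heavy fields (chromosome sequences).
Copying the file is the supported backup/sharing mechanism. Queries go
through `get_records(store, kind, filter)`; results arrive in minimal
view, and heavy fields are materialized by a second, targeted read on
first access — observable through `load_events()`, which the tests use to
*prove* laziness rather than assume it. Records are per-session
singletons, so two handles to one gene are one object and an inflation
through either is visible to both; several personalized genomes over one
reference therefore share its chromosome sequences. Derived heavy fields
cascade: a protein's `sequence` pulls its transcript's CDS, which pulls
the chromosome sequence, each exactly once.

Per-field global indexes (`ensure_global_index()`) are deliberately under
user control — indexing everything would bloat a store holding several
genomes and variant sets — and are contractually invisible: query results
are identical with or without them. Filters apply only to light fields;
filtering on a deferred field would force bulk inflation, defeating the
design, so it raises a field error instead. Sessions are single-writer;
concurrent mutation is unsupported.

One namespace note: record ids are unique per kind across the whole
store. Two genomes reusing the same annotation ids cannot coexist;
re-importing under `force = TRUE` replaces the previous copy.

## The fixture generator and what passing tests mean

`generate_genome_datawrap()` / `generate_variant_datawrap()` emit complete
toy datawraps (FASTA + GTF + VCF + manifests) with planted ground truth.
The defaults are the package's reference study conditions: seed 42, one
10 kb chromosome, two genes (one per strand), three transcripts with
3+2+2 exons (120–240 bp exons, 60–120 bp introns, 12 bp 5' UTRs), and a
variant set of three substitutions (the first multi-allelic; qualities
30/10/25 so quality filters have something to reject), one validated 2 bp
insertion and one validated 3 bp deletion, all inside CDS. Each CDS
starts with ATG and contains no in-frame stop, so reference proteins span
their CDS and planted effects are attributable. The same seed produces
byte-identical files.

Ground truth comes from a naive oracle that shares no code with the
pipeline: a position-tagged-list editor (each reference base keeps its
genomic coordinate, so edit order cannot matter), a hand-written
64-codon table with brute-force ambiguity expansion, a `chartr`-based
reverse complement, and an independent restatement of the default filter
semantics. The tests then require byte-equality between pipeline and
oracle end to end, plus oracle equivalence of the edit engine on 2,000
random edit sets (1 kb regions, 10 seeds) and of the interval index on
10,000 random intervals × 500 queries × 10 seeds. These sizes are chosen
to probe boundary behaviour densely while keeping the whole suite fast;
`scripts/acceptance.R` recomputes the same agreement rates from scratch
at the same sizes.

What passing does **not** show: the toy genome has uniform base
composition, short clean introns, disjoint transcripts, no overlapping
genes, no soft-masking, and VCF records that are well-formed and
build-consistent. Real annotation is messier in exactly the ways the
error paths (reference-allele mismatch, conflicts, clipping warnings,
mixed-strand rejection) exist to surface — those paths are tested, but
their real-world frequency is not represented by the fixture.

## Open choices, made explicitly

- **IUPAC vs. picked allele for heterozygous SNPs.** Both are legitimate;
  the default preserves ambiguity, and `filter_qual_ge()` shows the
  pick-the-alternate style. The filter interface keeps this a user
  decision rather than an engine constant.
- **Unphased, single-sequence output.** A heterozygous site yields one
  sequence with an ambiguity code, not two haplotype sequences. Phased
  diploid output would double the sequence space and requires phase
  information the supported inputs do not carry.
- **Locus-grouped filter signature.** Filters see `(chromosome, position,
  candidates)` with all sets' candidates together. Alternatives (one call
  per record, or per overlapping window) make cross-set reasoning or
  determinism harder.
- **Proteins exist only for coding transcripts**, created at import when
  CDS features are present.
- **Intronic and intergenic variants** never enter transcript
  personalization; they are stored and queryable but outside the exon
  intervals the pipeline edits.

## Limitations

No structural variants, RNA editing, selenocysteine or alternative
genetic codes (the code table is a single implementation point if that
ever changes). No remote datawrap resolution: manifests may list URLs,
which are recorded but never fetched. The store is optimized for
desk-scale exploration — whole-genome stores work but indexes are rebuilt
per session, and the singleton cache is unbounded by design (it holds
only what was actually touched).
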