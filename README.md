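# genolite

Precision-medicine analyses keep asking the same question: *given this
subject's variants, what do their transcripts and proteins actually look
like?* Proteogenomics workflows in particular need subject-specific
protein databases — replacing a generic reference with one that carries
the subject's SNPs and INDELs measurably improves peptide identification
by mass spectrometry. genolite is an R package for exactly this: it keeps
reference genome annotations, chromosome sequences and polymorphism sets
together in one embedded store file and materializes **variant-personalized
transcript and protein sequences** on demand.

It is aimed at bioinformaticians and computational biologists who want
personalized sequences inside scripts and pipelines, without a server, a
remote API, or loading whole genomes into memory.

## The model

A personalized genome is a triple *(R, P, f)*:

- *R* — a reference genome: chromosomes with sequences, genes,
  transcripts, exons and CDS intervals (imported from FASTA + Ensembl-style
  GTF). All internal coordinates are 0-based, half-open.
- *P* — an ordered list of polymorphism sets (imported from VCF or
  dbSNP-like tables; one record per alternate allele, anchor-trimmed and
  classified as substitution / insertion / deletion).
- *f* — an **allele filter**: a deterministic function
  `f(chromosome, position, candidates) -> decision` that sees all
  polymorphisms at a locus together and decides what to insert — keep the
  reference, substitute one base, insert a sequence, or delete bases.

Requesting a protein sequence runs, lazily and exactly once:

```
polymorphisms in exon regions  --f-->  allele decisions
        --insert at loci-->  personalized exon slices
        --assemble (+ reverse complement on minus strand)-->  cDNA
        --translate (standard code)-->  protein
```

Edits are applied in descending genomic position, so insertions and
deletions never shift the coordinates of edits upstream of them. The
default filter is heterozygosity-preserving: substitutions become the
minimal IUPAC code covering reference + alternates (an A/G site becomes
`R`), and translation emits the unique amino acid when all codon
expansions agree, else `X`. Indels are applied only when validated or
high-quality. Everything is deterministic: same store, same sets, same
filter — byte-identical sequences.

The store itself is a single file. Records come back from the one query
entry point, `get_records()`, in minimal view: heavy fields (sequences)
are fetched by a second read only when first accessed, every record is a
per-session singleton, and per-field indexes are under explicit user
control (`ensure_global_index()` / `drop_global_index()`).

## Worked example

The package bundles a deterministic toy fixture (a 10 kb genome with 2
genes / 3 transcripts / 7 exons, plus a variant set with substitutions,
an insertion and a deletion planted inside CDS), so everything below runs
offline:

```r
library(genolite)

store <- store_create("demo.store")
bootstrap_install(store, "toy-genome")
bootstrap_install(store, "toy-snps")

pg   <- make_personalized_genome(store, "toy_genome", "toy_snps")
prot <- get_records(store, "Protein")[[1]]
prot
#> <Protein 'toy_genome_G1_1_T1_prot'>
#>   id: toy_genome_G1_1_T1_prot
#>   genome: toy_genome
#>   transcript: toy_genome_G1_1_T1
#>   sequence: <deferred>

pg_protein_sequence(pg, prot$id)
#> [1] "MFRDGVTHQCAYTCAGMXAAETDLVDTLSR"

nchar(prot$sequence)   # reference protein, loaded on first access
#> [1] 150
load_events(store, "Chromosome", "sequence")
#> [1] 1
```

Reading it: the record prints in minimal view (`sequence: <deferred>`).
The personalized protein is 30 residues against a 150-residue reference —
the planted 2 bp insertion shifts the reading frame and an early stop
truncates translation — and carries an `X` where a heterozygous SNP
(IUPAC `H` in the cDNA) makes the codon ambiguous. The chromosome
sequence was loaded exactly once, even though both the personalized and
the reference protein needed it.

The same operations are scriptable from a shell via the thin CLI wrapper:

```sh
Rscript inst/cli/genolite.R --store demo.store bootstrap install toy-genome
Rscript inst/cli/genolite.R --store demo.store sequence \
    --genome toy_genome --snps toy_snps --type protein \
    --out proteins.fa toy_genome_G1_1_T1_prot
```

## Scope

Phased diploid haplotype pairs, structural variants, splice-site effect
prediction, alternative genetic codes and remote (Ensembl/dbSNP) downloads
are out of scope; datawraps are local directories or tar archives. See the
methods vignette (`vignettes/personalized-genomes.Rmd`) for the design
decisions, parameter defaults and known limitations.
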