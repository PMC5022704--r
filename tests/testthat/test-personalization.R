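# The personalization engine: edit application, locus decisions, allele
# filters, strand handling, laziness, and planted-variant effects.

test_that("personalize_region applies single edits as specified", {
  expect_identical(
    personalize_region("ATGCCC", 0, list(
      c(list(position = 3), unclass(decision_substitute("G"))))),
    "ATGGCC")
  expect_identical(
    personalize_region("ATGCCC", 0, list(
      c(list(position = 2), unclass(decision_insert("TT"))))),
    "ATGTTCCC")
  # delete 2 at pos 1 plus substitute pos 4 -> A; expected value computed
  # with the position-tagged-list oracle
  edits <- list(
    c(list(position = 1), unclass(decision_delete(2))),
    c(list(position = 4), unclass(decision_substitute("A")))
  )
  expect_identical(oracle_edit_sequence("ATGCCC", 0, edits), "ACAC")
  expect_identical(personalize_region("ATGCCC", 0, edits), "ACAC")
  # empty decision list is the identity
  expect_identical(personalize_region("ATGCCC", 0, list()), "ATGCCC")
})

test_that("substitutions are checked against the expected reference base", {
  expect_error(
    personalize_region("ATGCCC", 10, list(
      c(list(position = 12), unclass(decision_substitute("A", ref = "C"))))),
    "expected 'C', found 'G'")
  expect_error(
    personalize_region("ATG", 0, list(
      c(list(position = 7), unclass(decision_substitute("A"))))),
    "outside region")
})

test_that("deletions crossing the region end clip or error by policy", {
  d <- list(c(list(position = 4), unclass(decision_delete(5))))
  expect_warning(out <- personalize_region("ATGCCC", 0, d, "clip"),
                 "clipped")
  expect_identical(out, "ATGC")
  expect_error(personalize_region("ATGCCC", 0, d, "strict"),
               "runs past the region end")
})

test_that("personalize_region equals the tagged-list oracle on random edit sets", {
  for (seed in 1:5) {
    set.seed(seed)
    for (i in 1:40) {
      n <- 200L
      region_start <- sample.int(1000L, 1L)
      s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
      edits <- random_edit_set(n, region_start)
      expect_identical(personalize_region(s, region_start, edits),
                       oracle_edit_sequence(s, region_start, edits))
    }
  }
})

test_that("quality filters drop low-quality loci", {
  store <- new_test_store()
  import_genome(store, tiny_datawrap())
  import_polymorphisms(store, tiny_snp_datawrap(c(
    "1\t16\t.\tG\tA\t30\tPASS\t.",
    "1\t25\t.\tC\tT\t10\tPASS\t."
  )))
  pg <- make_personalized_genome(store, "tiny_genome", "tiny_snps",
                                 filter = filter_qual_ge(20))
  decs <- collect_locus_decisions(pg, "1", 10, 40)
  expect_length(decs, 1L)
  expect_identical(decs[[1L]]$position, 15)
  expect_identical(decs[[1L]]$sequence, "A")
})

test_that("the filter sees all candidates of a locus at once, across sets", {
  store <- new_test_store()
  import_genome(store, tiny_datawrap())
  row <- "1\t16\t.\tG\tA\t30\tPASS\t."
  import_polymorphisms(store, tiny_snp_datawrap(row, set_name = "set_a"))
  import_polymorphisms(store, tiny_snp_datawrap(row, set_name = "set_b"))
  calls <- 0L; seen <- integer(0)
  counting_filter <- function(chromosome, position, candidates) {
    calls <<- calls + 1L
    seen <<- c(seen, length(candidates))
    decision_keep()
  }
  pg <- make_personalized_genome(store, "tiny_genome", c("set_a", "set_b"),
                                 filter = counting_filter)
  decs <- collect_locus_decisions(pg, "1", 10, 40)
  expect_length(decs, 0L)          # keep_reference decisions are dropped
  expect_identical(calls, 1L)      # one locus, one call
  expect_identical(seen, 2L)       # both sets' candidates together
})

test_that("overlapping retained decisions are a conflict, not a guess", {
  store <- new_test_store()
  import_genome(store, tiny_datawrap())
  import_polymorphisms(store, tiny_snp_datawrap(c(
    "1\t20\t.\tTGTCC\tT\t60\tPASS\tVLD",   # deletes internal [20, 24)
    "1\t22\t.\tT\tA\t50\tPASS\t."          # SNP at internal 21, inside it
  )))
  pg <- make_personalized_genome(store, "tiny_genome", "tiny_snps")
  expect_error(collect_locus_decisions(pg, "1", 10, 40),
               "conflicting allele decisions")
})

test_that("with no variant sets every personalized sequence is the reference", {
  store <- toy_store(with_snps = FALSE)
  fx <- toy_fixture()
  pg <- make_personalized_genome(store, "toy_genome")
  for (tid in names(fx$genome$ledger$transcripts)) {
    led <- fx$genome$ledger$transcripts[[tid]]
    expect_identical(pg_transcript_sequence(pg, tid, "full"), led$ref_full)
    expect_identical(pg_transcript_sequence(pg, tid, "cds"), led$ref_cds)
    expect_identical(pg_protein_sequence(pg, led$protein), led$ref_protein)
  }
  expect_error(make_personalized_genome(store, "missing_genome"),
               "not found")
  expect_error(make_personalized_genome(store, "toy_genome", "missing_set"),
               "not found")
})

test_that("minus-strand assembly reverse-complements the genomic concatenation", {
  store <- toy_store(with_snps = FALSE)
  fx <- toy_fixture()
  pg <- make_personalized_genome(store, "toy_genome")
  chrom_seq <- get_records(store, "Chromosome")[[1L]]$sequence
  minus <- Filter(function(tx) tx$strand == "-",
                  fx$genome$ledger$transcripts)
  expect_gt(length(minus), 0L)
  for (tx in minus) {
    slices <- substring(chrom_seq, tx$exons$start + 1L, tx$exons$end)
    expect_identical(pg_transcript_sequence(pg, tx$id, "full"),
                     reverse_complement(paste(slices, collapse = "")))
  }
})

test_that("a planted missense SNP changes exactly one residue (K -> R)", {
  store <- new_test_store()
  import_genome(store, tiny_datawrap())
  import_polymorphisms(store, tiny_snp_datawrap(
    "1\t18\t.\tA\tG\t60\tPASS\t."   # middle base of codon 2: AAA -> AGA
  ))
  ref_pg <- make_personalized_genome(store, "tiny_genome")
  ref_prot <- pg_protein_sequence(ref_pg, "TP1")
  expect_identical(ref_prot, "MKCPADFGELIKNQSGT")

  hom <- make_personalized_genome(store, "tiny_genome", "tiny_snps",
                                  filter = filter_qual_ge(20))
  prot <- pg_protein_sequence(hom, "TP1")
  expect_identical(prot, "MRCPADFGELIKNQSGT")
  diff <- which(strsplit(prot, "")[[1L]] != strsplit(ref_prot, "")[[1L]])
  expect_identical(diff, 2L)
})

test_that("heterozygous SNPs become IUPAC codes and translate by expansion agreement", {
  store <- new_test_store()
  import_genome(store, tiny_datawrap())
  import_polymorphisms(store, tiny_snp_datawrap(
    "1\t18\t.\tA\tG\t60\tPASS\t."
  ))
  het <- make_personalized_genome(store, "tiny_genome", "tiny_snps")
  cds <- pg_transcript_sequence(het, "TT1", "cds")
  expect_identical(substr(cds, 4, 6), "ARA")   # IUPAC R = A/G
  # AAA (K) and AGA (R) disagree -> X at residue 2
  expect_identical(pg_protein_sequence(het, "TP1"), "MXCPADFGELIKNQSGT")
})

test_that("indel length bookkeeping matches the planted variants", {
  fx <- toy_fixture()
  store <- toy_store(with_snps = TRUE)
  pg <- make_personalized_genome(store, "toy_genome", "toy_snps")
  vars <- fx$snps$ledger$variants
  for (tx in fx$genome$ledger$transcripts) {
    # planted indels falling inside this transcript's exons
    within <- vapply(seq_len(nrow(vars)), function(i) {
      any(vars$position[i] >= tx$exons$start &
            vars$position[i] < tx$exons$end)
    }, NA)
    v <- vars[within, , drop = FALSE]
    delta <- sum(nchar(v$alt_allele[v$kind == "insertion"])) -
      sum(nchar(v$ref_allele[v$kind == "deletion"]))
    got <- pg_transcript_sequence(pg, tx$id, "full")
    expect_identical(nchar(got) - nchar(tx$ref_full), as.integer(delta))
  }
})

test_that("personalization is lazy, cached, and shares reference loads", {
  store <- toy_store(with_snps = TRUE)
  prot <- get_records(store, "Protein")[[1L]]
  pg1 <- make_personalized_genome(store, "toy_genome", "toy_snps")
  expect_identical(load_events(store, "Chromosome", "sequence"), 0L)

  aa1 <- pg_protein_sequence(pg1, prot$id)
  expect_identical(load_events(store, "Chromosome", "sequence"), 1L)
  aa2 <- pg_protein_sequence(pg1, prot$id)   # cached
  expect_identical(aa2, aa1)
  expect_identical(load_events(store, "Chromosome", "sequence"), 1L)

  # a second personalized genome over the same reference shares the
  # already-loaded chromosome through the store's singleton cache
  pg2 <- make_personalized_genome(store, "toy_genome", "toy_snps")
  aa3 <- pg_protein_sequence(pg2, prot$id)
  expect_identical(aa3, aa1)
  expect_identical(load_events(store, "Chromosome", "sequence"), 1L)
})

test_that("determinism: identical inputs give byte-identical outputs", {
  store <- toy_store(with_snps = TRUE)
  pg_a <- make_personalized_genome(store, "toy_genome", "toy_snps")
  pg_b <- make_personalized_genome(store, "toy_genome", "toy_snps")
  for (tx in get_records(store, "Transcript")) {
    expect_identical(pg_transcript_sequence(pg_a, tx$id, "full"),
                     pg_transcript_sequence(pg_b, tx$id, "full"))
  }
})

test_that("FASTA export writes sorted records with pipeline sequences", {
  store <- toy_store(with_snps = TRUE)
  pg <- make_personalized_genome(store, "toy_genome", "toy_snps")
  tids <- vapply(get_records(store, "Transcript"), function(t) t$id, "")
  out <- tempfile(fileext = ".fa")
  pg_export_fasta(pg, rev(tids), out, type = "transcript")
  rec <- parse_fasta(out)
  expect_identical(rec$id,
                   sprintf("%s|toy_genome|toy_snps", sort(tids)))
  for (i in seq_len(nrow(rec))) {
    expect_identical(rec$sequence[[i]],
                     pg_transcript_sequence(pg, sort(tids)[[i]], "full"))
  }
})
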