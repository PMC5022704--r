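# Object store: minimal-view lazy records, singleton identity, the
# get_records() query surface, global indexes and file round-trips.

test_that("get_records filters by equality, comparison and prefix", {
  store <- toy_store(with_snps = FALSE)
  genes <- get_records(store, "Gene")
  expect_length(genes, 2L)

  g1 <- get_records(store, "Gene", list(id = genes[[1L]]$id))
  expect_length(g1, 1L)
  expect_identical(g1[[1L]]$id, genes[[1L]]$id)

  expect_length(get_records(store, "Gene", list(id = "no_such_id")), 0L)

  lo <- get_records(store, "Gene", list(where("start", "<", genes[[2L]]$start)))
  expect_identical(vapply(lo, function(g) g$id, ""), genes[[1L]]$id)
  hi <- get_records(store, "Gene", list(where("start", ">", genes[[1L]]$start)))
  expect_identical(vapply(hi, function(g) g$id, ""), genes[[2L]]$id)

  pre <- get_records(store, "Transcript", list(where("id", "prefix", "toy_genome_G1_2")))
  expect_length(pre, 2L)

  both <- get_records(store, "Exon",
                      list(where("transcript", "==", "toy_genome_G1_1_T1"),
                           where("rank", "==", 1)))
  expect_length(both, 1L)
})

test_that("unknown kinds and fields are schema/field errors", {
  store <- toy_store(with_snps = FALSE)
  expect_error(get_records(store, "Widget"), "unknown record kind")
  expect_error(get_records(store, "Gene", list(colour = "red")),
               "unknown field 'colour'")
  expect_error(get_records(store, "Chromosome", list(sequence = "A")),
               "lazily loaded field")
})

test_that("records are served in minimal view and inflate exactly once", {
  store <- toy_store(with_snps = FALSE)
  chrom <- get_records(store, "Chromosome")[[1L]]
  expect_false("sequence" %in% record_loaded_fields(chrom))
  expect_identical(load_events(store, "Chromosome", "sequence"), 0L)

  expect_identical(chrom$id, paste0("toy_genome:", chrom$name))  # light access
  expect_identical(load_events(store, "Chromosome", "sequence"), 0L)

  seq1 <- chrom$sequence
  expect_identical(nchar(seq1), as.integer(chrom$length))
  expect_true("sequence" %in% record_loaded_fields(chrom))
  expect_identical(load_events(store, "Chromosome", "sequence"), 1L)

  seq2 <- chrom$sequence  # cached: same value, no second load event
  expect_identical(seq2, seq1)
  expect_identical(load_events(store, "Chromosome", "sequence"), 1L)

  expect_error(chrom$bogus, "unknown field 'bogus'")
  expect_error({chrom$name <- "x"}, "read-only")
})

test_that("accessing a protein sequence triggers the dependent load chain", {
  store <- toy_store(with_snps = FALSE)
  prot <- get_records(store, "Protein")[[1L]]
  expect_false("sequence" %in% record_loaded_fields(prot))
  expect_identical(load_events(store), 0L)
  aa <- prot$sequence
  expect_gt(nchar(aa), 0L)
  # the chain pulled the transcript CDS and the chromosome sequence
  expect_identical(load_events(store, "Chromosome", "sequence"), 1L)
  expect_identical(load_events(store, "Transcript", "cds_sequence"), 1L)
  aa2 <- prot$sequence
  expect_identical(aa2, aa)
  expect_identical(load_events(store, "Chromosome", "sequence"), 1L)
})

test_that("records are per-session singletons and share inflation", {
  store <- toy_store(with_snps = FALSE)
  ids <- vapply(get_records(store, "Gene"), function(g) g$id, "")
  a <- get_records(store, "Gene", list(id = ids[[1L]]))[[1L]]
  b <- get_records(store, "Gene", list(id = ids[[1L]]))[[1L]]
  expect_true(identical(a, b))           # same environment
  c <- get_records(store, "Gene", list(id = ids[[2L]]))[[1L]]
  expect_false(identical(a, c))

  ch1 <- get_records(store, "Chromosome")[[1L]]
  invisible(ch1$sequence)
  ch2 <- get_records(store, "Chromosome")[[1L]]
  expect_true("sequence" %in% record_loaded_fields(ch2))
  invisible(ch2$sequence)
  expect_identical(load_events(store, "Chromosome", "sequence"), 1L)
})

test_that("loaded_fields only grows", {
  store <- toy_store(with_snps = FALSE)
  tx <- get_records(store, "Transcript")[[1L]]
  before <- record_loaded_fields(tx)
  invisible(tx$sequence)
  invisible(tx$cds_sequence)
  after <- record_loaded_fields(tx)
  expect_true(all(before %in% after))
  expect_true(all(c("sequence", "cds_sequence") %in% after))
})

test_that("global indexes are idempotent and never change results", {
  store <- toy_store(with_snps = TRUE)
  h1 <- ensure_global_index(store, "Transcript", "id")
  h2 <- ensure_global_index(store, "Transcript", "id")
  expect_identical(h1$name, h2$name)
  expect_identical(sum(list_global_indexes(store) == "Transcript.id"), 1L)

  tid <- get_records(store, "Transcript")[[1L]]$id
  with_ix <- get_records(store, "Transcript", list(id = tid))
  drop_global_index(store, "Transcript", "id")
  without_ix <- get_records(store, "Transcript", list(id = tid))
  expect_identical(vapply(with_ix, function(r) r$id, ""),
                   vapply(without_ix, function(r) r$id, ""))

  drop_global_index(store, "Transcript", "id")  # drop twice: no-op
  expect_error(ensure_global_index(store, "Transcript", "bogus"),
               "unknown field")
})

test_that("random filters give identical results with and without indexes", {
  store <- toy_store(with_snps = TRUE)
  set.seed(99)
  kinds <- c("Gene", "Transcript", "Exon", "Polymorphism")
  run_query <- function(kind, filt) {
    sort(vapply(get_records(store, kind, filt), function(r) r$id, ""))
  }
  for (i in 1:50) {
    kind <- sample(kinds, 1L)
    tab_ids <- vapply(get_records(store, kind), function(r) r$id, "")
    filt <- switch(sample(3L, 1L),
      list(id = sample(c(tab_ids, "missing_id"), 1L)),
      list(where("id", "prefix", substr(sample(tab_ids, 1L), 1L, 8L))),
      if (kind == "Polymorphism") list(where("position", "<", sample(10000L, 1L)))
      else list(where("start", "<", sample(10000L, 1L)))
    )
    baseline <- run_query(kind, filt)
    ensure_global_index(store, kind, "id")
    expect_identical(run_query(kind, filt), baseline)
    drop_global_index(store, kind, "id")
    expect_identical(run_query(kind, filt), baseline)
  }
})

test_that("the store file round-trips through close/reopen and copy", {
  store <- toy_store(with_snps = TRUE)
  snapshot <- function(st) {
    lapply(c("Genome", "Chromosome", "Gene", "Transcript", "Exon",
             "Protein", "Polymorphism", "PolymorphismSet"), function(k) {
      sort(vapply(get_records(st, k), function(r) r$id, ""))
    })
  }
  chrom_seq <- get_records(store, "Chromosome")[[1L]]$sequence
  before <- snapshot(store)
  path <- store_close(store)

  reopened <- store_open(path)
  expect_identical(snapshot(reopened), before)
  expect_identical(get_records(reopened, "Chromosome")[[1L]]$sequence,
                   chrom_seq)

  copy <- tempfile(fileext = ".store")
  file.copy(path, copy)
  from_copy <- store_open(copy)
  expect_identical(snapshot(from_copy), before)
  expect_identical(get_records(from_copy, "Chromosome")[[1L]]$sequence,
                   chrom_seq)
  # indexes survive the round-trip too
  st2 <- store_open(path)
  ensure_global_index(st2, "Gene", "id")
  p2 <- store_close(st2)
  st3 <- store_open(p2)
  expect_true("Gene.id" %in% list_global_indexes(st3))
})
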