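# Shared fixture builders. Everything is generated in code at test time;
# the default toy genome/variant datawraps are generated once per test
# run and imported into a fresh store on demand.

new_test_store <- function() {
  store_create(tempfile(fileext = ".store"))
}

# Generate the default toy datawraps once and cache the paths + ledgers.
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- fixture_spec()
      g <- generate_genome_datawrap(spec, tempfile("toy_genome_dw_"))
      v <- generate_variant_datawrap(spec, g$ledger, tempfile("toy_snps_dw_"))
      cache <<- list(spec = spec, genome = g, snps = v)
    }
    cache
  }
})

# Fresh store with the toy genome (and optionally its variant set) imported.
toy_store <- function(with_snps = TRUE) {
  fx <- toy_fixture()
  store <- new_test_store()
  import_genome(store, fx$genome$path)
  if (with_snps) import_polymorphisms(store, fx$snps$path)
  store
}

# A tiny hand-built genome datawrap for precise, human-checkable cases:
# one 120 bp chromosome, one + strand gene, one transcript with two exons
# [10,40) and [60,90), CDS = [13,40) + [60,84) (51 bp = 17 codons).
# The CDS spells ATG AAA ... so codon 2 is AAA (Lys); a SNP at the middle
# base of codon 2 (position 17, A->G) turns it into AGA (Arg).
tiny_datawrap <- function(dir = tempfile("tiny_dw_")) {
  dir.create(dir)
  cds_tx <- paste0(
    "ATGAAA",
    "TGTCCTGCAGATTTCGGCGAA",      # codons 3..9, no stops
    "CTGATCAAGAACCAGTCTGGCACG"    # codons 10..17
  )
  stopifnot(nchar(cds_tx) == 51L)
  chars <- strsplit(paste(rep("T", 120), collapse = ""), "")[[1L]]
  chars[11:13] <- c("G", "C", "C")                       # 5' UTR
  chars[14:40] <- strsplit(substr(cds_tx, 1, 27), "")[[1L]]
  chars[61:84] <- strsplit(substr(cds_tx, 28, 51), "")[[1L]]
  chars[85:90] <- c("C", "A", "C", "A", "C", "A")        # 3' UTR
  writeLines(c(">chr1", paste(chars, collapse = "")),
             file.path(dir, "genome.fa"))
  gtf <- c(
    "#!genolite tiny fixture",
    "1\ttiny\tgene\t11\t90\t.\t+\t.\tgene_id \"TG1\"; gene_name \"TINY1\";",
    "1\ttiny\ttranscript\t11\t90\t.\t+\t.\tgene_id \"TG1\"; transcript_id \"TT1\";",
    "1\ttiny\texon\t11\t40\t.\t+\t.\tgene_id \"TG1\"; transcript_id \"TT1\"; exon_number \"1\";",
    "1\ttiny\texon\t61\t90\t.\t+\t.\tgene_id \"TG1\"; transcript_id \"TT1\"; exon_number \"2\";",
    "1\ttiny\tCDS\t14\t40\t.\t+\t0\tgene_id \"TG1\"; transcript_id \"TT1\"; protein_id \"TP1\";",
    "1\ttiny\tCDS\t61\t84\t.\t+\t0\tgene_id \"TG1\"; transcript_id \"TT1\"; protein_id \"TP1\";"
  )
  writeLines(gtf, file.path(dir, "annotation.gtf"))
  writeLines(c(
    "[package]",
    "description = tiny hand-built fixture",
    "version = 1.0",
    "maintainer = tests",
    "[genome]",
    "name = tiny_genome",
    "species = Toyus minimus",
    "[files]",
    "fasta = genome.fa",
    "gtf = annotation.gtf"
  ), file.path(dir, "manifest.ini"))
  invisible(dir)
}

# Companion variant datawrap for the tiny genome. `rows` are VCF body
# lines (CHROM POS ID REF ALT QUAL FILTER INFO).
tiny_snp_datawrap <- function(rows, dir = tempfile("tiny_snp_dw_"),
                              set_name = "tiny_snps") {
  dir.create(dir)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    rows
  ), file.path(dir, "variants.vcf"))
  writeLines(c(
    "[package]",
    "description = tiny hand-built variants",
    "version = 1.0",
    "maintainer = tests",
    "[snps]",
    sprintf("name = %s", set_name),
    "species = Toyus minimus",
    "[files]",
    "snp = variants.vcf"
  ), file.path(dir, "manifest.ini"))
  invisible(dir)
}

# Brute-force expected translation of one (possibly ambiguous) codon:
# enumerate every expansion, translate each with the hand codon table,
# emit the amino acid iff the result set is a singleton, else "X".
oracle_codon_expected <- function(codon) {
  grid <- expand.grid(expand_ambiguity(substr(codon, 1, 1)),
                      expand_ambiguity(substr(codon, 2, 2)),
                      expand_ambiguity(substr(codon, 3, 3)),
                      stringsAsFactors = FALSE)
  aas <- unique(vapply(seq_len(nrow(grid)), function(j) {
    oracle_translate(paste0(grid[j, 1], grid[j, 2], grid[j, 3]),
                     truncate_at_stop = FALSE)
  }, ""))
  if (length(aas) == 1L) aas else "X"
}

# Naive O(n) overlap scan: the oracle for interval-index equivalence.
naive_overlap_scan <- function(entries, qs, qe) {
  if (qs >= qe) return(character(0))  # degenerate point query
  hit <- entries$start < qe & qs < entries$end
  ids <- entries$id[hit]
  o <- order(entries$start[hit], entries$end[hit], ids)
  as.character(ids[o])
}

# Random non-overlapping edit set on a sequence of length n starting at
# region_start; returns a list of decision-shaped edits.
random_edit_set <- function(n, region_start, max_edits = 8L) {
  k <- sample.int(max_edits, 1L)
  pos_pool <- seq.int(region_start, region_start + n - 1L)
  edits <- list()
  used_until <- region_start - 1L
  for (i in seq_len(k)) {
    cand <- pos_pool[pos_pool > used_until + 1L]
    if (length(cand) < 4L) break
    p <- sort(sample(cand, 1L))
    action <- sample(c("substitute", "insert", "delete"), 1L)
    if (action == "substitute") {
      edits[[length(edits) + 1L]] <- list(position = p, action = "substitute",
                                          sequence = sample(c("A", "C", "G", "T"), 1L),
                                          length = 0L, ref = NA)
      used_until <- p
    } else if (action == "insert") {
      edits[[length(edits) + 1L]] <- list(position = p, action = "insert",
                                          sequence = paste(sample(c("A", "C", "G", "T"),
                                                                  sample.int(4L, 1L),
                                                                  replace = TRUE),
                                                           collapse = ""),
                                          length = 0L, ref = NA)
      used_until <- p
    } else {
      max_len <- min(5L, region_start + n - p)
      len <- sample.int(max_len, 1L)
      edits[[length(edits) + 1L]] <- list(position = p, action = "delete",
                                          sequence = "", length = len, ref = NA)
      used_until <- p + len - 1L
    }
  }
  edits
}

# Run the CLI dispatcher with its stdout captured (tests only check the
# exit status / messages; data output goes to files anyway).
quiet_cli <- function(args) {
  status <- NULL
  capture.output(status <- cli_main(args))
  status
}
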