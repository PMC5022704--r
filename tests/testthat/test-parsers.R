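# Format parsers: manifest.ini, FASTA, GTF (and its export round-trip),
# VCF normalization, FASTQ, CSV.

test_that("parse_manifest reads a minimal genome manifest", {
  m <- parse_manifest(c(
    "[package]",
    "description = a toy genome",
    "version = 1.2",
    "maintainer = someone@example.org",
    "[genome]",
    "name = toy",
    "species = Toyus minimus",
    "[files]",
    "fasta = genome.fa",
    "gtf = annotation.gtf"
  ))
  expect_identical(m$type, "genome")
  expect_identical(m$name, "toy")
  expect_identical(m$version, "1.2")
  expect_identical(nrow(m$files), 2L)
  expect_false(any(m$files$remote))
})

test_that("parse_manifest enforces mandatory keys and known roles", {
  base <- c("[package]", "description = d", "maintainer = m",
            "[genome]", "name = g", "[files]", "fasta = f.fa")
  expect_error(parse_manifest(base), "'version'")
  expect_error(parse_manifest(c(base[1:3], "version = 1", base[4:6],
                                "bam = x.bam")),
               "unknown file role 'bam'")
  expect_error(parse_manifest(c("[package]", "description = d",
                                "version = 1", "maintainer = m",
                                "[files]", "fasta = f.fa")),
               "'name'")
})

test_that("URL file locations are flagged remote and never fetched", {
  m <- parse_manifest(c(
    "[package]", "description = d", "version = 1", "maintainer = m",
    "[snps]", "name = s",
    "[files]", "snp = https://example.org/variants.vcf.gz"
  ))
  expect_true(m$files$remote)
  # importing such a datawrap fails cleanly instead of fetching
  dw <- tempfile("remote_dw_"); dir.create(dw)
  writeLines(c("[package]", "description = d", "version = 1",
               "maintainer = m", "[snps]", "name = s", "[files]",
               "snp = https://example.org/variants.vcf.gz"),
             file.path(dw, "manifest.ini"))
  store <- new_test_store()
  expect_error(import_polymorphisms(store, dw), "remote")
})

test_that("parse_fasta splits headers and concatenates sequence lines", {
  r <- parse_fasta(c(">chr1 primary assembly", "ACGT", "ACGT"))
  expect_identical(nrow(r), 1L)
  expect_identical(r$id, "chr1")
  expect_identical(r$description, "primary assembly")
  expect_identical(nchar(r$sequence), 8L)

  expect_identical(nrow(parse_fasta(character(0))), 0L)

  two <- parse_fasta(c(">b", "AA", ">a", "cc"))
  expect_identical(two$id, c("b", "a"))      # file order, not sorted
  expect_identical(two$sequence, c("AA", "CC"))

  expect_error(parse_fasta(c("ACGT", ">chr1", "ACGT")),
               "before the first '>'")
})

test_that("parse_gtf converts coordinates and extracts attributes", {
  line <- paste("1", "src", "exon", "11", "20", ".", "+", ".",
                'gene_id "G"; transcript_id "T"; exon_number "2";',
                sep = "\t")
  f <- parse_gtf(line)
  expect_identical(f$start, 10)
  expect_identical(f$end, 20)
  expect_identical(f$end - f$start, 10)
  expect_identical(f$gene_id, "G")
  expect_identical(f$exon_number, 2)

  expect_identical(nrow(parse_gtf(c("# header", "#!genebuild x"))), 0L)

  expect_error(parse_gtf("1\tsrc\texon\t11\t20\t.\t+"),
               "line 1: expected 9 tab-separated columns, got 7")
  expect_error(parse_gtf(paste("1", "s", "exon", "20", "11", ".", "+", ".",
                               'gene_id "G";', sep = "\t")),
               "end \\(11\\) < start \\(20\\)")
})

test_that("GTF internal coordinates round-trip through export", {
  fx <- toy_fixture()
  gtf_path <- file.path(fx$genome$path, "annotation.gtf")
  parsed <- parse_gtf(gtf_path)
  expect_identical(sum(parsed$feature == "gene"), 2L)
  expect_identical(sum(parsed$feature == "transcript"), 3L)
  expect_identical(sum(parsed$feature == "exon"), 7L)

  reparsed <- parse_gtf(write_gtf(parsed))
  expect_identical(reparsed$start, parsed$start)
  expect_identical(reparsed$end, parsed$end)
  expect_identical(reparsed$feature, parsed$feature)
  expect_identical(reparsed$frame, parsed$frame)
})

test_that("VCF alleles are anchor-trimmed and classified", {
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           "1\t5\t.\tC\tG\t30\tPASS\t.",
           "1\t6\t.\tCA\tC\t40\tPASS\tVLD",
           "1\t9\t.\tC\tCTT\t50\tPASS\t.")
  v <- parse_vcf(vcf)
  expect_identical(v$kind, c("substitution", "deletion", "insertion"))
  expect_identical(v$position, c(4, 6, 8))
  expect_identical(v$ref_allele, c("C", "A", ""))
  expect_identical(v$alt_allele, c("G", "", "TT"))
  md <- lapply(v$metadata, jsonlite::fromJSON)
  expect_identical(vapply(md, function(m) isTRUE(m$validated), NA),
                   c(FALSE, TRUE, FALSE))
  expect_identical(v$quality, c(30, 40, 50))
})

test_that("variant normalization is idempotent", {
  set.seed(21)
  cases <- list(
    list(pos0 = 4, ref = "C", alt = "G"),
    list(pos0 = 4, ref = "CA", alt = "C"),
    list(pos0 = 4, ref = "C", alt = "CTT"),
    list(pos0 = 10, ref = "CATTA", alt = "CA"),
    list(pos0 = 10, ref = "TTAC", alt = "TGAC")  # shared trailing base
  )
  for (cs in cases) {
    n1 <- normalize_variant(cs$pos0, cs$ref, cs$alt)
    n2 <- normalize_variant(n1$position, n1$ref, n1$alt)
    expect_identical(n2, n1)  # normalization is the identity on its image
  }
  expect_error(normalize_variant(0, "AT", "GC"), "complex")
})

test_that("FASTQ records parse and malformed input errors", {
  fq <- c("@r1", "ACGT", "+", "IIII", "@r2 desc", "GGTT", "+", "FFFF")
  r <- parse_fastq(fq)
  expect_identical(r$id, c("r1", "r2"))
  expect_identical(r$sequence, c("ACGT", "GGTT"))
  expect_error(parse_fastq(fq[1:6]), "truncated")
  expect_error(parse_fastq(c("@r1", "ACGT", "+", "III")),
               "lengths differ")
})

test_that("CSV parses with header keys", {
  r <- parse_csv(c("a,b", "1,2"))
  expect_identical(r$a, "1")
  expect_identical(r$b, "2")
  t <- parse_csv(c("x\ty", "p\tq"), delimiter = "\t")
  expect_identical(t$y, "q")
})
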