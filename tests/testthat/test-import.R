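# Datawrap ingestion: genome and polymorphism imports, error paths,
# re-import protection.

test_that("importing the toy genome populates the hierarchy with the planted counts", {
  fx <- toy_fixture()
  store <- new_test_store()
  name <- import_genome(store, fx$genome$path)
  expect_identical(name, "toy_genome")
  expect_length(get_records(store, "Genome"), 1L)
  expect_length(get_records(store, "Chromosome"), 1L)
  expect_length(get_records(store, "Gene"), 2L)
  expect_length(get_records(store, "Transcript"), 3L)
  expect_length(get_records(store, "Exon"), 7L)
  expect_length(get_records(store, "Protein"), 3L)
  expect_identical(nrow(validate_hierarchy(store, "toy_genome")), 0L)
})

test_that("a tar.gz datawrap archive imports like the directory form", {
  fx <- toy_fixture()
  tarball <- tempfile(fileext = ".tar.gz")
  old <- setwd(fx$genome$path)
  on.exit(setwd(old))
  utils::tar(tarball, files = list.files("."), compression = "gzip")
  setwd(old)
  store <- new_test_store()
  expect_identical(import_genome(store, tarball), "toy_genome")
  expect_length(get_records(store, "Transcript"), 3L)
})

test_that("re-import of the same genome is rejected unless forced", {
  fx <- toy_fixture()
  store <- new_test_store()
  import_genome(store, fx$genome$path)
  expect_error(import_genome(store, fx$genome$path), "already imported")
  expect_identical(import_genome(store, fx$genome$path, force = TRUE),
                   "toy_genome")
  expect_length(get_records(store, "Gene"), 2L)  # replaced, not duplicated
})

test_that("a datawrap missing its GTF is a manifest error", {
  dw <- tempfile("nogtf_dw_"); dir.create(dw)
  writeLines(c(">1", "ACGTACGT"), file.path(dw, "genome.fa"))
  writeLines(c("[package]", "description = d", "version = 1",
               "maintainer = m", "[genome]", "name = g", "[files]",
               "fasta = genome.fa"), file.path(dw, "manifest.ini"))
  store <- new_test_store()
  expect_error(import_genome(store, dw), "no file with role 'gtf'")
})

test_that("GTF features on chromosomes absent from the FASTA abort the import", {
  dw <- tempfile("mismatch_dw_"); dir.create(dw)
  writeLines(c(">1", paste(rep("ACGT", 25), collapse = "")),
             file.path(dw, "genome.fa"))
  writeLines(paste("2", "src", "exon", "11", "20", ".", "+", ".",
                   'gene_id "G"; transcript_id "T";', sep = "\t"),
             file.path(dw, "annotation.gtf"))
  writeLines(c("[package]", "description = d", "version = 1",
               "maintainer = m", "[genome]", "name = g", "[files]",
               "fasta = genome.fa", "gtf = annotation.gtf"),
             file.path(dw, "manifest.ini"))
  store <- new_test_store()
  expect_error(import_genome(store, dw), "absent from the FASTA: 2")
})

test_that("chr-prefixed FASTA names match bare GTF names", {
  store <- new_test_store()
  import_genome(store, tiny_datawrap())  # FASTA says chr1, GTF says 1
  chrom <- get_records(store, "Chromosome")[[1L]]
  expect_identical(chrom$name, "1")
  expect_length(get_records(store, "Exon"), 2L)
})

test_that("multi-allelic VCF lines split into one polymorphism per ALT", {
  fx <- toy_fixture()
  # the toy VCF has 5 variant lines, the first substitution with 2 ALTs
  vcf_lines <- readLines(file.path(fx$snps$path, "variants.vcf"))
  body <- vcf_lines[!startsWith(vcf_lines, "#")]
  expect_identical(length(body), 5L)
  store <- toy_store(with_snps = TRUE)
  polys <- get_records(store, "Polymorphism")
  expect_length(polys, 6L)
  kinds <- vapply(polys, function(p) p$kind, "")
  expect_identical(sum(kinds == "substitution"), 4L)  # 2+1+1 alleles
  expect_identical(sum(kinds == "insertion"), 1L)
  expect_identical(sum(kinds == "deletion"), 1L)
})

test_that("an empty VCF registers the set with zero polymorphisms", {
  dw <- tiny_snp_datawrap(character(0), set_name = "empty_set")
  store <- new_test_store()
  import_genome(store, tiny_datawrap())
  expect_identical(import_polymorphisms(store, dw), "empty_set")
  expect_length(get_records(store, "PolymorphismSet",
                            list(id = "empty_set")), 1L)
  expect_length(get_records(store, "Polymorphism"), 0L)
})

test_that("re-import of a polymorphism set needs force", {
  fx <- toy_fixture()
  store <- toy_store(with_snps = TRUE)
  expect_error(import_polymorphisms(store, fx$snps$path), "already imported")
  expect_identical(import_polymorphisms(store, fx$snps$path, force = TRUE),
                   "toy_snps")
  expect_length(get_records(store, "Polymorphism"), 6L)
})

test_that("dbSNP-style tab tables import through the same polymorphism type", {
  dw <- tempfile("dbsnp_dw_"); dir.create(dw)
  writeLines(c("chromosome\tposition\tref\talt\tquality\tvalidated",
               "1\t18\tA\tG\t55\tyes",
               "1\t25\tC\tA,T\t10\tno"),
             file.path(dw, "snps.tsv"))
  writeLines(c("[package]", "description = d", "version = 1",
               "maintainer = m", "[snps]", "name = tab_set", "[files]",
               "snp = snps.tsv"), file.path(dw, "manifest.ini"))
  store <- new_test_store()
  import_genome(store, tiny_datawrap())
  import_polymorphisms(store, dw)
  polys <- get_records(store, "Polymorphism")
  expect_length(polys, 3L)  # one per ALT
  first <- get_records(store, "Polymorphism", list(position = 17))[[1L]]
  expect_identical(first$ref_allele, "A")
  md <- jsonlite::fromJSON(first$metadata)
  expect_true(md$validated)
})
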