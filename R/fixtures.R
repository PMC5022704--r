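# Deterministic synthetic-datawrap generator: toy genomes (FASTA + GTF +
# manifest.ini) and variant sets (VCF + manifest.ini) with planted,
# independently computed ground truth, so the whole pipeline is testable
# offline with known answers. Ground-truth sequences come from the naive
# oracle (oracle.R), which shares no code with the main pipeline.

#' Describe a synthetic fixture
#'
#' The defaults describe the bundled toy genome: one 10 kb chromosome,
#' two genes (one per strand), three transcripts with 3 + 2 + 2 exons,
#' and a variant set of three substitutions (the first multi-allelic,
#' qualities 30/10/25), one validated 2 bp insertion and one validated
#' 3 bp deletion, all planted inside CDS. The same seed always yields
#' byte-identical datawrap files.
#'
#' @param seed RNG seed driving every random choice.
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length chromosome length in bp.
#' @param n_genes genes per chromosome.
#' @param transcripts_per_gene integer vector, recycled over genes.
#' @param exons_per_transcript integer vector, recycled over transcripts
#'   (in global transcript order).
#' @param gene_strands strand per gene, recycled.
#' @param exon_length_range min/max exon length (bp).
#' @param utr5_length 5' UTR length on every transcript (bp).
#' @param n_substitutions,n_insertions,n_deletions planted variant counts.
#' @param multiallelic give the first substitution two alternate alleles.
#' @param substitution_qualities VCF QUAL per substitution, recycled.
#' @param insertion_length,deletion_length indel sizes (bp).
#' @param indel_quality VCF QUAL for indels.
#' @param validate_indels mark indels with the `VLD` INFO flag.
#' @param genome_name,set_name,species identity written to the manifests.
#' @return a `fixture_spec` object.
#' @export
fixture_spec <- function(seed = 42L,
                         n_chromosomes = 1L,
                         chromosome_length = 10000L,
                         n_genes = 2L,
                         transcripts_per_gene = c(1L, 2L),
                         exons_per_transcript = c(3L, 2L, 2L),
                         gene_strands = c("+", "-"),
                         exon_length_range = c(120L, 240L),
                         utr5_length = 12L,
                         n_substitutions = 3L,
                         n_insertions = 1L,
                         n_deletions = 1L,
                         multiallelic = TRUE,
                         substitution_qualities = c(30, 10, 25),
                         insertion_length = 2L,
                         deletion_length = 3L,
                         indel_quality = 40,
                         validate_indels = TRUE,
                         genome_name = "toy_genome",
                         set_name = "toy_snps",
                         species = "Toyus minimus") {
  spec <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    n_genes = as.integer(n_genes),
    transcripts_per_gene = as.integer(transcripts_per_gene),
    exons_per_transcript = as.integer(exons_per_transcript),
    gene_strands = gene_strands,
    exon_length_range = as.integer(exon_length_range),
    utr5_length = as.integer(utr5_length),
    n_substitutions = as.integer(n_substitutions),
    n_insertions = as.integer(n_insertions),
    n_deletions = as.integer(n_deletions),
    multiallelic = isTRUE(multiallelic),
    substitution_qualities = as.numeric(substitution_qualities),
    insertion_length = as.integer(insertion_length),
    deletion_length = as.integer(deletion_length),
    indel_quality = as.numeric(indel_quality),
    validate_indels = isTRUE(validate_indels),
    genome_name = genome_name, set_name = set_name, species = species
  )
  stopifnot(spec$n_chromosomes >= 1L, spec$n_genes >= 1L,
            all(spec$transcripts_per_gene >= 1L),
            all(spec$exons_per_transcript >= 1L),
            spec$exon_length_range[1L] >= 30L,
            diff(spec$exon_length_range) >= 0L)
  class(spec) <- "fixture_spec"
  spec
}

.FIX_MARGIN <- 200L       # chromosome ends left gene-free
.FIX_GENE_GAP <- 300L     # intergenic gap (annotate_position tests rely on it)
.FIX_TX_GAP <- 100L       # gap between sibling transcripts
.FIX_INTRON <- c(60L, 120L)

# Per-gene transcript counts and per-transcript exon counts, recycled.
fixture_layout <- function(spec) {
  tpg <- rep_len(spec$transcripts_per_gene, spec$n_genes)
  n_tx <- sum(tpg)
  epx <- rep_len(spec$exons_per_transcript, n_tx)
  list(tpg = tpg, n_tx = n_tx, epx = epx)
}

check_genome_feasible <- function(spec) {
  lay <- fixture_layout(spec)
  usable <- spec$chromosome_length - 2L * .FIX_MARGIN -
    (spec$n_genes - 1L) * .FIX_GENE_GAP
  block <- usable %/% spec$n_genes
  k <- 0L
  for (g in seq_len(spec$n_genes)) {
    sub_block <- (block - (lay$tpg[g] - 1L) * .FIX_TX_GAP) %/% lay$tpg[g]
    for (t in seq_len(lay$tpg[g])) {
      k <- k + 1L
      need <- lay$epx[k] * spec$exon_length_range[2L] +
        (lay$epx[k] - 1L) * .FIX_INTRON[2L]
      if (need > sub_block) {
        stop(sprintf("fixture spec error: transcript %d needs up to %d bp but only %d bp fit on the chromosome",
                     k, need, sub_block), call. = FALSE)
      }
    }
  }
  invisible(spec)
}

rand_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Genomic CDS intervals from genomic-order exons: trim `front` bases off
# the genomic-left end of the exon chain and `back` off the right end.
trim_exon_chain <- function(exons, front, back) {
  starts <- exons$start; ends <- exons$end
  i <- 1L
  while (front > 0L) {
    w <- ends[i] - starts[i]
    if (w > front) { starts[i] <- starts[i] + front; front <- 0L }
    else { starts[i] <- ends[i]; front <- front - w; i <- i + 1L }
  }
  j <- length(ends)
  while (back > 0L) {
    w <- ends[j] - starts[j]
    if (w > back) { ends[j] <- ends[j] - back; back <- 0L }
    else { ends[j] <- starts[j]; back <- back - w; j <- j - 1L }
  }
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate a toy reference-genome datawrap
#'
#' Writes `genome.fa`, `annotation.gtf` and `manifest.ini` into
#' `out_dir` and returns a ground-truth ledger: every planted id,
#' interval and strand, plus each transcript's reference transcript, CDS
#' and protein sequence computed by the naive oracle (slicing + reverse
#' complement + table-driven translation), independently of the import
#' and personalization pipeline. Every CDS starts with ATG and contains
#' no in-frame stop codon, so proteins span the whole CDS.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir directory to create/fill (the datawrap, directory form).
#' @return list with `path` and `ledger`.
#' @export
generate_genome_datawrap <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  check_genome_feasible(spec)
  lay <- fixture_layout(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  chrom_seqs <- list()
  genes <- list(); txs <- list()
  gtf <- list()
  add_gtf <- function(chrom, feature, start, end, strand, frame, attrs) {
    gtf[[length(gtf) + 1L]] <<- data.frame(
      chrom = chrom, source = "genolite_fixture", feature = feature,
      start = start, end = end, score = ".", strand = strand,
      frame = frame, gene_id = NA_character_, gene_name = NA_character_,
      transcript_id = NA_character_, exon_number = NA_real_,
      exon_id = NA_character_, protein_id = NA_character_,
      attributes = attrs, stringsAsFactors = FALSE
    )
  }

  usable <- spec$chromosome_length - 2L * .FIX_MARGIN -
    (spec$n_genes - 1L) * .FIX_GENE_GAP
  block <- usable %/% spec$n_genes
  k <- 0L
  for (ci in seq_len(spec$n_chromosomes)) {
    chrom <- as.character(ci)
    chars <- strsplit(rand_bases(spec$chromosome_length), "", fixed = TRUE)[[1L]]
    for (g in seq_len(spec$n_genes)) {
      gid <- sprintf("%s_G%d_%d", spec$genome_name, ci, g)
      strand <- rep_len(spec$gene_strands, spec$n_genes)[g]
      bs <- .FIX_MARGIN + (g - 1L) * (block + .FIX_GENE_GAP)
      sub_block <- (block - (lay$tpg[g] - 1L) * .FIX_TX_GAP) %/% lay$tpg[g]
      gene_tx <- character(0)
      for (t in seq_len(lay$tpg[g])) {
        k <- k + 1L
        tid <- sprintf("%s_T%d", gid, t)
        ss <- bs + (t - 1L) * (sub_block + .FIX_TX_GAP)
        n_ex <- lay$epx[k]
        cur <- ss
        ex_start <- integer(n_ex); ex_end <- integer(n_ex)
        for (e in seq_len(n_ex)) {
          if (e > 1L) cur <- cur + sample(.FIX_INTRON[1L]:.FIX_INTRON[2L], 1L)
          len <- sample(spec$exon_length_range[1L]:spec$exon_length_range[2L], 1L)
          ex_start[e] <- cur; ex_end[e] <- cur + len
          cur <- ex_end[e]
        }
        exons <- data.frame(start = ex_start, end = ex_end)
        total <- sum(exons$end - exons$start)
        utr5 <- spec$utr5_length
        utr3 <- 9L + (total - utr5 - 9L) %% 3L
        front <- if (strand == "+") utr5 else utr3
        back <- if (strand == "+") utr3 else utr5
        cds <- trim_exon_chain(exons, front, back)
        cds_len <- sum(cds$end - cds$start)

        # rewrite the CDS so it starts with ATG and has no in-frame stop
        n_codons <- cds_len %/% 3L
        body <- character(n_codons - 1L)
        for (cc in seq_len(n_codons - 1L)) {
          repeat {
            cand <- rand_bases(3L)
            if (!(cand %in% .STOP_CODONS)) break
          }
          body[cc] <- cand
        }
        cds_tx_seq <- paste0("ATG", paste(body, collapse = ""))
        cds_genomic <- if (strand == "-") {
          oracle_reverse_complement(cds_tx_seq)
        } else {
          cds_tx_seq
        }
        offset <- 0L
        for (j in seq_len(nrow(cds))) {
          w <- cds$end[j] - cds$start[j]
          piece <- substr(cds_genomic, offset + 1L, offset + w)
          chars[(cds$start[j] + 1L):cds$end[j]] <-
            strsplit(piece, "", fixed = TRUE)[[1L]]
          offset <- offset + w
        }

        gene_tx <- c(gene_tx, tid)
        pid <- paste0(tid, "_prot")
        txs[[tid]] <- list(id = tid, gene = gid, chromosome = chrom,
                           strand = strand, exons = exons, cds = cds,
                           frame = 0L, protein = pid)
        add_gtf(chrom, "transcript", min(exons$start), max(exons$end), strand,
                NA_real_,
                sprintf('gene_id "%s"; transcript_id "%s";', gid, tid))
        for (e in seq_len(n_ex)) {
          rank <- if (strand == "-") n_ex - e + 1L else e
          add_gtf(chrom, "exon", exons$start[e], exons$end[e], strand,
                  NA_real_,
                  sprintf('gene_id "%s"; transcript_id "%s"; exon_number "%d"; exon_id "%s.E%d";',
                          gid, tid, rank, tid, rank))
        }
        # per-interval frames in transcription order
        ord <- if (strand == "-") rev(seq_len(nrow(cds))) else seq_len(nrow(cds))
        cum <- 0L
        frames <- integer(nrow(cds))
        for (j in ord) {
          frames[j] <- (3L - cum %% 3L) %% 3L
          cum <- cum + (cds$end[j] - cds$start[j])
        }
        for (j in seq_len(nrow(cds))) {
          add_gtf(chrom, "CDS", cds$start[j], cds$end[j], strand, frames[j],
                  sprintf('gene_id "%s"; transcript_id "%s"; protein_id "%s";',
                          gid, tid, pid))
        }
      }
      g_start <- min(vapply(txs[gene_tx], function(x) min(x$exons$start), 0))
      g_end <- max(vapply(txs[gene_tx], function(x) max(x$exons$end), 0))
      genes[[gid]] <- list(id = gid, chromosome = chrom, strand = strand,
                           start = g_start, end = g_end,
                           transcripts = gene_tx)
      add_gtf(chrom, "gene", g_start, g_end, strand, NA_real_,
              sprintf('gene_id "%s"; gene_name "%s";', gid, gid))
    }
    chrom_seqs[[chrom]] <- paste(chars, collapse = "")
  }

  # reference sequences via the naive oracle
  for (tid in names(txs)) {
    tx <- txs[[tid]]
    cs <- chrom_seqs[[tx$chromosome]]
    txs[[tid]]$ref_full <- oracle_transcript_sequence(cs, tx$exons, tx$strand)
    txs[[tid]]$ref_cds <- oracle_transcript_sequence(cs, tx$cds, tx$strand,
                                                     frame = tx$frame)
    txs[[tid]]$ref_protein <- oracle_translate(txs[[tid]]$ref_cds)
  }

  fasta_lines <- unlist(lapply(names(chrom_seqs), function(ch) {
    s <- chrom_seqs[[ch]]
    c(paste0(">", ch),
      substring(s, seq(1L, nchar(s), 60L),
                pmin(seq(1L, nchar(s), 60L) + 59L, nchar(s))))
  }), use.names = FALSE)
  writeLines(fasta_lines, file.path(out_dir, "genome.fa"))

  gtf_df <- do.call(rbind, gtf)
  gtf_df <- gtf_df[order(gtf_df$chrom, gtf_df$start,
                         match(gtf_df$feature,
                               c("gene", "transcript", "exon", "CDS"))), ]
  writeLines(write_gtf(gtf_df), file.path(out_dir, "annotation.gtf"))

  writeLines(c(
    "[package]",
    "description = synthetic toy reference genome (generated fixture)",
    "version = 1.0",
    "maintainer = genolite fixtures",
    "[genome]",
    sprintf("name = %s", spec$genome_name),
    sprintf("species = %s", spec$species),
    "[files]",
    "fasta = genome.fa",
    "gtf = annotation.gtf"
  ), file.path(out_dir, "manifest.ini"))

  list(path = out_dir,
       ledger = list(spec = spec, chromosomes = chrom_seqs,
                     genes = genes, transcripts = txs))
}

#' Generate a toy variant-set datawrap
#'
#' Plants the spec's substitutions, insertion(s) and deletion(s) inside
#' CDS intervals of the ledger's transcripts (round-robin), writes
#' `variants.vcf` and `manifest.ini`, and extends the ledger with the
#' planted variant table plus, for every transcript, the expected
#' personalized transcript/CDS/protein sequences under the default
#' heterozygosity-preserving filter -- all computed by the naive
#' tagged-list oracle.
#'
#' @param spec a [fixture_spec()].
#' @param genome_ledger the `ledger` from [generate_genome_datawrap()].
#' @param out_dir directory to create/fill.
#' @return list with `path` and `ledger` (variants + expected sequences).
#' @export
generate_variant_datawrap <- function(spec, genome_ledger, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 1L)
  txs <- genome_ledger$transcripts
  tx_ids <- names(txs)
  margin <- max(6L, spec$deletion_length + 2L)

  # candidate in-CDS loci per transcript, away from interval edges
  pools <- lapply(txs, function(tx) {
    unlist(lapply(seq_len(nrow(tx$cds)), function(j) {
      lo <- tx$cds$start[j] + margin
      hi <- tx$cds$end[j] - margin
      if (hi <= lo) integer(0) else lo:hi
    }), use.names = FALSE)
  })

  kinds <- c(rep("substitution", spec$n_substitutions),
             rep("insertion", spec$n_insertions),
             rep("deletion", spec$n_deletions))
  variants <- list(); vcf_rows <- list()
  sub_i <- 0L
  for (vi in seq_along(kinds)) {
    tid <- tx_ids[(vi - 1L) %% length(tx_ids) + 1L]
    tx <- txs[[tid]]
    pool <- pools[[tid]]
    if (!length(pool)) {
      stop("fixture spec error: in-CDS variant count exceeds CDS capacity",
           call. = FALSE)
    }
    p <- pool[sample.int(length(pool), 1L)]
    pools[[tid]] <- pool[abs(pool - p) > 2L * margin]
    chrom_seq <- genome_ledger$chromosomes[[tx$chromosome]]
    base_at <- function(i0) substr(chrom_seq, i0 + 1L, i0 + 1L)
    kind <- kinds[vi]
    if (kind == "substitution") {
      sub_i <- sub_i + 1L
      ref <- base_at(p)
      n_alts <- if (spec$multiallelic && sub_i == 1L) 2L else 1L
      alts <- sample(setdiff(c("A", "C", "G", "T"), ref), n_alts)
      qual <- rep_len(spec$substitution_qualities, spec$n_substitutions)[sub_i]
      for (a in alts) {
        variants[[length(variants) + 1L]] <- data.frame(
          chromosome = tx$chromosome, position = p, ref_allele = ref,
          alt_allele = a, kind = "substitution", quality = qual,
          validated = FALSE, stringsAsFactors = FALSE)
      }
      vcf_rows[[length(vcf_rows) + 1L]] <- list(
        chrom = tx$chromosome, pos1 = p + 1L, ref = ref,
        alt = paste(alts, collapse = ","), qual = qual, info = ".")
    } else if (kind == "insertion") {
      ins <- rand_bases(spec$insertion_length)
      variants[[length(variants) + 1L]] <- data.frame(
        chromosome = tx$chromosome, position = p, ref_allele = "",
        alt_allele = ins, kind = "insertion", quality = spec$indel_quality,
        validated = spec$validate_indels, stringsAsFactors = FALSE)
      vcf_rows[[length(vcf_rows) + 1L]] <- list(
        chrom = tx$chromosome, pos1 = p + 1L, ref = base_at(p),
        alt = paste0(base_at(p), ins), qual = spec$indel_quality,
        info = if (spec$validate_indels) "VLD" else ".")
    } else {
      dl <- spec$deletion_length
      deleted <- substr(chrom_seq, p + 1L, p + dl)
      variants[[length(variants) + 1L]] <- data.frame(
        chromosome = tx$chromosome, position = p, ref_allele = deleted,
        alt_allele = "", kind = "deletion", quality = spec$indel_quality,
        validated = spec$validate_indels, stringsAsFactors = FALSE)
      vcf_rows[[length(vcf_rows) + 1L]] <- list(
        chrom = tx$chromosome, pos1 = p, ref = paste0(base_at(p - 1L), deleted),
        alt = base_at(p - 1L), qual = spec$indel_quality,
        info = if (spec$validate_indels) "VLD" else ".")
    }
  }
  variants <- do.call(rbind, variants)

  ord <- order(vapply(vcf_rows, function(r) r$chrom, ""),
               vapply(vcf_rows, function(r) r$pos1, 0))
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    "##source=genolite_fixture",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    vapply(vcf_rows[ord], function(r) {
      sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\t%s", r$chrom, r$pos1, r$ref,
              r$alt, format(r$qual, trim = TRUE), r$info)
    }, "")
  )
  writeLines(vcf_lines, file.path(out_dir, "variants.vcf"))
  writeLines(c(
    "[package]",
    "description = synthetic toy variant set (generated fixture)",
    "version = 1.0",
    "maintainer = genolite fixtures",
    "[snps]",
    sprintf("name = %s", spec$set_name),
    sprintf("species = %s", spec$species),
    "[files]",
    "snp = variants.vcf"
  ), file.path(out_dir, "manifest.ini"))

  expected <- list()
  for (tid in names(txs)) {
    tx <- txs[[tid]]
    cs <- genome_ledger$chromosomes[[tx$chromosome]]
    v <- variants[variants$chromosome == tx$chromosome, , drop = FALSE]
    expected[[tid]] <- list(
      full = oracle_transcript_sequence(cs, tx$exons, tx$strand, v),
      cds = oracle_transcript_sequence(cs, tx$cds, tx$strand, v,
                                       frame = tx$frame)
    )
    expected[[tid]]$protein <- oracle_translate(expected[[tid]]$cds)
  }

  list(path = out_dir,
       ledger = list(spec = spec, variants = variants, expected = expected))
}
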