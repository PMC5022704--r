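# Datawrap ingestion: reference genomes (FASTA + GTF) and polymorphism
# sets (VCF or dbSNP-like tables) populate the store.

# A datawrap is a directory or a tar(.gz) archive containing manifest.ini
# plus the data files it names. Returns the directory holding the files.
resolve_datawrap <- function(path) {
  if (dir.exists(path)) return(path)
  if (!file.exists(path)) {
    stop(sprintf("datawrap not found: %s", path), call. = FALSE)
  }
  ex <- tempfile("datawrap_")
  dir.create(ex)
  utils::untar(path, exdir = ex)
  # archives may nest the files in one top-level directory
  if (!file.exists(file.path(ex, "manifest.ini"))) {
    subs <- list.dirs(ex, recursive = FALSE)
    for (s in subs) {
      if (file.exists(file.path(s, "manifest.ini"))) return(s)
    }
  }
  ex
}

read_datawrap_manifest <- function(dw_dir) {
  mf <- file.path(dw_dir, "manifest.ini")
  if (!file.exists(mf)) {
    stop(sprintf("datawrap has no manifest.ini: %s", dw_dir), call. = FALSE)
  }
  parse_manifest(mf)
}

datawrap_file <- function(dw_dir, manifest, role) {
  rows <- manifest$files[manifest$files$role == role, , drop = FALSE]
  if (!nrow(rows)) {
    stop(sprintf("manifest lists no file with role '%s'", role), call. = FALSE)
  }
  local <- rows[!rows$remote, , drop = FALSE]
  if (!nrow(local)) {
    stop(sprintf("all '%s' entries are remote URLs; remote locations are not resolved",
                 role), call. = FALSE)
  }
  file.path(dw_dir, local$location)
}

#' Import a reference genome datawrap
#'
#' Reads the datawrap's FASTA and GTF, builds the full annotation
#' hierarchy (genome, chromosomes with sequences, genes, transcripts,
#' exons, CDS intervals and proteins for coding transcripts) and persists
#' it. Chromosome names are matched between FASTA and GTF after stripping
#' a leading "chr" prefix; GTF features on chromosomes absent from the
#' FASTA abort the import. Transcripts mixing strands are rejected.
#'
#' @param store a store handle.
#' @param path datawrap directory or tar(.gz) archive.
#' @param force replace an already-imported genome of the same name.
#' @return the genome name, invisibly.
#' @export
import_genome <- function(store, path, force = FALSE) {
  check_store(store)
  dw <- resolve_datawrap(path)
  manifest <- read_datawrap_manifest(dw)
  if (manifest$type != "genome") {
    stop("datawrap is not a genome datawrap (no [genome] section)", call. = FALSE)
  }
  gname <- manifest$name
  existing <- base::get("Genome", envir = store$tables)
  if (gname %in% existing$id) {
    if (!force) {
      stop(sprintf("genome '%s' is already imported (use force = TRUE to replace)",
                   gname), call. = FALSE)
    }
    remove_genome(store, gname)
  }

  fasta <- do.call(rbind, lapply(datawrap_file(dw, manifest, "fasta"), parse_fasta))
  fasta$id <- normalize_chrom(fasta$id)
  for (i in seq_len(nrow(fasta))) {
    normalize_nucleotides(fasta$sequence[[i]],
                          what = sprintf("chromosome '%s'", fasta$id[[i]]))
  }
  gtf <- do.call(rbind, lapply(datawrap_file(dw, manifest, "gtf"), parse_gtf))
  gtf$chrom <- normalize_chrom(gtf$chrom)

  missing_chroms <- setdiff(unique(gtf$chrom), fasta$id)
  if (length(missing_chroms)) {
    stop(sprintf("GTF references chromosome(s) absent from the FASTA: %s",
                 paste(missing_chroms, collapse = ", ")), call. = FALSE)
  }

  store_insert(store, "Genome", list(
    id = gname, name = gname, species = manifest$species,
    description = manifest$description, version = manifest$version,
    maintainer = manifest$maintainer,
    chromosome_names = paste(fasta$id, collapse = ",")
  ))
  for (i in seq_len(nrow(fasta))) {
    store_insert(store, "Chromosome",
                 list(id = paste(gname, fasta$id[[i]], sep = ":"),
                      genome = gname, name = fasta$id[[i]],
                      length = nchar(fasta$sequence[[i]])),
                 heavy = list(sequence = fasta$sequence[[i]]))
  }

  exons <- gtf[gtf$feature == "exon", , drop = FALSE]
  cds <- gtf[gtf$feature == "CDS", , drop = FALSE]
  tx_rows <- gtf[gtf$feature == "transcript", , drop = FALSE]
  gene_rows <- gtf[gtf$feature == "gene", , drop = FALSE]
  if (any(is.na(exons$transcript_id))) {
    stop("GTF exon line without transcript_id", call. = FALSE)
  }

  # derive transcript/gene extents when explicit lines are absent
  tx_ids <- unique(c(tx_rows$transcript_id, exons$transcript_id))
  tx_ids <- tx_ids[!is.na(tx_ids)]
  gene_of_tx <- list(); tx_meta <- list()
  for (tid in tx_ids) {
    tex <- exons[exons$transcript_id == tid, , drop = FALSE]
    trow <- tx_rows[tx_rows$transcript_id == tid, , drop = FALSE]
    if (!nrow(tex) && !nrow(trow)) next
    strands <- unique(c(tex$strand, trow$strand))
    if (length(strands) != 1L) {
      stop(sprintf("transcript '%s' mixes strands (%s); mixed-strand transcripts are rejected",
                   tid, paste(strands, collapse = ",")), call. = FALSE)
    }
    gid <- unique(c(tex$gene_id, trow$gene_id))
    gid <- gid[!is.na(gid)]
    if (length(gid) != 1L) {
      stop(sprintf("transcript '%s' must belong to exactly one gene", tid),
           call. = FALSE)
    }
    chrom <- unique(c(tex$chrom, trow$chrom))
    if (length(chrom) != 1L) {
      stop(sprintf("transcript '%s' spans multiple chromosomes", tid),
           call. = FALSE)
    }
    tx_meta[[tid]] <- list(
      gene = gid, chrom = chrom, strand = strands,
      start = min(c(tex$start, trow$start)), end = max(c(tex$end, trow$end))
    )
    gene_of_tx[[tid]] <- gid
  }

  gene_ids <- unique(c(gene_rows$gene_id, unlist(gene_of_tx, use.names = FALSE)))
  gene_ids <- gene_ids[!is.na(gene_ids)]
  for (gid in gene_ids) {
    grow <- gene_rows[gene_rows$gene_id == gid, , drop = FALSE]
    member_tx <- names(gene_of_tx)[vapply(gene_of_tx, identical, TRUE, gid)]
    spans <- do.call(rbind, lapply(member_tx, function(t) {
      c(tx_meta[[t]]$start, tx_meta[[t]]$end)
    }))
    # an explicit gene line is authoritative; bounds are derived from the
    # transcripts only when the GTF has no gene feature
    if (nrow(grow)) {
      g_start <- min(grow$start); g_end <- max(grow$end)
    } else {
      g_start <- min(spans[, 1L]); g_end <- max(spans[, 2L])
    }
    g_strand <- unique(c(grow$strand,
                         vapply(member_tx, function(t) tx_meta[[t]]$strand, "")))
    if (length(g_strand) != 1L) {
      stop(sprintf("gene '%s' mixes strands across its transcripts", gid),
           call. = FALSE)
    }
    g_chrom <- unique(c(grow$chrom,
                        vapply(member_tx, function(t) tx_meta[[t]]$chrom, "")))
    store_insert(store, "Gene", list(
      id = gid, genome = gname,
      name = if (nrow(grow) && !is.na(grow$gene_name[[1L]])) grow$gene_name[[1L]] else gid,
      chromosome = g_chrom[[1L]], start = g_start, end = g_end,
      strand = g_strand
    ))
  }

  for (tid in names(tx_meta)) {
    tm <- tx_meta[[tid]]
    tcds <- cds[!is.na(cds$transcript_id) & cds$transcript_id == tid, , drop = FALSE]
    tcds <- tcds[order(tcds$start), , drop = FALSE]
    if (nrow(tcds)) {
      if (any(tcds$strand != tm$strand)) {
        stop(sprintf("transcript '%s' has CDS on the opposite strand", tid),
             call. = FALSE)
      }
      # frame of the transcription-first CDS interval
      first_i <- if (tm$strand == "-") nrow(tcds) else 1L
      frame <- tcds$frame[[first_i]]
      if (is.na(frame)) frame <- 0
      cds_starts <- paste(tcds$start, collapse = ",")
      cds_ends <- paste(tcds$end, collapse = ",")
    } else {
      frame <- NA_real_; cds_starts <- ""; cds_ends <- ""
    }
    store_insert(store, "Transcript", list(
      id = tid, genome = gname, gene = tm$gene, chromosome = tm$chrom,
      strand = tm$strand, start = tm$start, end = tm$end,
      cds_starts = cds_starts, cds_ends = cds_ends, cds_frame = frame
    ))
    tex <- exons[exons$transcript_id == tid, , drop = FALSE]
    tex <- tex[order(tex$start), , drop = FALSE]
    n_ex <- nrow(tex)
    for (j in seq_len(n_ex)) {
      rank <- tex$exon_number[[j]]
      if (is.na(rank)) {
        rank <- if (tm$strand == "-") n_ex - j + 1L else j
      }
      eid <- tex$exon_id[[j]]
      if (is.na(eid)) eid <- sprintf("%s.E%d", tid, rank)
      store_insert(store, "Exon", list(
        id = eid, genome = gname, transcript = tid, gene = tm$gene,
        chromosome = tm$chrom, strand = tm$strand,
        start = tex$start[[j]], end = tex$end[[j]], rank = rank
      ))
    }
    if (nrow(tcds)) {
      pid <- tcds$protein_id[[1L]]
      if (is.na(pid)) pid <- paste0(tid, "_prot")
      store_insert(store, "Protein",
                   list(id = pid, genome = gname, transcript = tid))
    }
  }
  store_flush(store)
  invisible(gname)
}

remove_genome <- function(store, gname) {
  for (kind in c("Chromosome", "Gene", "Transcript", "Exon", "Protein")) {
    tab <- base::get(kind, envir = store$tables)
    store_delete(store, kind, tab$id[tab$genome == gname])
  }
  store_delete(store, "Genome", gname)
  invisible(store)
}

#' Import a polymorphism-set datawrap
#'
#' Reads the datawrap's variant file(s) (VCF, or a dbSNP-like
#' tab-delimited dialect with columns `chromosome`, `position` (1-based),
#' `ref`, `alt`, and optional `quality` / `validated`) and persists one
#' polymorphism per alternate allele under the set name.
#'
#' @param store a store handle.
#' @param path datawrap directory or tar(.gz) archive.
#' @param force replace an already-imported set of the same name.
#' @return the polymorphism-set name, invisibly.
#' @export
import_polymorphisms <- function(store, path, force = FALSE) {
  check_store(store)
  dw <- resolve_datawrap(path)
  manifest <- read_datawrap_manifest(dw)
  if (manifest$type != "snps") {
    stop("datawrap is not a polymorphism datawrap (no [snps] section)",
         call. = FALSE)
  }
  sname <- manifest$name
  existing <- base::get("PolymorphismSet", envir = store$tables)
  if (sname %in% existing$id) {
    if (!force) {
      stop(sprintf("polymorphism set '%s' is already imported (use force = TRUE to replace)",
                   sname), call. = FALSE)
    }
    tab <- base::get("Polymorphism", envir = store$tables)
    store_delete(store, "Polymorphism", tab$id[tab$set_name == sname])
    store_delete(store, "PolymorphismSet", sname)
  }
  files <- datawrap_file(dw, manifest, "snp")
  variants <- do.call(rbind, lapply(files, function(f) {
    first <- readLines(f, n = 1L, warn = FALSE)
    if (grepl("\\.vcf$", f, ignore.case = TRUE) ||
        (length(first) && startsWith(first, "##fileformat"))) {
      parse_vcf(f)
    } else {
      parse_dbsnp_table(f)
    }
  }))
  store_insert(store, "PolymorphismSet", list(
    id = sname, name = sname, species = manifest$species,
    description = manifest$description, version = manifest$version,
    maintainer = manifest$maintainer
  ))
  for (i in seq_len(NROW(variants))) {
    store_insert(store, "Polymorphism", list(
      id = sprintf("%s:%s:%d:%d", sname, variants$chromosome[[i]],
                   as.integer(variants$position[[i]]), i),
      set_name = sname,
      chromosome = variants$chromosome[[i]],
      position = variants$position[[i]],
      ref_allele = variants$ref_allele[[i]],
      alt_allele = variants$alt_allele[[i]],
      kind = variants$kind[[i]],
      quality = variants$quality[[i]],
      metadata = variants$metadata[[i]]
    ))
  }
  store_flush(store)
  invisible(sname)
}

# dbSNP-like tab-delimited dialect: header + columns chromosome, position
# (1-based), ref, alt (comma-separated), optional quality, validated.
parse_dbsnp_table <- function(path) {
  df <- parse_csv(path, delimiter = "\t")
  names(df) <- tolower(names(df))
  need <- c("chromosome", "position", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("dbSNP-style table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(df))) {
    pos1 <- suppressWarnings(as.numeric(df$position[[i]]))
    if (is.na(pos1)) {
      stop(sprintf("dbSNP-style table: non-numeric position '%s'",
                   df$position[[i]]), call. = FALSE)
    }
    qual <- if ("quality" %in% names(df)) {
      suppressWarnings(as.numeric(df$quality[[i]]))
    } else NA_real_
    validated <- if ("validated" %in% names(df)) {
      toupper(df$validated[[i]]) %in% c("TRUE", "YES", "1", "VLD")
    } else FALSE
    meta <- jsonlite::toJSON(list(filter = NA, info = NA, validated = validated),
                             auto_unbox = TRUE, na = "null")
    for (alt in strsplit(toupper(df$alt[[i]]), ",", fixed = TRUE)[[1L]]) {
      nv <- normalize_variant(pos1 - 1, toupper(df$ref[[i]]), alt)
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = normalize_chrom(df$chromosome[[i]]),
        position = nv$position, ref_allele = nv$ref, alt_allele = nv$alt,
        kind = nv$kind, quality = qual, metadata = as.character(meta),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(chromosome = character(0), position = numeric(0),
                      ref_allele = character(0), alt_allele = character(0),
                      kind = character(0), quality = numeric(0),
                      metadata = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
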