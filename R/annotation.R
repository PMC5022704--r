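# Containment and ordering checks over the imported annotation hierarchy.

#' Validate the annotation hierarchy of an imported genome
#'
#' Checks every containment/ordering invariant of the object hierarchy:
#' chromosome sequence length, gene intervals within chromosome bounds,
#' exons within their gene and non-overlapping within a transcript, exon
#' rank order matching genomic order (reversed on the minus strand), CDS
#' intervals contained in the exon union, strand consistency, and protein
#' records pointing at coding transcripts.
#'
#' @param store a store handle.
#' @param genome_name name of an imported genome.
#' @return data frame of violations (`kind`, `id`, `rule`); zero rows when
#'   the hierarchy is well-formed.
#' @export
validate_hierarchy <- function(store, genome_name) {
  check_store(store)
  genomes <- base::get("Genome", envir = store$tables)
  if (!(genome_name %in% genomes$id)) {
    stop(sprintf("genome '%s' not found", genome_name), call. = FALSE)
  }
  v <- list()
  flag <- function(kind, id, rule) {
    v[[length(v) + 1L]] <<- data.frame(kind = kind, id = id, rule = rule,
                                       stringsAsFactors = FALSE)
  }
  chroms <- subset_tab(store, "Chromosome", genome_name)
  chrom_len <- stats::setNames(chroms$length, chroms$name)
  for (i in seq_len(nrow(chroms))) {
    seq_len_i <- nchar(store_fetch_heavy(store, "Chromosome",
                                         chroms$id[[i]], "sequence"))
    if (seq_len_i != chroms$length[[i]]) {
      flag("Chromosome", chroms$id[[i]],
           "sequence length differs from declared length")
    }
  }
  genes <- subset_tab(store, "Gene", genome_name)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (!(g$chromosome %in% names(chrom_len))) {
      flag("Gene", g$id, "chromosome not present in genome")
      next
    }
    if (!(g$start >= 0 && g$start < g$end && g$end <= chrom_len[[g$chromosome]])) {
      flag("Gene", g$id, "interval outside chromosome bounds")
    }
  }
  gene_iv <- stats::setNames(
    lapply(seq_len(nrow(genes)), function(i) genes[i, ]), genes$id)
  txs <- subset_tab(store, "Transcript", genome_name)
  exons <- subset_tab(store, "Exon", genome_name)
  for (i in seq_len(nrow(txs))) {
    tx <- txs[i, ]
    tex <- exons[exons$transcript == tx$id, , drop = FALSE]
    tex <- tex[order(tex$start, tex$end), , drop = FALSE]
    g <- gene_iv[[tx$gene]]
    if (is.null(g)) {
      flag("Transcript", tx$id, "gene not found")
      next
    }
    if (!identical(tx$strand, g$strand)) {
      flag("Transcript", tx$id, "strand differs from gene strand")
    }
    for (j in seq_len(nrow(tex))) {
      e <- tex[j, ]
      if (!(e$start >= g$start && e$end <= g$end)) {
        flag("Exon", e$id, "exon extends outside its gene interval")
      }
      if (!identical(e$strand, tx$strand)) {
        flag("Exon", e$id, "strand differs from transcript strand")
      }
    }
    if (nrow(tex) > 1L) {
      for (j in 2:nrow(tex)) {
        if (tex$start[[j]] < tex$end[[j - 1L]]) {
          flag("Exon", tex$id[[j]], "overlaps the previous exon of its transcript")
        }
      }
      ranks <- tex$rank
      expected <- if (tx$strand == "-") rev(seq_len(nrow(tex))) else seq_len(nrow(tex))
      if (!identical(as.integer(ranks), as.integer(expected))) {
        flag("Transcript", tx$id,
             "exon ranks do not follow transcription order")
      }
    }
    civ <- transcript_cds_intervals(tx)
    if (nrow(civ)) {
      for (j in seq_len(nrow(civ))) {
        covered <- any(tex$start <= civ$start[[j]] & civ$end[[j]] <= tex$end)
        if (!covered) {
          flag("Transcript", tx$id,
               sprintf("CDS interval [%d,%d) not contained in an exon",
                       civ$start[[j]], civ$end[[j]]))
        }
      }
    }
  }
  prots <- subset_tab(store, "Protein", genome_name)
  for (i in seq_len(nrow(prots))) {
    p <- prots[i, ]
    tx <- txs[txs$id == p$transcript, , drop = FALSE]
    if (!nrow(tx)) {
      flag("Protein", p$id, "transcript not found")
    } else if (is.na(tx$cds_starts[[1L]]) || !nzchar(tx$cds_starts[[1L]])) {
      flag("Protein", p$id, "transcript has no CDS intervals")
    }
  }
  if (!length(v)) {
    return(data.frame(kind = character(0), id = character(0),
                      rule = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

subset_tab <- function(store, kind, genome_name) {
  tab <- base::get(kind, envir = store$tables)
  tab[tab$genome == genome_name, , drop = FALSE]
}
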