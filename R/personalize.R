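# Personalized genomes: bind a reference genome to polymorphism sets and
# an allele filter; lazily produce personalized transcript and protein
# sequences by filter -> insert -> assemble -> translate.

#' Allele decisions
#'
#' The value an allele filter returns for one locus: keep the reference,
#' substitute one base (possibly an IUPAC ambiguity code encoding
#' heterozygosity), insert a sequence immediately after the locus
#' position, or delete `length` bases starting at it.
#'
#' @param sequence replacement base (`decision_substitute`) or inserted
#'   sequence (`decision_insert`).
#' @param ref for substitutions, the expected reference base at the locus;
#'   checked against the actual reference during editing when supplied.
#' @param length number of bases removed by a deletion.
#' @return an `allele_decision` object.
#' @name allele_decision
NULL

new_decision <- function(action, sequence = "", length = 0L, ref = NA_character_) {
  structure(list(action = action, sequence = sequence,
                 length = as.integer(length), ref = ref),
            class = "allele_decision")
}

#' @rdname allele_decision
#' @export
decision_keep <- function() new_decision("keep_reference")

#' @rdname allele_decision
#' @export
decision_substitute <- function(sequence, ref = NA_character_) {
  sequence <- normalize_nucleotides(sequence, "substitution allele")
  if (nchar(sequence) != 1L) {
    stop("substitution decisions are per-base (length-1 allele)", call. = FALSE)
  }
  new_decision("substitute", sequence = sequence, ref = ref)
}

#' @rdname allele_decision
#' @export
decision_insert <- function(sequence) {
  sequence <- normalize_nucleotides(sequence, "inserted allele")
  if (nchar(sequence) < 1L) {
    stop("insertion decisions need a non-empty sequence", call. = FALSE)
  }
  new_decision("insert", sequence = sequence)
}

#' @rdname allele_decision
#' @export
decision_delete <- function(length) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) {
    stop("deletion decisions need length >= 1", call. = FALSE)
  }
  new_decision("delete", length = length)
}

# ---- built-in allele filters -----------------------------------------------
# A filter is a function(chromosome, position, candidates) -> allele_decision,
# where candidates is a list of polymorphism records (plain lists with
# set_name, position, ref_allele, alt_allele, kind, quality, validated).
# It must be deterministic and return a decision for every locus offered.

indel_is_trusted <- function(cand) {
  isTRUE(cand$validated) || (!is.na(cand$quality) && cand$quality >= 30)
}

#' Built-in allele filters
#'
#' * `filter_het_iupac()` (the default): substitutions are encoded as the
#'   minimal IUPAC code covering the reference allele plus every observed
#'   alternate -- heterozygosity-preserving and information-preserving.
#'   Indels are applied only when trusted (metadata marks them validated,
#'   or quality >= 30); a trusted indel takes precedence over
#'   substitutions at the same locus.
#' * `filter_qual_ge(n)`: only candidates with quality >= `n` survive; a
#'   single surviving substitution is applied as its alternate allele,
#'   several as the IUPAC code over their alternates; surviving indels are
#'   applied directly.
#' * `filter_validated_only()`: like `filter_qual_ge` but the survivors
#'   are the candidates whose metadata marks them validated.
#' * `filter_ref_only()`: always keeps the reference.
#'
#' @param n minimum quality for `filter_qual_ge`.
#' @return a filter function for [make_personalized_genome()].
#' @name allele_filters
NULL

#' @rdname allele_filters
#' @export
filter_het_iupac <- function() {
  function(chromosome, position, candidates) {
    indels <- Filter(function(c) c$kind %in% c("insertion", "deletion") &&
                       indel_is_trusted(c), candidates)
    if (length(indels)) {
      ind <- indels[[1L]]
      return(if (ind$kind == "insertion") decision_insert(ind$alt_allele)
             else decision_delete(nchar(ind$ref_allele)))
    }
    subs <- Filter(function(c) c$kind == "substitution", candidates)
    if (!length(subs)) return(decision_keep())
    ref <- subs[[1L]]$ref_allele
    alts <- vapply(subs, function(c) c$alt_allele, "")
    decision_substitute(iupac_code(c(ref, alts)), ref = ref)
  }
}

apply_survivors <- function(survivors) {
  if (!length(survivors)) return(decision_keep())
  indels <- Filter(function(c) c$kind %in% c("insertion", "deletion"), survivors)
  if (length(indels)) {
    ind <- indels[[1L]]
    return(if (ind$kind == "insertion") decision_insert(ind$alt_allele)
           else decision_delete(nchar(ind$ref_allele)))
  }
  alts <- vapply(survivors, function(c) c$alt_allele, "")
  ref <- survivors[[1L]]$ref_allele
  if (length(unique(alts)) == 1L) {
    decision_substitute(alts[[1L]], ref = ref)
  } else {
    decision_substitute(iupac_code(alts), ref = ref)
  }
}

#' @rdname allele_filters
#' @export
filter_qual_ge <- function(n) {
  force(n)
  function(chromosome, position, candidates) {
    apply_survivors(Filter(function(c) !is.na(c$quality) && c$quality >= n,
                           candidates))
  }
}

#' @rdname allele_filters
#' @export
filter_validated_only <- function() {
  function(chromosome, position, candidates) {
    apply_survivors(Filter(function(c) isTRUE(c$validated), candidates))
  }
}

#' @rdname allele_filters
#' @export
filter_ref_only <- function() {
  function(chromosome, position, candidates) decision_keep()
}

#' Resolve a named filter (CLI convenience)
#'
#' @param name `"het-iupac"`, `"qual-ge:<N>"`, `"validated-only"` or
#'   `"ref-only"`.
#' @return the corresponding filter function.
#' @export
resolve_filter <- function(name) {
  if (identical(name, "het-iupac")) return(filter_het_iupac())
  if (identical(name, "validated-only")) return(filter_validated_only())
  if (identical(name, "ref-only")) return(filter_ref_only())
  m <- regmatches(name, regexec("^qual-ge:([0-9.]+)$", name))[[1L]]
  if (length(m) == 2L) return(filter_qual_ge(as.numeric(m[[2L]])))
  stop(sprintf("unknown filter '%s' (known: het-iupac, qual-ge:<N>, validated-only, ref-only)",
               name), call. = FALSE)
}

# ---- personalized genome handle --------------------------------------------

#' Create a personalized genome
#'
#' Binds an imported reference genome to an ordered list of imported
#' polymorphism sets and an allele filter. Construction is cheap and
#' loads no sequences; personalized transcript and protein sequences are
#' materialized lazily by [pg_transcript_sequence()] /
#' [pg_protein_sequence()] and cached on the handle. Several handles over
#' the same reference share its records (and thus its chromosome
#' sequences) through the store's singleton cache.
#'
#' @param store a store handle.
#' @param reference name of an imported reference genome.
#' @param sets character vector of imported polymorphism-set names.
#' @param filter an allele filter function (see [allele_filters]);
#'   defaults to `filter_het_iupac()`.
#' @param clip_policy what to do when a retained deletion runs past an
#'   exon/CDS boundary: `"clip"` truncates it to the overlapping part
#'   with a warning, `"strict"` raises an error.
#' @return a `personalized_genome` handle.
#' @export
make_personalized_genome <- function(store, reference, sets = character(),
                                     filter = filter_het_iupac(),
                                     clip_policy = c("clip", "strict")) {
  check_store(store)
  clip_policy <- match.arg(clip_policy)
  genomes <- base::get("Genome", envir = store$tables)
  if (!(reference %in% genomes$id)) {
    stop(sprintf("reference genome '%s' not found", reference), call. = FALSE)
  }
  known_sets <- base::get("PolymorphismSet", envir = store$tables)$id
  missing <- setdiff(sets, known_sets)
  if (length(missing)) {
    stop(sprintf("polymorphism set(s) not found: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  stopifnot(is.function(filter))
  pg <- new.env(parent = emptyenv())
  pg$store <- store
  pg$reference <- reference
  pg$sets <- as.character(sets)
  pg$filter <- filter
  pg$clip_policy <- clip_policy
  pg$cache <- new.env(parent = emptyenv())
  class(pg) <- "personalized_genome"
  pg
}

#' @export
print.personalized_genome <- function(x, ...) {
  cat(sprintf("<personalized genome over '%s'; sets: %s>\n", x$reference,
              if (length(x$sets)) paste(x$sets, collapse = ", ") else "(none)"))
  invisible(x)
}

# ---- locus decisions -------------------------------------------------------

poly_candidates <- function(store, set_name, chromosome, start, end) {
  idx <- annotation_index(store, "Polymorphism", "set_name", set_name,
                          chromosome)
  ids <- query_overlaps(idx, start, end)
  if (!length(ids)) return(list())
  tab <- base::get("Polymorphism", envir = store$tables)
  rows <- tab[match(ids, tab$id), , drop = FALSE]
  lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    md <- tryCatch(jsonlite::fromJSON(r$metadata), error = function(e) list())
    list(id = r$id, set_name = r$set_name, chromosome = r$chromosome,
         position = r$position, ref_allele = r$ref_allele,
         alt_allele = r$alt_allele, kind = r$kind, quality = r$quality,
         validated = isTRUE(md$validated), metadata = md)
  })
}

# Edited span of a decision at `position`, used for the overlap check.
# Substitutions cover [p, p+1), deletions [p, p+len); an insertion edits
# the boundary between p and p+1, represented as the zero-width point at
# p + 1.
decision_span <- function(position, decision) {
  switch(decision$action,
    substitute = c(position, position + 1L),
    delete = c(position, position + decision$length),
    insert = c(position + 1L, position + 1L),
    keep_reference = c(position, position)
  )
}

#' Collect filtered allele decisions for a genomic interval
#'
#' Polymorphisms from all of the personalized genome's sets overlapping
#' `[start, end)` are grouped by locus (position) and offered to the
#' allele filter once per locus; `keep_reference` decisions are dropped.
#' Retained deletions crossing the interval boundary are clipped (or
#' rejected under `clip_policy = "strict"`). Two retained decisions whose
#' edited spans overlap are a conflict: the filter must resolve them, the
#' engine refuses to guess.
#'
#' @param pg a personalized genome.
#' @param chromosome chromosome name.
#' @param start,end interval, 0-based half-open.
#' @return list of decisions sorted by position; each element carries
#'   `position` and the `allele_decision` fields.
#' @export
collect_locus_decisions <- function(pg, chromosome, start, end) {
  stopifnot(inherits(pg, "personalized_genome"))
  chromosome <- normalize_chrom(chromosome)
  cands <- list()
  for (s in pg$sets) {
    cands <- c(cands, poly_candidates(pg$store, s, chromosome, start, end))
  }
  if (!length(cands)) return(list())
  positions <- vapply(cands, function(c) c$position, 0)
  decisions <- list()
  for (p in sort(unique(positions))) {
    at_locus <- cands[positions == p]
    d <- pg$filter(chromosome, p, at_locus)
    if (!inherits(d, "allele_decision")) {
      stop("allele filter must return an allele_decision", call. = FALSE)
    }
    if (d$action == "keep_reference") next
    pos <- p
    if (d$action == "delete") {
      del_start <- pos; del_end <- pos + d$length
      if (del_start < start || del_end > end) {
        if (pg$clip_policy == "strict") {
          stop(sprintf("deletion at %d (length %d) crosses the interval boundary [%d, %d)",
                       pos, d$length, start, end), call. = FALSE)
        }
        new_start <- max(del_start, start)
        new_end <- min(del_end, end)
        warning(sprintf("deletion at %d clipped to [%d, %d) at an interval boundary",
                        pos, new_start, new_end), call. = FALSE)
        pos <- new_start
        d <- decision_delete(new_end - new_start)
      }
    }
    decisions[[length(decisions) + 1L]] <-
      c(list(position = pos), unclass(d))
  }
  if (length(decisions) > 1L) {
    spans <- t(vapply(decisions, function(d) {
      decision_span(d$position, d)
    }, c(0, 0)))
    o <- order(spans[, 1L], spans[, 2L])
    for (i in seq_len(length(o) - 1L)) {
      a <- spans[o[i], ]; b <- spans[o[i + 1L], ]
      overlap <- if (a[2L] > a[1L] && b[2L] > b[1L]) {
        b[1L] < a[2L]                      # two real spans
      } else {
        # zero-width (insertion point) vs a real span: conflict only when
        # the point falls strictly inside the span
        pt <- if (a[2L] == a[1L]) a[1L] else b[1L]
        sp <- if (a[2L] == a[1L]) b else a
        sp[1L] < pt && pt < sp[2L]
      }
      if (overlap) {
        stop(sprintf("conflicting allele decisions at loci %s and %s on chromosome %s; the filter must resolve overlaps",
                     format(decisions[[o[i]]]$position, trim = TRUE),
                     format(decisions[[o[i + 1L]]]$position, trim = TRUE),
                     chromosome), call. = FALSE)
      }
    }
  }
  decisions[order(vapply(decisions, function(d) d$position, 0))]
}

# ---- the edit engine -------------------------------------------------------

#' Apply allele decisions to a reference slice
#'
#' Edits are applied in descending position order, so coordinate shifts
#' from insertions/deletions stay local and earlier coordinates never
#' move. Substitutions replace one base (checked against the decision's
#' expected reference allele when present), insertions add their sequence
#' immediately after the anchor position, deletions remove `length`
#' bases.
#'
#' @param ref_seq reference sequence of the region.
#' @param region_start genomic coordinate of the first base of `ref_seq`.
#' @param decisions sorted, non-overlapping decisions from
#'   [collect_locus_decisions()] (or built by hand).
#' @param clip_policy `"clip"` truncates deletions running past the
#'   region end (with a warning); `"strict"` errors.
#' @return the personalized sequence; its length is
#'   `nchar(ref_seq) + sum(insertions) - sum(deletions)`.
#' @export
#' @examples
#' personalize_region("ATGCCC", 0,
#'   list(c(list(position = 3), unclass(decision_substitute("G")))))
personalize_region <- function(ref_seq, region_start, decisions,
                               clip_policy = c("clip", "strict")) {
  clip_policy <- match.arg(clip_policy)
  s <- normalize_nucleotides(ref_seq, "region sequence")
  n <- nchar(s)
  if (!length(decisions)) return(s)
  pos <- vapply(decisions, function(d) as.numeric(d$position), 0)
  if (any(pos < region_start | pos >= region_start + n)) {
    stop(sprintf("decision position outside region [%d, %d)",
                 region_start, region_start + n), call. = FALSE)
  }
  for (k in order(pos, decreasing = TRUE)) {
    d <- decisions[[k]]
    i <- pos[[k]] - region_start + 1L   # 1-based index into s
    if (d$action == "substitute") {
      found <- substr(s, i, i)
      if (!is.null(d$ref) && !is.na(d$ref) && nzchar(d$ref) && found != d$ref) {
        stop(sprintf("reference mismatch at position %s: expected '%s', found '%s'",
                     format(pos[[k]], trim = TRUE), d$ref, found),
             call. = FALSE)
      }
      s <- paste0(substr(s, 1L, i - 1L), d$sequence,
                  substr(s, i + 1L, nchar(s)))
    } else if (d$action == "insert") {
      s <- paste0(substr(s, 1L, i), d$sequence, substr(s, i + 1L, nchar(s)))
    } else if (d$action == "delete") {
      len <- d$length
      if (i + len - 1L > nchar(s)) {
        if (clip_policy == "strict") {
          stop(sprintf("deletion at position %s (length %d) runs past the region end",
                       format(pos[[k]], trim = TRUE), len), call. = FALSE)
        }
        warning(sprintf("deletion at position %s clipped at the region end",
                        format(pos[[k]], trim = TRUE)), call. = FALSE)
        len <- nchar(s) - i + 1L
      }
      s <- paste0(substr(s, 1L, i - 1L), substr(s, i + len, nchar(s)))
    } else {
      stop(sprintf("unknown decision action '%s'", d$action), call. = FALSE)
    }
  }
  s
}

# ---- transcript / protein assembly -----------------------------------------

#' Personalized transcript sequence
#'
#' Each exon (or CDS interval) is personalized independently --
#' polymorphisms overlapping it are collected, filtered and inserted --
#' then the pieces are concatenated in genomic order; minus-strand
#' transcripts are reverse-complemented, and for the CDS a nonzero frame
#' on the transcription-first CDS interval trims that many leading bases.
#' Results are cached on the personalized genome.
#'
#' @param pg a personalized genome.
#' @param transcript_id transcript id.
#' @param which `"full"` (exons) or `"cds"`.
#' @return the personalized nucleotide sequence.
#' @export
pg_transcript_sequence <- function(pg, transcript_id, which = c("full", "cds")) {
  stopifnot(inherits(pg, "personalized_genome"))
  which <- match.arg(which)
  key <- paste(transcript_id, which, sep = "\x01")
  hit <- pg$cache[[key]]
  if (!is.null(hit)) return(hit)
  store <- pg$store
  tx <- one_row(store, "Transcript", transcript_id)
  if (!identical(tx$genome, pg$reference)) {
    stop(sprintf("transcript '%s' belongs to genome '%s', not '%s'",
                 transcript_id, tx$genome, pg$reference), call. = FALSE)
  }
  iv <- if (which == "full") {
    transcript_exon_intervals(store, transcript_id)
  } else {
    transcript_cds_intervals(tx)
  }
  if (!nrow(iv)) {
    pg$cache[[key]] <- ""
    return("")
  }
  chrom <- record_by_id(store, "Chromosome",
                        paste(tx$genome, tx$chromosome, sep = ":"))
  chrom_seq <- chrom$sequence
  parts <- vapply(seq_len(nrow(iv)), function(j) {
    s0 <- iv$start[[j]]; e0 <- iv$end[[j]]
    tryCatch({
      decs <- collect_locus_decisions(pg, tx$chromosome, s0, e0)
      personalize_region(substring(chrom_seq, s0 + 1L, e0), s0, decs,
                         clip_policy = pg$clip_policy)
    }, error = function(e) {
      stop(sprintf("while personalizing transcript '%s': %s",
                   transcript_id, conditionMessage(e)), call. = FALSE)
    })
  }, "")
  s <- paste(parts, collapse = "")
  if (identical(tx$strand, "-")) s <- reverse_complement(s)
  if (which == "cds") {
    frame <- tx$cds_frame
    if (!is.na(frame) && frame > 0) s <- substring(s, frame + 1L)
  }
  pg$cache[[key]] <- s
  s
}

#' Personalized protein sequence
#'
#' Translates the personalized CDS of the protein's transcript
#' (truncating at the first stop codon). Heterozygous substitutions
#' encoded as IUPAC codes translate to the unique amino acid when every
#' expansion agrees, otherwise `X`. Computed lazily on first access and
#' cached.
#'
#' @param pg a personalized genome.
#' @param protein_id protein id (as created at import).
#' @return the personalized amino-acid sequence.
#' @export
pg_protein_sequence <- function(pg, protein_id) {
  stopifnot(inherits(pg, "personalized_genome"))
  key <- paste("prot", protein_id, sep = "\x01")
  hit <- pg$cache[[key]]
  if (!is.null(hit)) return(hit)
  prot <- one_row(pg$store, "Protein", protein_id)
  cds <- pg_transcript_sequence(pg, prot$transcript, "cds")
  if (!nzchar(cds)) {
    warning(sprintf("protein '%s': transcript has an empty CDS", protein_id),
            call. = FALSE)
    pg$cache[[key]] <- ""
    return("")
  }
  aa <- translate_cds(cds, "truncate_at_stop")
  pg$cache[[key]] <- aa
  aa
}

#' Export personalized sequences as FASTA
#'
#' One record per id, written in sorted-id order; headers follow
#' `<id>|<genome>|<set names>`.
#'
#' @param pg a personalized genome.
#' @param ids transcript or protein ids.
#' @param path output FASTA path.
#' @param type `"transcript"` or `"protein"`.
#' @param which for transcripts, `"full"` or `"cds"`.
#' @return `path`, invisibly.
#' @export
pg_export_fasta <- function(pg, ids, path, type = c("transcript", "protein"),
                            which = "full") {
  stopifnot(inherits(pg, "personalized_genome"))
  type <- match.arg(type)
  ids <- sort(ids)
  seqs <- vapply(ids, function(id) {
    if (type == "transcript") pg_transcript_sequence(pg, id, which)
    else pg_protein_sequence(pg, id)
  }, "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- sprintf("%s|%s|%s", ids, pg$reference,
                        paste(pg$sets, collapse = ","))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
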