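# Independent naive oracle used by the fixture generator's ground-truth
# ledger (and by tests as the second route of dual-route checks). Nothing
# here calls the sequence, store or personalization code paths: the
# complement table, genetic code, ambiguity expansions, editor and
# assembly are all separate, deliberately naive implementations.

.ORACLE_CODON <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

.ORACLE_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.ORACLE_IUPAC <- local({
  keys <- vapply(.ORACLE_EXPAND, function(b) paste(sort(b), collapse = ""), "")
  stats::setNames(names(.ORACLE_EXPAND), keys)
})

#' Naive reference implementations (the oracle)
#'
#' Deliberately simple, table-driven re-implementations of reverse
#' complementation, ambiguity-aware translation and sequence editing,
#' kept fully independent of the main pipeline so they can serve as
#' ground truth: the fixture generator's ledger is computed with these,
#' and property tests compare the pipeline against them.
#'
#' @param seq a nucleotide string.
#' @return `oracle_reverse_complement`: the reverse complement.
#' @name oracle
NULL

#' @rdname oracle
#' @export
oracle_reverse_complement <- function(seq) {
  if (!nzchar(seq)) return(seq)
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(seq))
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

# Translate one codon (possibly ambiguous) by brute-force expansion:
# emit the amino acid iff every expansion agrees, else "X".
oracle_codon <- function(codon) {
  bases <- strsplit(toupper(codon), "", fixed = TRUE)[[1L]]
  grid <- expand.grid(.ORACLE_EXPAND[[bases[1L]]],
                      .ORACLE_EXPAND[[bases[2L]]],
                      .ORACLE_EXPAND[[bases[3L]]],
                      stringsAsFactors = FALSE)
  aas <- unique(.ORACLE_CODON[paste0(grid[[1L]], grid[[2L]], grid[[3L]])])
  if (length(aas) == 1L) aas else "X"
}

#' @rdname oracle
#' @param cds in-frame coding sequence.
#' @param truncate_at_stop stop translating before the first stop codon
#'   (default) instead of marking stops with `*`.
#' @export
oracle_translate <- function(cds, truncate_at_stop = TRUE) {
  s <- chartr("U", "T", toupper(cds))
  n <- nchar(s) %/% 3L
  out <- character(0)
  for (i in seq_len(n)) {
    aa <- oracle_codon(substr(s, 3L * i - 2L, 3L * i))
    if (truncate_at_stop && aa == "*") break
    out <- c(out, aa)
  }
  paste(out, collapse = "")
}

#' @rdname oracle
#' @param ref_seq reference sequence of a region.
#' @param region_start genomic coordinate of its first base.
#' @param edits list of edits, each a list with `position` and `action`
#'   (`"substitute"`/`"insert"`/`"delete"`) plus `sequence` or `length`.
#' @details `oracle_edit_sequence` edits a position-tagged character
#'   list: every reference base keeps its original genomic coordinate, so
#'   edits address bases by tag and never shift each other, whatever
#'   order they are applied in.
#' @export
oracle_edit_sequence <- function(ref_seq, region_start, edits) {
  chars <- strsplit(toupper(ref_seq), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  keep <- rep(TRUE, n)
  after <- rep("", n)           # sequence inserted after base i
  for (e in edits) {
    i <- as.integer(e$position - region_start + 1L)
    if (i < 1L || i > n) {
      stop(sprintf("oracle: edit position %s outside region",
                   format(e$position, trim = TRUE)), call. = FALSE)
    }
    if (e$action == "substitute") {
      chars[i] <- toupper(e$sequence)
    } else if (e$action == "insert") {
      after[i] <- paste0(after[i], toupper(e$sequence))
    } else if (e$action == "delete") {
      j <- min(n, i + e$length - 1L)
      keep[i:j] <- FALSE
    } else {
      stop(sprintf("oracle: unknown action '%s'", e$action), call. = FALSE)
    }
  }
  pieces <- character(0)
  for (i in seq_len(n)) {
    if (keep[i]) pieces <- c(pieces, chars[i])
    if (nzchar(after[i])) pieces <- c(pieces, after[i])
  }
  paste(pieces, collapse = "")
}

# Naive re-statement of the default het-IUPAC filter semantics, used by
# the ledger: trusted indel first, else IUPAC over {ref} + alts of the
# substitutions, else keep.
oracle_default_decisions <- function(variants, start, end) {
  # variants: data frame (position, ref_allele, alt_allele, kind, quality,
  # validated); spans: sub/ins anchor [p, p+1), del [p, p+len)
  span_end <- variants$position + pmax(1L, nchar(variants$ref_allele))
  inside <- variants$position < end & span_end > start
  v <- variants[inside, , drop = FALSE]
  edits <- list()
  for (p in sort(unique(v$position))) {
    at <- v[v$position == p, , drop = FALSE]
    trusted <- at$kind %in% c("insertion", "deletion") &
      (at$validated | (!is.na(at$quality) & at$quality >= 30))
    if (any(trusted)) {
      ind <- at[which(trusted)[1L], ]
      edits[[length(edits) + 1L]] <- if (ind$kind == "insertion") {
        list(position = p, action = "insert", sequence = ind$alt_allele)
      } else {
        len <- nchar(ind$ref_allele)
        # mirror the engine's boundary clipping
        list(position = max(p, start), action = "delete",
             length = min(p + len, end) - max(p, start))
      }
      next
    }
    subs <- at[at$kind == "substitution", , drop = FALSE]
    if (nrow(subs)) {
      bases <- sort(unique(c(subs$ref_allele[[1L]], subs$alt_allele)))
      code <- .ORACLE_IUPAC[[paste(bases, collapse = "")]]
      edits[[length(edits) + 1L]] <-
        list(position = p, action = "substitute", sequence = code)
    }
  }
  edits
}

#' @rdname oracle
#' @param chrom_seq full chromosome sequence.
#' @param intervals data frame of genomic intervals (`start`, `end`).
#' @param strand `"+"` or `"-"`.
#' @param variants optional planted-variant table (as in the fixture
#'   ledger) applied under the default-filter semantics.
#' @param frame leading bases to trim after assembly (CDS frame).
#' @details `oracle_transcript_sequence` assembles one transcript the
#'   naive way: slice each interval from the chromosome, edit it with the
#'   tagged-list editor, concatenate, reverse-complement on the minus
#'   strand, frame-trim.
#' @export
oracle_transcript_sequence <- function(chrom_seq, intervals, strand,
                                       variants = NULL, frame = 0) {
  parts <- vapply(seq_len(nrow(intervals)), function(j) {
    s0 <- intervals$start[[j]]; e0 <- intervals$end[[j]]
    slice <- substr(chrom_seq, s0 + 1L, e0)
    if (is.null(variants) || !nrow(variants)) return(slice)
    edits <- oracle_default_decisions(variants, s0, e0)
    oracle_edit_sequence(slice, s0, edits)
  }, "")
  s <- paste(parts, collapse = "")
  if (identical(strand, "-")) s <- oracle_reverse_complement(s)
  if (!is.na(frame) && frame > 0) s <- substring(s, frame + 1L)
  s
}
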