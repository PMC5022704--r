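# Nucleotide/protein string primitives: alphabet validation, complementation,
# IUPAC ambiguity expansion and CDS translation.

# IUPAC ambiguity expansions (concrete bases expand to themselves).
.IUPAC_EXPAND <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# Reverse lookup: sorted concatenation of bases -> IUPAC code.
.IUPAC_FROM_BASES <- local({
  keys <- vapply(strsplit(.IUPAC_EXPAND, ""),
                 function(b) paste(sort(b), collapse = ""), "")
  stats::setNames(names(.IUPAC_EXPAND), keys)
})

.NUC_ALPHABET <- c(names(.IUPAC_EXPAND), "-")

#' Normalize and validate a nucleotide string
#'
#' Upper-cases the input, converts RNA `U` to `T`, and verifies that every
#' character is a concrete base, an IUPAC ambiguity code, or the gap
#' character `-`.
#'
#' @param seq a single character string.
#' @param what label used in error messages.
#' @return the normalized string.
#' @export
#' @examples
#' normalize_nucleotides("acgu")  # "ACGT"
normalize_nucleotides <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  s <- chartr("u", "U", toupper(seq))
  s <- chartr("U", "T", s)
  if (!nzchar(s)) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% .NUC_ALPHABET))
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d in %s",
                 chars[bad[1L]], bad[1L], what), call. = FALSE)
  }
  s
}

#' Reverse complement of a nucleotide string
#'
#' IUPAC ambiguity codes map to their IUPAC complements (R<->Y, K<->M,
#' S<->S, W<->W, B<->V, D<->H, N<->N); gaps are preserved.
#'
#' @param seq nucleotide string (DNA or RNA; RNA is normalized to DNA).
#' @return the reverse-complemented string.
#' @export
#' @examples
#' reverse_complement("AAC")  # "GTT"
#' reverse_complement("RG")   # "CY"
reverse_complement <- function(seq) {
  s <- normalize_nucleotides(seq)
  if (!nzchar(s)) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Expand an IUPAC ambiguity code to its concrete bases
#'
#' @param code a single character; concrete bases expand to themselves.
#' @return character vector of concrete bases, sorted.
#' @export
#' @examples
#' expand_ambiguity("R")  # c("A", "G")
expand_ambiguity <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  code <- chartr("U", "T", toupper(code))
  if (nchar(code) != 1L || !(code %in% names(.IUPAC_EXPAND))) {
    stop(sprintf("'%s' is not a nucleotide or IUPAC ambiguity code", code),
         call. = FALSE)
  }
  sort(strsplit(.IUPAC_EXPAND[[code]], "", fixed = TRUE)[[1L]])
}

#' Minimal IUPAC code covering a set of bases
#'
#' @param bases character vector of concrete bases (A/C/G/T).
#' @return the single IUPAC character whose expansion is exactly the set.
#' @export
#' @examples
#' iupac_code(c("A", "G"))  # "R"
iupac_code <- function(bases) {
  bases <- sort(unique(chartr("U", "T", toupper(bases))))
  if (!length(bases) || !all(bases %in% c("A", "C", "G", "T"))) {
    stop("iupac_code() expects a non-empty set of concrete bases",
         call. = FALSE)
  }
  .IUPAC_FROM_BASES[[paste(bases, collapse = "")]]
}

#' Translate an in-frame coding sequence
#'
#' Codon-by-codon translation under the standard genetic code. A codon
#' containing ambiguity codes yields the unique amino acid when every
#' expansion agrees, otherwise `X`. A trailing incomplete codon is
#' ignored. Under `truncate_at_stop` (the default) translation ends
#' before the first stop codon; under `mark_stops` stops emit `*` and
#' translation continues.
#'
#' @param cds in-frame coding sequence (frame 0; the caller supplies any
#'   frame-trimmed CDS).
#' @param stop_policy `"truncate_at_stop"` or `"mark_stops"`.
#' @return amino-acid string (one-letter codes, `X` ambiguous, `*` stop).
#' @export
#' @examples
#' translate_cds("ATGAAA")                  # "MK"
#' translate_cds("ATGTAAAAA")               # "M"
#' translate_cds("ATGTAAAAA", "mark_stops") # "M*K"
translate_cds <- function(cds, stop_policy = c("truncate_at_stop", "mark_stops")) {
  stop_policy <- match.arg(stop_policy)
  s <- normalize_nucleotides(cds, what = "CDS")
  if (grepl("-", s, fixed = TRUE)) {
    stop("cannot translate a gapped sequence", call. = FALSE)
  }
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  s <- substr(s, 1L, 3L * n)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           if.fuzzy.codon = "solve",
                                           no.init.codon = TRUE))
  if (stop_policy == "truncate_at_stop") {
    aa <- sub("\\*.*$", "", aa)
  }
  aa
}
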