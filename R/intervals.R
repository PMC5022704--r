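# Interval indexing: map genomic positions/ranges to overlapping
# annotation records and polymorphisms. Intervals are internal 0-based
# half-open; the balanced search structure behind the index is IRanges'
# nested containment list, wrapped so the contract stays "exactly the
# entries overlapping the query range".

#' Build an interval index
#'
#' Duplicate intervals are allowed and preserved (multiset semantics).
#' Zero-length loci (insertion anchors) must be indexed by the caller as
#' `[pos, pos + 1)`.
#'
#' @param entries data frame with numeric `start`, `end` (0-based
#'   half-open, `start < end`) and `id` payload.
#' @return an interval index for [query_overlaps()].
#' @export
build_interval_index <- function(entries) {
  if (!is.data.frame(entries) || !all(c("start", "end", "id") %in% names(entries))) {
    stop("entries must be a data frame with start, end, id", call. = FALSE)
  }
  start <- as.numeric(entries$start)
  end <- as.numeric(entries$end)
  if (any(is.na(start)) || any(is.na(end))) {
    stop("interval error: non-numeric start/end", call. = FALSE)
  }
  if (any(start < 0)) {
    stop("interval error: negative start coordinate", call. = FALSE)
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("interval error: start >= end for entry %d ([%s, %s))",
                 bad[[1L]], format(start[bad[[1L]]], trim = TRUE),
                 format(end[bad[[1L]]], trim = TRUE)), call. = FALSE)
  }
  o <- order(start, end, as.character(entries$id))
  entries <- data.frame(start = start[o], end = end[o],
                        id = as.character(entries$id)[o],
                        stringsAsFactors = FALSE)
  structure(
    list(entries = entries,
         ranges = IRanges::IRanges(start = entries$start + 1L,
                                   end = entries$end)),
    class = "interval_index"
  )
}

#' @export
print.interval_index <- function(x, ...) {
  cat(sprintf("<interval index: %d entries>\n", nrow(x$entries)))
  invisible(x)
}

#' Query an interval index for overlapping entries
#'
#' Half-open overlap: an entry is returned iff `entry.start < end` and
#' `start < entry.end`. A point query (`start == end`) therefore returns
#' nothing; use `[pos, pos + 1)` for point lookups. Results are sorted by
#' (start, end, id) for determinism.
#'
#' @param index an index from [build_interval_index()].
#' @param start,end query range, 0-based half-open, `0 <= start <= end`.
#' @return character vector of payload ids (duplicates preserved).
#' @export
query_overlaps <- function(index, start, end) {
  stopifnot(inherits(index, "interval_index"))
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || end < start) {
    stop("interval error: query must satisfy 0 <= start <= end", call. = FALSE)
  }
  if (start == end || nrow(index$entries) == 0L) return(character(0))
  hits <- IRanges::findOverlaps(IRanges::IRanges(start + 1L, end), index$ranges)
  index$entries$id[sort(S4Vectors::subjectHits(hits))]
}

# Cached interval index over one kind of record on one chromosome of one
# genome (or one polymorphism set). Rebuilt whenever the store mutates.
annotation_index <- function(store, kind, key_field, key_value, chromosome) {
  cache_key <- paste(kind, key_value, chromosome, sep = "\x01")
  hit <- store$ix_cache[[cache_key]]
  if (!is.null(hit) && identical(hit$built_gen, store$generation)) {
    return(hit$index)
  }
  tab <- base::get(kind, envir = store$tables)
  tab <- tab[tab[[key_field]] == key_value & tab$chromosome == chromosome, ,
             drop = FALSE]
  entries <- if (kind == "Polymorphism") {
    # substitution [p, p+1); deletion [p, p+len(ref)); insertion anchored
    # [p, p+1) so exon-range queries find it
    data.frame(start = tab$position,
               end = tab$position + pmax(1L, nchar(tab$ref_allele)),
               id = tab$id, stringsAsFactors = FALSE)
  } else {
    data.frame(start = tab$start, end = tab$end, id = tab$id,
               stringsAsFactors = FALSE)
  }
  index <- build_interval_index(entries)
  store$ix_cache[[cache_key]] <- list(built_gen = store$generation,
                                      index = index)
  index
}

#' Annotation records overlapping one genomic position
#'
#' @param store a store handle.
#' @param genome genome name.
#' @param chromosome chromosome name.
#' @param pos 0-based position; must satisfy `0 <= pos < chromosome length`.
#' @return data frame (`kind`, `id`) of the genes, transcripts and exons
#'   whose half-open intervals contain `pos`.
#' @export
annotate_position <- function(store, genome, chromosome, pos) {
  check_store(store)
  chromosome <- normalize_chrom(chromosome)
  chrom <- one_row(store, "Chromosome", paste(genome, chromosome, sep = ":"))
  pos <- as.numeric(pos)
  if (is.na(pos) || pos < 0 || pos >= chrom$length) {
    stop(sprintf("coordinate error: position %s outside chromosome '%s' [0, %d)",
                 format(pos, trim = TRUE), chromosome, chrom$length),
         call. = FALSE)
  }
  out <- list()
  for (kind in c("Gene", "Transcript", "Exon")) {
    idx <- annotation_index(store, kind, "genome", genome, chromosome)
    ids <- query_overlaps(idx, pos, pos + 1L)
    if (length(ids)) {
      out[[kind]] <- data.frame(kind = kind, id = ids, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(kind = character(0), id = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
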