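# Lazy singleton records. A record is an environment holding its light
# fields; heavy fields (sequences) are inflated through the store on first
# `$` access and cached on the record, which is shared by every handle
# that resolves the same (kind, id) within a session.

record_skey <- function(kind, id) paste(kind, id, sep = "\x01")

# Construct (or return the cached singleton for) a record from a light row.
make_record <- function(store, kind, row) {
  skey <- record_skey(kind, row$id)
  cached <- store$singletons[[skey]]
  if (!is.null(cached)) return(cached)
  rec <- new.env(parent = emptyenv())
  assign(".store", store, envir = rec)
  assign(".kind", kind, envir = rec)
  assign(".id", row$id, envir = rec)
  light <- .GENO_SCHEMA[[kind]]$light
  for (cl in light) assign(cl, row[[cl]], envir = rec)
  assign(".loaded", light, envir = rec)
  class(rec) <- "geno_record"
  store$singletons[[skey]] <- rec
  rec
}

#' Names of the fields currently materialized on a record
#'
#' Grows monotonically: a fresh record from [get_records()] holds only its
#' light fields; heavy fields join the set on first access and are never
#' dropped.
#'
#' @param record a record returned by [get_records()].
#' @return character vector of loaded field names.
#' @export
record_loaded_fields <- function(record) {
  stopifnot(inherits(record, "geno_record"))
  base::get(".loaded", envir = record, inherits = FALSE)
}

#' Record kind
#' @param record a record.
#' @return the record-kind tag, e.g. `"Gene"`.
#' @export
record_kind <- function(record) {
  stopifnot(inherits(record, "geno_record"))
  base::get(".kind", envir = record, inherits = FALSE)
}

record_store <- function(record) base::get(".store", envir = record, inherits = FALSE)

#' Access a record field (inflating heavy fields on first use)
#'
#' @param x a record.
#' @param name field name.
#' @export
`$.geno_record` <- function(x, name) {
  record_field(x, name)
}

#' @export
`[[.geno_record` <- function(x, name) record_field(x, name)

#' @export
`$<-.geno_record` <- function(x, name, value) {
  stop("records are read-only; modify data through imports", call. = FALSE)
}

#' @export
names.geno_record <- function(x) kind_fields(record_kind(x))

#' @export
print.geno_record <- function(x, ...) {
  kind <- record_kind(x)
  loaded <- record_loaded_fields(x)
  cat(sprintf("<%s '%s'>\n", kind, base::get(".id", envir = x, inherits = FALSE)))
  for (f in kind_fields(kind)) {
    if (f %in% loaded) {
      v <- base::get(f, envir = x, inherits = FALSE)
      v <- as.character(v)
      if (!is.na(v) && nchar(v) > 40L) v <- paste0(substr(v, 1L, 37L), "...")
      cat(sprintf("  %s: %s\n", f, v))
    } else {
      cat(sprintf("  %s: <deferred>\n", f))
    }
  }
  invisible(x)
}

#' @export
as.list.geno_record <- function(x, ...) {
  loaded <- record_loaded_fields(x)
  stats::setNames(lapply(loaded, function(f) {
    base::get(f, envir = x, inherits = FALSE)
  }), loaded)
}

record_field <- function(rec, name) {
  loaded <- base::get(".loaded", envir = rec, inherits = FALSE)
  if (name %in% loaded) {
    return(base::get(name, envir = rec, inherits = FALSE))
  }
  kind <- base::get(".kind", envir = rec, inherits = FALSE)
  sch <- .GENO_SCHEMA[[kind]]
  if (!(name %in% sch$heavy)) {
    stop(sprintf("unknown field '%s' for kind %s", name, kind), call. = FALSE)
  }
  store <- record_store(rec)
  id <- base::get(".id", envir = rec, inherits = FALSE)
  val <- inflate_heavy(store, kind, id, name)
  assign(name, val, envir = rec)
  assign(".loaded", c(loaded, name), envir = rec)
  val
}

# Heavy-field inflation. Chromosome sequences are stored values fetched
# from the file by a second read; transcript and protein sequences are
# derived from other records (which may cascade further loads). Each call
# here is one load event.
inflate_heavy <- function(store, kind, id, field) {
  bump_counter(store, kind, field)
  if (kind == "Chromosome" && field == "sequence") {
    return(store_fetch_heavy(store, kind, id, field))
  }
  if (kind == "Transcript" && field == "sequence") {
    return(reference_transcript_sequence(store, id, "full"))
  }
  if (kind == "Transcript" && field == "cds_sequence") {
    return(reference_transcript_sequence(store, id, "cds"))
  }
  if (kind == "Protein" && field == "sequence") {
    tx_id <- one_row(store, "Protein", id)$transcript
    tx <- record_by_id(store, "Transcript", tx_id)
    return(translate_cds(tx$cds_sequence, "truncate_at_stop"))
  }
  stop(sprintf("no inflation rule for %s.%s", kind, field), call. = FALSE)
}

one_row <- function(store, kind, id) {
  tab <- base::get(kind, envir = store$tables)
  i <- match(id, tab$id)
  if (is.na(i)) {
    stop(sprintf("%s '%s' not found", kind, id), call. = FALSE)
  }
  tab[i, , drop = FALSE]
}

record_by_id <- function(store, kind, id) {
  make_record(store, kind, one_row(store, kind, id))
}

# Assemble a reference transcript ("full" = exons, "cds" = CDS intervals)
# in transcription direction from the owning chromosome sequence.
reference_transcript_sequence <- function(store, transcript_id, which) {
  tx <- one_row(store, "Transcript", transcript_id)
  iv <- if (which == "full") {
    transcript_exon_intervals(store, transcript_id)
  } else {
    transcript_cds_intervals(tx)
  }
  if (!nrow(iv)) return("")
  chrom <- record_by_id(store, "Chromosome",
                        paste(tx$genome, tx$chromosome, sep = ":"))
  chrom_seq <- chrom$sequence
  parts <- substring(chrom_seq, iv$start + 1L, iv$end)
  s <- paste(parts, collapse = "")
  if (identical(tx$strand, "-")) s <- reverse_complement(s)
  if (which == "cds") {
    frame <- tx$cds_frame
    if (!is.na(frame) && frame > 0) s <- substring(s, frame + 1L)
  }
  s
}

# Genomic-order exon intervals of a transcript.
transcript_exon_intervals <- function(store, transcript_id) {
  ex <- base::get("Exon", envir = store$tables)
  ex <- ex[ex$transcript == transcript_id, , drop = FALSE]
  ex <- ex[order(ex$start, ex$end), , drop = FALSE]
  data.frame(start = ex$start, end = ex$end, stringsAsFactors = FALSE)
}

# Genomic-order CDS intervals from the comma-joined columns.
transcript_cds_intervals <- function(tx_row) {
  if (is.na(tx_row$cds_starts) || !nzchar(tx_row$cds_starts)) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  starts <- as.numeric(strsplit(tx_row$cds_starts, ",", fixed = TRUE)[[1L]])
  ends <- as.numeric(strsplit(tx_row$cds_ends, ",", fixed = TRUE)[[1L]])
  o <- order(starts, ends)
  data.frame(start = starts[o], end = ends[o])
}
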