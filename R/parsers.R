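# Datawrap manifest and file-format parsers. All genomic coordinates are
# converted at parse time to the internal 0-based half-open convention
# (GTF is 1-based inclusive, VCF positions 1-based) and back-converted on
# export.

as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

#' Parse a datawrap manifest (manifest.ini)
#'
#' A manifest carries package metadata (`[package]` description, version,
#' maintainer), the payload identity (`[genome]` or `[snps]` with `name`
#' and `species`), and a `[files]` section of `role = location` entries
#' with roles `fasta`, `gtf` or `snp`. Locations may be archive-member
#' paths or URLs; URL entries are recorded as remote and never fetched.
#'
#' @param x path to a manifest.ini file, or its text.
#' @return list with `type` ("genome" or "snps"), `name`, `species`,
#'   `description`, `version`, `maintainer` and a `files` data frame
#'   (`role`, `location`, `remote`).
#' @export
parse_manifest <- function(x) {
  lines <- as_lines(x)
  lines <- sub("[;#].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  kv <- list()
  files <- list(role = character(0), location = character(0))
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- tolower(gsub("^\\[|\\]$", "", ln))
      next
    }
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1L]]
    if (length(m) != 3L) {
      stop(sprintf("manifest line is not 'key = value': %s", ln), call. = FALSE)
    }
    key <- trimws(m[[2L]]); val <- trimws(m[[3L]])
    if (section == "files") {
      role <- tolower(key)
      if (!(role %in% c("fasta", "gtf", "snp"))) {
        stop(sprintf("unknown file role '%s' in manifest", key), call. = FALSE)
      }
      files$role <- c(files$role, role)
      files$location <- c(files$location, val)
    } else {
      kv[[paste(section, tolower(key), sep = ".")]] <- val
    }
  }
  for (need in c("package.description", "package.version", "package.maintainer")) {
    if (is.null(kv[[need]])) {
      stop(sprintf("manifest is missing mandatory key '%s'",
                   sub("^package\\.", "", need)), call. = FALSE)
    }
  }
  type <- if (!is.null(kv[["genome.name"]])) "genome"
          else if (!is.null(kv[["snps.name"]])) "snps"
          else stop("manifest is missing mandatory key 'name' ([genome] or [snps])",
                    call. = FALSE)
  if (!length(files$role)) {
    stop("manifest has no [files] entries", call. = FALSE)
  }
  list(
    type = type,
    name = kv[[paste0(type, ".name")]],
    species = kv[[paste0(type, ".species")]] %||% NA_character_,
    description = kv[["package.description"]],
    version = kv[["package.version"]],
    maintainer = kv[["package.maintainer"]],
    files = data.frame(
      role = files$role,
      location = files$location,
      remote = grepl("^[a-z][a-z0-9+.-]*://", files$location),
      stringsAsFactors = FALSE
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse FASTA text
#'
#' @param x path or text.
#' @return data frame with `id` (first word of the header),
#'   `description` (rest of the header) and upper-cased `sequence`.
#' @export
parse_fasta <- function(x) {
  lines <- as_lines(x)
  meaningful <- lines[nzchar(trimws(lines))]
  if (!length(meaningful)) {
    return(data.frame(id = character(0), description = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  if (!startsWith(meaningful[[1L]], ">")) {
    stop("FASTA format error: sequence data before the first '>' header",
         call. = FALSE)
  }
  f <- tempfile(fileext = ".fa")
  on.exit(unlink(f), add = TRUE)
  writeLines(lines, f)
  set <- Biostrings::readBStringSet(f)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  data.frame(
    id = ids, description = desc,
    sequence = toupper(gsub("\\s", "", as.character(set))),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Parse GTF text (Ensembl attribute dialect)
#'
#' Coordinates are converted from GTF's 1-based inclusive convention to
#' the internal 0-based half-open one; `#` comment lines are skipped.
#'
#' @param x path or text.
#' @return data frame of features with internal `start`/`end`, `strand`,
#'   `frame` (NA when "."), extracted `gene_id`, `gene_name`,
#'   `transcript_id`, `exon_number`, `exon_id`, `protein_id`, and the raw
#'   `attributes` string.
#' @export
parse_gtf <- function(x) {
  lines <- as_lines(x)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  line_no <- which(keep)
  lines <- lines[keep]
  cols <- c("chrom", "source", "feature", "start", "end", "score", "strand",
            "frame")
  out <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 9L) {
      stop(sprintf("GTF format error at line %d: expected 9 tab-separated columns, got %d",
                   line_no[[i]], length(parts)), call. = FALSE)
    }
    start1 <- suppressWarnings(as.numeric(parts[[4L]]))
    end1 <- suppressWarnings(as.numeric(parts[[5L]]))
    if (is.na(start1) || is.na(end1)) {
      stop(sprintf("GTF format error at line %d: non-numeric coordinates",
                   line_no[[i]]), call. = FALSE)
    }
    if (end1 < start1) {
      stop(sprintf("GTF coordinate error at line %d: end (%d) < start (%d)",
                   line_no[[i]], end1, start1), call. = FALSE)
    }
    attrs <- parse_gtf_attributes(parts[[9L]])
    list(chrom = parts[[1L]], source = parts[[2L]], feature = parts[[3L]],
         start = start1 - 1, end = end1,
         score = parts[[6L]], strand = parts[[7L]],
         frame = if (parts[[8L]] == ".") NA_real_ else as.numeric(parts[[8L]]),
         gene_id = attrs[["gene_id"]] %||% NA_character_,
         gene_name = attrs[["gene_name"]] %||% NA_character_,
         transcript_id = attrs[["transcript_id"]] %||% NA_character_,
         exon_number = as.numeric(attrs[["exon_number"]] %||% NA),
         exon_id = attrs[["exon_id"]] %||% NA_character_,
         protein_id = attrs[["protein_id"]] %||% NA_character_,
         attributes = parts[[9L]])
  })
  if (!length(out)) {
    return(data.frame(
      chrom = character(0), source = character(0), feature = character(0),
      start = numeric(0), end = numeric(0), score = character(0),
      strand = character(0), frame = numeric(0), gene_id = character(0),
      gene_name = character(0), transcript_id = character(0),
      exon_number = numeric(0), exon_id = character(0),
      protein_id = character(0), attributes = character(0),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, lapply(out, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
}

parse_gtf_attributes <- function(s) {
  # Ensembl dialect: key "value"; ... (unquoted numeric values tolerated)
  m <- regmatches(s, gregexpr('([A-Za-z_]+)\\s+(\"[^\"]*\"|[^;\\s]+)\\s*;', s))[[1L]]
  out <- list()
  for (pair in m) {
    key <- sub("^([A-Za-z_]+).*$", "\\1", pair)
    val <- sub("^[A-Za-z_]+\\s+", "", pair)
    val <- sub(";\\s*$", "", val)
    val <- gsub('^\"|\"$', "", trimws(val))
    out[[key]] <- val
  }
  out
}

#' Write features back to GTF (export convention round-trip)
#'
#' Inverse of [parse_gtf()]: internal 0-based half-open coordinates are
#' re-exported as 1-based inclusive.
#'
#' @param features data frame in the layout produced by [parse_gtf()].
#' @param path output path (or `NULL` to return the lines).
#' @return the GTF lines, invisibly when written to `path`.
#' @export
write_gtf <- function(features, path = NULL) {
  lines <- vapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    paste(f$chrom, f$source, f$feature,
          format(f$start + 1, scientific = FALSE, trim = TRUE),
          format(f$end, scientific = FALSE, trim = TRUE),
          f$score, f$strand,
          if (is.na(f$frame)) "." else format(f$frame, trim = TRUE),
          f$attributes, sep = "\t")
  }, "")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Normalize one VCF allele pair into a classified variant
#'
#' Shared leading then trailing bases of REF/ALT are trimmed and the
#' variant classified: equal-length-1 leftovers are a substitution; empty
#' REF an insertion (anchored *after* the base preceding the inserted
#' sequence); empty ALT a deletion. Normalization is idempotent.
#'
#' @param pos0 internal 0-based position of the first REF base.
#' @param ref,alt REF and ALT allele strings (VCF style).
#' @return list with `kind`, `position`, `ref`, `alt`.
#' @export
#' @examples
#' normalize_variant(4, "C", "G")    # substitution at 4
#' normalize_variant(4, "C", "CTT")  # insertion of TT after 4
#' normalize_variant(4, "CA", "C")   # deletion of A at 5
normalize_variant <- function(pos0, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  lead <- 0L
  while (nchar(ref) > lead && nchar(alt) > lead &&
         substr(ref, lead + 1L, lead + 1L) == substr(alt, lead + 1L, lead + 1L)) {
    lead <- lead + 1L
  }
  r <- substring(ref, lead + 1L)
  a <- substring(alt, lead + 1L)
  while (nchar(r) > 0L && nchar(a) > 0L &&
         substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
    r <- substr(r, 1L, nchar(r) - 1L)
    a <- substr(a, 1L, nchar(a) - 1L)
  }
  if (nchar(r) == 1L && nchar(a) == 1L) {
    list(kind = "substitution", position = pos0 + lead, ref = r, alt = a)
  } else if (nchar(r) == 0L && nchar(a) >= 1L) {
    # with an anchor base trimmed, the insertion sits after the last
    # shared base; an already-normalized record (empty REF) stays put
    pos <- if (lead > 0L) pos0 + lead - 1L else pos0
    list(kind = "insertion", position = pos, ref = "", alt = a)
  } else if (nchar(r) >= 1L && nchar(a) == 0L) {
    list(kind = "deletion", position = pos0 + lead, ref = r, alt = "")
  } else {
    stop(sprintf("unsupported complex variant at position %d (REF '%s', ALT '%s')",
                 pos0 + 1, ref, alt), call. = FALSE)
  }
}

#' Parse VCF text into polymorphisms
#'
#' A VCF 4.x subset (columns CHROM POS ID REF ALT QUAL FILTER INFO). Each
#' ALT of a multi-allelic line yields one polymorphism; alleles are
#' normalized with [normalize_variant()]. QUAL, FILTER, and INFO flags are
#' kept as metadata; an INFO flag `VLD`/`VALIDATED` marks the variant
#' validated.
#'
#' @param x path or text.
#' @return data frame with `chromosome`, `position` (internal 0-based),
#'   `ref_allele`, `alt_allele`, `kind`, `quality`, `metadata` (JSON).
#' @export
parse_vcf <- function(x) {
  lines <- as_lines(x)
  path <- tempfile(fileext = ".vcf")
  on.exit(unlink(path), add = TRUE)
  writeLines(lines, path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  empty <- data.frame(
    chromosome = character(0), position = numeric(0),
    ref_allele = character(0), alt_allele = character(0),
    kind = character(0), quality = numeric(0), metadata = character(0),
    stringsAsFactors = FALSE
  )
  if (is.null(fix) || nrow(fix) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    pos1 <- suppressWarnings(as.numeric(fix[i, "POS"]))
    if (is.na(pos1)) {
      stop(sprintf("VCF format error: non-numeric POS '%s'", fix[i, "POS"]),
           call. = FALSE)
    }
    ref <- toupper(fix[i, "REF"])
    if (!grepl("^[ACGT]+$", ref)) {
      stop(sprintf("VCF alphabet error: REF '%s' contains non-bases", ref),
           call. = FALSE)
    }
    alts <- strsplit(toupper(fix[i, "ALT"]), ",", fixed = TRUE)[[1L]]
    qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    info <- fix[i, "INFO"]
    if (is.na(info)) info <- "."
    flags <- strsplit(info, ";", fixed = TRUE)[[1L]]
    validated <- any(toupper(flags) %in% c("VLD", "VALIDATED"))
    meta <- jsonlite::toJSON(
      list(filter = as.character(fix[i, "FILTER"]), info = info,
           validated = validated),
      auto_unbox = TRUE, null = "null", na = "null"
    )
    for (alt in alts) {
      nv <- normalize_variant(pos1 - 1, ref, alt)
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = normalize_chrom(fix[i, "CHROM"]),
        position = nv$position, ref_allele = nv$ref, alt_allele = nv$alt,
        kind = nv$kind, quality = qual, metadata = as.character(meta),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# Leading "chr" prefix is stripped so FASTA/GTF/VCF naming dialects match.
normalize_chrom <- function(x) sub("^chr", "", x, ignore.case = TRUE)

#' Parse FASTQ text
#'
#' @param x path or text (standard 4-line records).
#' @return data frame with `id`, `sequence`, `quality`.
#' @export
parse_fastq <- function(x) {
  lines <- as_lines(x)
  lines <- lines[nzchar(lines) | seq_along(lines) <= suppressWarnings(max(which(nzchar(lines)), 0L))]
  if (!length(lines)) {
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ format error: truncated record (line count is not a multiple of 4)",
         call. = FALSE)
  }
  n <- length(lines) %/% 4L
  ids <- character(n); seqs <- character(n); quals <- character(n)
  for (i in seq_len(n)) {
    b <- 4L * (i - 1L)
    if (!startsWith(lines[b + 1L], "@") || !startsWith(lines[b + 3L], "+")) {
      stop(sprintf("FASTQ format error in record %d: malformed header/separator",
                   i), call. = FALSE)
    }
    if (nchar(lines[b + 2L]) != nchar(lines[b + 4L])) {
      stop(sprintf("FASTQ format error in record %d: sequence and quality lengths differ",
                   i), call. = FALSE)
    }
    ids[i] <- sub("\\s.*$", "", substring(lines[b + 1L], 2L))
    seqs[i] <- toupper(lines[b + 2L])
    quals[i] <- lines[b + 4L]
  }
  data.frame(id = ids, sequence = seqs, quality = quals,
             stringsAsFactors = FALSE)
}

#' Parse delimited text with a header row
#'
#' @param x path or text.
#' @param delimiter field delimiter (default `","`).
#' @return data frame of character columns keyed by the header.
#' @export
parse_csv <- function(x, delimiter = ",") {
  lines <- as_lines(x)
  utils::read.csv(text = paste(lines, collapse = "\n"), sep = delimiter,
                  colClasses = "character", check.names = FALSE,
                  stringsAsFactors = FALSE)
}
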