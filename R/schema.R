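# Record-kind schema shared by the store, the importers and validation.
# Light fields live in the per-kind table; heavy fields are deferred until
# first access (stored in the payload section of the store file, or
# computed from other records on inflation).

.GENO_SCHEMA <- list(
  Genome = list(
    light = c("id", "name", "species", "description", "version",
              "maintainer", "chromosome_names"),
    heavy = character()
  ),
  Chromosome = list(
    light = c("id", "genome", "name", "length"),
    heavy = "sequence"
  ),
  Gene = list(
    light = c("id", "genome", "name", "chromosome", "start", "end", "strand"),
    heavy = character()
  ),
  Transcript = list(
    light = c("id", "genome", "gene", "chromosome", "strand", "start", "end",
              "cds_starts", "cds_ends", "cds_frame"),
    heavy = c("sequence", "cds_sequence")
  ),
  Exon = list(
    light = c("id", "genome", "transcript", "gene", "chromosome", "strand",
              "start", "end", "rank"),
    heavy = character()
  ),
  Protein = list(
    light = c("id", "genome", "transcript"),
    heavy = "sequence"
  ),
  Polymorphism = list(
    light = c("id", "set_name", "chromosome", "position", "ref_allele",
              "alt_allele", "kind", "quality", "metadata"),
    heavy = character()
  ),
  PolymorphismSet = list(
    light = c("id", "name", "species", "description", "version", "maintainer"),
    heavy = character()
  )
)

.GENO_NUMERIC_COLS <- c("length", "start", "end", "rank", "position",
                        "quality", "cds_frame")

#' Record kinds known to the store
#' @return character vector of record-kind tags.
#' @export
geno_kinds <- function() names(.GENO_SCHEMA)

check_kind <- function(kind) {
  if (!is.character(kind) || length(kind) != 1L ||
      !(kind %in% names(.GENO_SCHEMA))) {
    stop(sprintf("unknown record kind '%s' (known kinds: %s)",
                 paste(kind, collapse = ","),
                 paste(names(.GENO_SCHEMA), collapse = ", ")), call. = FALSE)
  }
  kind
}

kind_fields <- function(kind) {
  sch <- .GENO_SCHEMA[[check_kind(kind)]]
  c(sch$light, sch$heavy)
}

empty_kind_table <- function(kind) {
  cols <- .GENO_SCHEMA[[kind]]$light
  df <- as.data.frame(
    stats::setNames(lapply(cols, function(cl) {
      if (cl %in% .GENO_NUMERIC_COLS) numeric(0) else character(0)
    }), cols),
    stringsAsFactors = FALSE
  )
  df
}

coerce_kind_table <- function(kind, df) {
  cols <- .GENO_SCHEMA[[kind]]$light
  out <- empty_kind_table(kind)
  if (is.null(df) || !length(df) || (is.data.frame(df) && nrow(df) == 0L)) {
    return(out)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  n <- nrow(df)
  out <- as.data.frame(
    stats::setNames(lapply(cols, function(cl) {
      v <- if (cl %in% names(df)) df[[cl]] else rep(NA, n)
      if (cl %in% .GENO_NUMERIC_COLS) as.numeric(v) else as.character(v)
    }), cols),
    stringsAsFactors = FALSE
  )
  out
}
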