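# The single query entry point: get_records(store, kind, filter), plus
# user-controlled per-field global indexes.

#' Build one filter clause
#'
#' Clauses combine by conjunction (AND) inside the `filter` argument of
#' [get_records()].
#'
#' @param field light-field name on the queried kind.
#' @param op one of `"=="`, `"<"`, `">"`, `"prefix"`.
#' @param value comparison value.
#' @return a filter clause.
#' @export
#' @examples
#' where("start", "<", 5000)
where <- function(field, op = "==", value) {
  op <- match.arg(op, c("==", "<", ">", "prefix"))
  structure(list(field = field, op = op, value = value),
            class = "geno_where")
}

# Normalize the filter argument into a list of clauses. Accepts NULL /
# empty list (all records), a named list (equality shorthand), a single
# clause, or a list of clauses.
normalize_filter <- function(filter) {
  if (is.null(filter) || (is.list(filter) && !length(filter))) return(list())
  if (inherits(filter, "geno_where")) return(list(filter))
  if (!is.list(filter)) stop("filter must be a list", call. = FALSE)
  clauses <- list()
  nms <- names(filter)
  for (i in seq_along(filter)) {
    el <- filter[[i]]
    if (inherits(el, "geno_where")) {
      clauses[[length(clauses) + 1L]] <- el
    } else if (!is.null(nms) && nzchar(nms[[i]])) {
      clauses[[length(clauses) + 1L]] <- where(nms[[i]], "==", el)
    } else {
      stop("filter entries must be where() clauses or named values",
           call. = FALSE)
    }
  }
  clauses
}

#' Query the store: the single entry point for almost any lookup
#'
#' Returns every stored record of `kind` satisfying all filter clauses,
#' each in minimal view (heavy fields deferred until accessed). The result
#' is identical whether or not any global index exists; an empty filter
#' returns all records of the kind.
#'
#' @param store a store handle.
#' @param kind record kind (`"Genome"`, `"Gene"`, `"Transcript"`, ...).
#' @param filter `NULL` (everything), a named list (equality shorthand,
#'   e.g. `list(id = "TX1")`), or a list of [where()] clauses combined
#'   with AND.
#' @return list of records (per-session singletons).
#' @export
#' @examples
#' \dontrun{
#' get_records(store, "Gene", list(id = "GENE1"))
#' get_records(store, "Gene", list(where("start", "<", 5000)))
#' }
get_records <- function(store, kind, filter = NULL) {
  check_store(store)
  check_kind(kind)
  clauses <- normalize_filter(filter)
  sch <- .GENO_SCHEMA[[kind]]
  for (cl in clauses) {
    if (cl$field %in% sch$heavy) {
      stop(sprintf("cannot filter on lazily loaded field '%s' of %s",
                   cl$field, kind), call. = FALSE)
    }
    if (!(cl$field %in% sch$light)) {
      stop(sprintf("unknown field '%s' for kind %s", cl$field, kind),
           call. = FALSE)
    }
  }
  tab <- base::get(kind, envir = store$tables)
  rows <- seq_len(nrow(tab))
  # seed the candidate set from a global index when an equality clause
  # targets an indexed field; remaining clauses still apply below, so the
  # result never depends on the index
  for (cl in clauses) {
    if (cl$op != "==") next
    ix <- store$indexes[[paste(kind, cl$field, sep = ".")]]
    if (is.null(ix)) next
    map <- index_map(store, kind, cl$field)
    hit <- map[[as.character(cl$value)]]
    rows <- intersect(rows, if (is.null(hit)) integer(0) else hit)
    break
  }
  for (cl in clauses) {
    if (!length(rows)) break
    col <- tab[[cl$field]][rows]
    keep <- switch(cl$op,
      "==" = if (is.numeric(col)) col == as.numeric(cl$value)
             else col == as.character(cl$value),
      "<" = as.numeric(col) < as.numeric(cl$value),
      ">" = as.numeric(col) > as.numeric(cl$value),
      "prefix" = startsWith(as.character(col), as.character(cl$value))
    )
    keep[is.na(keep)] <- FALSE
    rows <- rows[keep]
  }
  lapply(rows, function(i) make_record(store, kind, tab[i, , drop = FALSE]))
}

# (Re)build the value -> row-positions map for an index if stale.
index_map <- function(store, kind, field) {
  name <- paste(kind, field, sep = ".")
  ix <- store$indexes[[name]]
  if (is.null(ix$map) || !identical(ix$built_gen, store$generation)) {
    tab <- base::get(kind, envir = store$tables)
    map <- split(seq_len(nrow(tab)), as.character(tab[[field]]))
    ix <- list(built_gen = store$generation, map = map)
    store$indexes[[name]] <- ix
  }
  ix$map
}

#' Ensure / drop a global index on one field of one kind
#'
#' Indexes are a pure lookup accelerator under user control: `ensure` is
#' idempotent, query results are identical with or without the index, and
#' dropping a non-existent index is a no-op.
#'
#' @param store a store handle.
#' @param kind record kind.
#' @param field light-field name to index.
#' @return for `ensure_global_index`, an index handle
#'   (`list(kind, field, name)`), invisibly for `drop_global_index`.
#' @export
ensure_global_index <- function(store, kind, field) {
  check_store(store)
  check_kind(kind)
  if (!(field %in% .GENO_SCHEMA[[kind]]$light)) {
    stop(sprintf("unknown field '%s' for kind %s", field, kind), call. = FALSE)
  }
  name <- paste(kind, field, sep = ".")
  if (is.null(store$indexes[[name]])) {
    store$indexes[[name]] <- list(built_gen = -1L, map = NULL)
  }
  index_map(store, kind, field)
  structure(list(kind = kind, field = field, name = name),
            class = "geno_index_handle")
}

#' @rdname ensure_global_index
#' @export
drop_global_index <- function(store, kind, field) {
  check_store(store)
  check_kind(kind)
  if (!(field %in% .GENO_SCHEMA[[kind]]$light)) {
    stop(sprintf("unknown field '%s' for kind %s", field, kind), call. = FALSE)
  }
  name <- paste(kind, field, sep = ".")
  if (!is.null(store$indexes[[name]])) rm(list = name, envir = store$indexes)
  invisible(NULL)
}

#' List existing global indexes
#' @param store a store handle.
#' @return character vector of `kind.field` index names.
#' @export
list_global_indexes <- function(store) {
  check_store(store)
  sort(ls(store$indexes))
}
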