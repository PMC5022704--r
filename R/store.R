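# Single-file embedded store with minimal-view lazy records.
#
# File layout (all ASCII):
#   bytes 1..26   : header "GENOLITE1 %015d\n" where %015d is the byte
#                   length of the JSON index that follows
#   next          : JSON index {tables, indexes, heavy}
#   rest          : heavy payload; the index records (offset, nbytes) per
#                   (kind, id, field), offsets relative to payload start
#
# Copying the file *is* the backup mechanism: the file is the complete
# state. Heavy fields are fetched by a second read (seek + readChar) only
# when a record inflates them. Sessions are single-writer by contract.

.STORE_HEADER_BYTES <- 26L  # "GENOLITE1 " + 15 digits + newline

heavy_key <- function(kind, id, field) paste(kind, id, field, sep = "\x01")

#' Create a new, empty store
#'
#' @param path file path for the store; must not already exist.
#' @return a store handle (used by every other store function).
#' @export
store_create <- function(path) {
  if (file.exists(path)) {
    stop(sprintf("store file already exists: %s", path), call. = FALSE)
  }
  store <- new_store_env(path)
  for (kind in geno_kinds()) {
    assign(kind, empty_kind_table(kind), envir = store$tables)
  }
  store_flush(store)
  store
}

#' Open an existing store file
#'
#' Light tables are read into memory; heavy payloads stay on disk and are
#' fetched individually when a record inflates the field.
#'
#' @param path path to a store file written by [store_create()]/[store_flush()].
#' @return a store handle.
#' @export
store_open <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("store file not found: %s", path), call. = FALSE)
  }
  store <- new_store_env(path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  header <- readChar(con, .STORE_HEADER_BYTES, useBytes = TRUE)
  if (!grepl("^GENOLITE1 [0-9]{15}\n$", header)) {
    stop(sprintf("not a genolite store file: %s", path), call. = FALSE)
  }
  idx_len <- as.integer(substr(header, 11L, 25L))
  idx <- jsonlite::fromJSON(readChar(con, idx_len, useBytes = TRUE),
                            simplifyVector = TRUE)
  for (kind in geno_kinds()) {
    assign(kind, coerce_kind_table(kind, idx$tables[[kind]]),
           envir = store$tables)
  }
  for (nm in as.character(idx$indexes)) {
    store$indexes[[nm]] <- list(built_gen = -1L, map = NULL)
  }
  if (length(idx$heavy)) {
    for (kind in names(idx$heavy)) {
      for (id in names(idx$heavy[[kind]])) {
        for (field in names(idx$heavy[[kind]][[id]])) {
          loc <- as.numeric(idx$heavy[[kind]][[id]][[field]])
          store$heavy_file[[heavy_key(kind, id, field)]] <- loc
        }
      }
    }
  }
  store$payload_start <- .STORE_HEADER_BYTES + idx_len
  store
}

new_store_env <- function(path) {
  store <- new.env(parent = emptyenv())
  store$path <- path
  store$tables <- new.env(parent = emptyenv())
  store$heavy_mem <- new.env(parent = emptyenv())   # key -> value (unflushed / cached)
  store$heavy_file <- new.env(parent = emptyenv())  # key -> c(offset, nbytes)
  store$singletons <- new.env(parent = emptyenv())
  store$counters <- new.env(parent = emptyenv())
  store$indexes <- new.env(parent = emptyenv())     # "Kind.field" -> list(built_gen, map)
  store$ix_cache <- new.env(parent = emptyenv())    # interval-index cache
  store$generation <- 0L
  store$payload_start <- NA_real_
  store$closed <- FALSE
  class(store) <- "geno_store"
  store
}

check_store <- function(store) {
  if (!inherits(store, "geno_store")) {
    stop("not a store handle; use store_create()/store_open()", call. = FALSE)
  }
  if (isTRUE(store$closed)) stop("store is closed", call. = FALSE)
  invisible(store)
}

#' @export
print.geno_store <- function(x, ...) {
  counts <- vapply(geno_kinds(), function(k) nrow(get(k, envir = x$tables)), 0L)
  cat(sprintf("<genolite store: %s>\n", x$path))
  for (k in names(counts)) if (counts[[k]] > 0L) cat(sprintf("  %s: %d\n", k, counts[[k]]))
  invisible(x)
}

# Fetch a heavy value from memory cache or from the store file.
store_fetch_heavy <- function(store, kind, id, field) {
  key <- heavy_key(kind, id, field)
  if (!is.null(store$heavy_mem[[key]])) return(store$heavy_mem[[key]])
  loc <- store$heavy_file[[key]]
  if (is.null(loc)) {
    stop(sprintf("no stored value for heavy field %s.%s of '%s'",
                 kind, field, id), call. = FALSE)
  }
  con <- file(store$path, "rb")
  on.exit(close(con), add = TRUE)
  seek(con, store$payload_start + loc[[1L]])
  val <- readChar(con, loc[[2L]], useBytes = TRUE)
  store$heavy_mem[[key]] <- val   # session cache; shared by all handles
  val
}

#' Write the store state back to its file
#'
#' The file written is the complete state; copying it is the supported
#' backup/sharing mechanism.
#'
#' @param store a store handle.
#' @return the store, invisibly.
#' @export
store_flush <- function(store) {
  check_store(store)
  # materialize every heavy value (unflushed ones are already in memory;
  # previously flushed ones are read through before the file is replaced)
  keys <- unique(c(ls(store$heavy_mem), ls(store$heavy_file)))
  payload_parts <- character(length(keys))
  heavy_index <- list()
  offset <- 0
  for (i in seq_along(keys)) {
    key <- keys[[i]]
    parts <- strsplit(key, "\x01", fixed = TRUE)[[1L]]
    val <- if (!is.null(store$heavy_mem[[key]])) {
      store$heavy_mem[[key]]
    } else {
      store_fetch_heavy(store, parts[[1L]], parts[[2L]], parts[[3L]])
    }
    nb <- nchar(val, type = "bytes")
    payload_parts[[i]] <- val
    heavy_index[[parts[[1L]]]][[parts[[2L]]]][[parts[[3L]]]] <- c(offset, nb)
    offset <- offset + nb
  }
  tables <- stats::setNames(lapply(geno_kinds(), function(k) {
    get(k, envir = store$tables)
  }), geno_kinds())
  idx_json <- jsonlite::toJSON(
    list(tables = tables, indexes = ls(store$indexes), heavy = heavy_index),
    dataframe = "columns", na = "null", auto_unbox = FALSE, digits = NA
  )
  idx_len <- nchar(idx_json, type = "bytes")
  tmp <- paste0(store$path, ".tmp")
  out <- file(tmp, "wb")
  writeChar(sprintf("GENOLITE1 %015d\n", idx_len), out, eos = NULL)
  writeChar(as.character(idx_json), out, eos = NULL)
  if (length(payload_parts)) {
    writeChar(paste(payload_parts, collapse = ""), out, eos = NULL)
  }
  close(out)
  file.rename(tmp, store$path)
  # after a flush every heavy value is on disk at a known offset
  store$payload_start <- .STORE_HEADER_BYTES + idx_len
  rm(list = ls(store$heavy_file), envir = store$heavy_file)
  for (kind in names(heavy_index)) {
    for (id in names(heavy_index[[kind]])) {
      for (field in names(heavy_index[[kind]][[id]])) {
        store$heavy_file[[heavy_key(kind, id, field)]] <-
          heavy_index[[kind]][[id]][[field]]
      }
    }
  }
  invisible(store)
}

#' Flush and close a store
#'
#' @param store a store handle.
#' @return invisibly, the path of the store file.
#' @export
store_close <- function(store) {
  check_store(store)
  store_flush(store)
  store$closed <- TRUE
  invisible(store$path)
}

# Insert one record. `fields` is a named list of light fields (id
# mandatory, unique within the kind); `heavy` a named list of heavy
# string values.
store_insert <- function(store, kind, fields, heavy = list()) {
  check_store(store)
  check_kind(kind)
  sch <- .GENO_SCHEMA[[kind]]
  if (is.null(fields$id) || !nzchar(fields$id)) {
    stop(sprintf("%s record needs a non-empty 'id'", kind), call. = FALSE)
  }
  unknown <- setdiff(names(fields), sch$light)
  if (length(unknown)) {
    stop(sprintf("unknown light field(s) for %s: %s", kind,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  tab <- get(kind, envir = store$tables)
  if (fields$id %in% tab$id) {
    stop(sprintf("duplicate %s id '%s'", kind, fields$id), call. = FALSE)
  }
  row <- stats::setNames(lapply(sch$light, function(cl) {
    v <- fields[[cl]]
    if (is.null(v)) v <- NA
    if (cl %in% .GENO_NUMERIC_COLS) as.numeric(v) else as.character(v)
  }), sch$light)
  assign(kind, rbind(tab, as.data.frame(row, stringsAsFactors = FALSE)),
         envir = store$tables)
  if (length(heavy)) {
    bad <- setdiff(names(heavy), sch$heavy)
    if (length(bad)) {
      stop(sprintf("unknown heavy field(s) for %s: %s", kind,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    for (field in names(heavy)) {
      store$heavy_mem[[heavy_key(kind, fields$id, field)]] <-
        as.character(heavy[[field]])
    }
  }
  store$generation <- store$generation + 1L
  invisible(fields$id)
}

# Remove all records of a kind matching a predicate on the light table.
store_delete <- function(store, kind, ids) {
  check_store(store)
  tab <- get(kind, envir = store$tables)
  keep <- !(tab$id %in% ids)
  assign(kind, tab[keep, , drop = FALSE], envir = store$tables)
  for (id in ids) {
    for (field in .GENO_SCHEMA[[kind]]$heavy) {
      key <- heavy_key(kind, id, field)
      if (!is.null(store$heavy_mem[[key]])) rm(list = key, envir = store$heavy_mem)
      if (!is.null(store$heavy_file[[key]])) rm(list = key, envir = store$heavy_file)
    }
    skey <- paste(kind, id, sep = "\x01")
    if (!is.null(store$singletons[[skey]])) rm(list = skey, envir = store$singletons)
  }
  store$generation <- store$generation + 1L
  invisible(store)
}

#' Count heavy-field load events
#'
#' Every inflation of a heavy field through the store backend increments a
#' per-`(kind, field)` counter; this exposes it so that laziness can be
#' observed (and tested) rather than assumed.
#'
#' @param store a store handle.
#' @param kind,field optionally restrict to one record kind / field.
#' @return total number of load events.
#' @export
load_events <- function(store, kind = NULL, field = NULL) {
  check_store(store)
  keys <- ls(store$counters)
  if (!is.null(kind)) keys <- keys[startsWith(keys, paste0(kind, "."))]
  if (!is.null(field)) keys <- keys[endsWith(keys, paste0(".", field))]
  if (!length(keys)) return(0L)
  sum(vapply(keys, function(k) store$counters[[k]], 0L))
}

bump_counter <- function(store, kind, field) {
  key <- paste(kind, field, sep = ".")
  cur <- store$counters[[key]]
  store$counters[[key]] <- if (is.null(cur)) 1L else cur + 1L
  invisible(NULL)
}
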