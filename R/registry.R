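# Data-table registry: table specifications, the tab-separated location-file
# persistence dialect, and the live in-memory registry that analysis tools
# would query. Location files are the on-disk source of truth; the in-memory
# state always equals their parse outside the commit critical section.
#
# Loc dialect: UTF-8, TAB field separator, '#' full-line comments, "\n" line
# terminator, no quoting or escaping. Values containing TAB, newline or
# carriage return are rejected rather than escaped, which keeps loc files
# grep-able and the dialect compatible with historical tool-data files.

#' Define a data table
#'
#' A data table is a named registry of reference-data entries with a fixed,
#' ordered set of columns, persisted as a tab-separated location (`.loc`)
#' file. The key column (by convention `value`) is an entry's identity: the
#' ID that analysis tools select, e.g. a genome build such as `hg19`.
#'
#' @param name Table name (letters, digits, underscore).
#' @param columns Character vector of column names, in file order.
#' @param loc_path Path of the table's location file, relative to the
#'   registry root.
#' @param key_column Column providing entry identity. Default `"value"`.
#' @param allow_duplicates Allow repeated key values. Default `FALSE`.
#' @return A `data_table_spec` object.
#' @examples
#' data_table_spec("all_fasta", c("value", "dbkey", "name", "path"),
#'                 "all_fasta.loc")
#' @export
data_table_spec <- function(name, columns, loc_path,
                            key_column = "value", allow_duplicates = FALSE) {
  if (!is_identifier(name)) {
    ra_config_error(sprintf("invalid table name: %s", deparse(name)))
  }
  columns <- as.character(columns)
  if (length(columns) == 0) ra_config_error("a table needs at least one column")
  bad <- columns[!vapply(columns, is_identifier, logical(1))]
  if (length(bad) > 0) {
    ra_config_error(sprintf("invalid column name(s): %s", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(columns)) {
    ra_config_error(sprintf("duplicate column names in table '%s'", name))
  }
  if (!is.character(loc_path) || length(loc_path) != 1L || !nzchar(loc_path)) {
    ra_config_error(sprintf("table '%s': loc_path must be a non-empty string", name))
  }
  if (!key_column %in% columns) {
    ra_config_error(sprintf("table '%s': key_column '%s' is not a declared column",
                            name, key_column))
  }
  structure(list(name = name, columns = columns, loc_path = loc_path,
                 key_column = key_column,
                 allow_duplicates = isTRUE(allow_duplicates)),
            class = "data_table_spec")
}

# Coerce entries (data.frame, named list, or list of named lists) to the
# canonical representation: a character data.frame with spec's columns in
# order. Validates the TableEntry invariants.
as_entries <- function(entries, spec) {
  if (is.data.frame(entries) && nrow(entries) == 0 && ncol(entries) == 0) {
    entries <- NULL
  }
  if (is.null(entries)) {
    entries <- as.data.frame(stats::setNames(rep(list(character(0)), length(spec$columns)),
                                             spec$columns))
  }
  if (!is.data.frame(entries)) {
    if (is.list(entries) && length(entries) > 0 && !is.null(names(entries)) &&
        !is.list(entries[[1]])) {
      entries <- list(entries)          # a single named entry
    }
    rows <- lapply(entries, function(e) {
      as.data.frame(as.list(vapply(e, as.character, character(1))))
    })
    entries <- if (length(rows) == 0) {
      as.data.frame(stats::setNames(rep(list(character(0)), length(spec$columns)),
                                    spec$columns))
    } else {
      do.call(rbind, rows)
    }
  }
  missing <- setdiff(spec$columns, names(entries))
  if (length(missing) > 0) {
    ra_validation_error(sprintf("table '%s': entries missing column(s): %s",
                                spec$name, paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(entries), spec$columns)
  if (length(extra) > 0) {
    ra_validation_error(sprintf("table '%s': entries have undeclared column(s): %s",
                                spec$name, paste(extra, collapse = ", ")))
  }
  entries <- entries[, spec$columns, drop = FALSE]
  entries[] <- lapply(entries, as.character)
  rownames(entries) <- NULL
  validate_entries(entries, spec)
  entries
}

validate_entries <- function(entries, spec) {
  for (col in spec$columns) {
    v <- entries[[col]]
    if (anyNA(v)) {
      ra_validation_error(sprintf("table '%s': NA value in column '%s'", spec$name, col))
    }
    bad <- grepl("[\t\n\r]", v)
    if (any(bad)) {
      ra_validation_error(sprintf(
        "table '%s': column '%s' contains TAB/newline/carriage return in entry %d",
        spec$name, col, which(bad)[1]))
    }
  }
  keys <- entries[[spec$key_column]]
  if (any(!nzchar(keys))) {
    ra_validation_error(sprintf("table '%s': empty key-column ('%s') value",
                                spec$name, spec$key_column))
  }
  # Key values name per-asset directories under the data root, so path
  # separators and parent references are rejected outright.
  unsafe <- grepl("[/\\\\]", keys) | vapply(keys, has_dotdot, logical(1))
  if (any(unsafe)) {
    ra_validation_error(sprintf(
      "table '%s': key value '%s' contains a path separator or '..'",
      spec$name, keys[which(unsafe)[1]]))
  }
  invisible(entries)
}

#' Parse location-file text into table entries
#'
#' Empty lines, whitespace-only lines and lines whose first non-whitespace
#' character is `#` are skipped. Every remaining line must split on TAB into
#' exactly as many fields as the table declares columns.
#'
#' @param text Location-file content (a single string, UTF-8).
#' @param spec A [data_table_spec()].
#' @return A data.frame with one row per entry, columns in spec order.
#' @export
parse_loc_text <- function(text, spec) {
  stopifnot(inherits(spec, "data_table_spec"))
  if (length(text) != 1L || !is.character(text)) {
    ra_format_error("loc text must be a single string")
  }
  lines <- if (nzchar(text)) strsplit(text, "\n", fixed = TRUE)[[1]] else character(0)
  keep <- !grepl("^\\s*$", lines) & !grepl("^\\s*#", lines)
  rows <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    # trailing empty field is dropped by strsplit; restore it
    if (grepl("\t$", lines[i])) fields <- c(fields, "")
    if (length(fields) != length(spec$columns)) {
      ra_format_error(sprintf(
        "loc file for table '%s': line %d has %d field(s), expected %d",
        spec$name, i, length(fields), length(spec$columns)),
        line = i)
    }
    j <- j + 1L
    rows[[j]] <- fields
  }
  entries <- if (j == 0) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(spec$columns)),
                                  spec$columns))
  } else {
    stats::setNames(as.data.frame(do.call(rbind, rows[seq_len(j)])), spec$columns)
  }
  entries[] <- lapply(entries, as.character)
  rownames(entries) <- NULL
  if (!spec$allow_duplicates) {
    keys <- entries[[spec$key_column]]
    if (anyDuplicated(keys)) {
      ra_stop(sprintf("loc file for table '%s': duplicate key '%s'",
                      spec$name, keys[duplicated(keys)][1]),
              c("refasset_duplicate_error", "refasset_format_error"))
    }
  }
  entries
}

#' Render table entries as location-file text
#'
#' The persistence twin of [parse_loc_text()]: one line per entry, fields
#' joined by TAB in declared column order, each line terminated by `"\n"`.
#' Byte-deterministic for a given input.
#'
#' @param entries Entries as a data.frame (or list of named lists).
#' @param spec A [data_table_spec()].
#' @return A single string; `""` for zero entries.
#' @export
render_loc_text <- function(entries, spec) {
  stopifnot(inherits(spec, "data_table_spec"))
  entries <- as_entries(entries, spec)
  if (nrow(entries) == 0) return("")
  lines <- do.call(paste, c(unname(as.list(entries)), sep = "\t"))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Load a registry from a configuration document
#'
#' The configuration lists the data tables (name, ordered columns, loc file
#' path, key column, duplicate policy). Present location files are parsed;
#' absent ones are treated as empty and created on first commit. The returned
#' registry is live: queries reflect every committed append immediately,
#' with no reload or restart step.
#'
#' @param config Path to a YAML configuration file, or an equivalent list
#'   with a `tables` element.
#' @param registry_root Directory that loc paths are resolved against.
#' @param data_root Directory under which installed assets live.
#' @return A `Registry` object (environment with reference semantics).
#' @examples
#' cfg <- list(tables = list(list(
#'   name = "all_fasta",
#'   columns = c("value", "dbkey", "name", "path"),
#'   loc_path = "all_fasta.loc")))
#' root <- tempfile(); dir.create(root)
#' reg <- load_registry(cfg, root, file.path(root, "data"))
#' list_tables(reg)
#' @export
load_registry <- function(config, registry_root, data_root) {
  doc <- read_structured_doc(config, what = "registry config")
  if (is.null(doc$tables) || !is.list(doc$tables) || length(doc$tables) == 0) {
    ra_config_error("registry config must define a non-empty 'tables' list")
  }
  if (!dir.exists(registry_root)) dir.create(registry_root, recursive = TRUE)
  if (!dir.exists(data_root)) dir.create(data_root, recursive = TRUE)
  reg <- new.env(parent = emptyenv())
  reg$registry_root <- normalizePath(registry_root)
  reg$data_root <- normalizePath(data_root)
  reg$tables <- list()
  class(reg) <- "Registry"
  for (t in doc$tables) {
    spec <- data_table_spec(
      name = t$name %||% ra_config_error("table config missing 'name'"),
      columns = unlist(t$columns),
      loc_path = t$loc_path %||% ra_config_error(sprintf("table '%s' missing loc_path", t$name)),
      key_column = t$key_column %||% "value",
      allow_duplicates = isTRUE(t$allow_duplicates))
    if (spec$name %in% names(reg$tables)) {
      ra_config_error(sprintf("table '%s' declared more than once", spec$name))
    }
    loc_file <- file.path(reg$registry_root, spec$loc_path)
    entries <- parse_loc_text(rawToChar(read_bytes(loc_file)), spec)
    reg$tables[[spec$name]] <- list(spec = spec, entries = entries,
                                    loc_file = loc_file)
  }
  reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_structured_doc <- function(x, what = "document") {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) ra_config_error(sprintf("%s not found: %s", what, x))
    doc <- tryCatch(yaml::read_yaml(x),
                    error = function(e) ra_config_error(sprintf("malformed %s (%s): %s",
                                                                what, x, conditionMessage(e))))
    return(doc)
  }
  if (!is.list(x)) ra_config_error(sprintf("%s must be a file path or a list", what))
  x
}

get_table <- function(registry, table) {
  stopifnot(inherits(registry, "Registry"))
  if (!table %in% names(registry$tables)) {
    ra_validation_error(sprintf("unknown table '%s'", table))
  }
  registry$tables[[table]]
}

#' List a registry's tables and entry counts
#'
#' @param registry A `Registry`.
#' @return A data.frame with columns `table` and `n_entries`.
#' @export
list_tables <- function(registry) {
  stopifnot(inherits(registry, "Registry"))
  data.frame(table = names(registry$tables),
             n_entries = vapply(registry$tables, function(t) nrow(t$entries), integer(1)),
             row.names = NULL)
}

#' Append entries to a data table
#'
#' Commits are atomic and append-only: the new loc content (the file's
#' previous bytes, extended with the rendered new lines) is written to a
#' temporary file in the same directory and renamed over the original, so a
#' reader never observes a torn file and pre-existing comments or blank lines
#' are preserved verbatim. The in-memory state is updated only after the
#' rename succeeds, making new entries queryable immediately.
#'
#' Duplicate policy (when the table forbids duplicates): an incoming entry
#' whose key matches an existing entry is silently skipped if all columns are
#' equal, and raises a conflict error -- committing nothing -- if any column
#' differs.
#'
#' @param registry A `Registry`.
#' @param table Table name.
#' @param entries New entries (data.frame or list of named lists).
#' @return Invisibly, the number of entries actually added.
#' @export
append_entries <- function(registry, table, entries) {
  tab <- get_table(registry, table)
  spec <- tab$spec
  entries <- as_entries(entries, spec)
  if (nrow(entries) == 0) return(invisible(0L))

  if (!spec$allow_duplicates) {
    existing <- tab$entries
    keep <- logical(nrow(entries))
    seen <- existing
    for (i in seq_len(nrow(entries))) {
      key <- entries[[spec$key_column]][i]
      hit <- which(seen[[spec$key_column]] == key)
      if (length(hit) == 0) {
        keep[i] <- TRUE
        seen <- rbind(seen, entries[i, , drop = FALSE])
      } else if (identical(unlist(seen[hit[1], , drop = TRUE]),
                           unlist(entries[i, , drop = TRUE]))) {
        keep[i] <- FALSE  # full-row duplicate: skip silently
      } else {
        ra_conflict_error(sprintf(
          "table '%s': key '%s' already present with different values", table, key),
          key = key)
      }
    }
    entries <- entries[keep, , drop = FALSE]
  }
  if (nrow(entries) == 0) return(invisible(0L))

  loc_file <- tab$loc_file
  with_loc_lock(loc_file, {
    old_bytes <- read_bytes(loc_file)
    new_bytes <- c(old_bytes, charToRaw(render_loc_text(entries, spec)))
    atomic_write_bytes(loc_file, new_bytes)
  })
  registry$tables[[table]]$entries <- rbind(tab$entries, entries)
  rownames(registry$tables[[table]]$entries) <- NULL
  invisible(nrow(entries))
}

#' Query a data table
#'
#' @param registry A `Registry`.
#' @param table Table name.
#' @param filter Optional named character vector/list of column = value
#'   pairs; entries matching all pairs exactly are returned, in insertion
#'   order. `NULL` (default) returns all entries.
#' @return A data.frame of matching entries.
#' @export
query_entries <- function(registry, table, filter = NULL) {
  tab <- get_table(registry, table)
  entries <- tab$entries
  if (!is.null(filter) && length(filter) > 0) {
    unknown <- setdiff(names(filter), tab$spec$columns)
    if (length(unknown) > 0) {
      ra_validation_error(sprintf("unknown filter column(s): %s",
                                  paste(unknown, collapse = ", ")))
    }
    keep <- rep(TRUE, nrow(entries))
    for (col in names(filter)) {
      keep <- keep & (entries[[col]] == as.character(filter[[col]]))
    }
    entries <- entries[keep, , drop = FALSE]
  }
  rownames(entries) <- NULL
  entries
}

#' @export
print.Registry <- function(x, ...) {
  cat("<Registry>", length(x$tables), "table(s); data_root:", x$data_root, "\n")
  tl <- list_tables(x)
  for (i in seq_len(nrow(tl))) {
    cat(sprintf("  %-20s %d entries\n", tl$table[i], tl$n_entries[i]))
  }
  invisible(x)
}
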