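# Internal helpers shared across modules: structured error conditions,
# digests, atomic file replacement, advisory locking, identifiers.

# All package errors carry a subclass of "refasset_error" so callers (and the
# CLI exit-code mapping) can distinguish domain errors from programming errors.
ra_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "refasset_error", "error", "condition"),
    list(message = msg, ...)
  ))
}

ra_format_error     <- function(msg, ...) ra_stop(msg, "refasset_format_error", ...)
ra_config_error     <- function(msg, ...) ra_stop(msg, "refasset_config_error", ...)
ra_validation_error <- function(msg, ...) ra_stop(msg, "refasset_validation_error", ...)
ra_conflict_error   <- function(msg, ...) ra_stop(msg, "refasset_conflict_error", ...)
ra_run_error        <- function(msg, ...) ra_stop(msg, "refasset_run_error", ...)
ra_usage_error      <- function(msg, ...) ra_stop(msg, "refasset_usage_error", ...)

is_identifier <- function(x) {
  is.character(x) && length(x) == 1L && nzchar(x) && grepl("^[A-Za-z0-9_]+$", x)
}

#' Compute the sha256 digest of a file
#'
#' Lowercase 64-character hex digest of the file's bytes.
#'
#' @param path Path to an existing file.
#' @return A length-1 character vector.
#' @export
sha256_file <- function(path) {
  if (!file.exists(path)) ra_validation_error(sprintf("file not found: %s", path))
  digest::digest(path, algo = "sha256", file = TRUE)
}

# Read a file's raw bytes; absent file -> raw(0).
read_bytes <- function(path) {
  if (!file.exists(path)) return(raw(0))
  readBin(path, what = "raw", n = file.size(path))
}

# Atomically replace `path` with `bytes`: write a temporary file in the same
# directory, then rename() over the destination (atomic on POSIX when source
# and destination share a filesystem). Never leaves a torn file at `path`.
atomic_write_bytes <- function(path, bytes) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(pattern = paste0(".", basename(path), ".tmp"), tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, open = "wb")
  writeBin(bytes, con)
  close(con)
  if (!file.rename(tmp, path)) {
    ra_stop(sprintf("atomic rename failed for %s", path), "refasset_io_error")
  }
  invisible(path)
}

# Advisory lock serializing commits to one location file. mkdir() is atomic on
# POSIX, so a lock directory doubles as a portable lock token.
with_loc_lock <- function(loc_path, expr, timeout = 10) {
  lock <- paste0(loc_path, ".lock")
  if (!dir.exists(dirname(lock))) dir.create(dirname(lock), recursive = TRUE)
  deadline <- Sys.time() + timeout
  repeat {
    if (dir.create(lock, showWarnings = FALSE)) break
    if (Sys.time() > deadline) {
      ra_stop(sprintf("timed out waiting for lock on %s", loc_path), "refasset_io_error")
    }
    Sys.sleep(0.05)
  }
  on.exit(unlink(lock, recursive = TRUE), add = TRUE)
  force(expr)
}

utc_now <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
}

.ra_state <- new.env(parent = emptyenv())
.ra_state$run_counter <- 0L

# Lexicographically sortable unique run id: UTC time prefix + pid + counter.
new_run_id <- function() {
  .ra_state$run_counter <- .ra_state$run_counter + 1L
  sprintf("%s-%d-%04d",
          format(Sys.time(), "%Y%m%dT%H%M%OS6", tz = "UTC"),
          Sys.getpid(), .ra_state$run_counter)
}

# Failure-injection hook for crash-safety testing. `fail_at` names one of the
# documented points in run_recipe(); when the executing stage reaches it, an
# error with class "refasset_injected_failure" is raised.
maybe_fail <- function(point, fail_at) {
  if (!is.null(fail_at) && identical(point, fail_at)) {
    ra_stop(sprintf("injected failure at '%s'", point),
            c("refasset_injected_failure", "refasset_run_error"))
  }
  invisible(NULL)
}

# Substitute ${name} placeholders in a template from a named character list.
# Unknown placeholders raise; known values are substituted literally.
substitute_placeholders <- function(template, values, error_fun = ra_validation_error) {
  found <- extract_placeholders(template)
  unknown <- setdiff(found, names(values))
  if (length(unknown) > 0) {
    error_fun(sprintf("unknown placeholder(s) in '%s': %s",
                      template, paste0("${", unknown, "}", collapse = ", ")))
  }
  out <- template
  for (nm in found) {
    out <- gsub(paste0("${", nm, "}"), values[[nm]], out, fixed = TRUE)
  }
  out
}

extract_placeholders <- function(template) {
  m <- gregexpr("\\$\\{([A-Za-z0-9_]+)\\}", template)[[1]]
  if (m[1] == -1) return(character(0))
  unique(gsub("[${}]", "", regmatches(template, list(m))[[1]]))
}

# TRUE when any path segment is "..".
has_dotdot <- function(x) {
  any(vapply(strsplit(x, "/", fixed = TRUE), function(p) any(p == ".."), logical(1)))
}

json_read <- function(path_or_text) {
  jsonlite::fromJSON(path_or_text, simplifyVector = FALSE)
}

json_write <- function(x, path, sort_keys = FALSE) {
  if (sort_keys) x <- sort_keys_rec(x)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA,
                              pretty = TRUE),
             path, useBytes = TRUE)
  invisible(path)
}

sort_keys_rec <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x) > 0) {
    x <- x[order(names(x))]
    lapply(x, sort_keys_rec)
  } else if (is.list(x)) {
    lapply(x, sort_keys_rec)
  } else {
    x
  }
}
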