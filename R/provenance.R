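# Provenance: every recipe run persists a record of who-ran-what -- recipe
# id and version, normalized bindings, UTC timestamps, terminal status, the
# raw entry bundle as received, the entries as committed, a sha256 manifest
# of every installed file, and the captured log. Records are append-only
# (one JSON document per run, never mutated), which makes installed assets
# verifiable against their manifests and whole runs replayable on another
# host. The recorded field set is this package's decided minimum for
# verification and replay.

#' Open (or create) a provenance store
#'
#' @param root Directory for the store; run records live under
#'   `<root>/runs/`, one JSON document each.
#' @return A `provenance_store` object.
#' @export
provenance_store <- function(root) {
  runs_dir <- file.path(root, "runs")
  if (!dir.exists(runs_dir)) dir.create(runs_dir, recursive = TRUE)
  structure(list(root = normalizePath(root),
                 runs_dir = normalizePath(runs_dir)),
            class = "provenance_store")
}

record_path <- function(store, run_id) {
  file.path(store$runs_dir, paste0(run_id, ".json"))
}

#' Persist a terminal run record
#'
#' Records are append-only: re-saving an existing run id is an error, and a
#' saved record's bytes are never touched again.
#'
#' @param store A [provenance_store()].
#' @param record A `run_record` in a terminal state.
#' @return The persisted path, invisibly.
#' @export
save_record <- function(store, record) {
  stopifnot(inherits(store, "provenance_store"), inherits(record, "run_record"))
  if (!record$status %in% c("succeeded", "failed", "rolled_back")) {
    ra_validation_error(sprintf("run record '%s' is not terminal", record$run_id))
  }
  path <- record_path(store, record$run_id)
  if (file.exists(path)) {
    ra_conflict_error(sprintf("run record '%s' already saved", record$run_id))
  }
  doc <- unclass(record)
  doc$manifest <- df_to_rows(record$manifest)
  doc$final_entries <- lapply(record$final_entries, df_to_rows)
  json_write(doc, path)
  invisible(path)
}

#' Load a persisted run record
#'
#' @param store A [provenance_store()].
#' @param run_id The run's id.
#' @return A `run_record`.
#' @export
load_record <- function(store, run_id) {
  path <- record_path(store, run_id)
  if (!file.exists(path)) ra_validation_error(sprintf("unknown run id '%s'", run_id))
  doc <- json_read(path)
  doc$manifest <- rows_to_df(doc$manifest,
                             c("table", "entry_key", "relpath", "size", "sha256"))
  doc$manifest$size <- as.numeric(doc$manifest$size)
  doc$final_entries <- lapply(doc$final_entries, function(rows) {
    cols <- if (length(rows) > 0) names(rows[[1]]) else character(0)
    rows_to_df(rows, cols)
  })
  doc$entries_added <- lapply(doc$entries_added, as.integer)
  class(doc) <- "run_record"
  doc
}

df_to_rows <- function(df) {
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

rows_to_df <- function(rows, cols) {
  if (length(rows) == 0) {
    return(as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols)))
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r[cols])))
  rownames(out) <- NULL
  out
}

#' Verify an installed run against its record
#'
#' Recomputes the sha256 digest of every file in the run's manifest (located
#' under the registry's current data root) and checks that every committed
#' entry is still present in the registry. Any mismatch, missing file or
#' absent entry fails the report.
#'
#' @param store A [provenance_store()].
#' @param registry The `Registry` the run committed into.
#' @param run_id Id of a succeeded run.
#' @return A list with `files` (per-file `ok`/`mismatch`/`missing`),
#'   `entries` (per-entry `present`/`absent`) and `pass` (logical).
#' @export
verify_run <- function(store, registry, run_id) {
  record <- load_record(store, run_id)
  if (record$status != "succeeded") {
    ra_validation_error(sprintf("run '%s' is %s; only succeeded runs are verifiable",
                                run_id, record$status))
  }
  m <- record$manifest
  file_status <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    path <- file.path(registry$data_root, m$table[i], m$entry_key[i], m$relpath[i])
    file_status[i] <- if (!file.exists(path)) "missing"
      else if (identical(sha256_file(path), m$sha256[i])) "ok"
      else "mismatch"
  }
  files <- cbind(m[, c("table", "entry_key", "relpath"), drop = FALSE],
                 status = file_status)

  entry_rows <- list()
  for (tn in names(record$final_entries)) {
    committed <- record$final_entries[[tn]]
    spec <- get_table(registry, tn)$spec
    live <- query_entries(registry, tn)
    for (i in seq_len(nrow(committed))) {
      want <- committed[i, spec$columns, drop = FALSE]
      present <- nrow(merge(live, want)) > 0
      entry_rows[[length(entry_rows) + 1L]] <-
        data.frame(table = tn, key = want[[spec$key_column]],
                   status = if (present) "present" else "absent")
    }
  }
  entries <- if (length(entry_rows) > 0) do.call(rbind, entry_rows) else
    data.frame(table = character(0), key = character(0), status = character(0))

  list(run_id = run_id, files = files, entries = entries,
       pass = all(file_status == "ok") && all(entries$status == "present"))
}

#' Replay a recorded run
#'
#' Re-executes the recorded recipe, at the recorded version, with the
#' recorded bindings, against a fresh registry and data root. The recipe
#' version must be available in the store: a different version is never
#' silently substituted. Use [compare_runs()] to check fidelity.
#'
#' @param store A [provenance_store()].
#' @param run_id Id of the recorded run.
#' @param registry A fresh `Registry` (its data root receives the replayed
#'   assets).
#' @param recipe_store Named list of recipes from [load_recipe_store()].
#' @param scratch_root Staging-directory root for the replay.
#' @param provenance_store Optional store in which to persist the new record.
#' @return The new `run_record`.
#' @export
replay_run <- function(store, run_id, registry, recipe_store,
                       scratch_root = file.path(tempdir(), "refasset-scratch"),
                       provenance_store = NULL) {
  record <- load_record(store, run_id)
  recipe <- recipe_store[[record$recipe_id]]
  if (is.null(recipe)) {
    ra_stop(sprintf("cannot replay '%s': recipe '%s' not in store",
                    run_id, record$recipe_id), "refasset_replay_error")
  }
  if (!identical(recipe$version, record$recipe_version)) {
    ra_stop(sprintf(
      "cannot replay '%s': recipe '%s' version %s recorded, %s available",
      run_id, record$recipe_id, record$recipe_version, recipe$version),
      "refasset_replay_error")
  }
  run_recipe(registry, recipe_store, record$recipe_id, record$bindings,
             scratch_root = scratch_root, provenance_store = provenance_store)
}

#' Compare two run records for replay fidelity
#'
#' Entries are compared modulo the data-root prefix (absolute install paths
#' legitimately differ between hosts); file manifests are compared by
#' relative path and sha256 digest.
#'
#' @param a,b Two `run_record`s (typically original and replay).
#' @return List with `entries_match`, `digests_match`, `match`.
#' @export
compare_runs <- function(a, b) {
  strip_root <- function(entries, root) {
    prefix <- paste0(sub("/+$", "", root), "/")
    lapply(entries, function(df) {
      df[] <- lapply(df, function(col) {
        ifelse(startsWith(col, prefix),
               paste0("${data_root}/", substring(col, nchar(prefix) + 1L)), col)
      })
      df
    })
  }
  ea <- strip_root(a$final_entries, a$data_root)
  eb <- strip_root(b$final_entries, b$data_root)
  entries_match <- identical(names(ea), names(eb)) &&
    all(vapply(names(ea), function(tn) {
      isTRUE(all.equal(ea[[tn]], eb[[tn]], check.attributes = FALSE))
    }, logical(1)))
  key <- function(m) paste(m$table, m$entry_key, m$relpath, m$sha256, sep = "\r")
  digests_match <- setequal(key(a$manifest), key(b$manifest))
  list(entries_match = entries_match, digests_match = digests_match,
       match = entries_match && digests_match)
}

#' Summarize recorded runs
#'
#' @param store A [provenance_store()].
#' @param recipe_id Optional filter: only runs of this recipe.
#' @return A data.frame sorted by run id (time order): `run_id`,
#'   `recipe_id`, `recipe_version`, `status`, `n_entries_added`.
#' @export
run_history <- function(store, recipe_id = NULL) {
  files <- sort(list.files(store$runs_dir, pattern = "\\.json$", full.names = TRUE))
  rows <- lapply(files, function(f) {
    doc <- json_read(f)
    data.frame(run_id = doc$run_id, recipe_id = doc$recipe_id,
               recipe_version = doc$recipe_version, status = doc$status,
               n_entries_added = sum(unlist(doc$entries_added, use.names = FALSE), 0L))
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(run_id = character(0), recipe_id = character(0),
               recipe_version = character(0), status = character(0),
               n_entries_added = integer(0))
  if (!is.null(recipe_id)) out <- out[out$recipe_id == recipe_id, , drop = FALSE]
  rownames(out) <- NULL
  out
}
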