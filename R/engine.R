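# Engine: executes a recipe end-to-end. The handshake with the recipe
# executable is two fixed filenames inside a per-run staging directory:
# the engine writes "params.json" (parameters + server settings) and the
# executable writes "entries.json" ({"data_tables": {table: [entry, ...]}}).
# The executable never touches a location file; entries always travel
# through this JSON layer. After a successful run the engine finalizes raw
# values, installs files under data_root/<table>/<key>/ and appends the
# entries atomically; any failure rolls everything back.

PARAMS_FILENAME <- "params.json"
ENTRIES_FILENAME <- "entries.json"

# ---- builtin actions ------------------------------------------------------

.builtins <- new.env(parent = emptyenv())

#' Register a builtin recipe action
#'
#' Builtins are in-process callables invoked with the same parameter-bundle
#' contract as subprocess commands: the function receives the bundle, reads
#' inputs from `bundle$params`, writes its outputs (including
#' `entries.json`) into `bundle$staging_dir`, and signals failure by raising
#' an error. They let a full pipeline run without any external binaries.
#'
#' @param name Action name (referenced by recipes as `builtin: <name>`).
#' @param fun Function of one argument (the parameter bundle).
#' @export
register_builtin <- function(name, fun) {
  stopifnot(is_identifier(name), is.function(fun))
  assign(name, fun, envir = .builtins)
  invisible(name)
}

#' @rdname register_builtin
#' @export
builtin_names <- function() sort(ls(.builtins))

get_builtin <- function(name) {
  if (!exists(name, envir = .builtins, inherits = FALSE)) {
    ra_run_error(sprintf("unknown builtin action '%s'", name))
  }
  get(name, envir = .builtins, inherits = FALSE)
}

# ---- staging & parameter bundle ------------------------------------------

#' Create a unique, empty staging directory
#'
#' @param scratch_root Directory under which per-run staging directories are
#'   created (created if absent).
#' @return Absolute path of the new directory.
#' @export
new_staging_dir <- function(scratch_root) {
  if (!dir.exists(scratch_root)) dir.create(scratch_root, recursive = TRUE)
  dir <- tempfile(pattern = "run-", tmpdir = normalizePath(scratch_root))
  dir.create(dir)
  normalizePath(dir)
}

#' Build the parameter bundle for a run
#'
#' Serializes the normalized bindings plus server settings as `params.json`
#' inside the staging directory, with stable (sorted) key ordering. For
#' subprocess recipes the file's path is appended as the command's final
#' token.
#'
#' @param recipe A `recipe_spec`.
#' @param bindings Normalized bindings from [validate_bindings()].
#' @param staging_dir An empty per-run directory from [new_staging_dir()].
#' @param settings Named list of server settings; must include `data_root`.
#' @return The bundle (named list), invisibly carrying `params_path`.
#' @export
build_param_bundle <- function(recipe, bindings, staging_dir, settings) {
  stopifnot(inherits(recipe, "recipe_spec"))
  if (is.null(settings$data_root)) ra_config_error("settings must include data_root")
  if (!dir.exists(staging_dir)) ra_run_error(sprintf("staging dir missing: %s", staging_dir))
  bundle <- list(params = bindings,
                 staging_dir = normalizePath(staging_dir),
                 settings = list(data_root = normalizePath(settings$data_root)))
  path <- file.path(bundle$staging_dir, PARAMS_FILENAME)
  json_write(bundle, path, sort_keys = TRUE)
  bundle$params_path <- path
  bundle
}

# ---- invocation -----------------------------------------------------------

#' Invoke a recipe's command or builtin action
#'
#' Subprocess commands have their `${param}` placeholders substituted
#' per-token (values are never re-parsed by a shell, so parameter content
#' cannot inject extra arguments), receive the `params.json` path as their
#' final token, and run with the staging directory as working directory.
#' Builtins run in-process with the same bundle. stdout and stderr are
#' captured into the returned log either way.
#'
#' @param recipe A `recipe_spec`.
#' @param bundle A parameter bundle from [build_param_bundle()].
#' @return List with `status` (0 on success) and `log` (character).
#' @export
invoke_recipe <- function(recipe, bundle) {
  if (!is.null(recipe$builtin)) {
    fun <- get_builtin(recipe$builtin)
    buf <- new.env(parent = emptyenv())
    buf$lines <- character(0)
    res <- withCallingHandlers(
      tryCatch({
        buf$lines <- c(buf$lines, utils::capture.output(fun(bundle)))
        0L
      }, error = function(e) {
        buf$lines <- c(buf$lines, paste("ERROR:", conditionMessage(e)))
        1L
      }),
      message = function(m) {
        buf$lines <- c(buf$lines, sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    return(list(status = res, log = paste(buf$lines, collapse = "\n")))
  }

  tokens <- vapply(recipe$command, function(tok) {
    substitute_placeholders(tok, lapply(bundle$params, as.character),
                            error_fun = ra_run_error)
  }, character(1))
  tokens <- c(tokens, bundle$params_path)
  exe <- tokens[1]
  if (Sys.which(exe) == "" && !file.exists(exe)) {
    return(list(status = 127L, log = sprintf("executable not found: %s", exe)))
  }
  log_file <- file.path(bundle$staging_dir, "run.log")
  old_wd <- setwd(bundle$staging_dir)
  on.exit(setwd(old_wd), add = TRUE)
  status <- suppressWarnings(
    system2(exe, args = shQuote(tokens[-1]), stdout = log_file, stderr = log_file))
  log <- if (file.exists(log_file)) paste(readLines(log_file, warn = FALSE), collapse = "\n") else ""
  list(status = as.integer(status), log = log)
}

# ---- entry bundle ---------------------------------------------------------

#' Parse and validate an entry bundle
#'
#' The entry bundle is the JSON document a recipe writes to describe the new
#' registry entries: `{"data_tables": {"<table>": [{<col>: <string>, ...}]}}`.
#' One bundle may span several tables, each with any number of entries.
#' Every named table must be declared by the recipe's output declarations,
#' and every entry value must be a string.
#'
#' @param text JSON text (typically the content of `entries.json`).
#' @param recipe A `recipe_spec`.
#' @return A validated list with element `data_tables`.
#' @export
parse_entry_bundle <- function(text, recipe) {
  stopifnot(inherits(recipe, "recipe_spec"))
  doc <- tryCatch(json_read(text),
                  error = function(e) ra_format_error(
                    sprintf("malformed entry bundle: %s", conditionMessage(e))))
  if (!is.list(doc) || is.null(doc$data_tables) || !is.list(doc$data_tables)) {
    ra_format_error("entry bundle must be an object with a 'data_tables' mapping")
  }
  tables <- doc$data_tables
  undeclared <- setdiff(names(tables), names(recipe$outputs))
  if (length(undeclared) > 0) {
    ra_validation_error(sprintf(
      "entry bundle names table(s) not declared by recipe '%s': %s",
      recipe$id, paste(undeclared, collapse = ", ")))
  }
  for (tn in names(tables)) {
    entries <- tables[[tn]]
    if (!is.list(entries)) ra_format_error(sprintf("entries for '%s' must be a list", tn))
    for (e in entries) {
      if (!is.list(e) || is.null(names(e)) || any(!nzchar(names(e)))) {
        ra_format_error(sprintf("each entry for '%s' must be a named mapping", tn))
      }
      ok <- vapply(e, function(v) is.character(v) && length(v) == 1L, logical(1))
      if (!all(ok)) {
        ra_format_error(sprintf(
          "entry for '%s': value of '%s' is not a string", tn, names(e)[which(!ok)[1]]))
      }
    }
  }
  list(data_tables = tables)
}

# ---- file installation ----------------------------------------------------

#' Install staged files into the permanent data store
#'
#' Copies files from the staging directory into the asset directory
#' (`data_root/<table>/<key>/`) according to the move policy: `copy_dir`
#' takes everything except the `params.json`/`entries.json` handshake files
#' (and the captured run log), preserving relative layout; `copy_file` takes
#' only the files named by translated path columns; `none` moves nothing.
#' The manifest is computed after the copy, from the installed bytes. A
#' pre-existing non-empty asset directory is a collision (never overwritten);
#' a failed copy removes the partially installed directory.
#'
#' @param staging_dir The run's staging directory.
#' @param asset_dir Destination directory (absent or empty).
#' @param policy One of `"copy_dir"`, `"copy_file"`, `"none"`.
#' @param files For `copy_file`: staging-relative names of the files to
#'   install.
#' @return A data.frame manifest: `relpath`, `size`, `sha256`.
#' @export
install_files <- function(staging_dir, asset_dir, policy, files = character(0)) {
  if (!policy %in% MOVE_POLICIES) ra_config_error(sprintf("unknown move policy '%s'", policy))
  empty_manifest <- data.frame(relpath = character(0), size = numeric(0),
                               sha256 = character(0))
  if (policy == "none") return(empty_manifest)

  if (dir.exists(asset_dir) && length(list.files(asset_dir, all.files = TRUE, no.. = TRUE)) > 0) {
    ra_conflict_error(sprintf("asset directory already populated: %s", asset_dir))
  }
  if (!dir.exists(asset_dir)) dir.create(asset_dir, recursive = TRUE)

  reserved <- c(PARAMS_FILENAME, ENTRIES_FILENAME, "run.log")
  src <- if (policy == "copy_dir") {
    setdiff(list.files(staging_dir, recursive = TRUE, all.files = TRUE, no.. = TRUE),
            reserved)
  } else {
    files
  }
  ok <- tryCatch({
    for (rel in src) {
      if (has_dotdot(rel)) ra_validation_error(sprintf("unsafe relative path: %s", rel))
      from <- file.path(staging_dir, rel)
      if (!file.exists(from)) {
        ra_run_error(sprintf("file to install not found in staging: %s", rel))
      }
      to <- file.path(asset_dir, rel)
      if (!dir.exists(dirname(to))) dir.create(dirname(to), recursive = TRUE)
      if (!file.copy(from, to, overwrite = FALSE)) {
        ra_stop(sprintf("copy failed: %s", rel), "refasset_io_error")
      }
    }
    TRUE
  }, refasset_error = function(e) e)
  if (!isTRUE(ok)) {
    unlink(asset_dir, recursive = TRUE)
    stop(ok)
  }
  manifest_of_dir(asset_dir)
}

# Walk a directory and digest every installed file.
manifest_of_dir <- function(dir) {
  rels <- sort(list.files(dir, recursive = TRUE, all.files = TRUE, no.. = TRUE))
  data.frame(
    relpath = rels,
    size = vapply(file.path(dir, rels), function(p) as.numeric(file.size(p)), numeric(1)),
    sha256 = vapply(file.path(dir, rels), sha256_file, character(1)),
    row.names = NULL)
}

# ---- orchestration --------------------------------------------------------

#' Run a recipe end-to-end
#'
#' Orchestrates one complete run: staging directory, parameter bundle,
#' command or builtin invocation, entry-bundle parsing, per-entry
#' finalization, file installation, and the atomic registry commit. The run
#' is all-or-nothing: a failure at any stage rolls back installed files and
#' restores every touched location file and in-memory table to its pre-run
#' state, and a terminal run record (`succeeded`, `failed` or `rolled_back`)
#' is returned -- and persisted, when a provenance store is supplied -- in
#' every case.
#'
#' @param registry A `Registry`.
#' @param recipe_store Named list of recipes from [load_recipe_store()].
#' @param recipe_id Id of the recipe to run.
#' @param bindings Raw parameter bindings (strings); validated internally.
#' @param scratch_root Directory for staging directories.
#' @param provenance_store Optional [provenance_store()]; the run record is
#'   saved there in every terminal state.
#' @param fail_at Failure-injection point for crash-safety testing: one of
#'   `"after_invoke"`, `"after_finalize"`, `"after_install"`, `"mid_append"`,
#'   or `NULL` (default) for a normal run.
#' @return A `run_record` object.
#' @export
run_recipe <- function(registry, recipe_store, recipe_id, bindings = list(),
                       scratch_root = file.path(tempdir(), "refasset-scratch"),
                       provenance_store = NULL, fail_at = NULL) {
  if (!recipe_id %in% names(recipe_store)) {
    ra_validation_error(sprintf("unknown recipe '%s'", recipe_id))
  }
  recipe <- recipe_store[[recipe_id]]
  norm <- validate_bindings(recipe, bindings)

  record <- list(run_id = new_run_id(), recipe_id = recipe$id,
                 recipe_version = recipe$version, bindings = norm,
                 started = utc_now(), finished = NULL, status = "failed",
                 data_root = registry$data_root,
                 raw_bundle = NULL, final_entries = list(),
                 entries_added = list(), manifest = empty_run_manifest(),
                 log = "")
  class(record) <- "run_record"

  installed_dirs <- character(0)
  loc_snapshots <- list()     # loc_file -> raw bytes before commit
  mem_snapshots <- list()     # table -> entries data.frame before commit

  result <- tryCatch({
    staging <- new_staging_dir(scratch_root)
    bundle <- build_param_bundle(recipe, norm, staging,
                                 settings = list(data_root = registry$data_root))
    inv <- invoke_recipe(recipe, bundle)
    record$log <- inv$log
    if (inv$status != 0L) {
      ra_run_error(sprintf("recipe '%s' exited with status %d", recipe$id, inv$status))
    }
    maybe_fail("after_invoke", fail_at)

    entries_path <- file.path(staging, ENTRIES_FILENAME)
    if (!file.exists(entries_path)) {
      ra_run_error(sprintf("recipe '%s' produced no %s", recipe$id, ENTRIES_FILENAME))
    }
    raw_bundle <- parse_entry_bundle(
      paste(readLines(entries_path, warn = FALSE), collapse = "\n"), recipe)
    record$raw_bundle <- raw_bundle

    # finalize raw entries table by table
    finalized <- list()
    for (tn in names(raw_bundle$data_tables)) {
      out <- recipe$outputs[[tn]]
      spec <- get_table(registry, tn)$spec
      ctx <- list(data_root = registry$data_root, table_spec = spec)
      rows <- lapply(raw_bundle$data_tables[[tn]], finalize_entry, out = out, ctx = ctx)
      finalized[[tn]] <- if (length(rows) > 0) do.call(rbind, rows) else
        as_entries(NULL, spec)
    }
    maybe_fail("after_finalize", fail_at)

    # classify each finalized entry against the live registry before any
    # file is installed: an exact duplicate of an existing entry is skipped
    # (a rerun with identical bindings is a no-op, not a collision), while a
    # key conflict with differing data aborts the run before installation
    is_new <- list()
    for (tn in names(finalized)) {
      spec <- get_table(registry, tn)$spec
      existing <- query_entries(registry, tn)
      fin <- finalized[[tn]]
      keep <- rep(TRUE, nrow(fin))
      if (!spec$allow_duplicates) {
        for (i in seq_len(nrow(fin))) {
          hit <- which(existing[[spec$key_column]] == fin[[spec$key_column]][i])
          if (length(hit) == 0) next
          if (identical(unlist(existing[hit[1], , drop = TRUE]),
                        unlist(fin[i, , drop = TRUE]))) {
            keep[i] <- FALSE
          } else {
            ra_conflict_error(sprintf(
              "table '%s': key '%s' already present with different values",
              tn, fin[[spec$key_column]][i]))
          }
        }
      }
      is_new[[tn]] <- keep
    }

    # install files before the registry commit: an entry pointing at missing
    # files is worse than orphaned files
    manifest <- empty_run_manifest()
    for (tn in names(finalized)) {
      out <- recipe$outputs[[tn]]
      if (out$move_policy == "none") next
      spec <- get_table(registry, tn)$spec
      raws <- raw_bundle$data_tables[[tn]]
      for (i in seq_along(raws)) {
        if (!is_new[[tn]][i]) next
        key <- raws[[i]][[spec$key_column]]
        asset_dir <- file.path(registry$data_root, tn, key)
        files <- if (out$move_policy == "copy_file") {
          basename(unlist(raws[[i]][names(out$translations)], use.names = FALSE))
        } else character(0)
        m <- install_files(staging, asset_dir, out$move_policy, files)
        installed_dirs <- c(installed_dirs, asset_dir)
        if (nrow(m) > 0) {
          manifest <- rbind(manifest,
                            cbind(data.frame(table = tn, entry_key = key), m))
        }
      }
    }
    record$manifest <- manifest
    maybe_fail("after_install", fail_at)

    # atomic commit; snapshot each touched table so a mid-commit failure can
    # restore both the loc bytes and the in-memory state
    added <- list()
    committed_tables <- character(0)
    for (tn in names(finalized)) {
      tab <- get_table(registry, tn)
      loc_snapshots[[tab$loc_file]] <- list(bytes = read_bytes(tab$loc_file),
                                            existed = file.exists(tab$loc_file))
      mem_snapshots[[tn]] <- tab$entries
    }
    first <- TRUE
    for (tn in names(finalized)) {
      n <- append_entries(registry, tn, finalized[[tn]][is_new[[tn]], , drop = FALSE])
      committed_tables <- c(committed_tables, tn)
      added[[tn]] <- as.integer(n)
      if (first) { maybe_fail("mid_append", fail_at); first <- FALSE }
    }
    record$final_entries <- finalized
    record$entries_added <- added
    record$status <- "succeeded"
    record
  }, refasset_error = function(e) {
    # rollback: remove installed asset dirs, restore loc files and memory
    if (length(installed_dirs) > 0 || length(loc_snapshots) > 0) {
      for (d in unique(installed_dirs)) unlink(d, recursive = TRUE)
      for (loc in names(loc_snapshots)) {
        snap <- loc_snapshots[[loc]]
        if (snap$existed) atomic_write_bytes(loc, snap$bytes) else unlink(loc)
      }
      for (tn in names(mem_snapshots)) {
        registry$tables[[tn]]$entries <- mem_snapshots[[tn]]
      }
      record$status <- "rolled_back"
    } else {
      record$status <- "failed"
    }
    record$log <- paste(c(record$log, paste("ERROR:", conditionMessage(e))),
                        collapse = "\n")
    record$error <- conditionMessage(e)
    record
  })

  result$finished <- utc_now()
  if (!is.null(provenance_store)) save_record(provenance_store, result)
  result
}

empty_run_manifest <- function() {
  data.frame(table = character(0), entry_key = character(0),
             relpath = character(0), size = numeric(0), sha256 = character(0))
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run> %s: %s %s [%s]\n", x$run_id, x$recipe_id, x$recipe_version, x$status))
  for (tn in names(x$entries_added)) {
    cat(sprintf("  %s: +%d entries\n", tn, x$entries_added[[tn]]))
  }
  invisible(x)
}
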