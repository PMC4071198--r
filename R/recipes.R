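# Recipes: declarative descriptions of how one reference-data asset is
# acquired or built, and how the raw registry values a recipe emits are
# finalized. A recipe document merges what a tool wrapper would split across
# a tool description and a separate output configuration: parameters and the
# command on one side, output tables, value translations and the file move
# policy on the other.

PARAM_KINDS <- c("text", "integer", "boolean", "choice", "input_path")
TRANSLATION_KINDS <- c("template", "abspath")
MOVE_POLICIES <- c("copy_dir", "copy_file", "none")
TEMPLATE_PLACEHOLDERS <- c("data_root", "table", "value", "dbkey", "raw")

#' Parse and validate a recipe document
#'
#' A recipe declares an id and version, its parameters, the command to run
#' (either an ordered token list with `${param}` placeholders, or the name of
#' a builtin action), and one or more output declarations: the data table the
#' recipe may modify, per-column value translations, and a move policy for
#' the files it produces. Validation is cross-checked against the registry
#' configuration: every declared output table and every translated column
#' must exist there.
#'
#' @param doc Path to a YAML recipe document, or an equivalent list.
#' @param registry A `Registry` (or a named list of [data_table_spec()]s)
#'   providing the declared tables.
#' @return A validated `recipe_spec` object.
#' @export
parse_recipe <- function(doc, registry) {
  doc <- read_structured_doc(doc, what = "recipe document")
  table_specs <- registry_table_specs(registry)

  for (field in c("id", "version", "name")) {
    if (is.null(doc[[field]]) || !nzchar(as.character(doc[[field]]))) {
      ra_config_error(sprintf("recipe document missing required field '%s'", field))
    }
  }
  if (!is_identifier(doc$id)) {
    ra_config_error(sprintf("recipe id '%s' is not a valid identifier", doc$id))
  }

  params <- lapply(doc$params %||% list(), parse_param_decl)
  names(params) <- vapply(params, `[[`, character(1), "name")
  if (anyDuplicated(names(params))) {
    ra_config_error(sprintf("recipe '%s': duplicate parameter names", doc$id))
  }

  builtin <- doc$builtin
  command <- if (!is.null(doc$command)) as.character(unlist(doc$command)) else NULL
  if (is.null(builtin) && is.null(command)) {
    ra_config_error(sprintf("recipe '%s': needs either 'command' tokens or a 'builtin' action",
                            doc$id))
  }
  if (!is.null(builtin) && !is.null(command)) {
    ra_config_error(sprintf("recipe '%s': 'command' and 'builtin' are mutually exclusive",
                            doc$id))
  }
  if (!is.null(command)) {
    for (tok in command) {
      for (ph in extract_placeholders(tok)) {
        if (!ph %in% names(params)) {
          ra_config_error(sprintf(
            "recipe '%s': command placeholder ${%s} names no declared parameter",
            doc$id, ph))
        }
      }
    }
  }

  outputs <- doc$outputs %||% list()
  if (length(outputs) == 0) {
    ra_config_error(sprintf("recipe '%s': at least one output declaration required", doc$id))
  }
  outputs <- lapply(outputs, parse_output_decl, table_specs = table_specs,
                    recipe_id = doc$id)
  if (anyDuplicated(vapply(outputs, `[[`, character(1), "table"))) {
    ra_config_error(sprintf("recipe '%s': multiple output declarations for one table",
                            doc$id))
  }
  names(outputs) <- vapply(outputs, `[[`, character(1), "table")

  structure(list(id = doc$id, version = as.character(doc$version),
                 name = doc$name, description = doc$description %||% "",
                 params = params, command = command, builtin = builtin,
                 outputs = outputs),
            class = "recipe_spec")
}

registry_table_specs <- function(registry) {
  if (inherits(registry, "Registry")) {
    lapply(registry$tables, `[[`, "spec")
  } else if (is.list(registry)) {
    registry
  } else {
    ra_config_error("expected a Registry or a named list of table specs")
  }
}

parse_param_decl <- function(p) {
  if (is.null(p$name) || !is_identifier(p$name)) {
    ra_config_error(sprintf("parameter declaration with invalid name: %s",
                            deparse(p$name)))
  }
  kind <- p$kind %||% "text"
  if (!kind %in% PARAM_KINDS) {
    ra_config_error(sprintf("parameter '%s': unknown kind '%s'", p$name, kind))
  }
  choices <- as.character(unlist(p$choices %||% character(0)))
  if (kind == "choice" && length(choices) == 0) {
    ra_config_error(sprintf("choice parameter '%s' declares no choices", p$name))
  }
  default <- if (!is.null(p$default)) as.character(p$default) else NULL
  if (!is.null(default)) {
    # defaults are normalized like user input; input_path defaults are
    # resolved at binding time, not declaration time
    if (kind == "choice" && !default %in% choices) {
      ra_config_error(sprintf("parameter '%s': default '%s' not among choices",
                              p$name, default))
    }
    if (kind == "integer" && is.na(suppressWarnings(as.integer(default)))) {
      ra_config_error(sprintf("parameter '%s': default '%s' is not an integer",
                              p$name, default))
    }
    if (kind == "boolean" && !tolower(default) %in% c("true", "false")) {
      ra_config_error(sprintf("parameter '%s': default '%s' is not a boolean",
                              p$name, default))
    }
  }
  list(name = p$name, kind = kind, default = default, choices = choices)
}

parse_output_decl <- function(o, table_specs, recipe_id) {
  table <- o$table %||% ra_config_error(
    sprintf("recipe '%s': output declaration missing 'table'", recipe_id))
  if (!table %in% names(table_specs)) {
    ra_config_error(sprintf("recipe '%s': output table '%s' is not declared in the registry",
                            recipe_id, table))
  }
  spec <- table_specs[[table]]
  move_policy <- o$move_policy %||% "none"
  if (!move_policy %in% MOVE_POLICIES) {
    ra_config_error(sprintf("recipe '%s': unknown move_policy '%s'", recipe_id, move_policy))
  }
  translations <- lapply(o$translations %||% list(), parse_translation,
                         table_spec = spec, recipe_id = recipe_id)
  if (anyDuplicated(vapply(translations, `[[`, character(1), "column"))) {
    ra_config_error(sprintf("recipe '%s': multiple translations for one column in table '%s'",
                            recipe_id, table))
  }
  names(translations) <- vapply(translations, `[[`, character(1), "column")
  list(table = table, translations = translations, move_policy = move_policy)
}

parse_translation <- function(tr, table_spec, recipe_id) {
  column <- tr$column %||% ra_config_error(
    sprintf("recipe '%s': translation missing 'column'", recipe_id))
  if (!column %in% table_spec$columns) {
    ra_config_error(sprintf(
      "recipe '%s': translation on column '%s' unknown to table '%s'",
      recipe_id, column, table_spec$name))
  }
  kind <- tr$kind %||% "template"
  if (!kind %in% TRANSLATION_KINDS) {
    ra_config_error(sprintf("recipe '%s': unknown translation kind '%s'", recipe_id, kind))
  }
  template <- tr$template
  if (kind == "template") {
    if (is.null(template)) {
      ra_config_error(sprintf("recipe '%s': template translation on '%s' missing 'template'",
                              recipe_id, column))
    }
    bad <- setdiff(extract_placeholders(template), TEMPLATE_PLACEHOLDERS)
    if (length(bad) > 0) {
      ra_config_error(sprintf(
        "recipe '%s': template for '%s' uses undefined placeholder(s): %s",
        recipe_id, column, paste0("${", bad, "}", collapse = ", ")))
    }
  }
  list(column = column, kind = kind, template = template)
}

#' Validate and normalize parameter bindings
#'
#' Missing parameters take their declared defaults; integers and booleans
#' are parsed; choice membership is enforced; `input_path` values must name
#' existing files and are resolved to absolute paths.
#'
#' @param recipe A `recipe_spec`.
#' @param bindings Named list/vector of parameter values (strings as they
#'   would arrive from a command line).
#' @return A named list of normalized values.
#' @export
validate_bindings <- function(recipe, bindings = list()) {
  stopifnot(inherits(recipe, "recipe_spec"))
  bindings <- as.list(bindings)
  unknown <- setdiff(names(bindings), names(recipe$params))
  if (length(unknown) > 0) {
    ra_validation_error(sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", ")))
  }
  out <- list()
  for (p in recipe$params) {
    raw <- bindings[[p$name]] %||% p$default
    if (is.null(raw)) {
      ra_validation_error(sprintf("missing required parameter '%s'", p$name))
    }
    raw <- as.character(raw)
    out[[p$name]] <- switch(p$kind,
      text = raw,
      integer = {
        v <- suppressWarnings(as.integer(raw))
        if (is.na(v)) ra_validation_error(sprintf("parameter '%s': '%s' is not an integer",
                                                  p$name, raw))
        v
      },
      boolean = {
        if (!tolower(raw) %in% c("true", "false")) {
          ra_validation_error(sprintf("parameter '%s': '%s' is not a boolean", p$name, raw))
        }
        tolower(raw) == "true"
      },
      choice = {
        if (!raw %in% p$choices) {
          ra_validation_error(sprintf("parameter '%s': '%s' is not one of {%s}",
                                      p$name, raw, paste(p$choices, collapse = ", ")))
        }
        raw
      },
      input_path = {
        if (!file.exists(raw)) {
          ra_validation_error(sprintf("parameter '%s': input path '%s' does not exist",
                                      p$name, raw))
        }
        normalizePath(raw)
      })
  }
  out
}

#' Apply one value translation
#'
#' `template` translations substitute the placeholders `${data_root}`,
#' `${table}`, `${value}`, `${dbkey}` and `${raw}` into the declared
#' template. `abspath` translations join a relative raw value under the data
#' root and leave an already-absolute value unchanged (hence idempotent).
#'
#' @param tr A translation (from a parsed recipe's output declaration).
#' @param raw The raw value emitted by the recipe executable.
#' @param ctx Named list with `data_root`, `table`, `value`, `dbkey`.
#' @return The finalized value (a string).
#' @export
apply_translation <- function(tr, raw, ctx) {
  for (k in c("data_root", "table", "value")) {
    if (is.null(ctx[[k]])) ra_validation_error(sprintf("translation context missing '%s'", k))
  }
  ctx$dbkey <- ctx$dbkey %||% ""
  raw <- as.character(raw)
  if (tr$kind == "abspath") {
    if (startsWith(raw, "/")) return(raw)
    if (has_dotdot(raw)) {
      ra_validation_error(sprintf("raw value '%s' contains a '..' segment", raw))
    }
    return(file.path(ctx$data_root, raw))
  }
  vals <- list(data_root = ctx$data_root, table = ctx$table,
               value = ctx$value, dbkey = ctx$dbkey, raw = raw)
  # substituted pieces must not climb out of the data root
  for (k in c("value", "dbkey", "raw")) {
    if (has_dotdot(vals[[k]])) {
      ra_validation_error(sprintf("translation input '%s' contains a '..' segment: '%s'",
                                  k, vals[[k]]))
    }
  }
  substitute_placeholders(tr$template, vals)
}

#' Finalize a raw registry entry
#'
#' Columns with a declared translation are replaced by the translation's
#' output; every other column passes through verbatim ("used as-is"). The
#' result must satisfy the target table's entry invariants.
#'
#' @param raw_entry Named list/vector of raw column values (must include at
#'   least the table's key column).
#' @param out An output declaration from a parsed recipe.
#' @param ctx Named list with `data_root` and the target [data_table_spec()]
#'   as `table_spec` (or `table`/`value`/`dbkey` supplied directly).
#' @return A one-row data.frame satisfying the table spec.
#' @export
finalize_entry <- function(raw_entry, out, ctx) {
  spec <- ctx$table_spec
  if (is.null(spec)) ra_validation_error("finalize context missing 'table_spec'")
  raw_entry <- lapply(as.list(raw_entry), as.character)
  key <- raw_entry[[spec$key_column]]
  if (is.null(key) || !nzchar(key)) {
    ra_validation_error(sprintf("raw entry missing key column '%s'", spec$key_column))
  }
  tctx <- list(data_root = ctx$data_root, table = out$table,
               value = key, dbkey = raw_entry$dbkey %||% "")
  final <- raw_entry
  for (col in names(out$translations)) {
    raw_val <- raw_entry[[col]]
    if (is.null(raw_val)) {
      ra_validation_error(sprintf("raw entry missing translated column '%s'", col))
    }
    final[[col]] <- apply_translation(out$translations[[col]], raw_val, tctx)
  }
  missing <- setdiff(spec$columns, names(final))
  if (length(missing) > 0) {
    ra_validation_error(sprintf("entry for table '%s' missing column(s): %s",
                                out$table, paste(missing, collapse = ", ")))
  }
  as_entries(final[spec$columns], spec)
}

#' Load all recipe documents from a directory
#'
#' Reads every `*.yml`/`*.yaml` file in `dir` as a recipe and validates it
#' against the registry. Recipe ids must be unique within the store.
#'
#' @param dir Directory of recipe documents.
#' @param registry A `Registry`.
#' @return A named list of `recipe_spec` objects keyed by id.
#' @export
load_recipe_store <- function(dir, registry) {
  if (!dir.exists(dir)) ra_config_error(sprintf("recipes directory not found: %s", dir))
  files <- list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE)
  store <- list()
  for (f in sort(files)) {
    r <- parse_recipe(f, registry)
    if (r$id %in% names(store)) {
      ra_config_error(sprintf("duplicate recipe id '%s' in %s", r$id, dir))
    }
    store[[r$id]] <- r
  }
  store
}

#' @export
print.recipe_spec <- function(x, ...) {
  cat(sprintf("<recipe> %s (version %s): %s\n", x$id, x$version, x$name))
  cat("  params: ", paste(names(x$params), collapse = ", "), "\n")
  cat("  outputs:", paste(names(x$outputs), collapse = ", "), "\n")
  invisible(x)
}
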