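# Fixtures: a seeded synthetic genome generator and toy recipe builders, so
# the whole pipeline -- acquisition, indexing, installation, registry commit,
# verification, replay -- runs with no downloads and no external aligner
# binaries. The toy indexer produces real, checkable derived data (per-
# sequence lengths and a sha256 of the input) rather than marker files, so
# verification and replay tests have content-level teeth.

# Total-bases cutoff for the toy indexer's algorithm=auto branch: genomes at
# or below this many bases are indexed "small", larger ones "large". This is
# a fixture constant chosen so both branches are cheap to exercise; it makes
# no claim about any real aligner's algorithm-selection threshold.
TOY_INDEX_AUTO_THRESHOLD <- 50000

#' Generate a deterministic synthetic FASTA file
#'
#' Standard FASTA with headers `>synth_<i>` and 60-character line wrap.
#' Sequences are uniform random draws from ACGT under a local RNG seeded
#' from `seed`; the same spec always produces byte-identical output (the
#' caller's RNG state is left untouched).
#'
#' @param out_path Destination file path.
#' @param n_sequences Number of sequences (>= 1).
#' @param length Bases per sequence (>= 1).
#' @param seed Integer seed.
#' @return `out_path`, invisibly.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' make_fasta(fa, n_sequences = 2, length = 120, seed = 7)
#' readLines(fa, n = 3)
#' @export
make_fasta <- function(out_path, n_sequences = 1, length = 1000, seed = 1) {
  if (n_sequences < 1 || length < 1) {
    ra_validation_error("make_fasta needs n_sequences >= 1 and length >= 1")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  seqs <- vapply(seq_len(n_sequences), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- paste0("synth_", seq_len(n_sequences))
  Biostrings::writeXStringSet(x, out_path, width = 60L)
  invisible(out_path)
}

# Read a FASTA for the toy builders, insisting on a well-formed first record.
read_fasta_checked <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    ra_run_error(sprintf("FASTA file missing or empty: %s", path))
  }
  first <- readLines(path, n = 1, warn = FALSE)
  if (length(first) == 0 || !startsWith(trimws(first), ">")) {
    ra_run_error(sprintf("malformed FASTA (no '>' first record): %s", path))
  }
  Biostrings::readDNAStringSet(path)
}

write_entry_bundle <- function(staging_dir, data_tables) {
  json_write(list(data_tables = data_tables),
             file.path(staging_dir, ENTRIES_FILENAME))
}

# Builtin: register a local FASTA file into the all_fasta table. Copies the
# FASTA into staging under its base name and emits one raw entry whose path
# is that base name -- finalization rewrites it to the installed location.
builtin_fetch_local_fasta <- function(bundle) {
  p <- bundle$params
  fasta <- p$fasta %||% ra_run_error("fetch_local_fasta: missing 'fasta' parameter")
  read_fasta_checked(fasta)   # validates readable, non-empty, well-formed
  dest <- file.path(bundle$staging_dir, basename(fasta))
  if (!file.copy(fasta, dest, overwrite = FALSE)) {
    ra_run_error(sprintf("could not stage FASTA: %s", fasta))
  }
  entry <- list(value = p$dbkey, dbkey = p$dbkey,
                name = if (nzchar(p$name %||% "")) p$name else p$dbkey,
                path = basename(fasta))
  write_entry_bundle(bundle$staging_dir, list(all_fasta = list(entry)))
  cat(sprintf("registered FASTA %s as dbkey %s\n", basename(fasta), p$dbkey))
  invisible(0L)
}

# Builtin: toy sequence indexer standing in for a real aligner indexer.
# Deterministically derives two index files next to a staged copy of the
# FASTA: <fasta>.sizes (one "<header>\t<length>" line per sequence) and
# <fasta>.sum (the sha256 hex digest of the FASTA bytes). algorithm=auto
# picks small/large by TOY_INDEX_AUTO_THRESHOLD on total bases.
builtin_toy_index <- function(bundle) {
  p <- bundle$params
  fasta <- p$fasta %||% ra_run_error("toy_index: missing 'fasta' parameter")
  seqs <- read_fasta_checked(fasta)
  algorithm <- p$algorithm %||% "auto"
  if (algorithm == "auto") {
    algorithm <- if (sum(Biostrings::width(seqs)) <= TOY_INDEX_AUTO_THRESHOLD)
      "small" else "large"
  }
  base <- basename(fasta)
  staged <- file.path(bundle$staging_dir, base)
  if (!file.copy(fasta, staged, overwrite = FALSE)) {
    ra_run_error(sprintf("could not stage FASTA: %s", fasta))
  }
  writeLines(paste(names(seqs), Biostrings::width(seqs), sep = "\t"),
             paste0(staged, ".sizes"))
  writeLines(sha256_file(staged), paste0(staged, ".sum"))
  entry <- list(value = p$dbkey, dbkey = p$dbkey,
                name = sprintf("%s (%s)",
                               if (nzchar(p$name %||% "")) p$name else p$dbkey,
                               algorithm),
                path = base)
  write_entry_bundle(bundle$staging_dir, list(toy_indexes = list(entry)))
  cat(sprintf("indexed %s (%d sequences, algorithm %s)\n",
              base, length(seqs), algorithm))
  invisible(0L)
}

# Builtin: multi-table demonstration recipe. Emits two entries into
# all_fasta and three into toy_indexes, derived deterministically from the
# 'prefix' parameter; no files are moved (move_policy none on both tables).
builtin_toy_multi <- function(bundle) {
  p <- bundle$params
  prefix <- p$prefix %||% "demo"
  mk <- function(i) list(value = sprintf("%s_%d", prefix, i),
                         dbkey = sprintf("%s_%d", prefix, i),
                         name = sprintf("Demo build %s %d", prefix, i),
                         path = sprintf("%s_%d.fa", prefix, i))
  write_entry_bundle(bundle$staging_dir,
                     list(all_fasta = lapply(1:2, mk),
                          toy_indexes = lapply(3:5, mk)))
  invisible(0L)
}

#' Path of the bundled fixture registry configuration
#'
#' A two-table configuration (`all_fasta`, `toy_indexes`, both with columns
#' value/dbkey/name/path) matching the bundled fixture recipes.
#'
#' @return Path to the installed YAML file.
#' @export
fixture_registry_config <- function() {
  system.file("extdata", "registry.yml", package = "refasset", mustWork = TRUE)
}

#' Directory of the bundled fixture recipe documents
#'
#' Contains builtin-backed recipes (`fetch_local_fasta`, `toy_index`,
#' `toy_multi`) exercising the full pipeline without external binaries.
#'
#' @return Path to the installed directory.
#' @export
fixture_recipes_dir <- function() {
  system.file("extdata", "recipes", package = "refasset", mustWork = TRUE)
}

#' Write a subprocess variant of the toy_index recipe
#'
#' The bundled builtin recipes run in-process. This helper writes a recipe
#' document whose command invokes the equivalent standalone script
#' (`Rscript inst/extdata/bin/toy_index.R <params.json>`), proving the
#' subprocess invocation path honors the same JSON contract.
#'
#' @param dir Directory in which to write `toy_index_script.yml`.
#' @return The document's path, invisibly.
#' @export
write_toy_index_script_recipe <- function(dir) {
  script <- system.file("extdata", "bin", "toy_index.R",
                        package = "refasset", mustWork = TRUE)
  doc <- list(
    id = "toy_index_script", version = "1.0.0",
    name = "Toy sequence indexer (subprocess)",
    description = "Subprocess twin of the toy_index builtin.",
    params = list(
      list(name = "dbkey", kind = "text"),
      list(name = "name", kind = "text", default = ""),
      list(name = "fasta", kind = "input_path"),
      list(name = "algorithm", kind = "choice",
           choices = list("auto", "small", "large"), default = "auto")),
    command = list("Rscript", script),
    outputs = list(list(
      table = "toy_indexes", move_policy = "copy_dir",
      translations = list(list(column = "path", kind = "template",
                               template = "${data_root}/${table}/${value}/${raw}")))))
  path <- file.path(dir, "toy_index_script.yml")
  yaml::write_yaml(doc, path)
  invisible(path)
}
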