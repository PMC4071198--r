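# Shared test fixtures: sandboxed registry/recipe/provenance trees under a
# fresh temporary directory, randomized table schemas and entry sets for
# property-style tests, and an independent digest oracle.

# A complete sandbox: registry (fixture two-table config), recipe store,
# provenance store, scratch root, and a seeded synthetic FASTA.
new_sandbox <- function(fasta_seed = 7, n_sequences = 2, bases = 120) {
  root <- tempfile("sandbox-")
  dir.create(root)
  registry <- load_registry(fixture_registry_config(),
                            file.path(root, "registry"), file.path(root, "data"))
  sandbox <- list(
    root = root,
    registry = registry,
    recipes = load_recipe_store(fixture_recipes_dir(), registry),
    prov = provenance_store(file.path(root, "prov")),
    scratch = file.path(root, "scratch"),
    fasta = file.path(root, "genome_build.fa"))
  make_fasta(sandbox$fasta, n_sequences = n_sequences, length = bases,
             seed = fasta_seed)
  sandbox
}

loc_file_of <- function(sandbox, table) {
  sandbox$registry$tables[[table]]$loc_file
}

loc_bytes_of <- function(sandbox, table) {
  path <- loc_file_of(sandbox, table)
  if (!file.exists(path)) raw(0) else readBin(path, "raw", file.size(path))
}

# Independent digest oracle: coreutils sha256sum, a second implementation
# entirely outside the package and the digest package.
oracle_sha256 <- function(path) {
  out <- system2("sha256sum", shQuote(path), stdout = TRUE)
  strsplit(out, " ", fixed = TRUE)[[1]][1]
}

# Randomized table schema: 2-6 identifier-named columns, key column first.
random_schema <- function() {
  k <- sample(2:6, 1)
  cols <- c("value", paste0("col_", sample(1000:9999, k - 1)))
  data_table_spec(name = paste0("tbl_", sample(1000:9999, 1)), columns = cols,
                  loc_path = paste0("tbl", sample(1e6, 1), ".loc"))
}

# Randomized valid entries for a schema. Non-key values draw from a charset
# including spaces, punctuation, '/' and the empty string; key values are
# unique, non-empty and path-safe.
random_entries <- function(spec, n) {
  charset <- c(letters, LETTERS, 0:9, " ", ".", "-", "_", ":", "/", "+", "(", ")")
  rand_val <- function() {
    len <- sample(0:12, 1)
    if (len == 0) "" else paste(sample(charset, len, replace = TRUE), collapse = "")
  }
  out <- as.data.frame(stats::setNames(
    rep(list(character(n)), length(spec$columns)), spec$columns))
  for (col in spec$columns) {
    out[[col]] <- if (col == spec$key_column) {
      if (n == 0) character(0) else paste0("key_", sample(1e7, n))
    } else {
      vapply(seq_len(n), function(i) rand_val(), character(1))
    }
  }
  out
}
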