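---
title: "Managing reference data with declarative recipes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing reference data with declarative recipes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refasset)
```

## The problem

Sequence-analysis servers keep a cache of *built-in reference data*: genome
FASTA files, short-read aligner indexes, BLAST databases. Tools locate these
assets through *data tables* — named registries with fixed columns,
persisted on disk as tab-separated *location files* (`.loc`). Maintaining
the cache by hand means downloading a genome, running an indexer, editing a
`.loc` file, and restarting the server. Each step is error-prone and leaves
no record, and a silently wrong index corrupts every downstream analysis
that trusts it.

refasset automates that procedure. A *recipe* declares how one asset is
built; the *engine* runs it in an isolated staging directory, talking to
the recipe executable only through a JSON contract; committed entries go
into *live* registries (queryable the moment the run returns, no restart)
backed by append-only location files; and every run leaves a *provenance
record* with parameters, timestamps, a sha256 manifest of the installed
files and the captured log, supporting verification and replay.

## The model

### Data tables and location files

A table is `data_table_spec(name, columns, loc_path, key_column,
allow_duplicates)`. The conventional four columns are `value` (the entry's
identity — a genome build such as `hg19`), `dbkey` (the build it is linked
to), `name` (display text) and `path` (where the asset lives). The loc
dialect is UTF-8, TAB-separated, `#` full-line comments, `\n` line
terminator, no quoting. Values containing TAB, newline or carriage return
are rejected rather than escaped: escaping would break the decades of ad
hoc tooling (grep, cut, awk) that reads these files.

Two invariants drive the persistence design:

* **Round-trip**: `parse_loc_text(render_loc_text(E)) == E` for any valid
  entry set — rendering and parsing are exact inverses.
* **Append-only atomicity**: a commit writes *old bytes + rendered new
  lines* to a temporary file in the same directory and `rename()`s it over
  the original (atomic on POSIX). Pre-existing comments and blank lines
  survive verbatim; a reader never sees a torn file; an advisory lock (an
  atomically created lock directory) serializes concurrent commits.

Entry identity is the key column. A re-committed identical row is silently
skipped; a key collision with *different* data is an error that commits
nothing — silent overwrite would destroy provenance. Deletion and editing
are deliberately out of scope: the registry only grows, and history stays
truthful.

### Recipes

One YAML document describes one recipe: identity (`id`, `version`),
parameters (`text`, `integer`, `boolean`, `choice`, `input_path`), the
command (an ordered token list with `${param}` placeholders, or the name of
a builtin action), and output declarations — the tables the recipe may
modify, per-column *value translations*, and a file move policy. Merging
what could be two artifacts (a tool description and an output
configuration) into one document with distinct sections keeps the
separation of concerns without duplicate bookkeeping.

Commands are token lists, never shell strings: placeholder substitution is
per-token, so a parameter value can never smuggle extra arguments or shell
syntax into the invocation.

### The JSON handshake

The engine and the recipe executable exchange two fixed-name files in the
per-run staging directory:

* `params.json` (engine → recipe): normalized parameters, the staging
  directory, and server settings (`data_root`). Its path is appended as the
  command's final token.
* `entries.json` (recipe → engine): `{"data_tables": {table: [entry, …]}}`
  — raw entries, any number, spanning any number of declared tables.

Machine-readable schemas for both ship under
`system.file("extdata/schema", package = "refasset")`. The executable never
touches a location file; the abstraction is what lets the engine guarantee
atomicity, rollback and provenance uniformly for every recipe.

### Value translation and installation

Recipes emit *raw* values — typically a file base name like
`genome_build.fa`. Translations finalize them: a `template` translation
substitutes `${data_root}`, `${table}`, `${value}`, `${dbkey}` and
`${raw}`; an `abspath` translation anchors a relative value under the data
root (idempotently). Untranslated columns pass through byte-for-byte.

The installed layout is `data_root/<table>/<value>/<files>` — one
self-contained directory per built asset. The default template
`${data_root}/${table}/${value}/${raw}` produces exactly that. Two
validation rules make the layout an invariant rather than a convention: key
values may not contain path separators or `..`, and translation inputs with
`..` segments are rejected, so no finalized path can escape the data root.

Move policies: `copy_dir` installs everything in staging except the
handshake files, `copy_file` only the files named by translated path
columns, `none` nothing. Installation happens *before* the registry append
— an entry pointing at missing files is worse than orphaned files, and
orphans are caught by the collision check on the next install.

### All-or-nothing runs

`run_recipe()` is transactional. Before any file is installed, each
finalized entry is classified against the live registry: an exact duplicate
makes the rerun a no-op for that entry (idempotency), a key conflict aborts
before anything is touched. On any later failure the engine removes the
installed asset directories, restores each touched loc file from a byte
snapshot (again via atomic rename) and restores the in-memory tables. The
`fail_at` argument exposes the four interesting interruption points
(`after_invoke`, `after_finalize`, `after_install`, `mid_append`) so the
rollback contract is directly testable; `mid_append` fires after the first
table's append in a multi-table commit, exercising the strongest path —
un-writing an already-persisted append.

### Provenance

Every terminal run — succeeded, failed or rolled back — yields a record:
run id (UTC-time-prefixed, so lexicographic order is execution order),
recipe id and version, normalized bindings, RFC-3339 UTC timestamps,
status, the raw bundle as received, the entries as committed, a sha256
manifest of every installed file, and the captured log. Records are one
JSON document each, append-only, never mutated.

* `verify_run()` re-digests every manifest file and re-checks every
  committed entry against the live registry; any flipped byte or deleted
  loc line is identified precisely.
* `replay_run()` re-executes the recorded recipe — at the recorded version,
  never a silent substitute — with the recorded bindings against a fresh
  registry. `compare_runs()` reports fidelity: installed files must be
  digest-identical, entries value-identical *modulo the data-root prefix*,
  because absolute install paths legitimately differ between hosts.

sha256 was chosen as the digest for ubiquity and collision resistance. What
a run record contains is this package's own decided minimum for
verification and replay; richer provenance models (e.g. W3C PROV export)
are extensions, not requirements.

## The fixture layer

The bundled fixtures make the whole pipeline exercisable offline:

* `make_fasta()` writes a seeded synthetic genome (uniform ACGT, headers
  `synth_<i>`, 60-column wrap). Same seed, same bytes — the determinism the
  replay tests rely on. It emulates only what the pipeline needs from a
  genome: a well-formed FASTA of known size. It has none of the structure
  of real genomes (GC skew, repeats, N runs), so passing tests demonstrate
  the *machinery* — contracts, atomicity, provenance — not the behavior of
  any real indexer on real data.
* The `toy_index` builder derives real, checkable content: per-sequence
  lengths (`.sizes`) and a sha256 of the input (`.sum`), instead of empty
  marker files — so verification and replay comparisons have teeth. Its
  `algorithm=auto` branch selects `small`/`large` at a documented fixture
  threshold of 50,000 total bases, purely to exercise the control flow; it
  claims nothing about any real aligner's cutoff.
* Every fixture recipe exists as a builtin action *and* (for `toy_index`)
  as a standalone subprocess script, proving the two invocation paths honor
  one contract. Wrapping a real indexer is a user-level recipe: point
  `command` at the binary and emit `entries.json` — untested here by
  design, since tests must not depend on external binaries.

## Worked example

```{r example}
root <- tempfile("demo-")
dir.create(root)
registry <- load_registry(fixture_registry_config(),
                          file.path(root, "registry"), file.path(root, "data"))
recipes <- load_recipe_store(fixture_recipes_dir(), registry)
prov <- provenance_store(file.path(root, "prov"))

fasta <- file.path(root, "genome_build.fa")
make_fasta(fasta, n_sequences = 2, length = 120, seed = 7)

run_recipe(registry, recipes, "fetch_local_fasta",
           list(dbkey = "hg19", name = "Human hg19", fasta = fasta),
           scratch_root = file.path(root, "scratch"), provenance_store = prov)
rec <- run_recipe(registry, recipes, "toy_index",
                  list(dbkey = "hg19", name = "Human hg19", fasta = fasta),
                  scratch_root = file.path(root, "scratch"),
                  provenance_store = prov)
query_entries(registry, "toy_indexes")
verify_run(prov, registry, rec$run_id)$pass
```

## Numerical and operational choices

* **Problem sizes.** The test suite and the acceptance script use small
  synthetic genomes (2 × 120 bases for most checks, 3 × 20,000 bases to
  exercise the `large` indexing branch) and 500 randomized entry sets for
  the round-trip property — sizes chosen so the full suite demonstrates
  every contract in seconds while still covering empty entry sets, empty
  field values, trailing empty fields and 2–6-column schemas.
* **Degenerate inputs.** Empty loc files parse to zero entries; an empty
  entry list renders to the empty string; a zero-entry bundle is a legal,
  zero-commit run; an empty or headerless FASTA fails the run before
  anything is installed.
* **Tie-breaks.** Within one incoming batch, a full-row duplicate of an
  already-accepted row is skipped and a conflicting reuse of a key is an
  error — the same policy as against the live registry.
* **Single host.** Atomicity relies on same-filesystem `rename()` and an
  advisory lock; multi-host shared registries (NFS) are out of scope.

## Limitations

The registry is add-only by design; pruning or editing entries means
editing loc files outside the tool (which `verify_run` will then flag).
Authentication is delegated to OS file permissions — the CLI assumes a
single administrator on a trusted host. Real index formats (BWT, suffix
arrays) are never produced by the fixtures; correctness of a wrapped real
indexer is the recipe author's concern, not the framework's.
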