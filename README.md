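# refasset

Declarative reference-data asset management with provenance, for
administrators of sequence-analysis servers.

Alignment and annotation tools depend on built-in reference data — genome
FASTA files, aligner indexes, BLAST databases — located through *data
tables*: named registries with fixed columns, persisted on disk as
tab-separated *location files* (`.loc`). Maintaining that cache by hand
(download the genome, run the indexer, edit `tool-data/bwa_index.loc`,
restart the server) is error-prone and unrecorded, and a silently wrong
index corrupts every analysis that trusts it.

refasset replaces the manual procedure:

- **Recipes** (YAML) declare how one asset is built: parameters, a command
  (token list with `${param}` placeholders, or a builtin action), output
  tables, value translations, and a file move policy.
- The **engine** runs a recipe in an isolated staging directory and talks
  to the executable only through a JSON contract: `params.json` in
  (parameters + server settings), `entries.json` out
  (`{"data_tables": {table: [entry, …]}}`). The executable never touches a
  location file.
- **Value translations** finalize raw values: the emitted file base name
  `genome_build.fa` becomes `data_root/<table>/<value>/genome_build.fa`
  via the template `${data_root}/${table}/${value}/${raw}`; the ID, dbkey
  and display text pass through byte-for-byte.
- The **registry** is live and atomic: commits append rendered lines to the
  loc file via write-temp-then-rename (old bytes are never rewritten, so
  hand-written comments survive), and entries are queryable the moment the
  run returns — no restart, no reload.
- **Provenance**: every run persists an append-only JSON record — recipe id
  and version, normalized bindings, UTC timestamps, status, the raw entry
  bundle, the committed entries, a sha256 manifest of installed files, the
  captured log. `verify_run()` detects any flipped byte or deleted registry
  line; `replay_run()` re-executes the recorded run on a fresh data root
  and `compare_runs()` checks digest-identical files and entries identical
  modulo the data-root prefix.

Runs are all-or-nothing: any failure rolls back installed files, restores
every touched loc file from a byte snapshot, and still persists a terminal
run record (`failed` or `rolled_back`).

## Worked example

The bundled fixtures run the full pipeline offline: a seeded synthetic
genome stands in for a download, and a toy indexer (per-sequence lengths +
sha256 of the input) stands in for a real aligner's index builder.

```r
library(refasset)

root <- tempfile("demo-"); dir.create(root)
registry <- load_registry(fixture_registry_config(),
                          file.path(root, "registry"), file.path(root, "data"))
recipes  <- load_recipe_store(fixture_recipes_dir(), registry)
prov     <- provenance_store(file.path(root, "prov"))

fasta <- file.path(root, "genome_build.fa")
make_fasta(fasta, n_sequences = 2, length = 120, seed = 7)

run_recipe(registry, recipes, "fetch_local_fasta",
           list(dbkey = "hg19", name = "Human hg19", fasta = fasta),
           scratch_root = file.path(root, "scratch"), provenance_store = prov)
#> <run> 20260930T222733.315409-1088-0001: fetch_local_fasta 1.0.0 [succeeded]
#>   all_fasta: +1 entries

rec <- run_recipe(registry, recipes, "toy_index",
                  list(dbkey = "hg19", name = "Human hg19", fasta = fasta),
                  scratch_root = file.path(root, "scratch"),
                  provenance_store = prov)
#> <run> 20260930T222733.367263-1088-0002: toy_index 1.0.0 [succeeded]
#>   toy_indexes: +1 entries

query_entries(registry, "toy_indexes")
#>   value dbkey               name                                     path
#> 1  hg19  hg19 Human hg19 (small)  <data_root>/toy_indexes/hg19/genome_build.fa

verify_run(prov, registry, rec$run_id)$pass
#> [1] TRUE
```

The entry is live immediately, and the loc file on disk holds exactly its
rendered line:

```
hg19	hg19	Human hg19 (small)	<data_root>/toy_indexes/hg19/genome_build.fa
```

`(small)` is the toy indexer's `algorithm=auto` branch: at or below a
documented 50,000-base threshold it selects the small-genome algorithm.

A command-line front end mirrors this (`inst/scripts/refasset`, or
`refasset::dispatch()` directly):

```sh
refasset --config refasset.yml run toy_index \
    --param dbkey=hg19 --param fasta=genome_build.fa
refasset --config refasset.yml tables
refasset --config refasset.yml verify <run_id>
refasset --config refasset.yml replay <run_id> --data-root /elsewhere
```

Exit codes: 0 success, 1 domain error, 2 usage error; `--json` gives
machine-readable output for every subcommand.

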