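# Engine: staging, JSON handshake, invocation, installation, orchestration
# with all-or-nothing commits.

test_that("the parameter bundle round-trips through params.json with the server settings", {
  sb <- new_sandbox()
  r <- sb$recipes$toy_index
  norm <- validate_bindings(r, list(dbkey = "hg19", fasta = sb$fasta))
  staging <- new_staging_dir(sb$scratch)
  bundle <- build_param_bundle(r, norm, staging,
                               settings = list(data_root = sb$registry$data_root))
  on_disk <- jsonlite::fromJSON(file.path(staging, "params.json"),
                                simplifyVector = FALSE)
  expect_equal(on_disk$params$dbkey, "hg19")
  expect_equal(on_disk$params$algorithm, "auto")
  expect_equal(on_disk$staging_dir, bundle$staging_dir)
  expect_equal(on_disk$settings$data_root, sb$registry$data_root)

  # staging directories are unique and created empty
  s2 <- new_staging_dir(sb$scratch)
  expect_false(identical(staging, s2))
  expect_length(list.files(s2, all.files = TRUE, no.. = TRUE), 0)

  # a recipe with no parameters yields an empty params mapping
  reg_cfg <- list(t = data_table_spec("t", "value", "t.loc"))
  r0 <- parse_recipe(list(id = "p0", version = "1", name = "none",
                          builtin = "toy_multi",
                          outputs = list(list(table = "t"))), reg_cfg)
  b0 <- build_param_bundle(r0, validate_bindings(r0, list()), new_staging_dir(sb$scratch),
                           settings = list(data_root = sb$registry$data_root))
  expect_length(b0$params, 0)
})

test_that("builtin invocation writes entries.json and captures the log in-process", {
  sb <- new_sandbox()
  r <- sb$recipes$toy_index
  norm <- validate_bindings(r, list(dbkey = "hg19", fasta = sb$fasta))
  staging <- new_staging_dir(sb$scratch)
  bundle <- build_param_bundle(r, norm, staging,
                               settings = list(data_root = sb$registry$data_root))
  inv <- invoke_recipe(r, bundle)
  expect_equal(inv$status, 0L)
  expect_true(file.exists(file.path(staging, "entries.json")))
  expect_match(inv$log, "indexed genome_build.fa")
})

test_that("missing executables and nonzero exits are run failures with the stderr captured", {
  sb <- new_sandbox()
  reg_cfg <- list(t = data_table_spec("t", "value", "t.loc"))
  make_cmd_recipe <- function(command) {
    parse_recipe(list(id = "c1", version = "1", name = "cmd",
                      command = command,
                      outputs = list(list(table = "t"))), reg_cfg)
  }
  bundle_for <- function(r) {
    build_param_bundle(r, validate_bindings(r, list()), new_staging_dir(sb$scratch),
                       settings = list(data_root = sb$registry$data_root))
  }

  r_missing <- make_cmd_recipe(list("no_such_executable_xyz"))
  inv <- invoke_recipe(r_missing, bundle_for(r_missing))
  expect_equal(inv$status, 127L)
  expect_match(inv$log, "not found")

  r_fail <- make_cmd_recipe(list("Rscript", "-e",
                                 "message('boom'); quit(status = 1, save = 'no')"))
  inv2 <- invoke_recipe(r_fail, bundle_for(r_fail))
  expect_equal(inv2$status, 1L)
  expect_match(inv2$log, "boom")
})

test_that("entry bundles are validated against the recipe's declared tables", {
  sb <- new_sandbox()
  r <- sb$recipes$toy_index
  good <- '{"data_tables":{"toy_indexes":[{"value":"hg19","dbkey":"hg19","name":"Human hg19","path":"hg19.fa"}]}}'
  b <- parse_entry_bundle(good, r)
  expect_length(b$data_tables$toy_indexes, 1)
  expect_equal(b$data_tables$toy_indexes[[1]]$path, "hg19.fa")

  expect_length(parse_entry_bundle('{"data_tables":{}}', r)$data_tables, 0)
  expect_error(parse_entry_bundle('{"data_tables":{"bwa_indexes":[]}}', r),
               class = "refasset_validation_error")
  expect_error(parse_entry_bundle('{"nope": 1}', r), class = "refasset_format_error")
  expect_error(parse_entry_bundle('not json', r), class = "refasset_format_error")
  expect_error(parse_entry_bundle(
    '{"data_tables":{"toy_indexes":[{"value":3}]}}', r),
    class = "refasset_format_error")
})

test_that("installation manifests match an independent digest of the installed bytes", {
  sb <- new_sandbox()
  staging <- new_staging_dir(sb$scratch)
  file.copy(sb$fasta, file.path(staging, "hg19.fa"))
  writeLines("fake index", file.path(staging, "hg19.fa.idx"))
  writeLines("{}", file.path(staging, "params.json"))    # handshake: excluded
  writeLines("{}", file.path(staging, "entries.json"))

  asset <- file.path(sb$registry$data_root, "toy_indexes", "hg19")
  m <- install_files(staging, asset, "copy_dir")
  expect_setequal(m$relpath, c("hg19.fa", "hg19.fa.idx"))
  for (i in seq_len(nrow(m))) {
    expect_identical(m$sha256[i],
                     oracle_sha256(file.path(asset, m$relpath[i])))
  }

  # collision: a populated asset dir is never overwritten
  expect_error(install_files(staging, asset, "copy_dir"),
               class = "refasset_conflict_error")

  # policy none installs nothing; copy_file installs only the named files
  expect_equal(nrow(install_files(staging, file.path(sb$root, "x"), "none")), 0)
  m2 <- install_files(staging, file.path(sb$registry$data_root, "t2", "hg19"),
                      "copy_file", files = "hg19.fa")
  expect_equal(m2$relpath, "hg19.fa")
})

test_that("a full run commits entries that are immediately queryable and exactly persisted", {
  sb <- new_sandbox()
  r1 <- run_recipe(sb$registry, sb$recipes, "fetch_local_fasta",
                   list(dbkey = "hg19", name = "Human hg19", fasta = sb$fasta),
                   scratch_root = sb$scratch, provenance_store = sb$prov)
  expect_equal(r1$status, "succeeded")
  expect_equal(r1$entries_added$all_fasta, 1L)
  got <- query_entries(sb$registry, "all_fasta", list(dbkey = "hg19"))
  expect_equal(nrow(got), 1)
  expect_equal(got$path,
               file.path(sb$registry$data_root, "all_fasta", "hg19",
                         "genome_build.fa"))
  expect_true(file.exists(got$path))   # installed file backs the entry
})

test_that("one run can feed several tables and commits exactly what the bundle holds", {
  sb <- new_sandbox()
  rec <- run_recipe(sb$registry, sb$recipes, "toy_multi", list(prefix = "demo"),
                    scratch_root = sb$scratch, provenance_store = sb$prov)
  expect_equal(rec$status, "succeeded")
  # conservation: committed == non-duplicate entries in the bundle
  expect_equal(rec$entries_added, list(all_fasta = 2L, toy_indexes = 3L))
  expect_equal(nrow(query_entries(sb$registry, "all_fasta")), 2)
  expect_equal(nrow(query_entries(sb$registry, "toy_indexes")), 3)
})

test_that("rerunning with identical bindings is a succeeded no-op", {
  sb <- new_sandbox()
  bind <- list(dbkey = "hg19", fasta = sb$fasta)
  r1 <- run_recipe(sb$registry, sb$recipes, "toy_index", bind,
                   scratch_root = sb$scratch, provenance_store = sb$prov)
  expect_equal(r1$entries_added$toy_indexes, 1L)
  before <- loc_bytes_of(sb, "toy_indexes")
  r2 <- run_recipe(sb$registry, sb$recipes, "toy_index", bind,
                   scratch_root = sb$scratch, provenance_store = sb$prov)
  expect_equal(r2$status, "succeeded")
  expect_equal(r2$entries_added$toy_indexes, 0L)
  expect_identical(loc_bytes_of(sb, "toy_indexes"), before)
})

test_that("a failing recipe leaves the registry and data root untouched", {
  sb <- new_sandbox()
  empty_fa <- file.path(sb$root, "empty.fa"); file.create(empty_fa)
  rec <- run_recipe(sb$registry, sb$recipes, "toy_index",
                    list(dbkey = "bad", fasta = empty_fa),
                    scratch_root = sb$scratch, provenance_store = sb$prov)
  expect_equal(rec$status, "failed")
  expect_match(rec$log, "missing or empty")
  expect_equal(nrow(query_entries(sb$registry, "toy_indexes")), 0)
  expect_false(dir.exists(file.path(sb$registry$data_root, "toy_indexes")))
})

test_that("every injected failure point rolls back to the exact pre-run state", {
  for (point in c("after_invoke", "after_finalize", "after_install", "mid_append")) {
    sb <- new_sandbox()
    # non-trivial pre-run state so rollback restores real bytes
    run_recipe(sb$registry, sb$recipes, "fetch_local_fasta",
               list(dbkey = "pre", fasta = sb$fasta), scratch_root = sb$scratch)
    pre_loc <- lapply(c("all_fasta", "toy_indexes"), function(tn) loc_bytes_of(sb, tn))
    rec <- run_recipe(sb$registry, sb$recipes, "toy_index",
                      list(dbkey = "hg19", fasta = sb$fasta),
                      scratch_root = sb$scratch, provenance_store = sb$prov,
                      fail_at = point)
    expect_true(rec$status %in% c("failed", "rolled_back"), label = point)
    post_loc <- lapply(c("all_fasta", "toy_indexes"), function(tn) loc_bytes_of(sb, tn))
    expect_identical(post_loc, pre_loc, label = point)
    expect_false(dir.exists(file.path(sb$registry$data_root, "toy_indexes", "hg19")),
                 label = point)
    # memory still coherent with disk
    expect_equal(nrow(query_entries(sb$registry, "toy_indexes")), 0, label = point)
    # the terminal record was persisted
    h <- run_history(sb$prov)
    expect_equal(h$status[nrow(h)], rec$status, label = point)
  }
})

test_that("finalized paths from the default translation never escape the data root", {
  set.seed(303)
  sb <- new_sandbox()
  out <- sb$recipes$toy_index$outputs$toy_indexes
  spec <- sb$registry$tables$toy_indexes$spec
  ctx <- list(data_root = sb$registry$data_root, table_spec = spec)
  for (i in 1:50) {
    key <- paste0("k", paste(sample(c(letters, 0:9, ".", "-"), 6, TRUE), collapse = ""))
    raw <- list(value = key, dbkey = key,
                name = paste(sample(c(letters, " "), 8, TRUE), collapse = ""),
                path = paste0(paste(sample(letters, 5), collapse = ""), ".fa"))
    final <- finalize_entry(raw, out, ctx)
    expect_true(startsWith(final$path, paste0(sb$registry$data_root, "/")))
    expect_false(grepl("\\.\\.", final$path))
  }
})

test_that("subprocess and builtin recipes honor the same contract end to end", {
  sb <- new_sandbox()
  rdir <- tempfile(); dir.create(rdir)
  write_toy_index_script_recipe(rdir)
  file.copy(list.files(fixture_recipes_dir(), full.names = TRUE), rdir)
  store <- load_recipe_store(rdir, sb$registry)

  rb <- run_recipe(sb$registry, store, "toy_index",
                   list(dbkey = "hg19", fasta = sb$fasta), scratch_root = sb$scratch)
  rs <- run_recipe(sb$registry, store, "toy_index_script",
                   list(dbkey = "mm10", fasta = sb$fasta), scratch_root = sb$scratch)
  expect_equal(rs$status, "succeeded")

  eb <- query_entries(sb$registry, "toy_indexes", list(value = "hg19"))
  es <- query_entries(sb$registry, "toy_indexes", list(value = "mm10"))
  # identical derived content, different identity: compare installed digests
  mb <- rb$manifest[order(rb$manifest$relpath), ]
  ms <- rs$manifest[order(rs$manifest$relpath), ]
  expect_identical(mb$relpath, ms$relpath)
  expect_identical(mb$sha256, ms$sha256)
  expect_identical(sub("hg19", "mm10", eb$name), es$name)
})
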