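#!/usr/bin/env Rscript
# Standalone subprocess twin of the toy_index builtin action. Reads the
# engine's params.json (passed as the final command token), derives the toy
# index files in the staging directory, and writes entries.json back. It is
# deliberately self-contained -- it demonstrates that any executable honoring
# the JSON handshake can serve as a recipe command.

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: toy_index.R <params.json>")
bundle <- jsonlite::fromJSON(args[length(args)], simplifyVector = FALSE)
p <- bundle$params
staging <- bundle$staging_dir

fasta <- p$fasta
if (is.null(fasta) || !file.exists(fasta) || file.size(fasta) == 0) {
  stop("FASTA file missing or empty: ", fasta)
}
first <- readLines(fasta, n = 1, warn = FALSE)
if (length(first) == 0 || !startsWith(trimws(first), ">")) {
  stop("malformed FASTA (no '>' first record): ", fasta)
}
seqs <- Biostrings::readDNAStringSet(fasta)

algorithm <- if (is.null(p$algorithm)) "auto" else p$algorithm
if (algorithm == "auto") {
  # same documented fixture threshold as the builtin: 50000 total bases
  algorithm <- if (sum(Biostrings::width(seqs)) <= 50000) "small" else "large"
}

base <- basename(fasta)
staged <- file.path(staging, base)
stopifnot(file.copy(fasta, staged, overwrite = FALSE))
writeLines(paste(names(seqs), Biostrings::width(seqs), sep = "\t"),
           paste0(staged, ".sizes"))
writeLines(digest::digest(staged, algo = "sha256", file = TRUE),
           paste0(staged, ".sum"))

label <- if (!is.null(p$name) && nzchar(p$name)) p$name else p$dbkey
entry <- list(value = p$dbkey, dbkey = p$dbkey,
              name = sprintf("%s (%s)", label, algorithm), path = base)
writeLines(jsonlite::toJSON(list(data_tables = list(toy_indexes = list(entry))),
                            auto_unbox = TRUE, pretty = TRUE),
           file.path(staging, "entries.json"))
cat(sprintf("indexed %s (%d sequences, algorithm %s)\n",
            base, length(seqs), algorithm))
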