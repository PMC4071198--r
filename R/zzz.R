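.onLoad <- function(libname, pkgname) {
  register_builtin("fetch_local_fasta", builtin_fetch_local_fasta)
  register_builtin("toy_index", builtin_toy_index)
  register_builtin("toy_multi", builtin_toy_multi)
  invisible(NULL)
}
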