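# Shared fixtures, built once per test run. The reference collection is
# the package's synthetic generated one, downsized for speed.
ref22 <- synthetic_reference_db(n_per_leaf = 2)
ref44 <- synthetic_reference_db(n_per_leaf = 4)

# write a FASTA string to a temp file and return the path
tmp_fasta <- function(text) {
  f <- tempfile(fileext = ".fasta")
  writeLines(text, f)
  f
}
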