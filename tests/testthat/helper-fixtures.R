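# Small fixtures shared across test files; everything is built in code.

toy_ref <- function(n_mirnas = 3L) makeToyReference(seed = 1L,
                                                    n_mirnas = n_mirnas)

# one-hairpin reference matching the classic 30-nt worked example
mini_ref <- function() {
  ReferenceSet(c(hp1 = "AAAAUAGCUUAUCAGACUGAUGUUGAGGGG"),
               data.frame(mirna_id = "miR-x", hairpin_id = "hp1",
                          start = 4L, end = 26L, arm = "5p"))
}

# write a 4-line-per-record FASTQ from sequences (DNA alphabet)
write_fastq <- function(seqs, path) {
  recs <- paste0("@r", seq_along(seqs), "\n", seqs, "\n+\n",
                 strrep("I", nchar(seqs)))
  writeLines(recs, path)
  path
}
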