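# Shared fixtures built in code at test time.

tiny_genome <- function(seed = 7) {
  generate_synthetic_genome(
    synthetic_genome_spec(n_contigs = 2, contig_length_range = c(10000, 20000),
                          seed = seed)
  )
}

random_seqs <- function(n, len, gc = 0.5, seed = 1) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) dnalm:::random_dna(len, gc), character(1))
  })
}

# The worked 18-mer used throughout the tokenizer examples.
EXAMPLE_18MER <- "AAGTCCAGGATCAAGATT"
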