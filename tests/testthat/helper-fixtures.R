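# Small fixtures built in code.

toy_raw_table <- function() {
  v <- matrix(c(10, 0, 5,
                2,  4, 6), nrow = 2, byrow = TRUE,
              dimnames = list(c("petB", "flex_001"), c("S1", "S2", "S3")))
  abundance_table(v, "raw",
                  gene_lengths = c(petB = 1000, flex_001 = 500),
                  read_lengths = c(S1 = 100, S2 = 100, S3 = 100))
}

toy_genome <- function(id, fams, topology = "circular",
                       replicon = "chr") {
  genome_annotation(id, data.frame(
    replicon_id = replicon, rank = seq_along(fams), strand = "+",
    family_id = fams, stringsAsFactors = FALSE), topology)
}

# reduced-scale study shared by several test files; computed once
small_sim_config <- function() {
  cfg <- ecag_config()
  cfg$simulate$n_genomes <- 12L
  cfg$simulate$n_estus <- 4L
  cfg$simulate$core_size <- 30L
  cfg$simulate$flex_size <- 80L
  cfg$simulate$n_neutral <- 32L
  cfg$simulate$n_ecags <- 4L
  cfg$simulate$n_stations <- 30L
  cfg$modules$min_module_size <- 5L
  cfg
}

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
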