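# one small simulated study shared across test files (built once)
.shared <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.shared$sim)) {
    cfg <- sim_config(seed = 11, n_novel_loci = 60, n_reference_genes = 80,
                      n_te = 50, n_chromosomes = 2, chrom_length = 1.2e6)
    .shared$sim <- simulate_xloc_study(cfg)
  }
  .shared$sim
}

small_run <- function() {
  if (is.null(.shared$run)) .shared$run <- run_pipeline(small_sim())
  .shared$run
}
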