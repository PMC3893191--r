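# One full-scale synthetic study (default sim_config, fixed seed), computed
# lazily and shared by the end-to-end and parameter-recovery tests.
.demo_cache <- new.env(parent = emptyenv())

demo_run <- function() {
  if (is.null(.demo_cache$res))
    .demo_cache$res <- run_holobiont(sim_config(seed = 1))
  .demo_cache$res
}

small_config <- function(seed = 5, ...) {
  sim_config(seed = seed, n_host_contigs = 60L, n_symbiont_contigs = 60L,
             genome_len = 50000L, n_read_pairs = 400L, ...)
}
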