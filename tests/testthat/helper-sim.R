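# Shared small simulated studies, built lazily once per test session.

.sim_cache <- new.env(parent = emptyenv())

# moderate cohort used by several module tests (not the acceptance run)
small_study <- function() {
  if (is.null(.sim_cache$small)) {
    cfg <- simulation_config(seed = 42, n_samples = 150,
                             n_background_genes = 12)
    .sim_cache$small <- run_simulation_study(cfg)
  }
  .sim_cache$small
}

# tiny handmade library: 3 genes, 2 alleles each, known sequences
tiny_library <- function() {
  kir_allele_library(list(
    GA = c(a1 = "ACGTACGTAATTCCGGACGT", a2 = "ACGTACGTAATTCCGGACGA"),
    GB = c(b1 = "TTTTGGGGCCCCAAAAGGTT", b2 = "TTTTGGGGCCCCAAAAGGTA"),
    GC = c(c1 = "GATCGATCGATCGATCGATC", c2 = "GATCGATCGATCGATCGATG")
  ), source = "tiny")
}
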