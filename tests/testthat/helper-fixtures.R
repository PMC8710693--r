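# Small seeded fixtures built in code at test time.

tiny_dataset <- function(seed = 7, n_p = 30, n_m = 20, n_edges = 90) {
  syn <- generate_synthetic(synthetic_spec(
    n_pseudogenes = n_p, n_mirnas = n_m, n_tissues = 8,
    n_edges = n_edges, seed = seed
  ))
  pma_dataset(syn$expression, syn$sequences, syn$associations)
}

fast_config <- function(...) {
  args <- utils::modifyList(
    list(sae_dim = 8, sae_epochs = 30, gae_epochs = 120,
         snf_iterations = 10, cv_repeats = 1, random_seed = 7),
    list(...)
  )
  do.call(run_config, args)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
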