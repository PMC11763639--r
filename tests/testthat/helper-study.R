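# The 30-dataset simulation comparison study is shared by several acceptance
# checks; build it once.

acceptance_study <- function() {
  memo("acceptance_study", function() {
    suppressWarnings(simulation_study(n_datasets = 30L, seed = 101L))
  })
}
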