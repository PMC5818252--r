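## the reduced sweep is expensive (~10 min); computed once and shared by the
## acceptance blocks and the sweep-level property tests
.sweep_cache <- new.env(parent = emptyenv())

acceptance_fixture <- function() {
  if (is.null(.sweep_cache$sw)) {
    cc <- synthetic_connectome(seed = 1)
    .sweep_cache$cc <- cc
    .sweep_cache$sw <- run_sweep(cc, sweep_config("reduced"), master_seed = 1)
  }
  list(cc = .sweep_cache$cc, sw = .sweep_cache$sw)
}
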