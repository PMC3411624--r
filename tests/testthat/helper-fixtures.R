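# small seeded probe-level dataset reused across tests
toy_probe_data <- function(genes = 12, probes = 4, arrays = 4, seed = 101,
                           noise_sd = 0.25, spread = 1) {
  gen_probe_data(genes = genes, probes_per_gene = probes, arrays = arrays,
                 array_effect_spread = spread, noise_sd = noise_sd,
                 seed = seed)
}

# off-diagonal rows of a jed table
offdiag <- function(tab) tab[tab$array_i != tab$array_j, , drop = FALSE]
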