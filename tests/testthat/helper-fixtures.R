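# Shared fixtures: small designs and a cheap sampler budget for tests.

const_design <- function(n_cells, depth = 10000) {
  design_spec(rep(depth, n_cells))
}

fast_sampler <- sampler_config(chains = 2, draws = 500, warmup = 300)

# classify a matrix at constant depth with the test sampler budget
classify_fast <- function(counts, total_umi, groups = NULL, k_list = 0:3,
                          seed = 1L) {
  classify_genes(counts, total_umi = total_umi, groups = groups,
                 k_list = k_list, sampler = fast_sampler, seed = seed)
}
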