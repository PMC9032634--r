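# Small MCMC settings for module-level tests; acceptance tests use the
# full study scale.
quick_mcmc <- function(seed = 1L, n_iter = 2000L, n_warmup = 500L,
                       n_chains = 2L) {
  mcmc_config(n_iter = n_iter, n_warmup = n_warmup, n_chains = n_chains,
              seed = seed)
}

records_of <- function(conc, heg_id = "X", year = 2020L,
                       campaign = "current") {
  data.frame(heg_id = heg_id, year = year, concentration = conc,
             campaign = campaign, stringsAsFactors = FALSE)
}
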