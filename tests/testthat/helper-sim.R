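# One shared small synthetic study, built once per test run. 2 x 20,000
# reads on a 60 kb toy chromosome keeps the whole suite fast while leaving
# every category populated.
.sim_cache <- new.env(parent = emptyenv())

sim_fixture <- function() {
  if (!is.null(.sim_cache$fx)) return(.sim_cache$fx)
  params <- sim_params(seed = 42, n_reads_per_library = 20000,
                       genome_length = 60000, n_genes = 12)
  bundle <- generate_reference(params)
  libs <- list(calli = simulate_library(bundle, params, "calli"),
               protoplasts = simulate_library(bundle, params, "protoplasts"))
  cleaned <- lapply(libs, clean_reads, adapter3 = params$adapter3,
                    adapter5 = params$adapter5)
  profiles <- lapply(cleaned, `[[`, "profile")
  ledgers <- lapply(cleaned, `[[`, "ledger")
  annotations <- lapply(profiles, classify, refs = bundle)
  .sim_cache$fx <- list(params = params, bundle = bundle, libs = libs,
                        profiles = profiles, ledgers = ledgers,
                        annotations = annotations)
  .sim_cache$fx
}
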