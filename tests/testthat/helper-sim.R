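# Shared small simulation fixtures, built once per test run.

tiny_config <- function(seed = 42, ...) {
  sim_config(seed = seed, n_families = 120, n_snps = 50,
             missing_rate = 0, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 120 families, full trio bookkeeping, some missingness
small_sim <- function() {
  cached("small_sim", simulate_cohort(
    sim_config(seed = 42, n_families = 120, n_snps = 50,
               missing_rate = 0.1,
               sibship_mix = c(singleton = 0.4, fullsib = 0.3,
                               dz = 0.15, mz = 0.15)),
    detail = "full"))
}

# noiseless weights: analyst PGS equals the true score
noiseless_sim <- function() {
  cached("noiseless_sim", simulate_cohort(
    tiny_config(seed = 7, gwas_noise_sd = 0), detail = "standard"))
}

truth_of <- function(sim, cols, ids) {
  sim$truth$persons[match(ids, sim$truth$persons$person_id), cols]
}

write_weights_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

write_raw_file <- function(df, path = tempfile(fileext = ".raw")) {
  write.table(df, path, sep = " ", row.names = FALSE, quote = FALSE,
              na = "NA")
  path
}
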