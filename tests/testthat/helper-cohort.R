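# Shared default synthetic cohort (memoised: simulated once per test run).

.cohort_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.cohort_cache$sim)) {
    .cohort_cache$sim <- simulate_cohort(cohort_config(seed = 42L))
  }
  .cohort_cache$sim
}

default_imputed_matrix <- function() {
  if (is.null(.cohort_cache$X)) {
    sim <- default_sim()
    ok <- rowSums(!is.na(sim$matrix)) > 0
    mm <- sim$matrix[ok, rownames(published_loadings())]
    imp <- impute_pmm(mm, m = 1L, maxit = 5L, seed = 1L,
                      age = sim$cohort$exact_age[ok],
                      id = sim$cohort$participant_id[ok])
    .cohort_cache$X <- imp$imputations[[1]]
    .cohort_cache$ok <- ok
  }
  list(X = .cohort_cache$X, ok = .cohort_cache$ok, sim = default_sim())
}
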