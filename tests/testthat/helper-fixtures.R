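# Small shared fixtures, generated in code.

small_pd_cohort <- function(n_pd = 6, seed = 3, ...) {
  simulate_cohort(cohort_config(n_pd = n_pd, n_controls = 0, ...), seed = seed)
}

# a tiny converged-ish fit used by several tests; cached per session
fixture_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ch <- small_pd_cohort(n_pd = 5, seed = 11)
      cache <<- suppressWarnings(fit_hierarchical(
        prepare_model_data(ch), "full",
        fit_config(chains = 2, iter = 1200, warmup = 600, seed = 4,
                   loglik_max_draws = 300)
      ))
    }
    cache
  }
})
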