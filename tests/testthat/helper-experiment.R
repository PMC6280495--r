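# The benchmark experiment shared by the prediction-error ordering and
# non-convergence-rate checks: 50 replicates per censoring level at the
# study's simulation settings (n = n_test = 100, p = 100, stratified 5-fold
# CV). Computed once per test run and cached.
.experiment_cache <- new.env(parent = emptyenv())

shared_benchmark <- function() {
  if (is.null(.experiment_cache$res)) {
    .experiment_cache$res <- run_mse_experiment(
      reps = 50, censoring_levels = c(0.2, 0.5, 0.7),
      methods = c("golds", "gaussbj_gauss", "nonparbj", "lod"),
      n = 100, p = 100, K = 5, seed = 20260930)
  }
  .experiment_cache$res
}
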