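# The end-to-end phantom experiment is expensive, so it is run once per test
# session and shared by the acceptance blocks that inspect it.

experiment_fixture <- function() {
  cached("experiment40", {
    dir <- file.path(tempdir(), "accept_cohort")
    if (!dir.exists(dir)) generate_cohort(dir, n_train = 20, n_test = 20, seed = 1)
    run_experiment(dir, out_dir = NULL, seed = 1, verbose = FALSE)
  })
}
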