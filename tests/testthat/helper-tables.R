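# Shared helpers: toy table construction and cached simulation runs.

`%||%` <- function(x, y) if (is.null(x)) y else x

toy_table <- function(mz, rt, intensity, snr = 20, peak_shape = 0.95,
                      mode = "positive", instrument_class = "orbitrap",
                      id = sprintf("F%03d", seq_along(mz))) {
  feature_table(
    tibble::tibble(id = id, mz = mz, rt = rt, intensity = intensity,
                   snr = snr, peak_shape = peak_shape,
                   detection_count = 10L),
    mode = mode, instrument_class = instrument_class
  )
}

# cache expensive simulations/pipelines across test files
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}

small_sim <- function(seed = 11, n_compounds = 110, n_noise = 35) {
  cached(sprintf("sim_%d_%d_%d", seed, n_compounds, n_noise),
         simulate_lcms(generator_config(seed = seed,
                                        n_compounds = n_compounds,
                                        n_noise_features = n_noise)))
}

full_run <- function(seed) {
  cached(sprintf("full_%d", seed), {
    sim <- simulate_lcms(generator_config(seed = seed))
    res <- suppressMessages(suppressWarnings(run_pipeline(sim$table)))
    score <- score_recovery(res$annotation, res$links, sim$truth, sim$table)
    list(sim = sim, res = res, score = score)
  })
}

small_run <- function(seed = 11) {
  cached(sprintf("smallrun_%d", seed), {
    sim <- small_sim(seed)
    res <- suppressMessages(suppressWarnings(
      run_pipeline(sim$table, msms = sim$library, masses = sim$masses)))
    list(sim = sim, res = res)
  })
}
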