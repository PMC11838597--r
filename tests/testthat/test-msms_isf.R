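coel <- coelution_model(0.5, n_pairs = 10L)

make_library <- function(ids, keys, precursors, peaks) {
  out <- tibble::tibble(
    spectrum_id = ids, precursor_mz = precursors, mode = "positive",
    inchikey = keys, n_peaks = vapply(peaks, nrow, integer(1)),
    peaks = peaks)
  class(out) <- c("msms_library", class(out))
  attr(out, "mode") <- "positive"
  out
}

test_that("cosine of a spectrum with itself is 1", {
  pk <- tibble::tibble(mz = c(100, 150.2, 301.1),
                       rel_intensity = c(0.3, 1, 0.4))
  cs <- spectral_cosine(pk, pk)
  expect_equal(cs$cosine, 1)
  expect_equal(cs$n_matched, 3L)
})

test_that("disjoint spectra score 0", {
  a <- tibble::tibble(mz = c(100, 200), rel_intensity = c(1, 1))
  b <- tibble::tibble(mz = c(150, 250), rel_intensity = c(1, 1))
  expect_equal(spectral_cosine(a, b)$cosine, 0)
  expect_equal(spectral_cosine(a, b[0, ])$cosine, 0)
})

test_that("greedy matching pairs closest peaks first, one use each", {
  a <- tibble::tibble(mz = c(100, 100.005), rel_intensity = c(1, 0.5))
  b <- tibble::tibble(mz = 100.004, rel_intensity = 1)
  cs <- spectral_cosine(a, b, match_tol = 0.01)
  # the 0.001-away peak wins over the 0.004-away one; norms use all peaks
  expect_equal(cs$n_matched, 1L)
  expect_equal(cs$cosine, 0.5 / sqrt(1.25), tolerance = 1e-12)
})

test_that("deduplication keeps the most representative spectrum per key", {
  peaks <- list(
    tibble::tibble(mz = 100, rel_intensity = 1),
    tibble::tibble(mz = c(100, 200), rel_intensity = c(1, 0.5)),
    tibble::tibble(mz = 200, rel_intensity = 1),
    tibble::tibble(mz = 300, rel_intensity = 1)
  )
  lib <- make_library(c("s1", "s2", "s3", "z1"),
                      c("KEY1", "KEY1", "KEY1", "KEY2"),
                      c(400, 400, 400, 500), peaks)
  dd <- deduplicate_by_inchikey(lib)
  # s2 overlaps both siblings; singleton group keeps its only member
  expect_equal(dd$exemplars$spectrum_id, c("s2", "z1"))
  expect_equal(dd$cluster_sizes$n, c(3L, 1L))

  perm <- lib[c(3, 1, 4, 2), ]
  class(perm) <- class(lib)
  dd2 <- deduplicate_by_inchikey(perm)
  expect_equal(dd2$exemplars$spectrum_id, dd$exemplars$spectrum_id)
})

test_that("screening statistics equal the triple-loop oracle", {
  sim <- small_sim()
  dd <- deduplicate_by_inchikey(sim$library)
  got <- search_msms_isf(sim$table, dd$exemplars, coel)
  want <- oracle_msms_stats(sim$table, dd$exemplars, coel$rt_half_width)
  expect_equal(got$stats$n_precursor_matched, want$P)
  expect_equal(got$stats$n_with_fragment, want$Y)
  expect_equal(got$stats$n_fragments_matched, want$n_frag)
  expect_gt(want$P, 0)
})

test_that("Y is a subset of P which is a subset of all features", {
  sim <- small_sim()
  dd <- deduplicate_by_inchikey(sim$library)
  st <- search_msms_isf(sim$table, dd$exemplars, coel)$stats
  expect_lte(st$n_with_fragment, st$n_precursor_matched)
  expect_lte(st$n_precursor_matched, st$n_features_total)
  expect_equal(st$pct_Y_of_P,
               100 * st$n_with_fragment / st$n_precursor_matched)
})

test_that("matched fragments respect coelution and the intensity floor", {
  # precursor feature with one coeluting fragment and one far-RT decoy
  tb <- toy_table(mz = c(400.2000, 250.1000, 250.1000),
                  rt = c(10, 10.2, 20),
                  intensity = c(1e5, 1e4, 1e4),
                  id = c("prec", "frag_in", "frag_out"))
  pk <- tibble::tibble(mz = c(250.1, 120.0, 400.2),
                       rel_intensity = c(0.8, 0.05, 1))
  lib <- make_library("s1", "KEY1", 400.2, list(pk))
  out <- search_msms_isf(tb, lib, coel)
  expect_equal(out$stats$n_precursor_matched, 1L)
  expect_equal(out$stats$n_with_fragment, 1L)
  expect_equal(out$matches$feature_id, "prec")
  # only the coeluting fragment matched; the 0.05 peak is below the floor
  expect_equal(out$matches$matched_fragment_mzs, "250.10000")
})

test_that("mode mismatch errors and empty library warns", {
  tb <- toy_table(mz = 100, rt = 10, intensity = 1e4, mode = "negative")
  lib <- make_library("s1", "KEY1", 400.2,
                      list(tibble::tibble(mz = 100, rel_intensity = 1)))
  expect_error(search_msms_isf(tb, lib, coel), "mode")
  expect_warning(out <- search_msms_isf(tb, lib[0, ], coel), "empty")
  expect_equal(out$stats$n_precursor_matched, 0L)
  expect_equal(nrow(out$matches), 0L)
})
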