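test_that("feature_table validates rows and attributes", {
  df <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    mz = c(100, -5, 200, 300),
    rt = c(10, 20, -1, 30),
    intensity = c(1e4, 1e4, 1e4, 1e4),
    snr = c(10, 10, 10, 10),
    peak_shape = c(0.95, 0.95, 0.95, 1.2),
    detection_count = 3L
  )
  expect_message(tb <- feature_table(df, "positive", "orbitrap"),
                 "3 row\\(s\\) rejected")
  expect_equal(nrow(tb), 1L)
  expect_equal(attr(tb, "n_rejected"), 3L)
  expect_equal(attr(tb, "mode"), "positive")
  expect_equal(attr(tb, "instrument_class"), "orbitrap")
  expect_s3_class(tb, "feature_table")
})

test_that("feature_table rejects duplicates and missing columns", {
  df <- tibble::tibble(id = c("a", "a"), mz = 1:2, rt = 1:2, intensity = 1:2)
  expect_error(feature_table(df, "positive"), "duplicate feature id")
  expect_error(feature_table(df[, c("id", "mz")], "positive"),
               "missing required column")
})

test_that("read_feature_table resolves aliases and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    `id_number` = c("x1", "x2"), `m/z` = c(100.1, 200.2),
    rtime = c(30, 60), peak_area = c(1e5, 2e5),
    snr = c(8, 9), goodness_fitting = c(0.93, 0.97),
    detection_counts = c(12L, 20L)
  ), tmp)
  tb <- read_feature_table(tmp, mode = "negative", instrument_class = "tof")
  expect_equal(tb$id, c("x1", "x2"))
  expect_equal(tb$mz, c(100.1, 200.2))
  expect_equal(tb$peak_shape, c(0.93, 0.97))
  expect_equal(attr(tb, "mode"), "negative")

  out <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tb, out)
  back <- read_feature_table(out, mode = "negative", instrument_class = "tof")
  expect_equal(as.data.frame(back), as.data.frame(tb))
})

test_that("read_feature_table names unresolvable columns", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(id = "a", mz = 1, rt = 1), tmp)
  expect_error(read_feature_table(tmp, "positive"), "intensity")
})

msp_text <- function() {
  c("Name: spec_a",
    "PrecursorMZ: 301.1412",
    "InChIKey: AAAAAAAAAAAAAA-BBBBBBBBBB-N",
    "Num Peaks: 3",
    "100.05 50", "150.10 999", "301.14 400",
    "",
    "Name: no_key",
    "PrecursorMZ: 111.0",
    "Num Peaks: 1",
    "100.0 1.0",
    "",
    "Name: bad_count",
    "PrecursorMZ: 222.0",
    "InChIKey: CCCCCCCCCCCCCC-DDDDDDDDDD-N",
    "Num Peaks: 4",
    "100.0 1.0", "101.0 2.0",
    "",
    "Name: spec_b",
    "precursormz: 415.2210",
    "InChIKey: EEEEEEEEEEEEEE-FFFFFFFFFF-N",
    "Num Peaks: 2",
    "90.1 10;200.2 90")
}

test_that("read_msp_library parses records, skips, and normalizes", {
  tmp <- withr::local_tempfile(fileext = ".msp")
  writeLines(msp_text(), tmp)
  expect_warning(lib <- read_msp_library(tmp, "positive"), "Num Peaks")
  expect_equal(lib$spectrum_id, c("spec_a", "spec_b"))
  expect_equal(attr(lib, "n_skipped"), 2L)
  pk <- lib$peaks[[1]]
  expect_equal(max(pk$rel_intensity), 1)       # normalized
  expect_equal(pk$mz, sort(pk$mz))             # sorted
  expect_equal(pk$rel_intensity[pk$mz == 100.05], 50 / 999)
  expect_equal(lib$precursor_mz[2], 415.2210)  # case-insensitive field
  expect_equal(lib$peaks[[2]]$mz, c(90.1, 200.2))  # semicolon separation
})

test_that("msp round trip preserves peak counts and intensities", {
  tmp <- withr::local_tempfile(fileext = ".msp")
  writeLines(msp_text()[1:7], tmp)
  lib <- read_msp_library(tmp, "positive")
  out <- withr::local_tempfile(fileext = ".msp")
  write_msp_library(lib, out)
  back <- read_msp_library(out, "positive")
  expect_equal(back$n_peaks, lib$n_peaks)
  expect_equal(back$peaks[[1]], lib$peaks[[1]], tolerance = 1e-12)
  expect_equal(back$precursor_mz, lib$precursor_mz)
})

test_that("read_compound_mass_list rejects bad masses with line numbers", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    compound_id = c("c1", "c2", "c3"),
    name = c("one", "two", "three"),
    neutral_mass = c("180.0634", "-5", "abc")
  ), tmp)
  expect_message(ml <- read_compound_mass_list(tmp), "line 3, 4")
  expect_equal(nrow(ml), 1L)
  expect_equal(ml$neutral_mass, 180.0634)
})
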