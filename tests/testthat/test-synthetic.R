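test_that("the generator is a pure function of its seed", {
  a <- simulate_lcms(generator_config(seed = 7, n_compounds = 50,
                                      n_noise_features = 10))
  b <- simulate_lcms(generator_config(seed = 7, n_compounds = 50,
                                      n_noise_features = 10))
  expect_identical(as.data.frame(a$table), as.data.frame(b$table))
  expect_identical(a$truth$compounds, b$truth$compounds)
  expect_identical(a$library$peaks, b$library$peaks)
  c_ <- simulate_lcms(generator_config(seed = 8, n_compounds = 50,
                                       n_noise_features = 10))
  expect_false(identical(as.data.frame(a$table), as.data.frame(c_$table)))
})

test_that("planted isotopologue ratios follow the carbon count, capped", {
  sim <- small_sim()
  cmp <- sim$truth$compounds
  expect_true(all(cmp$m1_ratio < 0.5))
  expect_equal(cmp$m1_ratio, pmin(cmp$carbon_count * 0.0107, 0.499))
  expect_true(all(cmp$carbon_count >= 1))
  # carbon counts scale with mass
  expect_gt(cor(cmp$neutral_mass, cmp$carbon_count), 0.95)
})

test_that("intensities are long-tailed and censored at the limit", {
  sim <- small_sim()
  x <- sim$table$intensity
  expect_gt(mean(x), stats::median(x))  # right skew on the raw scale
  expect_true(all(x >= generator_config(seed = 1)$detection_limit))
})

test_that("weak ions are censored more often than strong ones", {
  sim <- small_sim()
  cmp <- sim$truth$compounds
  roles <- sim$truth$roles
  has_m1 <- cmp$compound_id %in%
    roles$compound_id[roles$role == "isotopologue" & roles$iso_step == 1L]
  strong <- cmp$base_intensity > stats::median(cmp$base_intensity)
  expect_gt(mean(has_m1[strong]), mean(has_m1[!strong]))
})

test_that("the planted fragment fraction is the exact feature share", {
  sim <- small_sim()
  expect_equal(sim$truth$planted_isf_fraction,
               100 * mean(sim$truth$roles$role == "ISF"))
  sim0 <- simulate_lcms(generator_config(seed = 5, n_compounds = 60,
                                         n_noise_features = 10, isf_prob = 0))
  expect_equal(sim0$truth$planted_isf_fraction, 0)
  expect_false(any(sim0$truth$roles$role == "ISF"))
})

test_that("planted fragments coelute with their parent unless shifted", {
  cfg <- generator_config(seed = 3, n_compounds = 200, n_noise_features = 0,
                          isf_prob = 1, false_coelution_prob = 0,
                          rt_jitter_sd = 0, rt_apex_sd = 0)
  sim <- simulate_lcms(cfg)
  roles <- sim$truth$roles
  isf <- roles[roles$role == "ISF", ]
  m0 <- roles[roles$role == "M0", ]
  both <- merge(isf, m0, by = "compound_id")
  rt <- sim$table$rt
  names(rt) <- sim$table$id
  expect_gt(nrow(both), 0)
  expect_true(all(abs(rt[both$feature_id.x] - rt[both$feature_id.y]) < 1e-9))
})

test_that("library copies share identifiers; compounds get distinct ones", {
  sim <- small_sim()
  lib <- sim$library
  cmp_of <- sub("_s\\d+$", "", lib$spectrum_id)
  per_cmp <- split(lib$inchikey, cmp_of)
  expect_true(all(vapply(per_cmp, function(k) length(unique(k)) == 1L,
                         logical(1))))
  copies <- lengths(per_cmp)
  expect_true(all(copies >= 2 & copies <= 4))
  one_key <- vapply(per_cmp, `[`, character(1), 1)
  expect_false(any(duplicated(one_key)))
  expect_true(all(grepl("^[A-Z]{14}-[A-Z]{10}-N$", lib$inchikey)))
})

test_that("the synthetic library round-trips through MSP", {
  sim <- small_sim()
  lib <- sim$library[1:10, ]
  class(lib) <- class(sim$library)
  tmp <- withr::local_tempfile(fileext = ".msp")
  write_msp_library(lib, tmp)
  back <- read_msp_library(tmp, "positive")
  expect_equal(back$spectrum_id, lib$spectrum_id)
  expect_equal(back$precursor_mz, lib$precursor_mz, tolerance = 1e-9)
  expect_equal(back$n_peaks, lib$n_peaks)
})

test_that("score_recovery validates its inputs", {
  sim <- small_sim()
  bare <- generate_ground_truth(generator_config(seed = 2, n_compounds = 10))
  run <- small_run()
  expect_error(score_recovery(run$res$annotation, run$res$links, bare,
                              sim$table), "roles")
})

test_that("score_recovery is exact on a hand-built annotation", {
  # two compounds, both eligible; only one anchored correctly
  truth <- list(
    roles = tibble::tibble(
      feature_id = c("a1", "a2", "b1", "b2"),
      compound_id = c("C1", "C1", "C2", "C2"),
      role = c("M0", "isotopologue", "M0", "isotopologue"),
      modification = NA_character_, iso_step = c(0L, 1L, 0L, 1L)),
    planted_isf_fraction = 0)
  class(truth) <- "ground_truth"
  tb <- toy_table(mz = c(100, 101.003, 200, 201.003), rt = rep(10, 4),
                  intensity = c(1000, 100, 1000, 100),
                  id = c("a1", "a2", "b1", "b2"))
  ann <- list(
    khipus = tibble::tibble(khipu_id = "kp_a1", anchor_id = "a1",
                            n_members = 2L),
    grid = tibble::tibble(khipu_id = "kp_a1", feature_id = c("a1", "a2")),
    roles = tibble::tibble(feature_id = c("a1", "a2", "b1", "b2"),
                           role = c("M0", "isotopologue", "singleton",
                                    "singleton")),
    singletons = c("b1", "b2"))
  links <- tibble::tibble(parent_khipu = character(), child = character(),
                          child_kind = character())
  sc <- score_recovery(ann, links, truth, tb)
  expect_equal(sc$recovery_rate, 0.5)
  expect_equal(sc$n_eligible, 2L)
  expect_equal(sc$isf_pct_estimated, 0)
})
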