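empty_links <- tibble::tibble(child = character(), child_kind = character())

fake_annotation <- function(roles, grid = NULL) {
  list(
    roles = roles,
    grid = grid %||% tibble::tibble(khipu_id = character(),
                                    feature_id = character()),
    khipus = tibble::tibble(khipu_id = character(), anchor_id = character()),
    singletons = roles$feature_id[roles$role == "singleton"]
  )
}

test_that("quartiles are equal-count and deterministic under ties", {
  tb <- toy_table(mz = 100 + 1:8, rt = rep(10, 8),
                  intensity = c(5, 5, 5, 5, 10, 10, 20, 20))
  q <- assign_intensity_quartiles(tb)
  expect_equal(as.integer(table(q$quartile)), rep(2L, 4))
  # ties broken by id: F001 < F002 so F001 lands in the lower quartile
  expect_equal(q$quartile[q$feature_id == "F001"], 1L)
  expect_equal(q$quartile[q$feature_id == "F004"], 2L)
  expect_equal(q$quartile[q$feature_id == "F008"], 4L)
  expect_equal(q, assign_intensity_quartiles(tb))
})

test_that("strata fractions sum to 1 and absent roles appear with n = 0", {
  tb <- toy_table(mz = 100 + 1:8, rt = rep(10, 8), intensity = 1:8)
  roles <- tibble::tibble(
    feature_id = tb$id,
    role = c("singleton", "singleton", "singleton", "M0",
             "M0", "isotopologue", "M0", "adduct_M0"))
  ann <- fake_annotation(roles)
  q <- assign_intensity_quartiles(tb)
  s <- stratified_annotation_summary(ann, empty_links, q, tb)
  expect_equal(nrow(s), 16L)  # 4 quartiles x 4 role levels, zeros kept
  sums <- tapply(s$fraction, s$quartile, sum)
  expect_equal(as.numeric(sums), rep(1, 4))
  expect_equal(s$n[s$quartile == 1 & s$role == "ISF"], 0L)
  # adduct merges into M0 by default
  expect_equal(s$n[s$quartile == 4 & s$role == "M0"], 2L)
  expect_length(attr(s, "quartile_bounds"), 3L)
})

test_that("ISF links reclassify singletons and whole khipus", {
  roles <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    role = c("M0", "isotopologue", "singleton", "singleton"))
  grid <- tibble::tibble(khipu_id = c("kp_a", "kp_a"),
                         feature_id = c("a", "b"))
  ann <- fake_annotation(roles, grid)
  links <- tibble::tibble(child = c("kp_a", "c"),
                          child_kind = c("khipu", "singleton"))
  fr <- final_roles(ann, links)
  expect_equal(fr$role, c("ISF", "ISF", "ISF", "singleton"))
  fr0 <- final_roles(ann, empty_links, merge_adducts = FALSE)
  expect_equal(fr0$role, roles$role)
})

test_that("coverage curve reproduces a hand-built step function", {
  n <- 100
  ids <- sprintf("F%03d", 1:n)
  tb <- toy_table(mz = 100 + 1:n, rt = rep(10, n), intensity = 1:n)
  roles <- tibble::tibble(feature_id = ids,
                          role = rep(c("singleton", "M0"), each = 50))
  ann <- fake_annotation(roles)
  cc <- quantile_coverage_curve(ann, empty_links, tb)
  expect_equal(nrow(cc), 99L)
  expect_equal(cc$coverage[cc$quantile <= 50], rep(0, 50))
  expect_equal(cc$coverage[cc$quantile > 50], rep(1, 49))
  ccum <- quantile_coverage_curve(ann, empty_links, tb, cumulative = TRUE)
  expect_equal(ccum$coverage[99], 49 / 99)
  expect_true(all(diff(ccum$coverage) >= 0))
})

test_that("t test wiring matches a direct computation", {
  ids <- c("m1", "m2", "m3", "s1", "s2", "s3")
  li <- c(6.0, 6.1, 6.2, 5.0, 5.2, 5.3)
  tb <- toy_table(mz = 100 + 1:6, rt = rep(10, 6), intensity = 10^li,
                  id = ids)
  roles <- tibble::tibble(feature_id = ids,
                          role = rep(c("M0", "singleton"), each = 3))
  ann <- fake_annotation(roles)
  quart <- tibble::tibble(feature_id = ids, quartile = 4L)
  got <- compare_m0_vs_singleton(ann, quart, tb)
  ref <- stats::t.test(li[1:3], li[4:6], var.equal = TRUE)
  expect_equal(got$mean_log10_diff, mean(li[1:3]) - mean(li[4:6]))
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  expect_equal(got$n_m0, 3L)
  expect_equal(got$n_singleton, 3L)
})

test_that("explained singletons leave the comparison group", {
  ids <- c("m1", "m2", "s1", "s2", "s3")
  tb <- toy_table(mz = 100 + 1:5, rt = rep(10, 5),
                  intensity = 10^c(6, 6.1, 5, 5.1, 5.2), id = ids)
  roles <- tibble::tibble(feature_id = ids,
                          role = c("M0", "M0", rep("singleton", 3)))
  ann <- fake_annotation(roles)
  quart <- tibble::tibble(feature_id = ids, quartile = 4L)
  links <- tibble::tibble(child = "s3", child_kind = "singleton")
  got <- compare_m0_vs_singleton(ann, quart, tb, links = links)
  expect_equal(got$n_singleton, 2L)
})

test_that("an undersized group warns and returns NA statistics", {
  ids <- c("m1", "m2", "s1")
  tb <- toy_table(mz = 100 + 1:3, rt = rep(10, 3),
                  intensity = 10^c(6, 6.1, 5), id = ids)
  roles <- tibble::tibble(feature_id = ids, role = c("M0", "M0", "singleton"))
  ann <- fake_annotation(roles)
  quart <- tibble::tibble(feature_id = ids, quartile = 4L)
  expect_warning(got <- compare_m0_vs_singleton(ann, quart, tb), "t test")
  expect_true(is.na(got$t))
  expect_equal(got$n_m0, 2L)
  expect_equal(got$n_singleton, 1L)
})

test_that("synthetic run: coverage rises with abundance", {
  run <- small_run()
  res <- run$res
  expect_equal(nrow(res$curve), 99L)
  top <- res$curve$coverage[res$curve$quantile > 89]
  bot <- res$curve$coverage[res$curve$quantile <= 10]
  expect_gt(mean(top, na.rm = TRUE), mean(bot, na.rm = TRUE))
  sums <- tapply(res$strata$fraction, res$strata$quartile, sum)
  expect_equal(as.numeric(sums), rep(1, 4), tolerance = 1e-12)
})
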