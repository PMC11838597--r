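coel <- coelution_model(0.5, n_pairs = 10L)

test_that("relation graph equals the brute-force scan on synthetic data", {
  sim <- small_sim()
  pats <- default_patterns("positive")
  got <- build_relation_graph(sim$table, pats, coel)
  want <- oracle_edges(sim$table, pats, coel$rt_half_width)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$from_id, want$from_id)
  expect_equal(got$to_id, want$to_id)
  expect_equal(got$label, want$label)
  expect_equal(got$mass_error, want$mass_error, tolerance = 1e-12)
})

test_that("relation graph gates on coelution and the step-1 ratio", {
  na <- default_patterns("positive")$delta[
    default_patterns("positive")$label == "Na/H"]
  tb <- toy_table(mz = c(300, 300 + na, 300 + na, 300 + C13_DELTA),
                  rt = c(10, 10.2, 12, 10.1),
                  intensity = c(1000, 400, 400, 600),
                  id = c("m0", "nain", "naout", "m1heavy"))
  g <- build_relation_graph(tb, default_patterns("positive"), coel)
  expect_true(any(g$from_id == "m0" & g$to_id == "nain" & g$label == "Na/H"))
  expect_false(any(g$to_id == "naout"))          # outside the RT window
  expect_false(any(g$to_id == "m1heavy" &
                     g$label == "13C/12C"))      # ratio 0.6 >= 0.5
})

test_that("textbook 3-feature chain resolves to one khipu grid", {
  na <- 21.981944
  tb <- toy_table(mz = c(300, 300 + C13_DELTA, 300 + na),
                  rt = c(10, 10, 10),
                  intensity = c(1000, 200, 300),
                  id = c("a", "b", "c"))
  ann <- preannotate(tb, coel)
  expect_equal(nrow(ann$khipus), 1L)
  expect_equal(ann$khipus$anchor_id, "a")
  g <- ann$grid
  expect_equal(g$isotope_index[match(c("a", "b", "c"), g$feature_id)],
               c(0L, 1L, 0L))
  expect_equal(g$modification[match(c("a", "b", "c"), g$feature_id)],
               c("anchor", "anchor", "Na/H"))
  roles <- ann$roles
  expect_equal(roles$role[match(c("a", "b", "c"), roles$feature_id)],
               c("M0", "isotopologue", "adduct_M0"))
})

test_that("cell conflicts keep the smaller mass error", {
  na <- 21.981944
  tb <- toy_table(mz = c(300, 300 + C13_DELTA, 300 + na + 0.0001,
                         300 + na + 0.0004),
                  rt = rep(10, 4), intensity = c(1000, 200, 300, 300),
                  id = c("a", "b", "c", "d"))
  ann <- preannotate(tb, coel)
  g <- ann$grid
  expect_true("c" %in% g$feature_id)
  expect_false("d" %in% g$feature_id)
  expect_true("d" %in% ann$singletons)
})

test_that("khipus and singletons partition the features", {
  sim <- small_sim()
  ann <- cached("ann_small", preannotate(sim$table, coel))
  ids <- sort(c(ann$grid$feature_id, ann$singletons))
  expect_equal(ids, sort(sim$table$id))
  expect_false(any(duplicated(ann$grid$feature_id)))
})

test_that("per-cell grid identity holds for every khipu", {
  sim <- small_sim()
  ann <- cached("ann_small", preannotate(sim$table, coel))
  for (kid in unique(ann$grid$khipu_id)) {
    sub <- ann$grid[ann$grid$khipu_id == kid, ]
    anchor_id <- ann$khipus$anchor_id[ann$khipus$khipu_id == kid]
    anchor_mz <- sub$mz[sub$feature_id == anchor_id]
    expect_length(anchor_mz, 1L)
    tol <- mass_tolerance(anchor_mz)
    expect_true(all(abs(sub$mass_error) <= tol + 1e-12))
  }
  # one feature per (isotope_index, modification) cell within a khipu
  cells <- paste(ann$grid$khipu_id, ann$grid$isotope_index,
                 ann$grid$modification)
  expect_false(any(duplicated(cells)))
})

test_that("annotation is invariant to input row order", {
  sim <- small_sim()
  ann1 <- cached("ann_small", preannotate(sim$table, coel))
  perm <- withr::with_seed(99, sample(nrow(sim$table)))
  tb2 <- sim$table[perm, ]
  class(tb2) <- class(sim$table)
  for (a in c("mode", "instrument_class")) attr(tb2, a) <- attr(sim$table, a)
  ann2 <- preannotate(tb2, coel)
  expect_equal(ann1$khipus, ann2$khipus)
  expect_equal(ann1$grid, ann2$grid)
  expect_equal(ann1$singletons, ann2$singletons)
})

test_that("small components equal the exhaustive resolver", {
  sim <- small_sim()
  pats <- default_patterns("positive")
  edges <- build_relation_graph(sim$table, pats, coel)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  comp <- igraph::components(g)
  comp_ids <- split(names(comp$membership), comp$membership)
  small <- comp_ids[lengths(comp_ids) <= 8 & lengths(comp_ids) >= 2]
  expect_gt(length(small), 10)
  n_checked <- 0L
  for (ids in small) {
    feats <- sim$table[match(sort(ids), sim$table$id), ]
    sub_edges <- edges[edges$from_id %in% ids & edges$to_id %in% ids, ]
    got <- resolve_components_to_khipus(feats, sub_edges, "positive")
    want <- oracle_resolve(feats, "positive")
    if (is.null(want)) {
      expect_equal(nrow(got$grid), 0L)
    } else {
      grid <- got$grid[order(got$grid$feature_id), ]
      expect_equal(grid$feature_id, want$feature_id)
      expect_equal(grid$isotope_index, want$isotope_index)
      expect_equal(grid$modification, want$modification)
    }
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, length(small))
})

test_that("invalid neutral masses are flagged", {
  # an anchor below the proton mass in negative-mode inversion cannot occur;
  # force the positive branch with a sub-proton anchor
  tb <- toy_table(mz = c(0.9, 0.9 + C13_DELTA), rt = c(10, 10),
                  intensity = c(1000, 100))
  expect_warning(ann <- preannotate(tb, coel), "invalid")
  expect_false(any(ann$khipus$valid))
})

test_that("match_neutral_masses applies a ppm gate on the record mass", {
  kh <- tibble::tibble(khipu_id = c("k1", "k2"), anchor_id = c("a", "b"),
                       neutral_mass = c(180.0634, 250.0))
  masses <- tibble::tibble(compound_id = c("c1", "c2"),
                           name = c("x", "y"),
                           neutral_mass = c(180.0634, 250.0 * (1 + 1e-5)))
  res <- match_neutral_masses(kh, masses)
  expect_true(res$matches$matched[1])
  expect_false(res$matches$matched[2])  # 10 ppm away
  expect_equal(res$matched_fraction, 0.5)
  expect_warning(res0 <- match_neutral_masses(kh, masses[0, ]), "empty")
  expect_equal(res0$matched_fraction, 0)
})

test_that("synthetic khipu neutral masses match the planted compound list", {
  run <- small_run()
  mm <- suppressWarnings(
    match_neutral_masses(run$res$annotation, run$sim$masses))
  expect_gt(mm$matched_fraction, 0.8)
})
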