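#' Build the mass-difference relation graph
#'
#' Scans all coeluting feature pairs for the supplied mass-difference patterns.
#' An undirected edge (a, b) with a the lower-m/z partner is emitted when
#' `|rt(a) - rt(b)|` is within the coelution half-width and
#' `|mz(b) - mz(a) - delta|` is within [mass_tolerance()] evaluated at the
#' lower m/z. Single-step isotope edges additionally require the higher-m/z
#' partner's intensity to be below half of the lower's, reflecting
#' natural-abundance 13C.
#'
#' @param table a [feature_table()].
#' @param patterns pattern tibble from [default_patterns()].
#' @param coelution a [coelution_model()].
#' @param ppm,abs_cap tolerance parameters, see [mass_tolerance()].
#' @return tibble of edges: `from_id`, `to_id` (higher m/z), `label`, `kind`,
#'   `isotope_step`, `delta`, `mass_error`.
#' @export
build_relation_graph <- function(table, patterns, coelution,
                                 ppm = 5e-6, abs_cap = 5e-4) {
  empty <- tibble::tibble(from_id = character(), to_id = character(),
                          label = character(), kind = character(),
                          isotope_step = integer(), delta = numeric(),
                          mass_error = numeric())
  if (nrow(table) < 2) return(empty)
  w <- coelution$rt_half_width
  edges <- purrr::pmap(patterns, function(label, delta, kind, isotope_step, ...) {
    cand <- match_mz_offset(table, table, delta, ppm = ppm, abs_cap = abs_cap)
    if (nrow(cand) == 0) return(NULL)
    keep <- cand$i != cand$j &
      abs(table$rt[cand$j] - table$rt[cand$i]) <= w
    if (kind == "isotope" && isotope_step == 1L) {
      keep <- keep & table$intensity[cand$j] < 0.5 * table$intensity[cand$i]
    }
    if (!any(keep)) return(NULL)
    tibble::tibble(
      from_id = table$id[cand$i[keep]],
      to_id = table$id[cand$j[keep]],
      label = label, kind = kind, isotope_step = isotope_step,
      delta = delta, mass_error = cand$mass_error[keep]
    )
  })
  out <- dplyr::bind_rows(edges)
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, .data$from_id, .data$to_id, .data$label)
}

# Resolve one connected component of the relation graph into khipu grids.
# Deterministic assembly:
#   1. contract isotope edges into branches; each branch's lowest-mz member is
#      its root (isotope index 0); indices follow cumulative isotope deltas
#      along edges, processed in order of increasing |mass_error|;
#   2. the lowest-mz root is the khipu anchor;
#   3. every other branch attaches through an adduct edge (in either
#      direction) to an already-attached branch, so the anchor can be reached
#      through a path; the net modification along the path must be one
#      pattern or cancel to "anchor" (no stacked modifications); the
#      smallest-|mass_error| eligible edge wins and re-bases the branch's
#      isotope indices through it; unattached branches are ejected whole;
#   4. every member must satisfy the grid identity
#      |mz - (mz(anchor) + iso_delta + adduct_delta)| <= tol(mz(anchor));
#   5. cell conflicts keep the smaller |mass_error| (ties by id); losers and
#      single-feature remainders are ejected for the secondary pass.
resolve_component <- function(feats, edges, mode, ppm = 5e-6, abs_cap = 5e-4) {
  n <- nrow(feats)
  if (n < 2 || nrow(edges) == 0) {
    return(list(grid = NULL, ejected = feats$id))
  }
  idx <- stats::setNames(seq_len(n), feats$id)
  iso <- edges[edges$kind == "isotope", , drop = FALSE]
  add <- edges[edges$kind == "adduct", , drop = FALSE]

  # branches over isotope edges (union-find)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(iso) > 0) {
    for (k in seq_len(nrow(iso))) {
      a <- find(idx[[iso$from_id[k]]]); b <- find(idx[[iso$to_id[k]]])
      if (a != b) parent[b] <- a
    }
  }
  branch <- vapply(seq_len(n), find, integer(1))
  # root = lowest mz in branch
  root_of <- tapply(seq_len(n), branch, function(m) m[which.min(feats$mz[m])])
  root_idx <- stats::setNames(as.integer(root_of), names(root_of))
  member_root <- root_idx[as.character(branch)]

  # cumulative isotope delta from branch root, edges in |mass_error| order
  cum <- rep(NA_real_, n)
  cum[root_idx] <- 0
  if (nrow(iso) > 0) {
    iso_ord <- iso[order(abs(iso$mass_error), iso$from_id, iso$to_id), ]
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (k in seq_len(nrow(iso_ord))) {
        a <- idx[[iso_ord$from_id[k]]]; b <- idx[[iso_ord$to_id[k]]]
        if (!is.na(cum[a]) && is.na(cum[b])) { cum[b] <- cum[a] + iso_ord$delta[k]; changed <- TRUE }
        else if (!is.na(cum[b]) && is.na(cum[a])) { cum[a] <- cum[b] - iso_ord$delta[k]; changed <- TRUE }
      }
    }
  }
  roots <- unname(root_idx)
  anchor <- roots[which.min(feats$mz[roots])]
  tol <- mass_tolerance(feats$mz[anchor], ppm = ppm, abs_cap = abs_cap)

  # modification per branch: anchor branch = "anchor"; other branches attach
  # through adduct edges to already-attached branches, iteratively, so a
  # branch may reach the anchor through a multi-edge path. The net
  # modification along the path must still be a single pattern (or cancel to
  # "anchor"); an attaching edge also re-bases the branch's isotope ladder
  # (the edge joins equal isotope levels, so the branch-internal cumulative
  # delta is shifted by cum_final(attached endpoint) - cum(branch endpoint)).
  branch_mod <- stats::setNames(rep(NA_character_, length(roots)), roots)
  branch_mod_delta <- stats::setNames(rep(NA_real_, length(roots)), roots)
  branch_shift <- stats::setNames(rep(NA_real_, length(roots)), roots)
  branch_mod[as.character(anchor)] <- "anchor"
  branch_mod_delta[as.character(anchor)] <- 0
  branch_shift[as.character(anchor)] <- 0
  if (nrow(add) > 0) {
    vocab <- default_patterns(mode)
    vocab <- vocab[vocab$kind == "adduct", , drop = FALSE]
    net_label <- function(net) {
      if (abs(net) < 1e-9) return(list(label = "anchor", delta = 0))
      hit <- which(abs(vocab$delta - net) < 1e-9)
      if (length(hit) == 0) return(NULL)
      list(label = vocab$label[hit[1]], delta = vocab$delta[hit[1]])
    }
    repeat {
      attached <- as.integer(names(branch_mod)[!is.na(branch_mod)])
      unattached <- setdiff(roots, attached)
      if (length(unattached) == 0) break
      att_members <- feats$id[member_root %in% attached]
      progressed <- FALSE
      for (r in unattached) {
        rids <- feats$id[member_root == r]
        fwd <- add[add$from_id %in% att_members & add$to_id %in% rids, ,
                   drop = FALSE]
        bwd <- add[add$from_id %in% rids & add$to_id %in% att_members, ,
                   drop = FALSE]
        if (nrow(fwd) > 0) { fwd$u <- fwd$from_id; fwd$v <- fwd$to_id
                             fwd$sign <- 1 }
        if (nrow(bwd) > 0) { bwd$u <- bwd$to_id; bwd$v <- bwd$from_id
                             bwd$sign <- -1 }
        hit <- rbind(fwd, bwd)
        if (nrow(hit) == 0) next
        hit <- hit[order(abs(hit$mass_error), hit$label, hit$from_id,
                         hit$to_id), , drop = FALSE]
        for (k in seq_len(nrow(hit))) {
          u <- idx[[hit$u[k]]]
          ub <- as.character(member_root[u])
          nl <- net_label(branch_mod_delta[[ub]] + hit$sign[k] * hit$delta[k])
          if (is.null(nl)) next
          v <- idx[[hit$v[k]]]
          branch_mod[as.character(r)] <- nl$label
          branch_mod_delta[as.character(r)] <- nl$delta
          branch_shift[as.character(r)] <- cum[u] + branch_shift[[ub]] - cum[v]
          progressed <- TRUE
          break
        }
      }
      if (!progressed) break
    }
  }

  cum_final <- cum + unname(branch_shift[as.character(member_root)])
  iso_index <- as.integer(round(cum_final / C13_DELTA))
  keep <- !is.na(branch_mod[as.character(member_root)]) & !is.na(cum_final) &
    iso_index >= 0L
  grid <- tibble::tibble(
    feature_id = feats$id,
    row = seq_len(n),
    isotope_index = iso_index,
    modification = unname(branch_mod[as.character(member_root)]),
    expected_mz = feats$mz[anchor] + cum_final +
      unname(branch_mod_delta[as.character(member_root)])
  )[keep, , drop = FALSE]
  grid$mass_error <- feats$mz[grid$row] - grid$expected_mz
  ok <- abs(grid$mass_error) <= tol
  grid <- grid[ok, , drop = FALSE]

  # one feature per cell: smallest |mass_error| wins, ties by id
  grid <- grid[order(grid$isotope_index, grid$modification,
                     abs(grid$mass_error), grid$feature_id), , drop = FALSE]
  dup <- duplicated(grid[, c("isotope_index", "modification")])
  grid <- grid[!dup, , drop = FALSE]

  if (!feats$id[anchor] %in% grid$feature_id || nrow(grid) < 2) {
    return(list(grid = NULL, ejected = feats$id))
  }
  anchor_id <- feats$id[anchor]
  res <- tibble::tibble(
    khipu_id = paste0("kp_", anchor_id),
    anchor_id = anchor_id,
    feature_id = grid$feature_id,
    isotope_index = grid$isotope_index,
    modification = grid$modification,
    mz = feats$mz[grid$row],
    rt = feats$rt[grid$row],
    intensity = feats$intensity[grid$row],
    mass_error = grid$mass_error
  )
  list(grid = res, ejected = setdiff(feats$id, res$feature_id))
}

#' Resolve relation-graph components into khipus
#'
#' Splits the relation graph into connected components and assembles each into
#' a khipu grid (see [preannotate()] for the full contract). Exposed mainly for
#' validation against exhaustive small-component resolution.
#'
#' @param table a [feature_table()] (only features appearing in `edges` and
#'   their neighbors are used).
#' @param edges edge tibble from [build_relation_graph()].
#' @param mode ionization polarity.
#' @param ppm,abs_cap tolerance parameters.
#' @return list with `grid` (long tibble of khipu cells) and `ejected`
#'   (character ids not placed in any khipu).
#' @export
resolve_components_to_khipus <- function(table, edges,
                                         mode = c("positive", "negative"),
                                         ppm = 5e-6, abs_cap = 5e-4) {
  mode <- match.arg(mode)
  if (nrow(edges) == 0) {
    return(list(grid = empty_grid(), ejected = table$id))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from_id", "to_id")], directed = FALSE,
    vertices = unique(c(edges$from_id, edges$to_id))
  )
  comp <- igraph::components(g)
  membership <- comp$membership[table$id]
  in_graph <- !is.na(membership)
  grids <- list()
  ejected <- table$id[!in_graph]
  # deterministic component order: by smallest member id
  comp_ids <- split(table$id[in_graph], membership[in_graph])
  comp_ids <- comp_ids[order(vapply(comp_ids, min, character(1)))]
  for (ids in comp_ids) {
    feats <- table[match(ids, table$id), , drop = FALSE]
    sub <- edges[edges$from_id %in% ids & edges$to_id %in% ids, , drop = FALSE]
    res <- resolve_component(feats, sub, mode, ppm = ppm, abs_cap = abs_cap)
    if (!is.null(res$grid)) grids[[length(grids) + 1L]] <- res$grid
    ejected <- c(ejected, res$ejected)
  }
  grid <- if (length(grids)) dplyr::bind_rows(grids) else empty_grid()
  list(grid = grid, ejected = sort(ejected))
}

empty_grid <- function() {
  tibble::tibble(khipu_id = character(), anchor_id = character(),
                 feature_id = character(), isotope_index = integer(),
                 modification = character(), mz = numeric(), rt = numeric(),
                 intensity = numeric(), mass_error = numeric())
}

#' Pre-annotate a feature table into khipus and singletons
#'
#' Runs the full grid assembly: builds the mass-difference relation graph over
#' coeluting features, splits it into connected components, and resolves each
#' component into a khipu — a grid of features indexed by (isotope index,
#' modification) anchored at the lowest-m/z molecular ion — with one secondary
#' pass over ejected features. Every feature ends up either in exactly one
#' khipu or as a singleton.
#'
#' Roles assigned: the anchor's isotope-0 cell is `M0`; isotope-0 cells of
#' other modifications are `adduct_M0`; isotope index >= 1 is `isotopologue`;
#' features in no khipu are `singleton`.
#'
#' @param table a [feature_table()].
#' @param coelution a [coelution_model()].
#' @param patterns pattern tibble; defaults to [default_patterns()] for the
#'   table's mode.
#' @param mode ionization polarity; defaults to the table attribute.
#' @param ppm,abs_cap tolerance parameters, see [mass_tolerance()].
#' @return An object of class `khipu_annotation`: list with `khipus` (one row
#'   per khipu: `khipu_id`, `anchor_id`, `neutral_mass`, `rt`, `n_members`),
#'   `grid` (long cell-level tibble), `singletons` (character ids), `roles`
#'   (tibble `feature_id`, `role`), `mode`, `n_features`.
#' @export
preannotate <- function(table, coelution, patterns = NULL, mode = NULL,
                        ppm = 5e-6, abs_cap = 5e-4) {
  mode <- ft_mode(table, mode)
  patterns <- patterns %||% default_patterns(mode)
  if (nrow(table) == 0) {
    return(new_khipu_annotation(empty_grid(), character(), mode, table))
  }
  edges <- build_relation_graph(table, patterns, coelution,
                                ppm = ppm, abs_cap = abs_cap)
  first <- resolve_components_to_khipus(table, edges, mode,
                                        ppm = ppm, abs_cap = abs_cap)
  grid <- first$grid
  leftovers <- first$ejected
  if (length(leftovers) >= 2) {
    sub <- table[match(leftovers, table$id), , drop = FALSE]
    sub_edges <- build_relation_graph(sub, patterns, coelution,
                                      ppm = ppm, abs_cap = abs_cap)
    second <- resolve_components_to_khipus(sub, sub_edges, mode,
                                           ppm = ppm, abs_cap = abs_cap)
    grid <- dplyr::bind_rows(grid, second$grid)
    leftovers <- second$ejected
  }
  new_khipu_annotation(grid, sort(leftovers), mode, table)
}

new_khipu_annotation <- function(grid, singletons, mode, table) {
  khipus <- grid |>
    dplyr::group_by(.data$khipu_id, .data$anchor_id) |>
    dplyr::summarise(
      rt = .data$rt[.data$feature_id == .data$anchor_id[1]][1],
      n_members = dplyr::n(), .groups = "drop"
    )
  if (nrow(khipus) > 0) {
    anchor_mz <- grid$mz[match(khipus$anchor_id, grid$feature_id)]
    khipus$neutral_mass <- neutral_mass_from_anchor(anchor_mz, mode)
    bad <- khipus$neutral_mass <= 0
    if (any(bad)) {
      warning(sum(bad), " khipu(s) flagged invalid (non-positive neutral mass)",
              call. = FALSE)
    }
    khipus$valid <- !bad
  } else {
    khipus$neutral_mass <- numeric()
    khipus$valid <- logical()
  }
  khipus <- dplyr::arrange(khipus, .data$khipu_id)
  roles <- tibble::tibble(feature_id = sort(table$id)) |>
    dplyr::left_join(
      grid |>
        dplyr::transmute(
          .data$feature_id,
          role = dplyr::case_when(
            .data$isotope_index >= 1L ~ "isotopologue",
            .data$modification == "anchor" ~ "M0",
            TRUE ~ "adduct_M0"
          )
        ),
      by = "feature_id"
    ) |>
    dplyr::mutate(role = dplyr::coalesce(.data$role, "singleton"))
  structure(
    list(khipus = khipus, grid = dplyr::arrange(grid, .data$khipu_id,
                                                .data$isotope_index,
                                                .data$modification),
         singletons = singletons, roles = roles, mode = mode,
         n_features = nrow(table)),
    class = "khipu_annotation"
  )
}

#' @export
print.khipu_annotation <- function(x, ...) {
  cat("Khipu pre-annotation (", x$mode, " mode)\n", sep = "")
  cat("  features:   ", x$n_features, "\n", sep = "")
  cat("  khipus:     ", nrow(x$khipus), " (", nrow(x$grid),
      " member features)\n", sep = "")
  cat("  singletons: ", length(x$singletons), "\n", sep = "")
  invisible(x)
}

#' @method tidy khipu_annotation
#' @export
tidy.khipu_annotation <- function(x, ...) {
  x$roles |>
    dplyr::left_join(
      x$grid[, c("feature_id", "khipu_id", "isotope_index", "modification")],
      by = "feature_id"
    )
}

#' @method glance khipu_annotation
#' @export
glance.khipu_annotation <- function(x, ...) {
  tibble::tibble(
    n_features = x$n_features,
    n_khipus = nrow(x$khipus),
    n_in_khipus = nrow(x$grid),
    n_singletons = length(x$singletons),
    mean_features_per_khipu = if (nrow(x$khipus)) mean(x$khipus$n_members) else NA_real_
  )
}

#' Match khipu neutral masses to a compound mass list
#'
#' A khipu matches when some record's neutral mass lies within `ppm` of the
#' khipu's inferred neutral mass (tolerance evaluated on the record mass).
#'
#' @param annotation a `khipu_annotation` (or its `khipus` tibble).
#' @param masses tibble from [read_compound_mass_list()].
#' @param ppm relative tolerance, ratio.
#' @return list with `matches` (tibble `khipu_id`, `neutral_mass`, `matched`,
#'   `compound_id`, `mass_error_ppm`) and `matched_fraction`.
#' @export
match_neutral_masses <- function(annotation, masses, ppm = 5e-6) {
  khipus <- if (inherits(annotation, "khipu_annotation")) annotation$khipus else annotation
  if (nrow(masses) == 0) {
    warning("empty compound mass list; matched fraction is 0", call. = FALSE)
    return(list(
      matches = tibble::tibble(khipu_id = khipus$khipu_id,
                               neutral_mass = khipus$neutral_mass,
                               matched = FALSE, compound_id = NA_character_,
                               mass_error_ppm = NA_real_),
      matched_fraction = 0
    ))
  }
  masses <- dplyr::arrange(masses, .data$neutral_mass)
  pos <- findInterval(khipus$neutral_mass, masses$neutral_mass)
  best <- purrr::map2(khipus$neutral_mass, pos, function(m, p) {
    cand <- unique(pmax(pmin(c(p, p + 1L), nrow(masses)), 1L))
    err <- abs(m - masses$neutral_mass[cand])
    k <- cand[which.min(err)]
    within <- abs(m - masses$neutral_mass[k]) <= ppm * masses$neutral_mass[k]
    list(matched = within,
         compound_id = if (within) masses$compound_id[k] else NA_character_,
         err_ppm = if (within) (m - masses$neutral_mass[k]) / masses$neutral_mass[k] * 1e6 else NA_real_)
  })
  matches <- tibble::tibble(
    khipu_id = khipus$khipu_id,
    neutral_mass = khipus$neutral_mass,
    matched = purrr::map_lgl(best, "matched"),
    compound_id = purrr::map_chr(best, "compound_id"),
    mass_error_ppm = purrr::map_dbl(best, "err_ppm")
  )
  list(matches = matches,
       matched_fraction = if (nrow(matches)) mean(matches$matched) else 0)
}
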