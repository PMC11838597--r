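#' Search for in-source fragment links between khipus
#'
#' A khipu C is linked as an in-source fragment of khipu P when their anchors
#' coelute (|rt shift| within the coelution half-width), the child anchor m/z
#' is strictly below the parent's, and the anchor m/z difference matches one of
#' the candidate deltas within [mass_tolerance()] at the parent anchor m/z.
#' Each child is linked to at most one parent: smallest |mass error|, ties
#' broken by larger parent anchor intensity, then by parent id.
#'
#' @param annotation a `khipu_annotation` from the conservative (no-ISF) run.
#' @param candidates candidate-delta tibble with `label` and `delta` columns
#'   (see [isf_candidate_deltas()]).
#' @param coelution a [coelution_model()].
#' @param table the [feature_table()] (for anchor intensities).
#' @param ppm,abs_cap tolerance parameters.
#' @return tibble of links: `parent_khipu`, `child`, `child_kind`
#'   (`"khipu"`), `delta_label`, `delta`, `mass_error`, `rt_shift`.
#' @export
search_khipu_isf <- function(annotation, candidates, coelution, table,
                             ppm = 5e-6, abs_cap = 5e-4) {
  kh <- annotation$khipus
  anchors <- annotation$grid[match(kh$anchor_id, annotation$grid$feature_id), ]
  parents <- tibble::tibble(khipu_id = kh$khipu_id, mz = anchors$mz,
                            rt = anchors$rt, intensity = anchors$intensity)
  isf_link_scan(parents, parents, candidates, coelution,
                child_kind = "khipu", ppm = ppm, abs_cap = abs_cap)
}

#' Search for singleton features explainable as in-source fragments
#'
#' As [search_khipu_isf()], with singleton features playing the child role
#' (their own m/z stands in for the anchor m/z).
#'
#' @inheritParams search_khipu_isf
#' @return tibble of links with `child_kind = "singleton"`.
#' @export
search_singleton_isf <- function(annotation, candidates, coelution, table,
                                 ppm = 5e-6, abs_cap = 5e-4) {
  kh <- annotation$khipus
  anchors <- annotation$grid[match(kh$anchor_id, annotation$grid$feature_id), ]
  parents <- tibble::tibble(khipu_id = kh$khipu_id, mz = anchors$mz,
                            rt = anchors$rt, intensity = anchors$intensity)
  s <- table[match(annotation$singletons, table$id), , drop = FALSE]
  children <- tibble::tibble(khipu_id = s$id, mz = s$mz, rt = s$rt,
                             intensity = s$intensity)
  isf_link_scan(parents, children, candidates, coelution,
                child_kind = "singleton", ppm = ppm, abs_cap = abs_cap)
}

isf_link_scan <- function(parents, children, candidates, coelution, child_kind,
                          ppm = 5e-6, abs_cap = 5e-4) {
  empty <- tibble::tibble(parent_khipu = character(), child = character(),
                          child_kind = character(), delta_label = character(),
                          delta = numeric(), mass_error = numeric(),
                          rt_shift = numeric())
  if (nrow(parents) == 0 || nrow(children) == 0 || nrow(candidates) == 0) {
    return(empty)
  }
  w <- coelution$rt_half_width
  links <- purrr::map2(candidates$label, candidates$delta, function(lab, d) {
    # child anchor = parent anchor - delta; tolerance at the parent anchor m/z
    tol <- mass_tolerance(parents$mz, ppm = ppm, abs_cap = abs_cap)
    ord <- order(children$mz)
    mz_sorted <- children$mz[ord]
    target <- parents$mz - d
    lo <- findInterval(target - tol, mz_sorted)
    hi <- findInterval(target + tol, mz_sorted)
    n_hits <- hi - lo
    if (sum(n_hits) == 0) return(NULL)
    p <- rep.int(seq_len(nrow(parents)), n_hits)
    c_ <- ord[sequence(n_hits, from = lo + 1L)]
    rt_shift <- children$rt[c_] - parents$rt[p]
    keep <- parents$khipu_id[p] != children$khipu_id[c_] &
      children$mz[c_] < parents$mz[p] & abs(rt_shift) <= w
    if (!any(keep)) return(NULL)
    tibble::tibble(
      parent_khipu = parents$khipu_id[p][keep],
      child = children$khipu_id[c_][keep],
      child_kind = child_kind,
      delta_label = lab, delta = d,
      mass_error = (parents$mz[p] - children$mz[c_] - d)[keep],
      rt_shift = rt_shift[keep],
      parent_intensity = parents$intensity[p][keep]
    )
  })
  out <- dplyr::bind_rows(links)
  if (nrow(out) == 0) return(empty)
  out |>
    dplyr::arrange(.data$child, abs(.data$mass_error),
                   dplyr::desc(.data$parent_intensity), .data$parent_khipu) |>
    dplyr::distinct(.data$child, .keep_all = TRUE) |>
    dplyr::select(-"parent_intensity") |>
    dplyr::arrange(.data$parent_khipu, .data$child)
}

#' Summarize the impact of in-source fragment links
#'
#' Counts khipus and singletons explained as fragments and converts to
#' percentages of all khipus and of all features. A khipu counted as explained
#' contributes each member feature once, regardless of how many links touch
#' it.
#'
#' @param links link tibble (rows from [search_khipu_isf()] and
#'   [search_singleton_isf()] combined).
#' @param annotation the `khipu_annotation`.
#' @param table the [feature_table()].
#' @return one-row tibble: `n_khipus_explained`, `n_singletons_explained`,
#'   `n_features_explained`, `pct_khipus`, `pct_features_of_all`.
#' @export
summarize_isf_impact <- function(links, annotation, table) {
  kh_children <- unique(links$child[links$child_kind == "khipu"])
  sg_children <- unique(links$child[links$child_kind == "singleton"])
  n_member_features <- sum(annotation$khipus$n_members[
    annotation$khipus$khipu_id %in% kh_children])
  n_feat <- n_member_features + length(sg_children)
  n_all <- nrow(table)
  n_kh <- nrow(annotation$khipus)
  tibble::tibble(
    n_khipus_explained = length(kh_children),
    n_singletons_explained = length(sg_children),
    n_features_explained = n_feat,
    pct_khipus = if (n_kh > 0) 100 * length(kh_children) / n_kh else 0,
    pct_features_of_all = if (n_all > 0) 100 * n_feat / n_all else 0
  )
}

#' Retention-time-shift profile of ISF links
#'
#' Histogram of child-minus-parent RT shifts with bins centered symmetrically
#' about zero; the mode bin is flagged. Shoulders away from zero indicate
#' matched pairs that are not truly coeluting.
#'
#' @param links link tibble.
#' @param bin bin width in seconds.
#' @return tibble `bin_center`, `count`, `is_mode`.
#' @export
rt_shift_profile <- function(links, bin = 1) {
  if (nrow(links) == 0) {
    return(tibble::tibble(bin_center = numeric(), count = integer(),
                          is_mode = logical()))
  }
  centers <- round(links$rt_shift / bin) * bin
  tab <- table(centers)
  out <- tibble::tibble(
    bin_center = as.numeric(names(tab)),
    count = as.integer(tab)
  )
  out$is_mode <- out$count == max(out$count)
  dplyr::arrange(out, .data$bin_center)
}
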