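#' Assign features to intensity quartiles
#'
#' Rank-based split into 4 equal-count bins (quartile 4 = highest intensity);
#' intensity ties are broken by feature id so the split is deterministic.
#'
#' @param table a [feature_table()].
#' @return tibble `feature_id`, `quartile` (integer 1..4).
#' @export
assign_intensity_quartiles <- function(table) {
  n <- nrow(table)
  if (n == 0) return(tibble::tibble(feature_id = character(), quartile = integer()))
  ord <- order(table$intensity, table$id)
  q <- integer(n)
  q[ord] <- as.integer(ceiling(seq_len(n) * 4 / n))
  tibble::tibble(feature_id = table$id, quartile = q)
}

# Final feature roles after ISF explanation: explained singletons and all
# members of ISF-explained khipus become "ISF"; optionally adduct_M0 merges
# into M0 (matching reports where adducts count with the molecular ion).
final_roles <- function(annotation, links, merge_adducts = TRUE) {
  roles <- annotation$roles
  if (nrow(links) > 0) {
    sg <- links$child[links$child_kind == "singleton"]
    kh <- links$child[links$child_kind == "khipu"]
    kh_members <- annotation$grid$feature_id[annotation$grid$khipu_id %in% kh]
    roles$role[roles$feature_id %in% c(sg, kh_members)] <- "ISF"
  }
  if (merge_adducts) {
    roles$role[roles$role == "adduct_M0"] <- "M0"
  }
  roles
}

#' Annotation composition per intensity quartile
#'
#' For each intensity quartile, the fraction of features in each final role
#' (`M0`, `isotopologue`, `ISF`, `singleton`). In-source-fragment explanation
#' is applied first: explained singletons and members of explained khipus are
#' reclassified as `ISF`. With `merge_adducts = TRUE` (default) the isotope-0
#' features of adduct branches count as `M0`.
#'
#' @param annotation a `khipu_annotation`.
#' @param links ISF link tibble (may be empty).
#' @param quartiles tibble from [assign_intensity_quartiles()].
#' @param table the [feature_table()].
#' @param merge_adducts merge `adduct_M0` into `M0`.
#' @return tibble with one row per quartile x role: `quartile`, `role`, `n`,
#'   `fraction`; quartile bounds are in the `quartile_bounds` attribute.
#' @export
stratified_annotation_summary <- function(annotation, links, quartiles, table,
                                          merge_adducts = TRUE) {
  roles <- final_roles(annotation, links, merge_adducts = merge_adducts)
  role_levels <- c("M0", if (!merge_adducts) "adduct_M0", "isotopologue",
                   "ISF", "singleton")
  df <- dplyr::inner_join(roles, quartiles, by = "feature_id")
  out <- df |>
    dplyr::mutate(role = factor(.data$role, levels = role_levels)) |>
    dplyr::count(.data$quartile, .data$role, .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$quartile) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(role = as.character(.data$role))
  bounds <- stats::quantile(table$intensity, probs = c(0.25, 0.5, 0.75),
                            names = FALSE, type = 7)
  attr(out, "quartile_bounds") <- bounds
  out
}

#' Pre-annotation coverage across abundance quantiles
#'
#' Splits features by intensity rank into 99 one-percent-wide slices
#' (quantile q covers ranks in ((q-1)/100, q/100]) and reports, per slice, the
#' fraction of features that are pre-annotated, i.e. have any non-singleton
#' final role. With `cumulative = TRUE`, coverage at q is computed over all
#' features at or below that quantile instead.
#'
#' @param annotation a `khipu_annotation`.
#' @param links ISF link tibble (may be empty).
#' @param table the [feature_table()].
#' @param cumulative use cumulative slices.
#' @return tibble `quantile` (1..99), `n`, `coverage`; slices with no features
#'   carry `NA` coverage.
#' @export
quantile_coverage_curve <- function(annotation, links, table,
                                    cumulative = FALSE) {
  roles <- final_roles(annotation, links)
  n <- nrow(table)
  ord <- order(table$intensity, table$id)
  annotated <- roles$role[match(table$id, roles$feature_id)] != "singleton"
  annotated <- annotated[ord]
  slice_of <- ceiling(seq_len(n) * 100 / n) # 1..100
  purrr::map_dfr(1:99, function(q) {
    in_slice <- if (cumulative) slice_of <= q else slice_of == q
    n_q <- sum(in_slice)
    tibble::tibble(
      quantile = q, n = n_q,
      coverage = if (n_q > 0) mean(annotated[in_slice]) else NA_real_
    )
  })
}

#' Compare M0 and singleton intensities in the top quartile
#'
#' Two-sample Student t test (equal variances) on log10 intensities of M0
#' features versus singleton features within the highest intensity quartile.
#'
#' @param annotation a `khipu_annotation`.
#' @param quartiles tibble from [assign_intensity_quartiles()].
#' @param table the [feature_table()].
#' @param links optional ISF link tibble; explained features are removed from
#'   the singleton group first.
#' @return one-row tibble: `mean_log10_diff` (M0 minus singleton), `t`, `p`,
#'   `n_m0`, `n_singleton`. All-`NA` (with a warning) when either group is
#'   empty.
#' @export
compare_m0_vs_singleton <- function(annotation, quartiles, table,
                                    links = NULL) {
  roles <- final_roles(annotation,
                       links %||% tibble::tibble(child = character(),
                                                 child_kind = character()))
  top <- quartiles$feature_id[quartiles$quartile == 4L]
  df <- tibble::tibble(
    feature_id = top,
    role = roles$role[match(top, roles$feature_id)],
    log10_intensity = log10(table$intensity[match(top, table$id)])
  )
  m0 <- df$log10_intensity[df$role == "M0"]
  sg <- df$log10_intensity[df$role == "singleton"]
  if (length(m0) < 2 || length(sg) < 2) {
    warning("top quartile lacks enough M0 or singleton features for a t test",
            call. = FALSE)
    return(tibble::tibble(mean_log10_diff = NA_real_, t = NA_real_,
                          p = NA_real_, n_m0 = length(m0),
                          n_singleton = length(sg)))
  }
  tt <- stats::t.test(m0, sg, var.equal = TRUE)
  tibble::tibble(
    mean_log10_diff = mean(m0) - mean(sg),
    t = unname(tt$statistic),
    p = tt$p.value,
    n_m0 = length(m0),
    n_singleton = length(sg)
  )
}
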