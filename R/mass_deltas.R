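#' Histogram of m/z differences between khipu anchors and coeluting features
#'
#' For each khipu molecular ion (anchor), the absolute m/z differences to all
#' other features eluting within the coelution half-width are accumulated in a
#' fixed-width histogram. Members of the same khipu are excluded by default so
#' known isotope/adduct relations do not dominate the delta counts twice.
#'
#' @param annotation a `khipu_annotation` from [preannotate()].
#' @param table the [feature_table()] the annotation was computed on.
#' @param coelution a [coelution_model()].
#' @param bin_size histogram bin width in Da; defaults to 0.0001 for orbitrap
#'   and 0.0005 for tof tables.
#' @param max_delta largest difference recorded, Da.
#' @param exclude_same_khipu drop differences between an anchor and its own
#'   khipu members.
#' @return An object of class `delta_histogram`: tibble of nonzero bins
#'   (`bin`, `bin_center`, `count`) with attributes `bin_size`, `max_delta`,
#'   `n_pairs`.
#' @export
compute_delta_histogram <- function(annotation, table, coelution,
                                    bin_size = NULL, max_delta = 200,
                                    exclude_same_khipu = TRUE) {
  bin_size <- bin_size %||%
    switch(ft_instrument(table), orbitrap = 1e-4, tof = 5e-4)
  anchors <- annotation$khipus$anchor_id
  empty <- structure(
    tibble::tibble(bin = integer(), bin_center = numeric(), count = integer()),
    bin_size = bin_size, max_delta = max_delta, n_pairs = 0L,
    class = c("delta_histogram", class(tibble::tibble()))
  )
  if (length(anchors) == 0 || nrow(table) == 0) return(empty)
  ord <- order(table$rt)
  rt_sorted <- table$rt[ord]
  a_idx <- match(anchors, table$id)
  w <- coelution$rt_half_width
  lo <- findInterval(table$rt[a_idx] - w, rt_sorted)
  hi <- findInterval(table$rt[a_idx] + w, rt_sorted)
  n_hits <- hi - lo
  if (sum(n_hits) == 0) return(empty)
  ai <- rep.int(a_idx, n_hits)
  fj <- ord[sequence(n_hits, from = lo + 1L)]
  keep <- ai != fj
  if (exclude_same_khipu) {
    kp_of <- stats::setNames(rep(NA_character_, nrow(table)), table$id)
    kp_of[annotation$grid$feature_id] <- annotation$grid$khipu_id
    keep <- keep & (is.na(kp_of[table$id[fj]]) |
                      kp_of[table$id[ai]] != kp_of[table$id[fj]])
  }
  deltas <- abs(table$mz[ai[keep]] - table$mz[fj[keep]])
  deltas <- deltas[deltas <= max_delta]
  bins <- as.integer(floor(deltas / bin_size))
  tab <- table(bins)
  out <- tibble::tibble(
    bin = as.integer(names(tab)),
    count = as.integer(tab)
  )
  out$bin_center <- (out$bin + 0.5) * bin_size
  out <- out[, c("bin", "bin_center", "count")]
  structure(out, bin_size = bin_size, max_delta = max_delta,
            n_pairs = length(deltas),
            class = c("delta_histogram", class(tibble::tibble())))
}

#' Smooth the delta histogram and pick candidate peaks
#'
#' Applies a centered moving average, locates local maxima of the smoothed
#' series, keeps those whose raw apex count (maximum raw count within
#' `centroid_halfwidth` bins of the apex) reaches `threshold` with pairwise
#' bin separation of at least `min_separation`, and returns the `top_n`
#' highest. Each
#' selected peak's delta is the raw-count-weighted centroid of the bins within
#' `centroid_halfwidth` of the apex.
#'
#' @param hist a `delta_histogram`.
#' @param threshold minimum smoothed peak height (counts); defaults to 100 for
#'   orbitrap-sized bins (0.0001 Da) and 20 for tof-sized bins.
#' @param top_n number of candidates to keep.
#' @param smooth_window moving-average width in bins.
#' @param min_separation minimum apex separation in bins.
#' @param centroid_halfwidth bins on either side of the apex used for the
#'   centroid.
#' @return tibble of `candidate_delta`s: `rank`, `delta` (Da), `count`
#'   (smoothed apex height), `bin`.
#' @export
smooth_and_pick_peaks <- function(hist, threshold = NULL, top_n = 20,
                                  smooth_window = 5, min_separation = 10,
                                  centroid_halfwidth = 2) {
  bin_size <- attr(hist, "bin_size")
  threshold <- threshold %||% (if (isTRUE(all.equal(bin_size, 5e-4))) 20 else 100)
  empty <- tibble::tibble(rank = integer(), delta = numeric(),
                          count = numeric(), bin = integer())
  if (nrow(hist) == 0) return(empty)
  n_bins <- max(hist$bin) + smooth_window + 1L
  dense <- numeric(n_bins)
  dense[hist$bin + 1L] <- hist$count
  sm <- as.numeric(stats::filter(dense, rep(1 / smooth_window, smooth_window),
                                 sides = 2))
  sm[is.na(sm)] <- 0
  # strict-rise/fall apexes (plateaus take their first bin)
  d <- diff(sm)
  apex <- which(c(d, -1) <= 0 & c(1, d) > 0)
  # peak height is the raw apex count near the smoothed maximum: the moving
  # average locates peaks but divides narrow spikes by the window width, so
  # thresholding the smoothed series would silently rescale the count
  # threshold for sharp peaks
  raw_height <- vapply(apex, function(a) {
    span <- seq.int(max(1L, a - centroid_halfwidth),
                    min(n_bins, a + centroid_halfwidth))
    max(dense[span])
  }, numeric(1))
  keep <- raw_height >= threshold
  apex <- apex[keep]
  raw_height <- raw_height[keep]
  if (length(apex) == 0) {
    warning("no histogram peak reaches the threshold (", threshold, ")",
            call. = FALSE)
    return(empty)
  }
  ord <- order(-raw_height, apex)
  apex <- apex[ord]
  raw_height <- raw_height[ord]
  chosen <- integer()
  chosen_h <- numeric()
  for (k in seq_along(apex)) {
    a <- apex[k]
    if (all(abs(chosen - a) >= min_separation)) {
      chosen <- c(chosen, a)
      chosen_h <- c(chosen_h, raw_height[k])
    }
    if (length(chosen) >= top_n) break
  }
  centroid <- vapply(chosen, function(a) {
    span <- seq.int(max(1L, a - centroid_halfwidth),
                    min(n_bins, a + centroid_halfwidth))
    wts <- dense[span]
    if (sum(wts) == 0) return((a - 0.5) * bin_size)
    sum((span - 0.5) * bin_size * wts) / sum(wts)
  }, numeric(1))
  tibble::tibble(
    rank = seq_along(chosen),
    delta = centroid,
    count = chosen_h,
    bin = chosen - 1L
  )
}

#' Nominate in-source fragment candidate deltas
#'
#' Drops candidate deltas attributable to known isotope/adduct patterns or to
#' any pairwise sum or absolute difference of two known pattern deltas, within
#' a fixed tolerance ([mass_tolerance()] at m/z 500, i.e. the 0.0005 Da cap).
#'
#' @param candidates tibble from [smooth_and_pick_peaks()].
#' @param patterns known patterns, e.g. [default_patterns()].
#' @param tol matching tolerance in Da.
#' @return the candidate tibble with a logical `excluded_as_known` column;
#'   surviving rows keep their original rank order.
#' @export
nominate_isf_candidates <- function(candidates, patterns,
                                    tol = mass_tolerance(500)) {
  known <- known_delta_closure(patterns$delta)
  excluded <- vapply(candidates$delta,
                     function(d) any(abs(d - known) <= tol), logical(1))
  out <- candidates
  out$excluded_as_known <- excluded
  out
}

known_delta_closure <- function(deltas) {
  pairs <- expand.grid(a = deltas, b = deltas)
  out <- unique(c(deltas, pairs$a + pairs$b, abs(pairs$a - pairs$b)))
  sort(out[out > 0])
}

#' Assemble the working ISF candidate-delta list
#'
#' Combines data-driven nominations (histogram peaks not explained by known
#' isotope/adduct patterns) with the curated neutral-loss list. Data-driven
#' candidates within tolerance of a curated loss are reported once, under the
#' curated label.
#'
#' @param nominated tibble from [nominate_isf_candidates()] (may be empty).
#' @param include_curated also include [curated_neutral_losses()].
#' @param tol tolerance used to merge duplicates, Da.
#' @return tibble with `label`, `delta`, `source`
#'   (`"data"`, `"curated"`).
#' @export
isf_candidate_deltas <- function(nominated = NULL, include_curated = TRUE,
                                 tol = mass_tolerance(500)) {
  data_part <- NULL
  if (!is.null(nominated) && nrow(nominated) > 0) {
    surv <- nominated[!nominated$excluded_as_known, , drop = FALSE]
    if (nrow(surv) > 0) {
      data_part <- tibble::tibble(
        label = sprintf("delta_%.4f", surv$delta),
        delta = surv$delta, source = "data"
      )
    }
  }
  cur <- NULL
  if (include_curated) {
    cur <- curated_neutral_losses()
    cur$source <- "curated"
    if (!is.null(data_part)) {
      dup <- vapply(data_part$delta,
                    function(d) any(abs(d - cur$delta) <= tol), logical(1))
      data_part <- data_part[!dup, , drop = FALSE]
    }
  }
  out <- dplyr::bind_rows(cur, data_part)
  dplyr::arrange(out, .data$delta)
}
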