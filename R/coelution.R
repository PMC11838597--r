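#' @importFrom rlang %||% .data
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Filter to good features
#'
#' Keeps features with signal-to-noise ratio strictly above `snr_min` and peak
#' shape strictly above `shape_min`. The defaults reproduce the conventional
#' "good feature" definition (SNR > 5, gaussian peak shape > 0.9).
#'
#' @param table a [feature_table()].
#' @param snr_min SNR threshold (strict inequality).
#' @param shape_min peak-shape threshold (strict inequality).
#' @return the filtered feature table, original row order kept.
#' @export
filter_good_features <- function(table, snr_min = 5, shape_min = 0.9) {
  stopifnot(snr_min >= 0, shape_min >= 0)
  keep <- !is.na(table$snr) & !is.na(table$peak_shape) &
    table$snr > snr_min & table$peak_shape > shape_min
  out <- table[keep, , drop = FALSE]
  for (a in c("mode", "instrument_class")) attr(out, a) <- attr(table, a)
  class(out) <- class(table)
  out
}

#' Find 13C/12C isotopic pairs
#'
#' Pairs features (a, b) where b sits one 13C substitution above a
#' (`mz(b) - mz(a)` within tolerance of 1.003355), elutes within
#' `seed_rt_tolerance` seconds, and has intensity strictly below
#' `max_ratio` times that of a. Each 13C feature is matched to at most one
#' monoisotopic partner: smallest absolute mass error, ties broken by smaller
#' RT difference, then by id.
#'
#' @param table a [feature_table()].
#' @param delta expected isotopic mass difference in Da.
#' @param seed_rt_tolerance RT tolerance in seconds used for this initial
#'   pairing, before a coelution window has been estimated.
#' @param max_ratio maximum 13C/12C intensity ratio (strict).
#' @param ppm,abs_cap passed to [mass_tolerance()].
#' @return tibble with columns `m0_id`, `m13c_id`, `mass_error` (Da),
#'   `rt_diff` (s), `intensity_ratio`.
#' @export
find_isotope_pairs <- function(table, delta = C13_DELTA, seed_rt_tolerance = 2,
                               max_ratio = 0.5, ppm = 5e-6, abs_cap = 5e-4) {
  if (nrow(table) == 0) {
    return(tibble::tibble(m0_id = character(), m13c_id = character(),
                          mass_error = numeric(), rt_diff = numeric(),
                          intensity_ratio = numeric()))
  }
  zero_int <- table$intensity == 0
  if (any(zero_int)) {
    message(sum(zero_int), " zero-intensity feature(s) skipped as possible M0")
  }
  cand <- match_mz_offset(table, table, delta, ppm = ppm, abs_cap = abs_cap)
  if (nrow(cand) == 0) {
    return(tibble::tibble(m0_id = character(), m13c_id = character(),
                          mass_error = numeric(), rt_diff = numeric(),
                          intensity_ratio = numeric()))
  }
  a <- cand$i # candidate M0
  b <- cand$j # candidate 13C
  rt_diff <- table$rt[b] - table$rt[a]
  keep <- a != b & abs(rt_diff) <= seed_rt_tolerance & table$intensity[a] > 0 &
    table$intensity[b] / pmax(table$intensity[a], .Machine$double.xmin) < max_ratio
  pairs <- tibble::tibble(
    m0_id = table$id[a][keep],
    m13c_id = table$id[b][keep],
    mass_error = cand$mass_error[keep],
    rt_diff = rt_diff[keep],
    intensity_ratio = (table$intensity[b] / table$intensity[a])[keep]
  )
  # one M0 per 13C feature
  pairs |>
    dplyr::arrange(.data$m13c_id, abs(.data$mass_error), abs(.data$rt_diff),
                   .data$m0_id) |>
    dplyr::distinct(.data$m13c_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$m0_id, .data$m13c_id)
}

# All (i, j) index pairs with mz[j] - mz[i] within tolerance of `delta`.
# Tolerance is evaluated at the lower m/z. Vectorized via a sorted-mz interval
# scan; returns a tibble (i, j, mass_error).
match_mz_offset <- function(from, to, delta, ppm = 5e-6, abs_cap = 5e-4) {
  ord <- order(to$mz)
  mz_sorted <- to$mz[ord]
  tol <- mass_tolerance(from$mz, ppm = ppm, abs_cap = abs_cap)
  target <- from$mz + delta
  lo <- findInterval(target - tol, mz_sorted)
  hi <- findInterval(target + tol, mz_sorted)
  n_hits <- hi - lo
  if (sum(n_hits) == 0) {
    return(tibble::tibble(i = integer(), j = integer(), mass_error = numeric()))
  }
  i <- rep.int(seq_len(nrow(from)), n_hits)
  j <- ord[sequence(n_hits, from = lo + 1L)]
  tibble::tibble(i = i, j = j, mass_error = to$mz[j] - from$mz[i] - delta)
}

#' Estimate the retention-time coelution window
#'
#' The coelution window half-width is the sample standard deviation of the RT
#' differences of the 13C/12C pairs: downstream, two features are considered
#' coeluting when their RT difference is within one standard deviation on
#' either side (a total window of two standard deviations).
#'
#' @param pairs tibble from [find_isotope_pairs()].
#' @param fallback_half_width optional half-width in seconds to use when fewer
#'   than 2 pairs are available; without it, that situation is an error.
#' @param seed_rt_tolerance the seed tolerance used for the pairing, recorded
#'   on the model.
#' @return an object of class `coelution_model` with fields `rt_half_width`
#'   (s), `n_pairs`, `seed_rt_tolerance`.
#' @export
estimate_rt_window <- function(pairs, fallback_half_width = NULL,
                               seed_rt_tolerance = 2) {
  if (nrow(pairs) < 2) {
    if (is.null(fallback_half_width)) {
      stop("need at least 2 isotopic pairs to estimate the coelution window; ",
           "supply fallback_half_width to use a configured fallback",
           call. = FALSE)
    }
    return(coelution_model(fallback_half_width, n_pairs = nrow(pairs),
                           seed_rt_tolerance = seed_rt_tolerance))
  }
  coelution_model(stats::sd(pairs$rt_diff), n_pairs = nrow(pairs),
                  seed_rt_tolerance = seed_rt_tolerance)
}

#' Construct a coelution model directly
#'
#' @param rt_half_width half-width of the coelution window, seconds.
#' @param n_pairs number of isotopic pairs behind the estimate.
#' @param seed_rt_tolerance seed RT tolerance used for pairing, seconds.
#' @export
coelution_model <- function(rt_half_width, n_pairs = 0L, seed_rt_tolerance = 2) {
  stopifnot(rt_half_width > 0 || n_pairs < 2)
  structure(
    list(rt_half_width = rt_half_width, n_pairs = as.integer(n_pairs),
         seed_rt_tolerance = seed_rt_tolerance),
    class = "coelution_model"
  )
}

#' @export
print.coelution_model <- function(x, ...) {
  cat("Coelution model: |dRT| <= ", format(x$rt_half_width, digits = 4),
      " s (from ", x$n_pairs, " 13C/12C pairs)\n", sep = "")
  invisible(x)
}

#' @method tidy coelution_model
#' @export
tidy.coelution_model <- function(x, ...) {
  tibble::tibble(term = c("rt_half_width", "seed_rt_tolerance"),
                 estimate = c(x$rt_half_width, x$seed_rt_tolerance))
}

#' @method glance coelution_model
#' @export
glance.coelution_model <- function(x, ...) {
  tibble::tibble(rt_half_width = x$rt_half_width, n_pairs = x$n_pairs,
                 seed_rt_tolerance = x$seed_rt_tolerance)
}
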