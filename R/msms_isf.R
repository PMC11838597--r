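#' Cosine similarity between two MS/MS spectra
#'
#' Greedy one-to-one peak matching: candidate peak pairs within `match_tol` are
#' matched in order of ascending |delta m/z|, each peak used at most once. The
#' cosine is the sum of matched intensity products over the product of the full
#' spectrum norms (norms taken over all peaks of each spectrum, matched or
#' not).
#'
#' @param a,b peak tibbles with `mz` and `rel_intensity` columns.
#' @param match_tol peak matching tolerance, Da.
#' @return list with `cosine` in \[0, 1\] and `n_matched`.
#' @export
spectral_cosine <- function(a, b, match_tol = 0.01) {
  if (nrow(a) == 0 || nrow(b) == 0) return(list(cosine = 0, n_matched = 0L))
  dm <- abs(outer(a$mz, b$mz, "-"))
  cand <- which(dm <= match_tol, arr.ind = TRUE)
  if (nrow(cand) == 0) return(list(cosine = 0, n_matched = 0L))
  cand <- cand[order(dm[cand]), , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  dot <- 0; n_matched <- 0L
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      dot <- dot + a$rel_intensity[i] * b$rel_intensity[j]
      n_matched <- n_matched + 1L
    }
  }
  denom <- sqrt(sum(a$rel_intensity^2)) * sqrt(sum(b$rel_intensity^2))
  list(cosine = if (denom > 0) dot / denom else 0, n_matched = n_matched)
}

#' Deduplicate a spectral library by InChIKey
#'
#' Groups spectra by their full InChIKey, computes all pairwise cosine
#' similarities within each group, scores each spectrum by the sum of its
#' cosine scores weighted by the number of matched peaks, and keeps the
#' highest-scoring spectrum as the group's exemplar. Ties go to the spectrum
#' with more peaks, then to the lexicographically smallest spectrum id.
#' Singleton groups keep their only member.
#'
#' @param library an `msms_library` tibble from [read_msp_library()].
#' @param match_tol peak matching tolerance for the cosine, Da.
#' @return list with `exemplars` (the library subset, one row per InChIKey,
#'   sorted by InChIKey) and `cluster_sizes` (tibble `inchikey`, `n`).
#' @export
deduplicate_by_inchikey <- function(library, match_tol = 0.01) {
  if (nrow(library) == 0) {
    return(list(exemplars = library,
                cluster_sizes = tibble::tibble(inchikey = character(),
                                               n = integer())))
  }
  groups <- split(seq_len(nrow(library)), library$inchikey)
  pick <- vapply(groups, function(rows) {
    if (length(rows) == 1) return(rows)
    score <- numeric(length(rows))
    for (i in seq_along(rows)) {
      for (j in seq_along(rows)) {
        if (i == j) next
        cs <- spectral_cosine(library$peaks[[rows[i]]],
                              library$peaks[[rows[j]]], match_tol)
        score[i] <- score[i] + cs$cosine * cs$n_matched
      }
    }
    n_pk <- vapply(library$peaks[rows], nrow, integer(1))
    ids <- library$spectrum_id[rows]
    rows[order(-score, -n_pk, ids)][1]
  }, integer(1))
  exemplars <- library[pick[order(names(pick))], , drop = FALSE]
  class(exemplars) <- class(library)
  list(
    exemplars = exemplars,
    cluster_sizes = tibble::tibble(
      inchikey = names(groups)[order(names(groups))],
      n = unname(lengths(groups)[order(names(groups))])
    )
  )
}

#' Screen a feature table for in-source fragments via MS/MS spectra
#'
#' For each library exemplar, features matching the precursor m/z within `ppm`
#' form the P set. For each such (feature, spectrum) pair, the eligible
#' fragments are the `top_k` highest peaks with relative intensity above
#' `min_rel_intensity`, excluding peaks within `ppm` of the precursor. A
#' fragment is observed when some other feature matches its m/z within `ppm`
#' and elutes within the coelution half-width of the precursor feature. The Y
#' set is the subset of P with at least one observed fragment.
#'
#' @param table a [feature_table()].
#' @param exemplars deduplicated `msms_library` (mode must equal the table's).
#' @param coelution a [coelution_model()].
#' @param ppm relative tolerance (ratio) for precursor and fragment matching.
#' @param min_rel_intensity fragment intensity floor (relative units).
#' @param top_k number of fragments searched per spectrum.
#' @return list with `stats` (one-row tibble: `n_features_total`,
#'   `n_precursor_matched`, `n_with_fragment`, `n_fragments_matched`,
#'   `pct_P_of_T`, `pct_Y_of_T`, `pct_Y_of_P`) and `matches` (per-match tibble:
#'   `feature_id`, `spectrum_id`, `inchikey`, `matched_fragment_mzs`).
#' @export
search_msms_isf <- function(table, exemplars, coelution, ppm = 5e-6,
                            min_rel_intensity = 0.1, top_k = 5) {
  n_total <- nrow(table)
  empty_stats <- tibble::tibble(
    n_features_total = n_total, n_precursor_matched = 0L,
    n_with_fragment = 0L, n_fragments_matched = 0L,
    pct_P_of_T = 0, pct_Y_of_T = 0, pct_Y_of_P = NA_real_
  )
  empty_matches <- tibble::tibble(feature_id = character(),
                                  spectrum_id = character(),
                                  inchikey = character(),
                                  matched_fragment_mzs = character())
  if (nrow(exemplars) == 0) {
    warning("empty spectral library; MS/MS screening skipped", call. = FALSE)
    return(list(stats = empty_stats, matches = empty_matches))
  }
  lib_mode <- unique(exemplars$mode)
  tbl_mode <- attr(table, "mode")
  if (!is.null(tbl_mode) && length(lib_mode) == 1 && lib_mode != tbl_mode) {
    stop("spectral library mode (", lib_mode, ") does not match table mode (",
         tbl_mode, ")", call. = FALSE)
  }
  ord <- order(table$mz)
  mz_sorted <- table$mz[ord]
  w <- coelution$rt_half_width
  p_set <- character()
  y_set <- character()
  n_frag_matched <- 0L
  match_rows <- list()
  for (s in seq_len(nrow(exemplars))) {
    prec <- exemplars$precursor_mz[s]
    tol <- ppm * prec
    lo <- findInterval(prec - tol, mz_sorted)
    hi <- findInterval(prec + tol, mz_sorted)
    if (hi <= lo) next
    prec_feats <- ord[(lo + 1L):hi]
    p_set <- union(p_set, table$id[prec_feats])
    pk <- exemplars$peaks[[s]]
    pk <- pk[pk$rel_intensity > min_rel_intensity &
               abs(pk$mz - prec) > ppm * prec, , drop = FALSE]
    if (nrow(pk) == 0) next
    pk <- pk[order(-pk$rel_intensity, pk$mz), , drop = FALSE]
    pk <- utils::head(pk, top_k)
    for (f in prec_feats) {
      hits <- character()
      for (q in seq_len(nrow(pk))) {
        ftol <- ppm * pk$mz[q]
        flo <- findInterval(pk$mz[q] - ftol, mz_sorted)
        fhi <- findInterval(pk$mz[q] + ftol, mz_sorted)
        if (fhi <= flo) next
        frag_feats <- ord[(flo + 1L):fhi]
        frag_feats <- frag_feats[frag_feats != f &
                                   abs(table$rt[frag_feats] - table$rt[f]) <= w]
        if (length(frag_feats) > 0) {
          hits <- c(hits, sprintf("%.5f", pk$mz[q]))
          n_frag_matched <- n_frag_matched + 1L
        }
      }
      if (length(hits) > 0) {
        y_set <- union(y_set, table$id[f])
        match_rows[[length(match_rows) + 1L]] <- tibble::tibble(
          feature_id = table$id[f],
          spectrum_id = exemplars$spectrum_id[s],
          inchikey = exemplars$inchikey[s],
          matched_fragment_mzs = paste(hits, collapse = ";")
        )
      }
    }
  }
  P <- length(p_set); Y <- length(y_set)
  stats <- tibble::tibble(
    n_features_total = n_total,
    n_precursor_matched = P,
    n_with_fragment = Y,
    n_fragments_matched = n_frag_matched,
    pct_P_of_T = if (n_total > 0) 100 * P / n_total else 0,
    pct_Y_of_T = if (n_total > 0) 100 * Y / n_total else 0,
    pct_Y_of_P = if (P > 0) 100 * Y / P else NA_real_
  )
  matches <- if (length(match_rows)) {
    dplyr::arrange(dplyr::bind_rows(match_rows), .data$feature_id,
                   .data$spectrum_id)
  } else empty_matches
  list(stats = stats, matches = matches)
}
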