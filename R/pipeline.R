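#' Pipeline configuration
#'
#' Collects the tunable parameters of the pre-annotation pipeline. The
#' instrument class fixes the histogram defaults: bin size 0.0001 Da and peak
#' threshold 100 for orbitrap, 0.0005 Da and 20 for tof.
#'
#' @param snr_min,shape_min good-feature thresholds (reporting only; the
#'   pipeline pre-annotates the full table).
#' @param seed_rt_tolerance RT tolerance (s) for the initial isotopic pairing.
#' @param fallback_rt_half_width coelution half-width (s) used when fewer than
#'   2 isotopic pairs are found.
#' @param ppm,abs_cap mass-delta matching tolerance, see [mass_tolerance()].
#' @param max_isotope_ratio maximum 13C/12C intensity ratio.
#' @param max_delta histogram range, Da.
#' @param bin_size,peak_threshold histogram bin size and peak threshold;
#'   `NULL` = instrument default.
#' @param top_n_deltas candidate deltas kept from the histogram.
#' @param include_curated_losses union data-driven candidates with
#'   [curated_neutral_losses()].
#' @param merge_adducts count adduct isotope-0 features as M0 in strata.
#' @param match_ppm relative tolerance for neutral-mass and MS/MS matching.
#' @param min_rel_intensity,top_k MS/MS fragment eligibility, see
#'   [search_msms_isf()].
#' @param cosine_match_tol peak matching tolerance (Da) for library
#'   deduplication.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(snr_min = 5, shape_min = 0.9,
                            seed_rt_tolerance = 2,
                            fallback_rt_half_width = 1.5,
                            ppm = 5e-6, abs_cap = 5e-4,
                            max_isotope_ratio = 0.5,
                            max_delta = 200,
                            bin_size = NULL, peak_threshold = NULL,
                            top_n_deltas = 20,
                            include_curated_losses = TRUE,
                            merge_adducts = TRUE,
                            match_ppm = 5e-6,
                            min_rel_intensity = 0.1, top_k = 5,
                            cosine_match_tol = 0.01) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pre-annotation pipeline
#'
#' Executes, in order: isotopic-pair detection, coelution-window estimation,
#' conservative khipu pre-annotation (isotopes and adducts only),
#' mass-difference histogram and candidate-delta nomination, in-source
#' fragment search between khipus and from singletons to khipus, optional
#' MS/MS screening, optional neutral-mass matching, and abundance-stratified
#' summaries.
#'
#' @param features a [feature_table()] or a path readable by
#'   [read_feature_table()].
#' @param mode ionization polarity (required when `features` is a path).
#' @param instrument_class `"orbitrap"` or `"tof"`.
#' @param msms optional `msms_library` or MSP path for fragment screening.
#' @param masses optional compound mass list (tibble or TSV path).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, [write_report()] is called
#'   on the result.
#' @return object of class `preannotation_pipeline` bundling every stage's
#'   outputs (see [write_report()] for the file-level view) plus a `log`
#'   tibble of per-stage counts.
#' @export
run_pipeline <- function(features, mode = NULL, instrument_class = NULL,
                         msms = NULL, masses = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stage <- function(name) message("stage: ", name)
  if (is.character(features)) {
    if (is.null(mode)) stop("mode is required when reading from a path", call. = FALSE)
    stage("read")
    features <- read_feature_table(features, mode = mode,
                                   instrument_class = instrument_class %||% "orbitrap")
  }
  mode <- ft_mode(features, mode)
  instrument_class <- ft_instrument(features, instrument_class)
  logs <- list()
  note <- function(stage, ...) {
    logs[[length(logs) + 1L]] <<- tibble::tibble(stage = stage,
                                                 detail = paste0(...))
  }
  note("input", nrow(features), " features, ", mode, " mode, ",
       instrument_class)
  good <- filter_good_features(features, config$snr_min, config$shape_min)
  note("good_features", nrow(good), " features with SNR > ", config$snr_min,
       " and shape > ", config$shape_min)

  pairs <- find_isotope_pairs(features,
                              seed_rt_tolerance = config$seed_rt_tolerance,
                              max_ratio = config$max_isotope_ratio,
                              ppm = config$ppm, abs_cap = config$abs_cap)
  note("isotope_pairs", nrow(pairs), " 13C/12C pairs")
  coel <- estimate_rt_window(pairs,
                             fallback_half_width = config$fallback_rt_half_width,
                             seed_rt_tolerance = config$seed_rt_tolerance)
  note("coelution", "rt half-width ", format(coel$rt_half_width, digits = 4), " s")

  patterns <- default_patterns(mode)
  annotation <- preannotate(features, coel, patterns = patterns, mode = mode,
                            ppm = config$ppm, abs_cap = config$abs_cap)
  note("preannotation", nrow(annotation$khipus), " khipus, ",
       length(annotation$singletons), " singletons")

  hist <- compute_delta_histogram(annotation, features, coel,
                                  bin_size = config$bin_size,
                                  max_delta = config$max_delta)
  picked <- suppressWarnings(
    smooth_and_pick_peaks(hist, threshold = config$peak_threshold,
                          top_n = config$top_n_deltas))
  nominated <- nominate_isf_candidates(picked, patterns,
                                       tol = mass_tolerance(500, config$ppm,
                                                            config$abs_cap))
  candidates <- isf_candidate_deltas(nominated,
                                     include_curated = config$include_curated_losses)
  note("mass_deltas", attr(hist, "n_pairs"), " coeluting differences; ",
       sum(!nominated$excluded_as_known), " data-driven candidates; ",
       nrow(candidates), " working deltas")

  links <- dplyr::bind_rows(
    search_khipu_isf(annotation, candidates, coel, features,
                     ppm = config$ppm, abs_cap = config$abs_cap),
    search_singleton_isf(annotation, candidates, coel, features,
                         ppm = config$ppm, abs_cap = config$abs_cap)
  )
  isf_summary <- summarize_isf_impact(links, annotation, features)
  rt_profile <- rt_shift_profile(links)
  note("isf_search", isf_summary$n_khipus_explained, " khipus and ",
       isf_summary$n_singletons_explained,
       " singletons explained as in-source fragments")

  msms_result <- NULL
  if (!is.null(msms)) {
    if (is.character(msms)) msms <- read_msp_library(msms, mode = mode)
    dedup <- deduplicate_by_inchikey(msms, match_tol = config$cosine_match_tol)
    msms_result <- search_msms_isf(features, dedup$exemplars, coel,
                                   ppm = config$match_ppm,
                                   min_rel_intensity = config$min_rel_intensity,
                                   top_k = config$top_k)
    msms_result$dedup <- dedup
    note("msms", nrow(dedup$exemplars), " exemplar spectra; P = ",
         msms_result$stats$n_precursor_matched, ", Y = ",
         msms_result$stats$n_with_fragment)
  } else {
    note("msms", "skipped (no spectral library supplied)")
  }

  mass_match <- NULL
  if (!is.null(masses)) {
    if (is.character(masses)) masses <- read_compound_mass_list(masses)
    mass_match <- match_neutral_masses(annotation, masses,
                                       ppm = config$match_ppm)
    note("mass_match", format(100 * mass_match$matched_fraction, digits = 3),
         "% of khipus matched to the mass list")
  } else {
    note("mass_match", "skipped (no mass list supplied)")
  }

  quartiles <- assign_intensity_quartiles(features)
  strata <- stratified_annotation_summary(annotation, links, quartiles,
                                          features,
                                          merge_adducts = config$merge_adducts)
  curve <- quantile_coverage_curve(annotation, links, features)
  m0_vs_singleton <- suppressWarnings(
    compare_m0_vs_singleton(annotation, quartiles, features, links))
  note("strata", "quartile and quantile summaries computed")

  structure(
    list(features = features, mode = mode, instrument_class = instrument_class,
         config = config, n_good_features = nrow(good), pairs = pairs,
         coelution = coel, annotation = annotation, histogram = hist,
         picked_peaks = picked, nominated = nominated,
         candidates = candidates, links = links, isf_summary = isf_summary,
         rt_profile = rt_profile, msms = msms_result,
         mass_match = mass_match, quartiles = quartiles, strata = strata,
         curve = curve, m0_vs_singleton = m0_vs_singleton,
         log = dplyr::bind_rows(logs)),
    class = "preannotation_pipeline"
  )
}

#' @export
print.preannotation_pipeline <- function(x, ...) {
  cat("Pre-annotation pipeline (", x$mode, ", ", x$instrument_class, ")\n",
      sep = "")
  for (i in seq_len(nrow(x$log))) {
    cat(sprintf("  %-14s %s\n", x$log$stage[i], x$log$detail[i]))
  }
  invisible(x)
}

#' @method glance preannotation_pipeline
#' @export
glance.preannotation_pipeline <- function(x, ...) {
  g <- glance(x$annotation)
  dplyr::bind_cols(
    g,
    tibble::tibble(
      n_good_features = x$n_good_features,
      n_isotope_pairs = nrow(x$pairs),
      rt_half_width = x$coelution$rt_half_width,
      n_isf_links = nrow(x$links),
      pct_khipus_isf = x$isf_summary$pct_khipus,
      pct_features_isf = x$isf_summary$pct_features_of_all
    )
  )
}

#' @method tidy preannotation_pipeline
#' @export
tidy.preannotation_pipeline <- function(x, ...) {
  feature_report_table(x)
}

# feature-level annotation table used by tidy() and write_report()
feature_report_table <- function(result) {
  roles_final <- final_roles(result$annotation, result$links,
                             merge_adducts = result$config$merge_adducts)
  grid <- result$annotation$grid
  tibble::tibble(
    feature_id = result$features$id,
    mz = result$features$mz,
    rt = result$features$rt,
    intensity = result$features$intensity
  ) |>
    dplyr::left_join(grid[, c("feature_id", "khipu_id", "isotope_index",
                              "modification")], by = "feature_id") |>
    dplyr::mutate(khipu_id = dplyr::coalesce(.data$khipu_id, "singleton")) |>
    dplyr::left_join(roles_final, by = "feature_id") |>
    dplyr::left_join(result$quartiles, by = "feature_id") |>
    dplyr::arrange(.data$feature_id)
}

#' Write the pipeline report bundle
#'
#' Emits the feature-level annotation TSV, khipu-level TSV, isotopic pairs,
#' candidate deltas, in-source fragment links, delta histogram, quartile
#' strata, quantile coverage curve, optional MS/MS match table, a
#' machine-readable JSON summary, and a manifest with configuration and file
#' checksums. Output is deterministic: identical results yield byte-identical
#' files.
#'
#' @param result a `preannotation_pipeline` from [run_pipeline()].
#' @param path output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_report <- function(result, path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(path)) {
      stop("cannot create report directory: ", path, call. = FALSE)
    }
  }
  tsv <- function(df, name) {
    readr::write_tsv(df, file.path(path, name), progress = FALSE)
    name
  }
  feats <- feature_report_table(result)
  kh <- result$annotation$khipus
  kh_out <- tibble::tibble(
    khipu_id = kh$khipu_id,
    anchor_id = kh$anchor_id,
    neutral_mass = kh$neutral_mass,
    rt = kh$rt,
    n_members = kh$n_members,
    isf_explained = kh$khipu_id %in%
      result$links$child[result$links$child_kind == "khipu"]
  )
  if (!is.null(result$mass_match)) {
    kh_out$mass_list_match <- result$mass_match$matches$compound_id[
      match(kh_out$khipu_id, result$mass_match$matches$khipu_id)]
  }
  files <- c(
    tsv(feats, "features.tsv"),
    tsv(kh_out, "khipus.tsv"),
    tsv(result$pairs, "isotope_pairs.tsv"),
    tsv(result$annotation$grid, "khipugram.tsv"),
    tsv(tibble::as_tibble(result$histogram), "delta_histogram.tsv"),
    tsv(result$nominated, "candidate_deltas.tsv"),
    tsv(result$candidates, "isf_deltas_used.tsv"),
    tsv(result$links, "isf_links.tsv"),
    tsv(result$strata, "strata.tsv"),
    tsv(result$curve, "quantile_curve.tsv")
  )
  if (!is.null(result$msms)) {
    files <- c(files, tsv(result$msms$matches, "msms_matches.tsv"))
  }
  strata_tab <- result$strata |>
    dplyr::mutate(fraction = round(.data$fraction, 10)) |>
    tidyr::pivot_wider(id_cols = "quartile", names_from = "role",
                       values_from = "fraction")
  summary <- list(
    mode = result$mode,
    instrument_class = result$instrument_class,
    counts = list(
      n_features = nrow(result$features),
      n_good_features = result$n_good_features,
      n_isotope_pairs = nrow(result$pairs),
      n_khipus = nrow(kh),
      n_features_in_khipus = nrow(result$annotation$grid),
      n_singletons = length(result$annotation$singletons)
    ),
    coelution = list(rt_half_width = result$coelution$rt_half_width,
                     n_pairs = result$coelution$n_pairs),
    isf = as.list(result$isf_summary),
    msms = if (!is.null(result$msms)) as.list(result$msms$stats),
    mass_match = if (!is.null(result$mass_match))
      list(matched_fraction = result$mass_match$matched_fraction),
    quartile_fractions = strata_tab,
    m0_vs_singleton = as.list(result$m0_vs_singleton)
  )
  jsonlite::write_json(summary, file.path(path, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  files <- c(files, "summary.json")
  cfg <- result$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("preannotate")),
    config = cfg[order(names(cfg))],
    files = as.list(tools::md5sum(file.path(path, sort(files))))
  )
  names(manifest$files) <- sort(files)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
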