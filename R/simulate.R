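# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic LC-MS generator
#'
#' Defines the statistical structure of a simulated untargeted LC-MS study:
#' compounds with log-uniform neutral masses and long-tail (log-normal)
#' abundances, ESI adducts, natural-abundance 13C isotopologues, a minority of
#' compounds emitting an in-source neutral-loss fragment at the parent's
#' retention time, detection-limit censoring, ppm-scale m/z noise,
#' retention-time jitter, and pure-noise features.
#'
#' RT jitter is intensity-dependent, reflecting that apex localization
#' degrades as signal weakens: each feature's jitter is
#' N(0, `rt_apex_sd` + (`rt_jitter_sd` - `rt_apex_sd`) *
#' sqrt(`detection_limit` / intensity)), so ions at the detection limit
#' wobble with SD `rt_jitter_sd` while strong ions stay near `rt_apex_sd`.
#' The in-source fragments inherit the parent RT exactly before jitter,
#' except a `false_coelution_prob` subpopulation shifted by
#' `false_coelution_shift` seconds.
#'
#' @param seed integer seed; mandatory, all randomness derives from it.
#' @param n_compounds number of compounds.
#' @param mass_range neutral-mass range in Da (log-uniform draw).
#' @param rt_range retention-time range in seconds (uniform draw).
#' @param intensity_log10_mean,intensity_log10_sd log10 parameters of the
#'   compound base-intensity distribution.
#' @param adduct_probs named per-compound emission probabilities for the
#'   positive-mode adducts (`M+Na`, `M+K`, `M+ACN+H`); in negative mode the
#'   same probabilities drive the negative adduct set.
#' @param adduct_rel_range uniform range of adduct/parent intensity ratios.
#' @param isf_prob probability that a compound emits one neutral-loss
#'   fragment, drawn from [curated_neutral_losses()].
#' @param isf_rel_range uniform range of fragment/parent intensity ratios.
#' @param detection_limit intensity below which an ion is censored.
#' @param mz_noise_ppm_sd per-feature m/z noise, ppm standard deviation.
#' @param rt_jitter_sd RT jitter SD (seconds) for a feature at the detection
#'   limit.
#' @param rt_apex_sd asymptotic RT jitter SD (seconds) for strong features.
#' @param n_noise_features number of pure-noise features.
#' @param noise_log10_mean,noise_log10_sd log10 intensity parameters of noise
#'   features (truncated at the detection limit).
#' @param false_coelution_prob fraction of fragment features shifted in RT.
#' @param false_coelution_shift RT shift of falsely coeluting fragments, s.
#' @param msms_fraction fraction of compounds with an MS/MS library record.
#' @param msms_copies integer range of duplicate spectra per library compound.
#' @param good_feature_prob fraction of features passing the good-feature
#'   filter (SNR > 5, peak shape > 0.9).
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(seed,
                             n_compounds = 2000,
                             mass_range = c(100, 1200),
                             rt_range = c(30, 1200),
                             intensity_log10_mean = 5.0,
                             intensity_log10_sd = 0.8,
                             adduct_probs = c("M+Na" = 0.4, "M+K" = 0.1,
                                              "M+ACN+H" = 0.1),
                             adduct_rel_range = c(0.05, 0.6),
                             isf_prob = 0.15,
                             isf_rel_range = c(0.05, 0.5),
                             detection_limit = 1e3,
                             mz_noise_ppm_sd = 0.3,
                             rt_jitter_sd = 1.0,
                             rt_apex_sd = 0.1,
                             n_noise_features = 500,
                             noise_log10_mean = 3.8,
                             noise_log10_sd = 1.0,
                             false_coelution_prob = 0.05,
                             false_coelution_shift = 3,
                             msms_fraction = 0.3,
                             msms_copies = c(2L, 4L),
                             good_feature_prob = 0.65) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("a single integer seed is required", call. = FALSE)
  }
  stopifnot(all(adduct_probs >= 0 & adduct_probs <= 1),
            isf_prob >= 0, isf_prob <= 1,
            false_coelution_prob >= 0, false_coelution_prob <= 1)
  structure(as.list(environment()), class = "generator_config")
}

#' Generate compound-level ground truth
#'
#' Draws the planted compounds: neutral mass, retention time, base intensity,
#' carbon count (driving the M+1/M0 isotopologue ratio of 1.07% per carbon,
#' capped below 0.5 to respect the isotopic-pair intensity filter), adduct
#' emissions and relative intensities, and in-source fragment assignments.
#'
#' @param config a [generator_config()].
#' @return list of class `ground_truth` with a `compounds` tibble and the
#'   config; feature-level `roles` are filled by [render_feature_table()].
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, {
    n <- config$n_compounds
    mass <- 10^stats::runif(n, log10(config$mass_range[1]),
                            log10(config$mass_range[2]))
    rt <- stats::runif(n, config$rt_range[1], config$rt_range[2])
    base <- 10^stats::rnorm(n, config$intensity_log10_mean,
                            config$intensity_log10_sd)
    carbon <- pmax(1L, as.integer(round(mass / 17.0)) + stats::rpois(n, 1) - 1L)
    m1_ratio <- pmin(carbon * 0.0107, 0.499)
    adducts <- purrr::imap(config$adduct_probs, function(p, nm) {
      emit <- stats::runif(n) < p
      rel <- stats::runif(n, config$adduct_rel_range[1],
                          config$adduct_rel_range[2])
      tibble::tibble(adduct = nm, emit = emit, rel = rel)
    })
    losses <- curated_neutral_losses()
    has_isf <- stats::runif(n) < config$isf_prob
    isf_loss <- losses$label[sample.int(nrow(losses), n, replace = TRUE)]
    isf_loss[!has_isf] <- NA_character_
    isf_rel <- stats::runif(n, config$isf_rel_range[1], config$isf_rel_range[2])
    isf_false <- stats::runif(n) < config$false_coelution_prob
    compounds <- tibble::tibble(
      compound_id = sprintf("C%05d", seq_len(n)),
      neutral_mass = mass, rt = rt, base_intensity = base,
      carbon_count = carbon, m1_ratio = m1_ratio,
      isf_loss = isf_loss, isf_rel = isf_rel,
      isf_false_coelution = isf_false
    )
    for (ad in adducts) {
      compounds[[paste0("emit_", ad$adduct[1])]] <- ad$emit
      compounds[[paste0("rel_", ad$adduct[1])]] <- ad$rel
    }
    structure(list(compounds = compounds, roles = NULL,
                   planted_isf_fraction = NA_real_, config = config),
              class = "ground_truth")
  })
}

# adduct label -> pattern label + delta for each mode
adduct_map <- function(mode) {
  pat <- default_patterns(mode)
  if (mode == "positive") {
    tibble::tibble(
      adduct = c("M+Na", "M+K", "M+ACN+H"),
      label = c("Na/H", "K/H", "ACN"),
      delta = pat$delta[match(c("Na/H", "K/H", "ACN"), pat$label)]
    )
  } else {
    tibble::tibble(
      adduct = c("M+Na", "M+K", "M+ACN+H"),
      label = c("Na/H", "NaCOOH", "NaCH2COOH"),
      delta = pat$delta[match(c("Na/H", "NaCOOH", "NaCH2COOH"), pat$label)]
    )
  }
}

#' Render a feature table from ground truth
#'
#' Emits, per compound, the (de)protonated molecular ion, adducts, 13C
#' isotopologues of every emitted ion (M+1 at the per-compound ratio, M+2 at
#' the binomial second-order ratio), and the planted neutral-loss fragment;
#' censors ions below the detection limit; applies m/z noise and RT jitter;
#' appends pure-noise features; and samples SNR/peak-shape quality metrics.
#'
#' @param truth a `ground_truth` from [generate_ground_truth()].
#' @param config the same [generator_config()].
#' @param mode ionization polarity.
#' @return list with `table` (a [feature_table()]) and `truth` (the input with
#'   feature-level `roles` and `planted_isf_fraction` filled in).
#' @export
render_feature_table <- function(truth, config, mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "ground_truth"))
  cmp <- truth$compounds
  sign <- if (mode == "positive") 1 else -1
  amap <- adduct_map(mode)
  losses <- curated_neutral_losses()
  n <- nrow(cmp)
  anchor_mz <- cmp$neutral_mass + sign * PROTON_MASS
  base_ions <- tibble::tibble(
    ci = seq_len(n), mz = anchor_mz, intensity = cmp$base_intensity,
    role0 = "M0", modification = "anchor"
  )
  for (k in seq_len(nrow(amap))) {
    emit <- cmp[[paste0("emit_", amap$adduct[k])]]
    if (any(emit)) {
      base_ions <- dplyr::bind_rows(base_ions, tibble::tibble(
        ci = which(emit),
        mz = anchor_mz[emit] + amap$delta[k],
        intensity = cmp$base_intensity[emit] * cmp[[paste0("rel_", amap$adduct[k])]][emit],
        role0 = "adduct_M0", modification = amap$label[k]
      ))
    }
  }
  r1 <- cmp$m1_ratio[base_ions$ci]
  c_ <- cmp$carbon_count[base_ions$ci]
  r2 <- (0.0107 * c_)^2 * (c_ - 1) / (2 * c_)
  iso_role <- ifelse(base_ions$role0 == "M0", "isotopologue",
                     "adduct_isotopologue")
  iso <- dplyr::bind_rows(
    dplyr::mutate(base_ions, mz = .data$mz + C13_DELTA,
                  intensity = .data$intensity * r1, role0 = iso_role,
                  iso_step = 1L),
    dplyr::mutate(base_ions, mz = .data$mz + 2 * C13_DELTA,
                  intensity = .data$intensity * r2, role0 = iso_role,
                  iso_step = 2L)
  )
  base_ions$iso_step <- 0L
  feats <- dplyr::bind_rows(base_ions, iso)
  feats$rt <- cmp$rt[feats$ci]
  has_isf <- which(!is.na(cmp$isf_loss))
  if (length(has_isf) > 0) {
    ld <- losses$delta[match(cmp$isf_loss[has_isf], losses$label)]
    feats <- dplyr::bind_rows(feats, tibble::tibble(
      ci = has_isf,
      mz = anchor_mz[has_isf] - ld,
      intensity = cmp$base_intensity[has_isf] * cmp$isf_rel[has_isf],
      role0 = "ISF", modification = cmp$isf_loss[has_isf], iso_step = 0L,
      rt = cmp$rt[has_isf] +
        ifelse(cmp$isf_false_coelution[has_isf], config$false_coelution_shift, 0)
    ))
  }
  feats$compound_id <- cmp$compound_id[feats$ci]
  feats <- feats[feats$intensity >= config$detection_limit, , drop = FALSE]
  feats <- feats[order(feats$ci, feats$mz), , drop = FALSE]
  feats$ci <- NULL
  with_local_seed(config$seed + 1L, {
    nn <- config$n_noise_features
    lo <- stats::pnorm(log10(config$detection_limit), config$noise_log10_mean,
                       config$noise_log10_sd)
    noise <- tibble::tibble(
      mz = stats::runif(nn, config$mass_range[1] + 1, config$mass_range[2] + 1),
      intensity = 10^stats::qnorm(stats::runif(nn, lo, 1),
                                  config$noise_log10_mean,
                                  config$noise_log10_sd),
      role0 = "noise", modification = NA_character_, iso_step = NA_integer_,
      rt = stats::runif(nn, config$rt_range[1], config$rt_range[2]),
      compound_id = NA_character_
    )
    feats <- dplyr::bind_rows(feats, noise)
    m <- nrow(feats)
    feats$mz <- feats$mz *
      (1 + stats::rnorm(m, 0, config$mz_noise_ppm_sd * 1e-6))
    rt_sd <- config$rt_apex_sd + (config$rt_jitter_sd - config$rt_apex_sd) *
      sqrt(config$detection_limit / pmax(feats$intensity,
                                         config$detection_limit))
    feats$rt <- pmax(0, feats$rt + stats::rnorm(m, 0, rt_sd))
    good <- stats::runif(m) < config$good_feature_prob
    snr <- ifelse(good, stats::runif(m, 5.5, 60), stats::runif(m, 0.5, 5))
    shape <- ifelse(good, stats::runif(m, 0.905, 1), stats::runif(m, 0.5, 0.9))
    # among failing features, some fail only one of the two criteria
    relax <- stats::runif(m)
    snr[!good & relax < 0.3] <- stats::runif(sum(!good & relax < 0.3), 5.5, 60)
    shape[!good & relax > 0.7] <- stats::runif(sum(!good & relax > 0.7), 0.905, 1)
    p_det <- pmin(0.95, pmax(0.05, 0.2 * (log10(feats$intensity) - 2)))
    feats$snr <- snr
    feats$peak_shape <- shape
    feats$detection_count <- stats::rbinom(m, 100L, p_det)
  })
  feats$id <- sprintf("F%06d", seq_len(nrow(feats)))
  table <- feature_table(
    feats[, c("id", "mz", "rt", "intensity", "snr", "peak_shape",
              "detection_count")],
    mode = mode, instrument_class = "orbitrap"
  )
  roles <- tibble::tibble(feature_id = feats$id,
                          compound_id = feats$compound_id,
                          role = feats$role0,
                          modification = feats$modification,
                          iso_step = feats$iso_step)
  truth$roles <- roles
  truth$planted_isf_fraction <- 100 * mean(roles$role == "ISF")
  truth$mode <- mode
  list(table = table, truth = truth)
}

# deterministic InChIKey-shaped identifier for a planted compound
fake_inchikey <- function(i) {
  # base-26 digits of i (least significant first) keep keys distinct per i;
  # the position-dependent offset just varies the letters cosmetically
  block <- function(n, offset) {
    digits <- (i %/% 26^(seq_len(n) - 1) + offset * seq_len(n)) %% 26
    paste(LETTERS[digits + 1], collapse = "")
  }
  paste0(block(14, 1), "-", block(10, 2), "-N")
}

#' Render an MS/MS library matching the ground truth
#'
#' For a configurable fraction of compounds, writes duplicate MSP-style
#' spectra (2-4 noisy copies sharing an InChIKey-shaped identifier) with the
#' ionized molecular ion as precursor, the planted neutral-loss fragment (when
#' the compound has one) as a strong peak, and three decoy fragments below the
#' 0.1 relative-intensity floor.
#'
#' @param truth a `ground_truth` with roles rendered (so mode is known).
#' @param config the [generator_config()].
#' @param mode ionization polarity; defaults to the rendered mode.
#' @return an `msms_library` tibble (see [read_msp_library()]).
#' @export
render_msms_library <- function(truth, config, mode = NULL) {
  mode <- mode %||% truth$mode %||% "positive"
  sign <- if (mode == "positive") 1 else -1
  cmp <- truth$compounds
  losses <- curated_neutral_losses()
  with_local_seed(config$seed + 2L, {
    n <- nrow(cmp)
    in_lib <- stats::runif(n) < config$msms_fraction
    specs <- list()
    for (i in which(in_lib)) {
      prec <- cmp$neutral_mass[i] + sign * PROTON_MASS
      frag_mz <- numeric(); frag_int <- numeric()
      if (!is.na(cmp$isf_loss[i])) {
        frag_mz <- prec - losses$delta[losses$label == cmp$isf_loss[i]]
        frag_int <- stats::runif(1, 0.3, 0.9)
      }
      decoy_mz <- stats::runif(3, 50, max(60, prec - 5))
      decoy_int <- stats::runif(3, 0.01, 0.09)
      base_peaks <- tibble::tibble(
        mz = c(frag_mz, decoy_mz, prec),
        rel_intensity = c(frag_int, decoy_int, 1.0)
      )
      n_copies <- sample(seq(config$msms_copies[1], config$msms_copies[2]), 1)
      key <- fake_inchikey(i)
      for (cp in seq_len(n_copies)) {
        pk <- base_peaks
        pk$rel_intensity <- pmin(1, pmax(1e-4,
          pk$rel_intensity * (1 + stats::rnorm(nrow(pk), 0, 0.01))))
        pk <- pk[order(pk$mz), ]
        pk$rel_intensity <- pk$rel_intensity / max(pk$rel_intensity)
        specs[[length(specs) + 1L]] <- tibble::tibble(
          spectrum_id = sprintf("%s_s%d", cmp$compound_id[i], cp),
          precursor_mz = prec, mode = mode, inchikey = key,
          n_peaks = nrow(pk), peaks = list(pk)
        )
      }
    }
    out <- dplyr::bind_rows(specs)
    class(out) <- c("msms_library", class(out))
    out
  })
}

#' Compound mass list for the planted ground truth
#'
#' @param truth a `ground_truth`.
#' @return tibble `compound_id`, `name`, `neutral_mass`, usable with
#'   [match_neutral_masses()].
#' @export
truth_mass_list <- function(truth) {
  tibble::tibble(
    compound_id = truth$compounds$compound_id,
    name = paste0("synthetic_", truth$compounds$compound_id),
    neutral_mass = truth$compounds$neutral_mass
  )
}

#' Simulate a full synthetic study bundle
#'
#' Convenience wrapper: ground truth, feature table, MS/MS library and
#' compound mass list from one config.
#'
#' @param config a [generator_config()].
#' @param mode ionization polarity.
#' @return list with `table`, `truth`, `library`, `masses`.
#' @export
simulate_lcms <- function(config, mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  truth <- generate_ground_truth(config)
  rendered <- render_feature_table(truth, config, mode)
  library <- render_msms_library(rendered$truth, config, mode)
  list(table = rendered$table, truth = rendered$truth, library = library,
       masses = truth_mass_list(rendered$truth))
}

#' Score annotation recovery against the planted truth
#'
#' Reports (a) the khipu recovery rate — the fraction of compounds with at
#' least two detected non-fragment ions whose planted molecular ion is the
#' anchor of a khipu; (b) a feature-role confusion matrix (planted vs
#' assigned final role); and (c) the estimated vs planted in-source-fragment
#' feature percentage.
#'
#' @param annotation a `khipu_annotation`.
#' @param links ISF link tibble.
#' @param truth a rendered `ground_truth` (with roles).
#' @param table the feature table the annotation was computed on.
#' @return list with `recovery_rate`, `n_eligible`, `confusion` (tibble),
#'   `isf_pct_estimated`, `isf_pct_planted`.
#' @export
score_recovery <- function(annotation, links, truth, table) {
  roles <- truth$roles
  if (is.null(roles)) stop("truth has no rendered roles", call. = FALSE)
  if (!all(roles$feature_id %in% table$id)) {
    stop("feature ids in truth do not match the table", call. = FALSE)
  }
  ion_counts <- roles |>
    dplyr::filter(!is.na(.data$compound_id), .data$role != "ISF") |>
    dplyr::count(.data$compound_id, name = "n_ions")
  m0_ids <- roles |>
    dplyr::filter(.data$role == "M0") |>
    dplyr::select("compound_id", m0_id = "feature_id")
  eligible <- ion_counts |>
    dplyr::filter(.data$n_ions >= 2) |>
    dplyr::inner_join(m0_ids, by = "compound_id")
  # recovered = the planted M+H/M-H feature anchors a khipu
  recovered <- eligible$m0_id %in% annotation$khipus$anchor_id
  assigned <- final_roles(annotation, links, merge_adducts = FALSE)
  confusion <- roles |>
    dplyr::transmute(.data$feature_id, planted = .data$role) |>
    dplyr::inner_join(assigned, by = "feature_id") |>
    dplyr::count(.data$planted, assigned = .data$role)
  est <- summarize_isf_impact(links, annotation, table)
  list(
    recovery_rate = if (nrow(eligible)) mean(recovered) else NA_real_,
    n_eligible = nrow(eligible),
    confusion = confusion,
    isf_pct_estimated = est$pct_features_of_all,
    isf_pct_planted = truth$planted_isf_fraction
  )
}
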