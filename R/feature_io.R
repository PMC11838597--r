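# Column-name aliases accepted when reading feature tables. Different
# preprocessing tools name the same quantities differently.
default_column_aliases <- function() {
  list(
    id = c("id", "id_number", "feature_id", "feature"),
    mz = c("mz", "m/z", "mz_value"),
    rt = c("rt", "rtime", "retention_time", "rt_seconds"),
    intensity = c("intensity", "peak_area", "peak_height", "representative_intensity"),
    snr = c("snr", "signal_noise_ratio", "snr_value"),
    peak_shape = c("peak_shape", "goodness_fitting", "gaussian_shape"),
    detection_count = c("detection_count", "detection_counts", "n_detected")
  )
}

#' Construct a feature table
#'
#' A feature table is a tibble of LC-MS elution peaks with one row per feature
#' and the ionization mode and instrument class attached as attributes. Rows
#' violating the feature invariants (`mz > 0`, `rt >= 0`,
#' `0 <= peak_shape <= 1`, `intensity >= 0`) are dropped with a message.
#'
#' @param df data frame with at least `id`, `mz`, `rt`, `intensity` columns;
#'   `snr`, `peak_shape` and `detection_count` are optional (filled with `NA`).
#' @param mode ionization polarity, `"positive"` or `"negative"`.
#' @param instrument_class `"orbitrap"` or `"tof"`; drives histogram bin size
#'   and peak-picking threshold defaults downstream.
#' @return A tibble of class `feature_table`.
#' @export
feature_table <- function(df, mode = c("positive", "negative"),
                          instrument_class = c("orbitrap", "tof")) {
  mode <- match.arg(mode)
  instrument_class <- match.arg(instrument_class)
  required <- c("id", "mz", "rt", "intensity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("feature table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    stop("duplicate feature id(s): ",
         paste(utils::head(unique(df$id[duplicated(df$id)]), 3), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("snr", "peak_shape", "detection_count")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  ok <- df$mz > 0 & df$rt >= 0 & df$intensity >= 0 &
    (is.na(df$peak_shape) | (df$peak_shape >= 0 & df$peak_shape <= 1)) &
    (is.na(df$snr) | df$snr >= 0)
  ok[is.na(ok)] <- FALSE
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    message(n_bad, " row(s) rejected for violating feature invariants")
    df <- df[ok, , drop = FALSE]
  }
  df <- df[, c(required, "snr", "peak_shape", "detection_count"),
           drop = FALSE]
  attr(df, "mode") <- mode
  attr(df, "instrument_class") <- instrument_class
  attr(df, "n_rejected") <- n_bad
  class(df) <- c("feature_table", class(df))
  df
}

ft_mode <- function(table, mode = NULL) {
  mode %||% attr(table, "mode") %||%
    stop("ionization mode not set on the feature table", call. = FALSE)
}

ft_instrument <- function(table, instrument_class = NULL) {
  instrument_class %||% attr(table, "instrument_class") %||% "orbitrap"
}

#' Read a feature table from TSV
#'
#' Reads a tab-separated feature table (one row per feature) as produced by
#' LC-MS preprocessing tools. Column-name aliases (e.g. `m/z` for `mz`,
#' `peak_area` for `intensity`) are resolved via `col_aliases`.
#'
#' @param path path to a UTF-8, tab-separated file with a header row.
#' @param mode ionization polarity of the data.
#' @param instrument_class `"orbitrap"` or `"tof"`.
#' @param col_aliases named list mapping canonical column names to accepted
#'   aliases; see `default_column_aliases` in the package source.
#' @return A [feature_table()] tibble; the number of rejected rows is stored in
#'   the `n_rejected` attribute.
#' @export
read_feature_table <- function(path, mode = c("positive", "negative"),
                               instrument_class = c("orbitrap", "tof"),
                               col_aliases = default_column_aliases()) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  nm <- names(df)
  for (canon in names(col_aliases)) {
    hit <- which(tolower(nm) %in% tolower(col_aliases[[canon]]))
    if (length(hit) > 0) names(df)[hit[1]] <- canon
  }
  missing_cols <- setdiff(c("id", "mz", "rt", "intensity"), names(df))
  if (length(missing_cols) > 0) {
    stop("no column found for: ", paste(missing_cols, collapse = ", "),
         " (accepted aliases: ",
         paste(unlist(col_aliases[missing_cols]), collapse = ", "), ")",
         call. = FALSE)
  }
  feature_table(df, mode = mode, instrument_class = instrument_class)
}

#' Write a feature table to TSV
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(as.data.frame(table)), path, progress = FALSE)
  invisible(path)
}

#' Read an MSP spectral library
#'
#' Parses the MSP dialect used by public MS/MS libraries: records start at a
#' `Name:` line, carry `PrecursorMZ:` (any capitalization), `InChIKey:` and a
#' `Num Peaks:` line followed by whitespace-separated m/z-intensity pairs.
#' Unknown header lines are ignored. Per spectrum, intensities are rescaled to
#' a maximum of 1. Records missing a precursor m/z or InChIKey are skipped and
#' counted; records whose peak count disagrees with `Num Peaks` are dropped
#' with a warning, other records continue.
#'
#' @param path path to an MSP file.
#' @param mode polarity to record on the spectra (MSP files rarely carry it in
#'   a uniform field); one of `"positive"`, `"negative"`.
#' @return A tibble of class `msms_library`: one row per spectrum with columns
#'   `spectrum_id`, `precursor_mz`, `mode`, `inchikey`, `n_peaks`, and a list
#'   column `peaks` of tibbles (`mz`, `rel_intensity`, sorted by mz). The
#'   number of skipped records is stored in the `n_skipped` attribute.
#' @export
read_msp_library <- function(path, mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  lines <- readr::read_lines(path, progress = FALSE)
  starts <- grep("^Name:", lines, ignore.case = TRUE)
  n_skipped <- 0L
  records <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_along(starts)) {
    block <- lines[starts[i]:(bounds[i + 1L] - 1L)]
    get_field <- function(pattern) {
      hit <- grep(pattern, block, ignore.case = TRUE, value = TRUE)
      if (length(hit) == 0) return(NA_character_)
      trimws(sub("^[^:]+:", "", hit[1]))
    }
    name <- get_field("^Name:")
    prec <- suppressWarnings(as.numeric(get_field("^PrecursorMZ:")))
    inchikey <- get_field("^InChIKey:")
    npk_line <- grep("^Num ?Peaks:", block, ignore.case = TRUE)
    if (is.na(prec) || prec <= 0 || is.na(inchikey) || inchikey == "" ||
        length(npk_line) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    n_peaks <- suppressWarnings(as.integer(
      trimws(sub("^[^:]+:", "", block[npk_line[1]]))))
    peak_lines <- block[seq.int(npk_line[1] + 1L, length(block))]
    peak_lines <- peak_lines[nzchar(trimws(peak_lines))]
    vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(peak_lines), "[ \t;]+"))))
    vals <- vals[!is.na(vals)]
    if (length(vals) %% 2 != 0 || length(vals) / 2 != n_peaks || n_peaks == 0) {
      warning("MSP record '", name, "': peak list disagrees with Num Peaks; record dropped",
              call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    mz <- vals[seq(1, length(vals), by = 2)]
    int <- vals[seq(2, length(vals), by = 2)]
    ord <- order(mz)
    records[[i]] <- tibble::tibble(
      spectrum_id = name,
      precursor_mz = prec,
      mode = mode,
      inchikey = inchikey,
      n_peaks = n_peaks,
      peaks = list(tibble::tibble(mz = mz[ord],
                                  rel_intensity = int[ord] / max(int)))
    )
  }
  out <- dplyr::bind_rows(records)
  if (nrow(out) > 0 && anyDuplicated(out$spectrum_id)) {
    out$spectrum_id <- make.unique(out$spectrum_id, sep = "_dup")
  }
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("msms_library", class(out))
  out
}

#' Write an MSP spectral library
#'
#' Inverse of [read_msp_library()]; intensities are written as given (relative
#' scale is preserved on round trip up to the max-normalization).
#'
#' @param library an `msms_library` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msp_library <- function(library, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(library))) {
    pk <- library$peaks[[i]]
    writeLines(c(
      paste0("Name: ", library$spectrum_id[i]),
      paste0("PrecursorMZ: ", format(library$precursor_mz[i], digits = 15)),
      paste0("InChIKey: ", library$inchikey[i]),
      paste0("Num Peaks: ", nrow(pk)),
      paste(format(pk$mz, digits = 15, trim = TRUE),
            format(pk$rel_intensity, digits = 15, trim = TRUE)),
      ""
    ), con = con)
  }
  invisible(path)
}

#' Read a compound neutral-mass list
#'
#' Reads a TSV with columns `compound_id`, `name`, `neutral_mass` (monoisotopic
#' Da). Rows with non-positive or unparseable masses are rejected with a
#' message naming their line numbers.
#'
#' @param path path to a tab-separated file.
#' @return A tibble with the three columns above.
#' @export
read_compound_mass_list <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          compound_id = readr::col_character(),
                          name = readr::col_character(),
                          neutral_mass = readr::col_character()
                        ))
  missing_cols <- setdiff(c("compound_id", "name", "neutral_mass"), names(df))
  if (length(missing_cols) > 0) {
    stop("compound mass list is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  mass <- suppressWarnings(as.numeric(df$neutral_mass))
  bad <- is.na(mass) | mass <= 0
  if (any(bad)) {
    message(sum(bad), " row(s) rejected (line ",
            paste(which(bad) + 1L, collapse = ", "),
            "): non-positive or unparseable neutral_mass")
  }
  tibble::tibble(
    compound_id = df$compound_id[!bad],
    name = df$name[!bad],
    neutral_mass = mass[!bad]
  )
}
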