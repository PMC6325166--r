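# Centroided spectrum container, MGF (Mascot Generic Format) in/out and
# tolerance-based peak matching. Spectra live in a tibble, one row per scan,
# with the peak list as a nested tibble(mz, intensity) column.

#' Construct a spectra tibble
#'
#' @param scan_id Character scan identifiers.
#' @param scan_type `"NLS"`, `"PIS"`, `"EPI-MS2"` (negative-mode chain
#'   analysis) or `"EPI-PB"` (PB-MS/MS).
#' @param polarity `"positive"` or `"negative"`.
#' @param precursor_mz Precursor m/z (`NA` for NLS/PIS pseudo-spectra).
#' @param rt_min Retention time in minutes.
#' @param peaks List of tibbles/data frames with columns `mz`, `intensity`;
#'   each is sorted ascending in m/z on construction.
#' @param sample_id Source sample identifier.
#' @return A tibble with class-stable columns; peak lists sorted, validated.
#' @export
spectra_tibble <- function(scan_id, scan_type, polarity, precursor_mz,
                           rt_min, peaks, sample_id = "sample") {
  peaks <- lapply(peaks, function(p) {
    p <- tibble::as_tibble(p)
    stopifnot(all(c("mz", "intensity") %in% names(p)))
    if (any(p$intensity < 0)) stop("negative peak intensity", call. = FALSE)
    p[order(p$mz), c("mz", "intensity")]
  })
  if (any(rt_min < 0, na.rm = TRUE)) stop("negative retention time", call. = FALSE)
  tibble::tibble(
    scan_id = as.character(scan_id),
    scan_type = as.character(scan_type),
    polarity = as.character(polarity),
    precursor_mz = as.numeric(precursor_mz),
    rt_min = as.numeric(rt_min),
    sample_id = as.character(sample_id),
    peaks = peaks
  )
}

#' Read an MGF file into a spectra tibble
#'
#' Honors `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, `RTINSECONDS`,
#' `CHARGE` and `TITLE`. Scan type, polarity, scan id and sample id are parsed
#' from `key=value` tokens inside the TITLE (the dialect this package writes);
#' missing tokens default to polarity `"positive"` and type `"EPI-PB"` with a
#' warning. Retention time is stored in minutes internally.
#'
#' @param path Path to an MGF file.
#' @return A spectra tibble (see [spectra_tibble()]).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS", call. = FALSE)
  }
  defaulted <- FALSE
  specs <- lapply(seq_along(begins), function(i) {
    block <- lines[(begins[i] + 1):(ends[i] - 1)]
    is_header <- grepl("^[A-Z]+=", block)
    headers <- block[is_header]
    peak_lines <- block[!is_header & nzchar(trimws(block))]
    hv <- function(key) {
      hit <- headers[startsWith(headers, paste0(key, "="))]
      if (length(hit) == 0) return(NA_character_)
      sub(paste0("^", key, "="), "", hit[1])
    }
    title <- hv("TITLE")
    tv <- function(key, default = NA_character_) {
      if (is.na(title)) return(default)
      m <- regmatches(title,
                      regexec(paste0("(^|[ ;])", key, "=([^ ;]+)"), title))[[1]]
      if (length(m) == 0) default else m[3]
    }
    scan_type <- tv("scan_type")
    polarity <- tv("polarity")
    if (is.na(scan_type)) { scan_type <- "EPI-PB"; defaulted <<- TRUE }
    if (is.na(polarity)) { polarity <- "positive"; defaulted <<- TRUE }
    pepmass <- hv("PEPMASS")
    if (is.na(pepmass) && startsWith(scan_type, "EPI")) {
      stop("MGF block ", i, " (", scan_type, ") is missing PEPMASS",
           call. = FALSE)
    }
    prec <- if (is.na(pepmass)) NA_real_ else
      as.numeric(strsplit(trimws(pepmass), "[ \t]+")[[1]][1])
    rtsec <- hv("RTINSECONDS")
    rt_min <- if (is.na(rtsec)) NA_real_ else as.numeric(rtsec) / 60
    bad <- grep("^[0-9.eE+-]+([ \t]+[0-9.eE+-]+)?$", peak_lines, invert = TRUE)
    if (length(bad) > 0) {
      stop("malformed peak line at file line ",
           begins[i] + which(block == peak_lines[bad[1]])[1],
           ": '", peak_lines[bad[1]], "'", call. = FALSE)
    }
    pk <- if (length(peak_lines) == 0) {
      tibble::tibble(mz = numeric(), intensity = numeric())
    } else {
      mat <- do.call(rbind, strsplit(trimws(peak_lines), "[ \t]+"))
      tibble::tibble(mz = as.numeric(mat[, 1]),
                     intensity = as.numeric(mat[, 2]))
    }
    if (anyNA(pk$mz) || anyNA(pk$intensity)) {
      stop("malformed peak line in MGF block ", i, call. = FALSE)
    }
    list(scan_id = tv("scan_id", paste0("scan", i)),
         scan_type = scan_type, polarity = polarity,
         precursor_mz = prec, rt_min = rt_min,
         sample_id = tv("sample", "sample"), peaks = pk)
  })
  if (defaulted) {
    warning("one or more MGF TITLEs lacked scan_type/polarity tokens; ",
            "defaults (EPI-PB, positive) applied", call. = FALSE)
  }
  spectra_tibble(
    scan_id = vapply(specs, `[[`, character(1), "scan_id"),
    scan_type = vapply(specs, `[[`, character(1), "scan_type"),
    polarity = vapply(specs, `[[`, character(1), "polarity"),
    precursor_mz = vapply(specs, `[[`, numeric(1), "precursor_mz"),
    rt_min = vapply(specs, `[[`, numeric(1), "rt_min"),
    sample_id = vapply(specs, `[[`, character(1), "sample_id"),
    peaks = lapply(specs, `[[`, "peaks")
  )
}

#' Write a spectra tibble to MGF
#'
#' Text formatting is bit-stable: m/z with 4 decimals, intensity with 1.
#' Retention time is written as `RTINSECONDS`; scan metadata is encoded as
#' `key=value` tokens in the TITLE. NLS/PIS pseudo-spectra are written without
#' `PEPMASS`.
#'
#' @param spectra A spectra tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(spectra))) {
    row <- spectra[i, ]
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=scan_id=%s scan_type=%s polarity=%s sample=%s",
                       row$scan_id, row$scan_type, row$polarity,
                       row$sample_id), con)
    if (!is.na(row$precursor_mz)) {
      writeLines(sprintf("PEPMASS=%.4f", row$precursor_mz), con)
      writeLines(sprintf("CHARGE=1%s",
                         if (row$polarity == "negative") "-" else "+"), con)
    }
    if (!is.na(row$rt_min)) {
      writeLines(sprintf("RTINSECONDS=%.3f", row$rt_min * 60), con)
    }
    pk <- row$peaks[[1]]
    if (nrow(pk) > 0) {
      writeLines(sprintf("%.4f %.1f", pk$mz, pk$intensity), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Match the most intense peak within a tolerance window
#'
#' @param peaks A tibble with `mz`, `intensity` (or a spectra-tibble row's
#'   `peaks[[1]]`).
#' @param target_mz Target m/z.
#' @param tolerance Matching half-window; Da or ppm per `unit`.
#' @param unit `"Da"` (default, unit-resolution QTRAP context) or `"ppm"`.
#' @return A one-row tibble (`target_mz`, `mz`, `intensity`, `error_da`,
#'   `error_ppm`, `snr`) or a zero-row tibble when nothing matches. The
#'   signal-to-noise estimate divides the matched intensity by a local noise
#'   level: the median intensity of the low peaks (below 5 percent of the
#'   window maximum) within +-50 Da of the match. When the window holds fewer
#'   than 4 such peaks — a centroided spectrum whose noise has already been
#'   removed — the noise floor falls back to 1 so S/N reduces to the raw
#'   intensity.
#' @examples
#' pk <- tibble::tibble(mz = c(467.37, 493.39), intensity = c(300, 290))
#' match_peak(pk, 467.373, 0.3)
#' @export
match_peak <- function(peaks, target_mz, tolerance = 0.3,
                       unit = c("Da", "ppm")) {
  unit <- match.arg(unit)
  stopifnot(tolerance > 0)
  tol_da <- if (unit == "Da") tolerance else target_mz * tolerance * 1e-6
  empty <- tibble::tibble(target_mz = numeric(), mz = numeric(),
                          intensity = numeric(), error_da = numeric(),
                          error_ppm = numeric(), snr = numeric())
  if (nrow(peaks) == 0) return(empty)
  hit <- which(abs(peaks$mz - target_mz) <= tol_da)
  if (length(hit) == 0) return(empty)
  best <- hit[which.max(peaks$intensity[hit])]
  window <- which(abs(peaks$mz - peaks$mz[best]) <= 50)
  window <- setdiff(window, best)
  low <- window[peaks$intensity[window] <
                  0.05 * max(peaks$intensity[window], 0)]
  noise <- if (length(low) < 4) 1 else
    max(1, stats::median(peaks$intensity[low]))
  tibble::tibble(
    target_mz = target_mz,
    mz = peaks$mz[best],
    intensity = peaks$intensity[best],
    error_da = peaks$mz[best] - target_mz,
    error_ppm = (peaks$mz[best] - target_mz) / target_mz * 1e6,
    snr = peaks$intensity[best] / noise
  )
}
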