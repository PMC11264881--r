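#' MS/MS spectrum
#'
#' Container for one fragmentation (MS/MS) spectrum: precursor m/z in Da and a
#' peak list of (fragment m/z, intensity) pairs. Peaks are stored sorted by
#' ascending m/z; at least one peak is required and intensities must be finite
#' and non-negative.
#'
#' @param spectrum_id Identifier.
#' @param precursor_mz Precursor m/z in Da (> 0).
#' @param mz Numeric vector of fragment m/z values.
#' @param intensity Numeric vector of fragment intensities.
#' @return An object of class `ms2_spectrum`.
#' @export
ms2_spectrum <- function(spectrum_id, precursor_mz, mz, intensity) {
  if (length(mz) != length(intensity) || length(mz) < 1L)
    format_error("spectrum '%s': need >= 1 (mz, intensity) pair", spectrum_id)
  if (!is.finite(precursor_mz) || precursor_mz <= 0)
    format_error("spectrum '%s': precursor m/z must be a positive number", spectrum_id)
  if (any(!is.finite(mz)) || any(!is.finite(intensity)) || any(intensity < 0))
    format_error("spectrum '%s': peaks must be finite with non-negative intensity",
                 spectrum_id)
  o <- order(mz)
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = as.numeric(precursor_mz),
                 mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o])),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("ms2_spectrum '%s': precursor m/z %.4f, %d peaks\n",
              x$spectrum_id, x$precursor_mz, length(x$mz)))
  invisible(x)
}

#' Read MS/MS spectra from a Mascot Generic Format (MGF) file
#'
#' Supports the plain MGF dialect used for spectral exchange: `BEGIN IONS` /
#' `END IONS` blocks, a `PEPMASS=` line (first number taken as precursor m/z),
#' optional `TITLE=`/other `KEY=value` headers, and one `mz intensity` pair
#' per peak line. Peaks are returned sorted by ascending m/z.
#'
#' @param path Path to an MGF file.
#' @return A list of [ms2_spectrum] objects (empty list for an empty file).
#' @export
read_mgf <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  spectra <- list()
  in_block <- FALSE
  pep <- NA_real_; title <- NULL; mz <- c(); inten <- c(); nblock <- 0L
  for (ln in lines) {
    if (ln == "BEGIN IONS") {
      if (in_block) format_error("nested BEGIN IONS in '%s'", path)
      in_block <- TRUE; nblock <- nblock + 1L
      pep <- NA_real_; title <- NULL; mz <- c(); inten <- c()
    } else if (ln == "END IONS") {
      if (!in_block) format_error("END IONS without BEGIN IONS in '%s'", path)
      if (is.na(pep)) format_error("spectrum block %d lacks PEPMASS in '%s'", nblock, path)
      id <- title %||% sprintf("spectrum_%d", nblock)
      spectra[[length(spectra) + 1L]] <- ms2_spectrum(id, pep, mz, inten)
      in_block <- FALSE
    } else if (in_block) {
      if (grepl("=", ln, fixed = TRUE)) {
        key <- toupper(sub("=.*$", "", ln))
        val <- sub("^[^=]*=", "", ln)
        if (key == "PEPMASS") {
          pep <- suppressWarnings(as.numeric(strsplit(trimws(val), "\\s+")[[1]][1]))
          if (is.na(pep)) format_error("non-numeric PEPMASS in '%s'", path)
        } else if (key == "TITLE") {
          title <- trimws(val)
        }
      } else {
        parts <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1]]))
        if (length(parts) < 2 || any(is.na(parts[1:2])))
          format_error("non-numeric peak line '%s' in '%s'", ln, path)
        mz <- c(mz, parts[1]); inten <- c(inten, parts[2])
      }
    }
  }
  if (in_block) format_error("unterminated BEGIN IONS block in '%s'", path)
  spectra
}

#' Write MS/MS spectra to an MGF file
#'
#' @param spectra A list of [ms2_spectrum] objects.
#' @param path Output file path.
#' @return Invisibly, `spectra`.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (sp in spectra) {
    stopifnot(inherits(sp, "ms2_spectrum"))
    writeLines(c("BEGIN IONS",
                 sprintf("TITLE=%s", sp$spectrum_id),
                 sprintf("PEPMASS=%s", format(sp$precursor_mz, digits = 12)),
                 paste(format(sp$mz, digits = 12, trim = TRUE),
                       format(sp$intensity, digits = 12, trim = TRUE)),
                 "END IONS", ""), con)
  }
  invisible(spectra)
}
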