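#' Read a spectrum from disk
#'
#' Reads a single-sample spectrum from a CSV file (columns
#' `wavenumber_cm1,absorbance`, header required, comma separator, dot
#' decimal) or from a JCAMP-DX file written by [write_spectrum()]. The
#' result is validated and stored with descending wavenumber.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"jcamp"`.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension (for JCAMP, the `##TITLE` record when present).
#' @return An [ftir_spectrum()].
#' @seealso [write_spectrum()], [align_to_grid()]
#' @export
read_spectrum <- function(path, format = c("csv", "jcamp"),
                          sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sample_id) && format == "csv") {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (format == "csv") {
    df <- utils::read.csv(path, header = TRUE)
    if (ncol(df) < 2) stop("CSV '", path, "' needs two columns", call. = FALSE)
    if (!all(c("wavenumber_cm1", "absorbance") %in% names(df))) {
      stop("CSV '", path, "' must have header 'wavenumber_cm1,absorbance'",
           call. = FALSE)
    }
    ftir_spectrum(df$wavenumber_cm1, df$absorbance, sample_id)
  } else {
    read_jcamp(path, sample_id)
  }
}

#' Write a spectrum to disk
#'
#' CSV is written at full double precision so that a write/read cycle is
#' bit-identical. The JCAMP-DX writer emits an `XYDATA=(X++(Y..Y))` block in
#' AFFN form and requires a uniform wavenumber grid.
#'
#' @param s An [ftir_spectrum()].
#' @param path Output path.
#' @param format `"csv"` or `"jcamp"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, format = c("csv", "jcamp")) {
  format <- match.arg(format)
  stopifnot(is_spectrum(s))
  if (format == "csv") {
    lines <- c("wavenumber_cm1,absorbance",
               paste(num_chr(s$wavenumber), num_chr(s$absorbance), sep = ","))
    writeLines(lines, path)
  } else {
    write_jcamp(s, path)
  }
  invisible(path)
}

write_jcamp <- function(s, path) {
  wn <- s$wavenumber
  steps <- diff(wn)
  if (length(wn) > 1 &&
      max(abs(steps - steps[1])) > 1e-6 * abs(steps[1])) {
    stop("JCAMP-DX export requires a uniform wavenumber grid", call. = FALSE)
  }
  n <- length(wn)
  per_line <- 6L
  idx <- split(seq_len(n), ceiling(seq_len(n) / per_line))
  data_lines <- vapply(idx, function(i) {
    paste(sprintf("%.10g", c(wn[i[1]], s$absorbance[i])), collapse = " ")
  }, character(1))
  lines <- c(
    paste0("##TITLE=", s$sample_id),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ABSORBANCE",
    "##XFACTOR=1",
    "##YFACTOR=1",
    sprintf("##FIRSTX=%.10g", wn[1]),
    sprintf("##LASTX=%.10g", wn[n]),
    sprintf("##NPOINTS=%d", n),
    sprintf("##FIRSTY=%.10g", s$absorbance[1]),
    "##XYDATA=(X++(Y..Y))",
    data_lines,
    "##END="
  )
  writeLines(lines, path)
  invisible(path)
}

read_jcamp <- function(path, sample_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  get_ldr <- function(name) {
    rx <- paste0("^##", name, "=")
    hit <- grep(rx, lines, value = TRUE)
    if (length(hit) == 0) return(NULL)
    sub(rx, "", hit[1])
  }
  title <- get_ldr("TITLE")
  if (is.null(sample_id) || identical(sample_id, "")) sample_id <- title
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  npoints <- as.integer(get_ldr("NPOINTS"))
  firstx <- as.numeric(get_ldr("FIRSTX"))
  lastx <- as.numeric(get_ldr("LASTX"))
  xf <- as.numeric(get_ldr("XFACTOR")); if (is.na(xf)) xf <- 1
  yf <- as.numeric(get_ldr("YFACTOR")); if (is.na(yf)) yf <- 1
  start <- grep("^##XYDATA=", lines)
  if (length(start) == 0) stop("no XYDATA block in '", path, "'", call. = FALSE)
  end <- grep("^##END", lines)
  end <- end[end > start[1]][1]
  body <- lines[(start[1] + 1L):(end - 1L)]
  y <- unlist(lapply(strsplit(trimws(body), "[[:space:]]+"), function(tok) {
    as.numeric(tok[-1]) # first token per line is the X check value
  }))
  if (length(y) != npoints) {
    stop("JCAMP '", path, "': NPOINTS=", npoints, " but ", length(y),
         " ordinates found", call. = FALSE)
  }
  x <- seq(firstx, lastx, length.out = npoints) * xf
  ftir_spectrum(x, y * yf, sample_id)
}

#' Interpolate spectra onto a common wavenumber grid
#'
#' Linear interpolation only: higher-order schemes can invent curvature in
#' sharp bands. No extrapolation is performed; a grid point outside a
#' spectrum's support is an error.
#'
#' @param spectra A list of [ftir_spectrum()] objects (a single spectrum is
#'   accepted and wrapped).
#' @param grid Target wavenumber vector (any monotone order; output follows
#'   the descending convention).
#' @return A list of spectra on `grid`. Values at grid points already present
#'   in a spectrum are preserved exactly.
#' @export
align_to_grid <- function(spectra, grid) {
  if (is_spectrum(spectra)) spectra <- list(spectra)
  grid <- sort(as.numeric(grid), decreasing = TRUE)
  lapply(spectra, function(s) {
    stopifnot(is_spectrum(s))
    if (min(grid) < min(s$wavenumber) || max(grid) > max(s$wavenumber)) {
      stop("sample '", s$sample_id, "': target grid [", min(grid), ", ",
           max(grid), "] outside spectral support [", min(s$wavenumber),
           ", ", max(s$wavenumber), "]", call. = FALSE)
    }
    y <- stats::approx(rev(s$wavenumber), rev(s$absorbance), xout = grid,
                       method = "linear", ties = "ordered")$y
    ftir_spectrum(grid, y, s$sample_id)
  })
}
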