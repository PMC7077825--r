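#' Construct an FTIR spectrum
#'
#' A spectrum is a pair of equal-length vectors: a strictly monotone
#' wavenumber grid (cm^-1) and the absorbance sampled on it. Spectra are
#' stored with wavenumber *descending*, the conventional mid-infrared
#' plotting order; ascending input is reordered (with the absorbances
#' permuted accordingly).
#'
#' @param wavenumber Numeric vector of wavenumbers in cm^-1, strictly
#'   monotone.
#' @param absorbance Numeric vector of absorbances, same length as
#'   `wavenumber`.
#' @param sample_id Character scalar identifying the sample.
#' @return An object of class `ftir_spectrum`: a list with elements
#'   `wavenumber`, `absorbance`, `sample_id`.
#' @examples
#' s <- ftir_spectrum(seq(3000, 400, by = -4), rnorm(651, 0.2, 0.01), "demo")
#' print(s)
#' @export
ftir_spectrum <- function(wavenumber, absorbance, sample_id = "spectrum") {
  wavenumber <- as.numeric(wavenumber)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumber) != length(absorbance)) {
    stop("sample '", sample_id, "': wavenumber and absorbance lengths differ (",
         length(wavenumber), " vs ", length(absorbance), ")", call. = FALSE)
  }
  bad <- which(!is.finite(wavenumber) | !is.finite(absorbance))
  if (length(bad) > 0) {
    stop("sample '", sample_id, "': non-finite value at row ", bad[1],
         call. = FALSE)
  }
  d <- diff(wavenumber)
  if (length(d) > 0 && any(d >= 0) && any(d <= 0)) {
    off <- which(sign(d) != sign(d[1]))[1] + 1L
    stop("sample '", sample_id, "': wavenumber grid not strictly monotone ",
         "at row ", off, call. = FALSE)
  }
  if (length(d) > 0 && d[1] > 0) { # ascending input: store descending
    wavenumber <- rev(wavenumber)
    absorbance <- rev(absorbance)
  }
  structure(list(wavenumber = wavenumber, absorbance = absorbance,
                 sample_id = as.character(sample_id)),
            class = "ftir_spectrum")
}

is_spectrum <- function(x) inherits(x, "ftir_spectrum")

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat("ATR-FTIR spectrum '", x$sample_id, "': ", length(x$wavenumber),
      " points, ", format(max(x$wavenumber)), "-",
      format(min(x$wavenumber)), " cm^-1\n", sep = "")
  invisible(x)
}

#' @export
plot.ftir_spectrum <- function(x, ...,
                               xlab = expression(Wavenumber ~ (cm^-1)),
                               ylab = "Absorbance", type = "l") {
  graphics::plot(x$wavenumber, x$absorbance, xlim = rev(range(x$wavenumber)),
                 xlab = xlab, ylab = ylab, type = type, ...)
  invisible(x)
}

#' @export
as.data.frame.ftir_spectrum <- function(x, ...) {
  data.frame(wavenumber_cm1 = x$wavenumber, absorbance = x$absorbance)
}

# median grid spacing, always positive
grid_step <- function(s) {
  stats::median(abs(diff(s$wavenumber)))
}
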