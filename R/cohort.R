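#' Construct a cohort of spectra with per-animal metadata
#'
#' A cohort pairs a list of spectra with a metadata table holding, for each
#' sample, its group (`ND`, `D` or `D+I`) and blood glucose concentration in
#' mg/dL. Spectra and records are matched by `sample_id` and all spectra must
#' share one wavenumber grid (use [align_to_grid()] first if they do not).
#'
#' @param spectra List of [ftir_spectrum()] objects.
#' @param records Data frame with columns `sample_id`, `group`,
#'   `glycemia_mgdl`; one row per spectrum.
#' @return An object of class `ftir_cohort` with elements `spectra`,
#'   `records` and `grid` (the common descending wavenumber vector).
#' @export
ftir_cohort <- function(spectra, records) {
  stopifnot(is.list(spectra), is.data.frame(records))
  need <- c("sample_id", "group", "glycemia_mgdl")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records$sample_id <- as.character(records$sample_id)
  records$group <- as_group(records$group)
  records$glycemia_mgdl <- as.numeric(records$glycemia_mgdl)
  if (any(records$glycemia_mgdl <= 0)) {
    stop("glycemia must be positive", call. = FALSE)
  }
  if (anyDuplicated(records$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         records$sample_id[duplicated(records$sample_id)][1], call. = FALSE)
  }
  ids <- vapply(spectra, function(s) s$sample_id, character(1))
  if (!setequal(ids, records$sample_id) || length(ids) != nrow(records)) {
    stop("spectra and metadata sample_ids do not match one-to-one",
         call. = FALSE)
  }
  spectra <- spectra[match(records$sample_id, ids)]
  grid <- spectra[[1]]$wavenumber
  for (s in spectra) {
    if (length(s$wavenumber) != length(grid) ||
        any(abs(s$wavenumber - grid) > 1e-9)) {
      stop("sample '", s$sample_id, "' is not on the common grid; ",
           "run align_to_grid() first", call. = FALSE)
    }
  }
  rownames(records) <- NULL
  structure(list(spectra = spectra, records = records, grid = grid),
            class = "ftir_cohort")
}

#' @export
print.ftir_cohort <- function(x, ...) {
  tab <- table(x$records$group)
  cat("ATR-FTIR cohort: ", nrow(x$records), " samples (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "), grid ",
      format(max(x$grid)), "-", format(min(x$grid)), " cm^-1, ",
      length(x$grid), " points\n", sep = "")
  invisible(x)
}

# n x p absorbance matrix, rows = samples in record order
cohort_matrix <- function(cohort) {
  m <- do.call(rbind, lapply(cohort$spectra, function(s) s$absorbance))
  rownames(m) <- cohort$records$sample_id
  m
}

#' Write a cohort to a directory
#'
#' One CSV per spectrum (`<sample_id>.csv`, columns
#' `wavenumber_cm1,absorbance`, descending wavenumber) plus `metadata.csv`
#' with the schema `sample_id,group,glycemia_mgdl`. Optionally also one
#' JCAMP-DX file per spectrum.
#'
#' @param cohort An [ftir_cohort()].
#' @param dir Output directory (created if absent).
#' @param jcamp Also write a `.jdx` twin for every spectrum?
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, jcamp = FALSE) {
  stopifnot(inherits(cohort, "ftir_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$spectra) {
    write_spectrum(s, file.path(dir, paste0(s$sample_id, ".csv")), "csv")
    if (jcamp) {
      write_spectrum(s, file.path(dir, paste0(s$sample_id, ".jdx")), "jcamp")
    }
  }
  r <- cohort$records
  lines <- c("sample_id,group,glycemia_mgdl",
             paste(r$sample_id, as.character(r$group),
                   num_chr(r$glycemia_mgdl), sep = ","))
  writeLines(lines, file.path(dir, "metadata.csv"))
  invisible(dir)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' @param dir Directory containing `metadata.csv` and one `<sample_id>.csv`
#'   per sample.
#' @return An [ftir_cohort()].
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    stop("no metadata.csv in '", dir, "'", call. = FALSE)
  }
  records <- utils::read.csv(meta_path, header = TRUE,
                             colClasses = c(sample_id = "character"))
  spectra <- lapply(records$sample_id, function(id) {
    read_spectrum(file.path(dir, paste0(id, ".csv")), "csv", sample_id = id)
  })
  ftir_cohort(spectra, records)
}

#' Per-file validation diagnostics for a cohort directory
#'
#' Attempts to parse every spectrum listed in `metadata.csv` and reports, per
#' file, whether it validates and the error message otherwise.
#'
#' @param dir Cohort directory.
#' @return Data frame with columns `sample_id`, `ok`, `n_points`, `message`.
#' @export
validate_cohort_dir <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    stop("no metadata.csv in '", dir, "'", call. = FALSE)
  }
  records <- utils::read.csv(meta_path, header = TRUE,
                             colClasses = c(sample_id = "character"))
  rows <- lapply(records$sample_id, function(id) {
    res <- tryCatch(
      read_spectrum(file.path(dir, paste0(id, ".csv")), "csv", id),
      error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(sample_id = id, ok = FALSE, n_points = NA_integer_,
                 message = conditionMessage(res))
    } else {
      data.frame(sample_id = id, ok = TRUE,
                 n_points = length(res$wavenumber), message = "")
    }
  })
  do.call(rbind, rows)
}
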