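# Internal helpers shared across modules.

# Stable 31-bit polynomial string hash. Used to derive per-sample RNG
# substreams so that adding samples to a cohort config never perturbs the
# spectra of existing samples (the hash depends only on the sample_id, not on
# the sample's position in the cohort).
str_hash31 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Derive a deterministic 31-bit seed from a master seed and a string key.
derive_seed <- function(master, ...) {
  key <- paste(..., sep = "/")
  as.integer(((as.numeric(master) %% 2147483647) * 1103 + str_hash31(key)) %%
               2147483647)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Experimental group labels
#'
#' The three study arms: non-diabetic (`"ND"`), streptozotocin-diabetic
#' (`"D"`) and insulin-treated diabetic (`"D+I"`). All group columns in the
#' package are factors with these levels, in this order.
#'
#' @return Character vector `c("ND", "D", "D+I")`.
#' @export
group_levels <- function() c("ND", "D", "D+I")

as_group <- function(x) {
  g <- as.character(x)
  bad <- setdiff(unique(g), group_levels())
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected ND, D or D+I)", call. = FALSE)
  }
  factor(g, levels = group_levels())
}

# format a double so that read-back reproduces the identical binary value
num_chr <- function(x) sprintf("%.17g", x)
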