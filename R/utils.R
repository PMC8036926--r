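# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic half-up rounding used before grade-bin lookup, in place of
#' [base::round()]'s round-half-to-even. Published bin edges are printed at
#' integer (motor/respiratory items) or one-decimal (BMI, vitamin D)
#' precision; measurements are snapped to that precision first so that every
#' in-range value falls into exactly one closed bin.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a reproducible sub-seed (< 2^31) from a master seed and a component
# name, so that adding a simulation component never perturbs the draws of the
# others. Plain polynomial hash; all intermediates stay below 2^53.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- seed %% 2147483647
  for (b in utf8ToInt(name)) h <- (h * 69069 + b) %% 2147483647
  for (i in 1:3) h <- (h * 69069 + 1) %% 2147483647
  as.integer(h)
}

# Evaluate expr under a component-specific RNG substream, restoring the
# caller's RNG state afterwards.
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  expr
}

# Format numbers for TSV output without scientific notation and without
# spurious trailing zeros, so that identical inputs give byte-identical files.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    s <- format(v, scientific = FALSE, trim = TRUE, digits = 15)
    s
  }, character(1))
  out
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character",
                    na.strings = NULL, fileEncoding = "UTF-8", ...)
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "lopdkit")
  if (!nzchar(p)) stop("packaged resource not found: ", file, call. = FALSE)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
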