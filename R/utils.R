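`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a substream seed from a base seed by a fixed offset, keeping the
## result a valid 32-bit integer. Fixed offsets mean adding a condition or
## method never perturbs the streams of earlier tables.
.seedOffset <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% (.Machine$integer.max - 1L))
}

.assertScalarNumber <- function(x, field, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("invalid '%s': must be a single number in [%s, %s]",
                 field, format(min), format(max)), call. = FALSE)
  }
  invisible(x)
}

## Format a numeric column for TSV output with enough digits to round-trip
## through read.delim at double precision for practical purposes.
.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 15, trim = TRUE, scientific = NA)
  }, character(1))
  out
}

.writeTsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], .fmtNum)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
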