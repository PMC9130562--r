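## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a validation error
#'
#' Validation errors (bad inputs, malformed files, inconsistent
#' configuration) carry class `mosaicscan_validation_error` so callers --
#' notably the command line driver -- can map them to exit code 2.
#'
#' @param msg message, passed to [sprintf()] when `...` given.
#' @param ... sprintf arguments.
#' @noRd
ms_stop <- function(msg, ...) {
  if (length(list(...))) msg <- sprintf(msg, ...)
  stop(structure(
    class = c("mosaicscan_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ms_assert <- function(ok, msg, ...) {
  if (!isTRUE(ok)) ms_stop(msg, ...)
  invisible(TRUE)
}

## Seed derivation: one master seed fans out to independent stage seeds.
## Offsets are fixed so a pipeline run is a pure function of its config.
derive_seed <- function(seed, offset) {
  ms_assert(is.numeric(seed) && length(seed) == 1, "seed must be a single number")
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587L)
}

## Evaluate `code` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

## Strict half-open interval check used by interval consumers.
check_interval <- function(start, end) {
  ms_assert(all(end > start), "inverted or empty interval: end must exceed start")
  invisible(TRUE)
}

## Write a data.frame as the package's TSV dialect (NA -> "NA", no quotes).
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = "NA", check.names = FALSE, ...)
}

## Ordered unique chromosome names (order of first appearance, not lexical).
chrom_levels <- function(x) unique(as.character(x))
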