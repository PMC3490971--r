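#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published allele-frequency tables
#' round half up. Used only for display-layer formatting; all internal values
#' are kept at full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format a frequency for display (two decimals, half-up)
#'
#' @param x numeric vector of frequencies.
#' @return character vector such as "0.57".
#' @export
format_freq <- function(x) {
  formatC(round_half_up(x, 2), format = "f", digits = 2)
}

#' Format a percentage for display (integer, half-up)
#'
#' @param x numeric vector of proportions in \[0, 1\].
#' @return character vector such as "71%".
#' @export
format_percent <- function(x) {
  paste0(formatC(round_half_up(100 * x, 0), format = "d"), "%")
}

# Derive a stream-specific seed from a master seed. Keeps derived seeds
# within the 32-bit integer range.
derive_seed <- function(master, offset) {
  as.integer((as.double(master) * 48271 + offset) %% 2147483647L)
}

# Stable content hash for manifests: md5 of the deparsed object.
config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(x), tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}

# Write a tab-separated table with a metadata comment line (tool version +
# config hash), the convention for all pipeline outputs.
write_tsv_with_meta <- function(df, path, extra = NULL) {
  ver <- as.character(utils::packageVersion("freqscan"))
  meta <- sprintf("# freqscan %s%s", ver,
                  if (is.null(extra)) "" else paste0(" ", extra))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_table <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
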