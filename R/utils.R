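#' Stable identifier for an inventory record
#'
#' Computes a short, deterministic hexadecimal identifier from a resource's
#' best name and normalized URL key, so that identifiers are reproducible
#' across runs and machines. Uses a 32-bit FNV-1a hash over the UTF-8 bytes
#' of `name` and `url_key` joined by a tab.
#'
#' @param name Character vector of best names (case-sensitive).
#' @param url_key Character vector of normalized URL keys.
#' @return Character vector of 8-character lowercase hex identifiers.
#' @export
#' @examples
#' resource_id("PDB", "x.org")
resource_id <- function(name, url_key) {
  stopifnot(length(name) == length(url_key))
  vapply(paste(name, url_key, sep = "\t"), fnv1a32, character(1), USE.NAMES = FALSE)
}

# FNV-1a, 32-bit, carried out in double precision (exact below 2^53)
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor2(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# bitwXor on doubles that may exceed .Machine$integer.max
bitwXor2 <- function(a, b) {
  hi <- a %/% 2147483648
  lo <- a %% 2147483648
  lo <- bitwXor(as.integer(lo), as.integer(b))
  hi * 2147483648 + lo
}

#' Share of a count pair, as printed in a report
#'
#' Recomputes a "numerator/denominator (share)" statistic the way such counts
#' are quoted in papers and reports: as a proportion or percentage rounded to
#' a stated number of digits.
#'
#' @param numerator,denominator Non-negative counts; `denominator > 0`.
#' @param percent If `TRUE` (default) return a percentage, else a proportion.
#' @param digits Decimal digits to round to (default 1).
#' @return A single rounded number.
#' @export
#' @examples
#' count_ratio(2235, 3112)        # 71.8
#' count_ratio(439, 468, percent = FALSE, digits = 3)  # 0.938
count_ratio <- function(numerator, denominator, percent = TRUE, digits = 1) {
  stopifnot(is.numeric(numerator), is.numeric(denominator))
  if (any(denominator <= 0)) {
    abort("`denominator` must be positive.", class = "bioinventory_config_error")
  }
  scale <- if (percent) 100 else 1
  round(scale * numerator / denominator, digits)
}

# shared condition helpers ----------------------------------------------------

config_error <- function(msg) abort(msg, class = "bioinventory_config_error")
validation_error <- function(msg) abort(msg, class = "bioinventory_validation_error")

is_scalar_prob <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
}
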