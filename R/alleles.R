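## Allele tokens and cell formatting shared by readers, writers and keys.

#' Parse one allele token
#'
#' Y-STR alleles are named by repeat count; partial-repeat microvariants carry
#' one fractional digit (e.g. `"38.2"` for 38 full repeats plus 2 bases).
#'
#' @param token character scalar, e.g. `"17"` or `"38.2"`.
#' @return numeric repeat value.
#' @keywords internal
parse_allele <- function(token) {
  token <- trimws(token)
  if (!grepl("^[0-9]+(\\.[0-9])?$", token))
    stop("unparseable allele token: '", token, "'", call. = FALSE)
  x <- as.numeric(token)
  frac <- round(x %% 1, 1)
  if (x <= 0 || !frac %in% c(0, 0.1, 0.2, 0.3))
    stop("allele out of range (positive, fractional part .0/.1/.2/.3): '",
         token, "'", call. = FALSE)
  x
}

#' Format repeat values back to allele names
#'
#' Integers print without a decimal point; microvariants with one digit.
#' @param x numeric vector of repeat values.
#' @return character vector.
#' @keywords internal
format_allele <- function(x) {
  ifelse(abs(x - round(x)) < 1e-9,
         sprintf("%d", as.integer(round(x))),
         sprintf("%.1f", x))
}

## Cell <-> allele list. Empty cell / NA = null call (length-0 numeric).
parse_cell <- function(cell, sep = "-") {
  if (is.na(cell) || !nzchar(trimws(cell))) return(numeric(0))
  tokens <- strsplit(trimws(cell), paste0("[", sep, ",/]"))[[1]]
  tokens <- tokens[nzchar(tokens)]
  sort(vapply(tokens, parse_allele, numeric(1), USE.NAMES = FALSE))
}

format_cell <- function(alleles, sep = "-") {
  if (length(alleles) == 0) return("")
  paste(format_allele(sort(alleles)), collapse = sep)
}

#' Round half away from zero
#'
#' Display rounding used for parameter tables (base `round` rounds half to
#' even, which does not match conventional forensic reporting).
#' @param x numeric.
#' @param digits integer number of decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
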