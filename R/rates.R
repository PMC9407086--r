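## Packaged per-locus mutation-rate defaults and founder modal repeats.

# Per-generation father-son mutation rates, assembled from the published
# consensus magnitudes (slow loci like DYS426/DYS392 near 4e-4; rapidly
# mutating loci like DYS570/DYS576/DYS627/DYS449/DYS518 around 1e-2).
# Override any value through the sim config or the weights functions.
.default_rates <- c(
  DYS19 = 2.2e-3, DYS389I = 2.5e-3, DYS389II = 3.6e-3, DYS389b = 2.0e-3,
  DYS390 = 2.1e-3, DYS391 = 2.6e-3, DYS392 = 4.0e-4, DYS393 = 1.1e-3,
  DYS437 = 1.3e-3, DYS438 = 4.5e-4, DYS439 = 5.1e-3, DYS448 = 1.4e-3,
  DYS456 = 4.2e-3, DYS458 = 6.4e-3, DYS635 = 3.9e-3, YGATAH4 = 2.8e-3,
  `DYS385a/b` = 2.5e-3, DYS481 = 5.0e-3, DYS533 = 3.7e-3, DYS549 = 4.0e-3,
  DYS570 = 1.2e-2, DYS576 = 1.4e-2, DYS643 = 1.1e-3, DYS449 = 1.2e-2,
  DYS460 = 5.7e-3, DYS518 = 1.3e-2, DYS627 = 1.2e-2, `DYF387S1a/b` = 1.6e-2,
  DYS388 = 5.0e-4, DYS426 = 3.8e-4, DYS444 = 3.0e-3, DYS447 = 2.9e-3,
  DYS557 = 4.5e-3, DYS593 = 9.0e-4, DYS596 = 1.0e-3, DYS645 = 6.0e-4,
  `DYS527a/b` = 2.4e-3)

# founder repeat counts (population modal alleles); multi-copy loci list
# the two copies
.modal_repeats <- list(
  DYS19 = 15, DYS389I = 13, DYS389II = 29, DYS390 = 23, DYS391 = 10,
  DYS392 = 13, DYS393 = 12, DYS437 = 14, DYS438 = 10, DYS439 = 12,
  DYS448 = 19, DYS456 = 15, DYS458 = 17, DYS635 = 21, YGATAH4 = 12,
  `DYS385a/b` = c(13, 18), DYS481 = 25, DYS533 = 11, DYS549 = 12,
  DYS570 = 17, DYS576 = 18, DYS643 = 10, DYS449 = 30, DYS460 = 10,
  DYS518 = 38, DYS627 = 20, `DYF387S1a/b` = c(36, 38), DYS388 = 12,
  DYS426 = 11, DYS444 = 12, DYS447 = 25, DYS557 = 16, DYS593 = 15,
  DYS596 = 13, DYS645 = 8, `DYS527a/b` = c(20, 22))

#' Packaged per-locus mutation rates
#'
#' Default per-generation stepwise mutation rates for all panel loci
#' (including the derived DYS389b), on the order of published father-son
#' estimates. Used for median-joining locus weights and as simulator
#' defaults; override by passing your own named vector.
#'
#' @param loci optional subset of loci to return.
#' @return named numeric vector.
#' @export
default_mutation_rates <- function(loci = NULL) {
  if (is.null(loci)) return(.default_rates)
  loci <- normalize_locus(loci)
  missing_loci <- setdiff(loci, names(.default_rates))
  if (length(missing_loci))
    stop("no packaged rate for: ", paste(missing_loci, collapse = ", "))
  .default_rates[loci]
}

#' Read / write a locus mutation-rate table
#'
#' Tab-separated columns `locus, rate`.
#' @param path file path.
#' @return named numeric vector of rates.
#' @export
read_rate_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("locus", "rate") %in% names(df)))
    stop("rate table needs columns 'locus' and 'rate'")
  stats::setNames(as.numeric(df$rate), normalize_locus(df$locus))
}

#' @rdname read_rate_table
#' @param rates named numeric vector.
#' @export
write_rate_table <- function(rates, path) {
  utils::write.table(data.frame(locus = names(rates), rate = unname(rates)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
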