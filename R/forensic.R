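## Per-locus allele diversity, panel haplotype spectra, the four forensic
## parameters (FUH, HD, MP, DC) and microvariant/CNV/null screening.

# haplotype identity = tuple of sorted per-locus allele lists
haplotype_key <- function(profiles, loci) {
  vapply(seq_len(nrow(profiles)), function(i)
    paste(vapply(loci, function(l) format_cell(profiles[[l]][[i]]),
                 character(1)), collapse = "|"),
    character(1))
}

#' Per-locus allele frequencies
#'
#' For multi-copy loci the sorted allele list is one countable unit (a
#' per-locus "haplotype"), so e.g. DYS385a/b `13-17` is a single key. Null
#' calls are excluded from the denominator.
#'
#' @param profiles a `"str_profiles"` object (one population).
#' @param locus locus name.
#' @return object of class `"locus_freqs"`: list with `locus`, `n` (samples
#'   with a call) and `freqs` (named frequency vector).
#' @export
locus_frequencies <- function(profiles, locus) {
  if (!locus %in% names(profiles)) stop("locus not in profiles: ", locus)
  keys <- vapply(profiles[[locus]], format_cell, character(1))
  keys <- keys[nzchar(keys)]
  if (!length(keys)) stop("no non-null calls at ", locus)
  tab <- table(keys)
  structure(list(locus = locus, n = length(keys),
                 freqs = as.numeric(tab) / length(keys),
                 labels = names(tab)),
            class = "locus_freqs")
}

#' Gene diversity
#'
#' The unbiased per-locus diversity \eqn{GD = \frac{n}{n-1}(1 - \sum_i p_i^2)},
#' where \eqn{n} is the number of samples with a call and \eqn{p_i} the
#' allele (or multi-copy allele-list) frequencies.
#'
#' @param freqs a `"locus_freqs"` object, or a plain numeric frequency
#'   vector (then `n` must be given).
#' @param n sample count when `freqs` is a plain vector.
#' @return diversity in `[0, 1]`.
#' @export
gene_diversity <- function(freqs, n = NULL) {
  if (inherits(freqs, "locus_freqs")) {
    n <- freqs$n
    p <- freqs$freqs
  } else p <- freqs
  if (is.null(n) || n < 2) stop("gene diversity needs n >= 2")
  if (!length(p)) stop("empty frequency table")
  stopifnot(abs(sum(p) - 1) < 1e-9)
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Haplotype frequency spectrum
#'
#' Counts of distinct whole-panel haplotypes observed exactly k times.
#' Samples with a null call at any panel locus are excluded (with a
#' message). Haplotype identity is the tuple of sorted allele lists over the
#' panel loci, so duplicated alleles and microvariants simply make distinct
#' haplotypes.
#'
#' @param profiles a `"str_profiles"` object (one population).
#' @param panel a `"y_panel"`; its loci must all be present.
#' @param population label recorded in the result (defaults to the
#'   profiles' single population).
#' @return object of class `"hap_spectrum"`: list with `panel`,
#'   `population`, `n` (complete haplotypes) and `spectrum` (named integer
#'   vector, names = k).
#' @export
haplotype_spectrum <- function(profiles, panel, population = NULL) {
  if (!nrow(profiles)) stop("empty profile table")
  missing_loci <- setdiff(panel$loci, names(profiles))
  if (length(missing_loci))
    stop("profiles lack panel loci: ", paste(missing_loci, collapse = ", "))
  if (is.null(population)) {
    population <- unique(profiles$population)
    if (length(population) > 1)
      stop("profiles span several populations; pass them separately")
  }
  complete <- vapply(seq_len(nrow(profiles)), function(i)
    all(vapply(panel$loci, function(l) length(profiles[[l]][[i]]) > 0,
               logical(1))), logical(1))
  if (!all(complete))
    message(sum(!complete), " sample(s) with null calls excluded from the ",
            panel$name, " spectrum")
  profiles <- profiles[complete, , drop = FALSE]
  if (!nrow(profiles)) stop("no complete haplotypes under panel ", panel$name)
  counts <- table(haplotype_key(profiles, panel$loci))
  spec <- table(as.integer(counts))
  new_hap_spectrum(stats::setNames(as.integer(spec), names(spec)),
                   panel = panel$name, population = population)
}

#' Construct a spectrum from known counts
#'
#' Used to encode published spectra directly, e.g. a population in which 573
#' haplotypes were seen once, 30 twice, 9 three times, 6 four times and 1
#' five times.
#'
#' @param spectrum named integer vector: `spectrum[k]` = number of distinct
#'   haplotypes observed exactly `k` times (names are the k values).
#' @param panel,population labels.
#' @return a `"hap_spectrum"` object.
#' @export
#' @examples
#' s <- new_hap_spectrum(c(`1` = 573, `2` = 30, `3` = 9, `4` = 6, `5` = 1),
#'                       panel = "yfiler", population = "Pudong")
#' s$n  # 689
new_hap_spectrum <- function(spectrum, panel = "custom",
                             population = "unknown") {
  k <- as.integer(names(spectrum))
  if (any(is.na(k)) || any(k < 1)) stop("spectrum names must be counts >= 1")
  spectrum <- as.integer(spectrum)
  keep <- spectrum > 0
  structure(list(panel = panel, population = population,
                 n = sum(k * spectrum),
                 H = sum(spectrum),
                 spectrum = stats::setNames(spectrum[keep], k[keep])),
            class = "hap_spectrum")
}

#' @export
print.hap_spectrum <- function(x, ...) {
  cat(sprintf("Haplotype spectrum [%s / %s]: n = %d, H = %d\n",
              x$population, x$panel, x$n, x$H))
  print(x$spectrum)
  invisible(x)
}

#' Forensic summary parameters of a haplotype spectrum
#'
#' Computes, from a haplotype frequency spectrum with `n` samples and `H`
#' distinct haplotypes:
#' \itemize{
#'   \item FUH, fraction of unique haplotypes: `spectrum[1] / n`;
#'   \item MP, haplotype match probability: `sum_k spectrum[k] (k/n)^2`;
#'   \item HD, haplotype diversity: `(n/(n-1)) (1 - MP)`;
#'   \item DC, discrimination capacity: `H / n`.
#' }
#' Values are stored at full precision; `print` rounds half-up to 5
#' decimals, the conventional reporting precision.
#'
#' @param spectrum a `"hap_spectrum"` object.
#' @return object of class `"forensic_params"`: list with `panel`,
#'   `population`, `n`, `H`, `FUH`, `HD`, `MP`, `DC`.
#' @export
forensic_parameters <- function(spectrum) {
  stopifnot(inherits(spectrum, "hap_spectrum"))
  n <- spectrum$n
  if (n < 2) stop("forensic parameters need n >= 2")
  k <- as.integer(names(spectrum$spectrum))
  s <- as.numeric(spectrum$spectrum)
  mp <- sum(s * (k / n)^2)
  singletons <- if (any(k == 1)) s[k == 1] else 0
  structure(list(panel = spectrum$panel, population = spectrum$population,
                 n = n, H = spectrum$H,
                 FUH = singletons / n,
                 MP = mp,
                 HD = (n / (n - 1)) * (1 - mp),
                 DC = spectrum$H / n),
            class = "forensic_params")
}

#' @export
print.forensic_params <- function(x, digits = 5, ...) {
  cat(sprintf("Forensic parameters [%s / %s]\n", x$population, x$panel))
  cat(sprintf("  n = %d, H = %d\n", x$n, x$H))
  for (p in c("FUH", "HD", "MP", "DC"))
    cat(sprintf("  %-3s = %.*f\n", p, digits, round_half_up(x[[p]], digits)))
  invisible(x)
}

#' @export
as.data.frame.forensic_params <- function(x, ...) {
  data.frame(population = x$population, panel = x$panel, n = x$n, H = x$H,
             FUH = x$FUH, HD = x$HD, MP = x$MP, DC = x$DC,
             stringsAsFactors = FALSE)
}

#' Screen STR profiles for microvariants, duplications and null calls
#'
#' A microvariant is any allele with a nonzero fractional repeat part; a
#' copy-number variant (CNV) is a call with more alleles than the locus's
#' expected copy number; a null is a locus with no allele. A CNV whose
#' allele list contains a fractional allele appears in both categories.
#'
#' @param profiles a `"str_profiles"` object.
#' @param panel a `"y_panel"` giving expected copy numbers.
#' @return object of class `"variant_report"`: list of data frames
#'   `microvariants`, `cnvs` (`sample_id, locus, alleles`) and `nulls`
#'   (`sample_id, locus`), each sorted by locus then sample.
#' @export
variant_screen <- function(profiles, panel) {
  loci <- intersect(panel$loci, str_loci(profiles))
  mv <- cnv <- nul <- list()
  for (l in loci) {
    expected <- panel$copies[[l]]
    for (i in seq_len(nrow(profiles))) {
      a <- profiles[[l]][[i]]
      id <- profiles$sample_id[i]
      if (length(a) == 0) {
        nul[[length(nul) + 1L]] <- data.frame(sample_id = id, locus = l)
      } else {
        if (any(abs(a - round(a)) > 1e-9))
          mv[[length(mv) + 1L]] <- data.frame(
            sample_id = id, locus = l, alleles = format_cell(a))
        if (length(a) > expected)
          cnv[[length(cnv) + 1L]] <- data.frame(
            sample_id = id, locus = l, alleles = format_cell(a))
      }
    }
  }
  bind <- function(lst, cols) {
    if (!length(lst))
      return(stats::setNames(
        as.data.frame(replicate(length(cols), character(0),
                                simplify = FALSE)), cols))
    df <- do.call(rbind, lst)
    df[order(df$locus, df$sample_id), , drop = FALSE]
  }
  structure(list(microvariants = bind(mv, c("sample_id", "locus", "alleles")),
                 cnvs = bind(cnv, c("sample_id", "locus", "alleles")),
                 nulls = bind(nul, c("sample_id", "locus"))),
            class = "variant_report")
}

#' @export
print.variant_report <- function(x, ...) {
  cat(sprintf("Variant report: %d microvariant(s), %d CNV(s), %d null(s)\n",
              nrow(x$microvariants), nrow(x$cnvs), nrow(x$nulls)))
  invisible(x)
}

#' Microvariant-by-haplogroup contingency table
#'
#' Cross-tabulates carriers of a given fractional-repeat microvariant at one
#' locus against membership of a haplogroup clade (the clade or any of its
#' descendants), e.g. carriers of a ".2" allele at DYS518 versus the QR
#' clade.
#'
#' @param report a `"variant_report"`.
#' @param calls named character vector (sample id -> haplogroup label) or a
#'   data frame from [call_haplogroup()].
#' @param locus locus name.
#' @param fraction fractional offset defining the microvariant (e.g. `0.2`).
#' @param clade clade label membership is tested against.
#' @param tree a `"haplogroup_tree"` used to expand the clade.
#' @return 2x2 integer matrix, rows `carrier`/`non-carrier`, columns
#'   `in_clade`/`out_of_clade`.
#' @export
variant_haplogroup_crosstab <- function(report, calls, locus, fraction,
                                        clade, tree = yhaplogroup_tree()) {
  if (is.data.frame(calls))
    calls <- stats::setNames(calls$haplogroup, calls$sample_id)
  mv <- report$microvariants
  mv <- mv[mv$locus == locus, , drop = FALSE]
  has_frac <- vapply(mv$alleles, function(cell) {
    a <- parse_cell(cell)
    any(abs(round(a %% 1, 1) - fraction) < 1e-9)
  }, logical(1))
  carriers <- unique(mv$sample_id[has_frac])
  if (!all(carriers %in% names(calls)))
    stop("haplogroup call missing for carrier(s): ",
         paste(setdiff(carriers, names(calls)), collapse = ", "))
  members <- c(clade, tree_descendants(tree, clade))
  in_clade <- names(calls)[calls %in% members]
  n_in <- length(in_clade)
  carrier_in <- sum(carriers %in% in_clade)
  carrier_out <- length(carriers) - carrier_in
  noncarrier_in <- n_in - carrier_in
  noncarrier_out <- length(calls) - length(carriers) - noncarrier_in
  m <- matrix(c(carrier_in, noncarrier_in, carrier_out, noncarrier_out),
              nrow = 2,
              dimnames = list(c("carrier", "non-carrier"),
                              c("in_clade", "out_of_clade")))
  storage.mode(m) <- "integer"
  m
}
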