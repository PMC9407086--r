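# Fixtures built in code: published haplotype spectra and haplogroup
# frequency lists, plus small constructors used across tests.

# Haplotype frequency spectra of the two Shanghai Han populations under the
# four commercial panels (counts of haplotypes seen k times), with the
# published parameter values they must reproduce at 5-decimal rounding.
table1_spectra <- list(
  pudong = list(
    n = 689,
    yfiler          = c(`1` = 573, `2` = 30, `3` = 9, `4` = 6, `5` = 1),
    ppy23           = c(`1` = 630, `2` = 26, `3` = 1, `4` = 1),
    yfiler_plus     = c(`1` = 657, `2` = 16),
    yfiler_platinum = c(`1` = 669, `2` = 10)),
  chongming = list(
    n = 530,
    yfiler          = c(`1` = 388, `2` = 27, `3` = 9, `4` = 3, `5` = 3,
                        `6` = 3, `7` = 1, `9` = 1),
    ppy23           = c(`1` = 462, `2` = 15, `3` = 6, `4` = 2, `5` = 1,
                        `7` = 1),
    yfiler_plus     = c(`1` = 508, `2` = 8, `3` = 2),
    yfiler_platinum = c(`1` = 522, `2` = 4)))

table1_expected <- list(
  pudong = list(
    H   = c(yfiler = 619, ppy23 = 658, yfiler_plus = 673,
            yfiler_platinum = 679),
    FUH = c(yfiler = 0.83164, ppy23 = 0.91437, yfiler_plus = 0.95356,
            yfiler_platinum = 0.97097),
    HD  = c(yfiler = 0.99957, ppy23 = 0.99985, yfiler_plus = 0.99993,
            yfiler_platinum = 0.99996),
    MP  = c(yfiler = 0.00189, ppy23 = 0.00160, yfiler_plus = 0.00152,
            yfiler_platinum = 0.00149),
    DC  = c(yfiler = 0.89840, ppy23 = 0.95501, yfiler_plus = 0.97678,
            yfiler_platinum = 0.98549)),
  chongming = list(
    H   = c(yfiler = 435, ppy23 = 487, yfiler_plus = 518,
            yfiler_platinum = 526),
    FUH = c(yfiler = 0.73208, ppy23 = 0.87170, yfiler_plus = 0.95849,
            yfiler_platinum = 0.98491),
    HD  = c(yfiler = 0.99854, ppy23 = 0.99946, yfiler_plus = 0.99990,
            yfiler_platinum = 0.99997),
    MP  = c(yfiler = 0.00334, ppy23 = 0.00243, yfiler_plus = 0.00199,
            yfiler_platinum = 0.00192),
    DC  = c(yfiler = 0.82075, ppy23 = 0.91887, yfiler_plus = 0.97736,
            yfiler_platinum = 0.99245)))

# published terminal haplogroup frequency lists (percent)
hg_freqs_chongming <- c(
  C2 = 7.17, C = 0.19, D1a1a1 = 0.75, D = 0.19, N = 9.06, N1a1 = 4.53,
  O1a = 29.62, O1b2 = 0.19, O1b = 4.15, O2a1 = 13.4, O2a2a1a2 = 3.77,
  O2a2b1a1 = 9.43, O2a2b = 14.15, O2a2 = 1.13, O2 = 0.75, QR = 1.51)

hg_freqs_pudong <- c(
  C2 = 6.97, D1a1a1 = 1.31, N = 4.79, N1a1 = 2.47, O1a = 24.53,
  O1b2 = 0.15, O1b = 6.82, O2a1 = 22.35, O2a2a1a2 = 2.61,
  O2a2b1a1 = 10.89, O2a2b = 10.89, O2a2 = 1.89, O2 = 2.18, QR = 2.18)

# build an str_profiles object from a named list of per-sample allele lists
make_profiles <- function(pop, loci, ids = NULL) {
  n <- length(loci[[1]])
  if (is.null(ids)) ids <- sprintf("%s%02d", pop, seq_len(n))
  df <- data.frame(sample_id = ids, population = pop,
                   stringsAsFactors = FALSE)
  for (l in names(loci))
    df[[l]] <- lapply(loci[[l]], function(x) sort(as.numeric(x)))
  structure(df, class = c("str_profiles", "data.frame"))
}

# single-call profiles from an integer matrix (columns = loci)
profiles_from_matrix <- function(M, pop) {
  loci <- lapply(seq_len(ncol(M)), function(j) as.list(M[, j]))
  names(loci) <- colnames(M)
  make_profiles(pop, loci)
}

# net_haplotypes object straight from a vector matrix
haps_from_matrix <- function(M, counts = NULL) {
  if (is.null(counts))
    counts <- matrix(1L, nrow(M), 1, dimnames = list(NULL, "A"))
  structure(list(vectors = M, counts = counts,
                 members = as.list(paste0("s", seq_len(nrow(M)))),
                 loci = colnames(M), populations = colnames(counts)),
            class = "net_haplotypes")
}

quietly <- function(expr) suppressMessages(expr)
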