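test_that("gene diversity matches the closed form and its boundary cases", {
  # monomorphic locus
  expect_equal(gene_diversity(c(1), n = 50), 0)
  # n = 2, two distinct alleles
  expect_equal(gene_diversity(c(0.5, 0.5), n = 2), 1)
  expect_error(gene_diversity(c(1), n = 1), "n >= 2")

  # near-monomorphic locus, frequencies built from integer counts
  counts <- c(510, 8, 5, 4, 2, 1)   # 510/530 = 0.9623
  n <- sum(counts)
  p <- counts / n
  oracle <- (n / (n - 1)) * (1 - sum(p * p))  # direct summation
  expect_equal(gene_diversity(p, n = n), oracle, tolerance = 1e-12)
  expect_lt(oracle, 0.08)  # the low-diversity regime of a DYS645-like locus
})

test_that("locus frequencies treat multi-copy allele lists as one unit", {
  prof <- make_profiles("A", list(
    `DYS385a/b` = list(c(13, 17), c(17, 13), c(12, 18), numeric(0))))
  f <- locus_frequencies(prof, "DYS385a/b")
  expect_equal(f$n, 3)             # null call excluded
  expect_equal(sort(f$freqs), c(1 / 3, 2 / 3))  # 13-17 counted once per sample
  expect_equal(sum(f$freqs), 1, tolerance = 1e-12)
})

test_that("haplotype spectrum counts identical haplotypes", {
  panel <- ypanel("yfiler", loci = c("L1", "L2"))
  prof <- make_profiles("A", list(
    L1 = list(10, 10, 10, 11, 12),
    L2 = list(5, 5, 5, 5, 5)))
  sp <- haplotype_spectrum(prof, ypanel("custom", loci = c("L1", "L2")))
  expect_equal(sp$n, 5)
  expect_equal(sp$H, 3)
  expect_equal(sp$spectrum, c(`1` = 2L, `3` = 1L))
})

test_that("spectrum agrees with a brute-force group-by on simulated data", {
  cfg <- sim_config(n_founders = 60, n_generations = 60, n_sample = 50,
                    seed = 101, panel = ypanel("yfiler"))
  out <- simulate_population(cfg)
  panel <- ypanel("yfiler")
  sp <- quietly(haplotype_spectrum(out$str, panel))
  oracle <- spectrum_oracle(out$str, panel$loci)
  expect_equal(sp$spectrum[names(oracle)],
               stats::setNames(as.integer(oracle), names(oracle)))
  expect_equal(sum(as.integer(names(sp$spectrum)) * sp$spectrum), sp$n)
})

test_that("forensic parameters reproduce published values and invariants", {
  for (pop in names(table1_spectra)) {
    n_expected <- table1_spectra[[pop]]$n
    for (panel in c("yfiler", "ppy23", "yfiler_plus", "yfiler_platinum")) {
      sp <- new_hap_spectrum(table1_spectra[[pop]][[panel]],
                             panel = panel, population = pop)
      expect_equal(sp$n, n_expected, label = paste(pop, panel, "n"))
      fp <- forensic_parameters(sp)
      exp_tab <- table1_expected[[pop]]
      expect_equal(fp$H, unname(exp_tab$H[panel]),
                   label = paste(pop, panel, "H"))
      for (par in c("FUH", "HD", "MP", "DC"))
        expect_equal(round_half_up(fp[[par]], 5),
                     unname(exp_tab[[par]][panel]),
                     label = paste(pop, panel, par))
      # structural invariants
      expect_true(fp$FUH <= fp$DC && fp$DC <= 1)
      expect_gte(fp$MP, 1 / fp$n)
      expect_equal(fp$HD, (fp$n / (fp$n - 1)) * (1 - fp$MP),
                   tolerance = 1e-12)
    }
  }
})

test_that("spectrum-based parameters equal raw-count parameters", {
  set.seed(7)
  for (rep in 1:20) {
    counts <- table(sample(1:30, 60, replace = TRUE))
    sp <- new_hap_spectrum(table(as.integer(counts)))
    fp <- forensic_parameters(sp)
    orc <- params_from_counts_oracle(as.integer(counts))
    for (par in c("FUH", "HD", "MP", "DC"))
      expect_equal(fp[[par]], orc[[par]], tolerance = 1e-12)
  }
})

test_that("all-singleton spectrum attains the diversity maximum", {
  fp <- forensic_parameters(new_hap_spectrum(c(`1` = 40)))
  expect_equal(fp$FUH, 1)
  expect_equal(fp$DC, 1)
  expect_equal(fp$MP, 1 / 40)
  expect_equal(fp$HD, 1)
})

test_that("duplicating an existing haplotype never raises FUH or DC", {
  set.seed(13)
  for (rep in 1:10) {
    counts <- as.integer(table(sample(1:12, 25, replace = TRUE)))
    before <- params_from_counts_oracle(counts)
    pick <- sample(seq_along(counts), 1)
    counts[pick] <- counts[pick] + 1L
    sp <- new_hap_spectrum(table(counts))
    after <- forensic_parameters(sp)
    expect_lte(after$FUH, before$FUH + 1e-12)
    expect_lte(after$DC, before$DC + 1e-12)
  }
})

test_that("GD equals HD when the locus is the whole-panel haplotype", {
  cfg <- sim_config(n_founders = 50, n_generations = 50, n_sample = 40,
                    seed = 5, panel = ypanel("yfiler"))
  out <- simulate_population(cfg)
  panel <- ypanel("yfiler")
  sp <- quietly(haplotype_spectrum(out$str, panel))
  fp <- forensic_parameters(sp)
  # frequencies of whole haplotypes as "alleles"
  keys <- apply(sapply(panel$loci, function(l)
    sapply(out$str[[l]], paste, collapse = "-")), 1, paste, collapse = "|")
  tab <- table(keys)
  gd <- gene_diversity(as.numeric(tab) / sum(tab), n = sum(tab))
  expect_equal(gd, fp$HD, tolerance = 1e-12)
})

test_that("variant screen classifies microvariants, CNVs and nulls", {
  panel <- ypanel("yfiler_platinum")
  prof <- make_profiles("A", list(
    DYS19 = list(c(15, 16), 15, 15),          # duplication at single-copy
    `DYS385a/b` = list(c(12, 17.2), c(13, 17), c(13, 17)),  # microvariant
    `DYF387S1a/b` = list(c(36, 41, 42), c(36, 38), c(36, 38)),  # CNV
    DYS518 = list(38.2, 37, numeric(0))))
  rep <- variant_screen(prof, panel)
  expect_true(any(rep$cnvs$locus == "DYS19" & rep$cnvs$sample_id == "A01"))
  expect_true(any(rep$cnvs$locus == "DYF387S1a/b"))
  # two alleles at DYS385a/b is the expected copy number, not a CNV
  expect_false(any(rep$cnvs$locus == "DYS385a/b"))
  expect_true(any(rep$microvariants$locus == "DYS385a/b"))
  expect_true(any(rep$microvariants$locus == "DYS518"))
  expect_true(any(rep$nulls$locus == "DYS518" & rep$nulls$sample_id == "A03"))
})

test_that("microvariant-by-clade crosstab reproduces encoded counts", {
  # 22 carriers of a ".2" allele at DYS518, 21 of them in QR, out of 1219
  ids <- sprintf("s%04d", 1:1219)
  carriers <- ids[1:22]
  calls <- stats::setNames(rep("O1a", 1219), ids)
  calls[carriers[1:21]] <- "QR"
  calls[ids[23]] <- "QR"   # one non-carrier QR
  mv <- data.frame(sample_id = carriers, locus = "DYS518",
                   alleles = "38.2", stringsAsFactors = FALSE)
  rep <- structure(list(microvariants = mv,
                        cnvs = mv[0, ], nulls = mv[0, 1:2]),
                   class = "variant_report")
  tab <- variant_haplogroup_crosstab(rep, calls, "DYS518", 0.2, "QR")
  expect_equal(tab["carrier", "in_clade"], 21L)
  expect_equal(tab["carrier", "out_of_clade"], 1L)
  expect_equal(sum(tab), 1219L)

  # no carriers -> zero carrier row
  tab0 <- variant_haplogroup_crosstab(
    structure(list(microvariants = mv[0, ], cnvs = mv[0, ],
                   nulls = mv[0, 1:2]), class = "variant_report"),
    calls, "DYS518", 0.2, "QR")
  expect_equal(unname(tab0["carrier", ]), c(0L, 0L))
})

test_that("a clade-linked microvariant shows enrichment in simulation", {
  # seed a .2 microvariant into every QR founder lineage at one locus
  cfg <- sim_config(n_founders = 50, n_generations = 30, n_sample = 40,
                    founder_haplogroup_weights = c(QR = 0.3, O1a = 0.7),
                    microvariant_rate = 0, seed = 34,
                    panel = ypanel("yfiler"))
  out <- simulate_population(cfg)
  prof <- out$str
  qr <- names(out$true_haplogroups)[out$true_haplogroups == "QR"]
  for (i in seq_len(nrow(prof)))
    if (prof$sample_id[i] %in% qr)
      prof$DYS19[[i]] <- prof$DYS19[[i]] + 0.2
  repV <- variant_screen(prof, ypanel("yfiler"))
  tab <- variant_haplogroup_crosstab(repV, out$true_haplogroups,
                                     "DYS19", 0.2, "QR")
  # perfect linkage: all carriers in QR, none outside
  expect_gt(tab["carrier", "in_clade"], 0)
  expect_equal(tab["carrier", "out_of_clade"], 0L)
  or_num <- (tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)
  or_den <- (tab[1, 2] + 0.5) * (tab[2, 1] + 0.5)
  expect_gt(or_num / or_den, 1)
})
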