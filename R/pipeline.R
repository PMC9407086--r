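## End-to-end orchestration: simulate or load data, run the forensic,
## distance, haplogroup and network stages, write tables and a JSON report.

default_rst_loci <- function()
  setdiff(ypanel("yfiler")$loci, "DYS385a/b")

#' Run the full analysis pipeline
#'
#' Sequences the package's stages over one dataset: forensic parameters per
#' panel and population, variant screening, pairwise Rst (with MDS and a
#' neighbor-joining tree when at least three populations are present),
#' haplogroup calling with frequency tables and clade aggregates, PCA of
#' haplogroup frequencies, and the median-joining network. Stages whose
#' prerequisites are not met are skipped with a log entry. Deterministic
#' given the seed and inputs.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{simulate}{arguments for [sim_config()]; a divergent pair is
#'       simulated when `split_generations > 0` or `paired = TRUE`.
#'       Alternatively give `str_table` / `snp_table` file paths.}
#'     \item{panels}{panel names for the forensic stage (default: all four
#'       built-ins whose loci are present).}
#'     \item{rst_loci}{loci for the Rst stage (default: the single-copy
#'       17-locus panel set).}
#'     \item{network}{list: `haplogroup` (restrict to one called clade,
#'       default none), `loci`, `epsilon`.}
#'     \item{stages}{subset of `c("forensic", "variants", "distance",
#'       "haplogroup", "pca", "network")`; default all.}
#'     \item{outdir}{output directory (created).}
#'     \item{seed}{integer seed, overrides `simulate$seed`.}
#'   }
#' @return the run report (list), invisibly; also written as
#'   `report.json` in `outdir` together with per-stage TSV files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  outdir <- config$outdir %||% tempfile("ylineage_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||%
    c("forensic", "variants", "distance", "haplogroup", "pca", "network")
  seed <- as.integer(config$seed %||% config$simulate$seed %||% 1L)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  ## ---- inputs ----------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- seed
    paired <- isTRUE(sim_args$paired) ||
      (!is.null(sim_args$split_generations) && sim_args$split_generations > 0)
    sim_args$paired <- NULL
    cfg <- do.call(sim_config, sim_args)
    if (paired) {
      sim <- simulate_divergent_pair(cfg)
      str <- sim$str
      snp <- structure(rbind(as.data.frame(sim$popA$snp),
                             as.data.frame(sim$popB$snp)),
                       class = c("snp_profiles", "data.frame"))
      note("simulated divergent pair (split_generations = ",
           cfg$split_generations, ")")
    } else {
      sim <- simulate_population(cfg)
      str <- sim$str; snp <- sim$snp
      note("simulated single population")
    }
  } else {
    if (is.null(config$str_table)) stop("config needs 'simulate' or 'str_table'")
    str <- read_str_table(config$str_table)
    snp <- if (!is.null(config$snp_table)) read_snp_table(config$snp_table)
    note("loaded tables from disk")
  }
  pops <- split_populations(str)
  report <- list()

  ## ---- forensic stage --------------------------------------------------
  if ("forensic" %in% stages) {
    panel_names <- config$panels %||% ypanels()
    rows <- list()
    for (pn in panel_names) {
      panel <- ypanel(pn)
      if (!all(panel$loci %in% names(str))) {
        note("panel ", pn, " skipped (loci missing from data)")
        next
      }
      for (p in names(pops)) {
        sp <- suppressMessages(haplotype_spectrum(pops[[p]], panel))
        rows[[paste(pn, p)]] <- as.data.frame(forensic_parameters(sp))
      }
    }
    params <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    report$forensic <- params
    utils::write.table(params, file.path(outdir, "forensic_params.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## ---- variant screen --------------------------------------------------
  if ("variants" %in% stages) {
    panel <- ypanel(config$variant_panel %||% "yfiler_platinum")
    panel_ok <- all(panel$loci %in% names(str))
    if (!panel_ok) panel <- ypanel("yfiler")
    vr <- variant_screen(str, panel)
    report$variants <- list(microvariants = vr$microvariants,
                            cnvs = vr$cnvs, nulls = vr$nulls)
    utils::write.table(vr$microvariants,
                       file.path(outdir, "microvariants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(vr$cnvs, file.path(outdir, "cnvs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## ---- distance stage --------------------------------------------------
  if ("distance" %in% stages) {
    loci <- config$rst_loci %||% default_rst_loci()
    loci <- intersect(loci, names(str))
    if (length(pops) < 2) {
      note("distance stage skipped (needs >= 2 populations)")
    } else if (length(pops) == 2) {
      r <- suppressMessages(
        pairwise_rst(pops[[1]], pops[[2]], loci))
      report$distance <- list(pair = names(pops), rst = as.numeric(r))
      note("2 populations: pairwise Rst only, no MDS/NJ tree")
    } else {
      m <- rst_matrix(pops, loci)
      write_distance_matrix(m, file.path(outdir, "rst_matrix.tsv"))
      fit <- mds_rst(m)
      utils::write.table(
        data.frame(population = rownames(fit$points), fit$points),
        file.path(outdir, "mds_coordinates.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      tree <- neighbor_joining(pmax(unclass(m), 0))
      write_newick(tree, file.path(outdir, "nj_tree.nwk"))
      report$distance <- list(rst = unclass(m), mds_stress = fit$stress,
                              mds_method = fit$method,
                              newick = ape::write.tree(tree))
    }
  }

  ## ---- haplogroup stage ------------------------------------------------
  calls <- NULL
  if (("haplogroup" %in% stages || "network" %in% stages) &&
      !is.null(snp)) {
    tree_hg <- yhaplogroup_tree(config$haplogroup_tree)
    calls <- call_haplogroup(snp, tree_hg)
    if ("haplogroup" %in% stages) {
      freqs <- suppressMessages(haplogroup_frequencies(calls))
      agg <- do.call(rbind, lapply(unique(freqs$population), function(p) {
        data.frame(population = p,
                   clade = c("O", "O2", "N", "C"),
                   percent = vapply(c("O", "O2", "N", "C"), function(cl)
                     clade_frequency(freqs, cl, tree_hg, population = p),
                     numeric(1)), stringsAsFactors = FALSE)
      }))
      report$haplogroup <- list(frequencies = freqs, clade_aggregates = agg)
      utils::write.table(calls, file.path(outdir, "haplogroup_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(freqs, file.path(outdir, "haplogroup_freqs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else if ("haplogroup" %in% stages) {
    note("haplogroup stage skipped (no SNP table)")
  }

  ## ---- PCA stage -------------------------------------------------------
  if ("pca" %in% stages && !is.null(calls)) {
    freqs <- suppressMessages(haplogroup_frequencies(calls))
    wide <- stats::xtabs(percent_raw ~ population + haplogroup, data = freqs)
    if (nrow(wide) >= 3) {
      pc <- suppressMessages(haplogroup_pca(as.matrix(wide)))
      report$pca <- list(scores = pc$scores,
                         variance_explained = pc$variance_explained)
    } else note("PCA skipped (needs >= 3 populations)")
  }

  ## ---- network stage ---------------------------------------------------
  if ("network" %in% stages) {
    nloci <- config$network$loci %||% network_loci()
    strn <- str
    if (!is.null(calls) && !is.null(config$network$haplogroup)) {
      keep <- calls$sample_id[calls$haplogroup == config$network$haplogroup]
      strn <- new_str_profiles(str[str$sample_id %in% keep, , drop = FALSE])
      note("network restricted to haplogroup ", config$network$haplogroup,
           " (", nrow(strn), " samples)")
    }
    if (!all(setdiff(nloci, "DYS389b") %in% names(strn))) {
      note("network stage skipped (loci missing)")
    } else {
      haps <- suppressMessages(net_haplotypes(strn, nloci))
      wts <- weights_from_rates(default_mutation_rates(), nloci)
      if (nrow(haps$vectors) >= 2) {
        net <- build_network(haps, wts,
                             epsilon = config$network$epsilon %||% 0)
        anc <- ancestral_node(haps, wts)
        comp <- network_composition_summary(haps, wts, anc)
        write_network(net, file.path(outdir, "network"))
        report$network <- list(
          n_nodes = nrow(net$vectors), n_median = sum(net$is_median),
          cost = net$cost, ancestral = unname(anc$vector),
          composition = comp)
      } else note("network stage skipped (fewer than 2 distinct haplotypes)")
    }
  }

  ## ---- provenance ------------------------------------------------------
  tmp <- tempfile()
  hashed <- config[setdiff(names(config), "outdir")]  # content, not paths
  writeLines(paste(deparse(hashed), collapse = ""), tmp)
  report$provenance <- list(
    config_hash = unname(tools::md5sum(tmp)),
    seed = seed,
    package_version = as.character(utils::packageVersion("ylineage")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  unlink(tmp)
  report$log <- log
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
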