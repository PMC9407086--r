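## Forward-time Wright-Fisher simulation of male lineages: STR haplotypes
## under the single-step stepwise mutation model, inherited Y-SNP
## haplogroups, rare microvariant and duplication events.

#' Simulation configuration
#'
#' @param n_founders constant male population size.
#' @param n_generations generations of Wright-Fisher reproduction.
#' @param n_sample samples drawn (without replacement) per population.
#' @param founder_haplogroup_weights named probabilities over haplogroup
#'   labels of the built-in tree; founders draw their (immutable) lineage
#'   from these.
#' @param mutation_rates named per-locus per-generation stepwise rates;
#'   defaults to [default_mutation_rates()]. Rates apply per allele copy.
#' @param microvariant_rate per-allele per-generation probability of a
#'   partial-repeat event giving the allele a heritable ".2" offset.
#' @param duplication_rate per-allele per-generation probability of a copy
#'   gain (the call becomes a two-allele list, thereafter inherited).
#' @param split_generations divergence time used by
#'   [simulate_divergent_pair()].
#' @param seed integer RNG seed; the run is deterministic given the seed.
#' @param panel `"y_panel"` whose loci are simulated.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_founders = 100, n_generations = 200, n_sample = 100,
                       founder_haplogroup_weights = c(
                         O1a = 0.27, O2a1 = 0.18, O2a2b1a1 = 0.10,
                         O2a2b = 0.12, O1b = 0.06, C2 = 0.07, N = 0.07,
                         N1a1 = 0.04, O2a2a1a2 = 0.03, D1a1a1 = 0.01,
                         QR = 0.02, O2 = 0.02, O2a2 = 0.01),
                       mutation_rates = default_mutation_rates(),
                       microvariant_rate = 1e-4,
                       duplication_rate = 5e-5,
                       split_generations = 0,
                       seed = 1,
                       panel = ypanel("yfiler_platinum")) {
  founder_haplogroup_weights <-
    founder_haplogroup_weights / sum(founder_haplogroup_weights)
  stopifnot(n_founders >= 1, n_generations >= 0,
            n_sample >= 1, n_sample <= n_founders,
            split_generations >= 0,
            all(founder_haplogroup_weights >= 0),
            all(mutation_rates >= 0), all(mutation_rates <= 0.1),
            microvariant_rate >= 0, microvariant_rate <= 0.1,
            duplication_rate >= 0, duplication_rate <= 0.1)
  tree <- yhaplogroup_tree()
  unknown <- setdiff(names(founder_haplogroup_weights), tree$table$clade)
  if (length(unknown))
    stop("unknown haplogroup(s) in founder weights: ",
         paste(unknown, collapse = ", "))
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 n_sample = as.integer(n_sample),
                 founder_haplogroup_weights = founder_haplogroup_weights,
                 mutation_rates = mutation_rates,
                 microvariant_rate = microvariant_rate,
                 duplication_rate = duplication_rate,
                 split_generations = as.integer(split_generations),
                 seed = as.integer(seed), panel = panel),
            class = "sim_config")
}

# one allele "slot" per expected copy: multi-copy loci occupy two slots
panel_slots <- function(panel) {
  locus <- rep(panel$loci, panel$copies[panel$loci])
  copy <- unlist(lapply(panel$copies[panel$loci], seq_len), use.names = FALSE)
  data.frame(locus = locus, copy = copy, stringsAsFactors = FALSE)
}

init_state <- function(config) {
  slots <- panel_slots(config$panel)
  n <- config$n_founders
  A <- matrix(0, n, nrow(slots))
  for (s in seq_len(nrow(slots))) {
    modal <- .modal_repeats[[slots$locus[s]]]
    if (is.null(modal)) modal <- 12
    A[, s] <- modal[min(slots$copy[s], length(modal))]
  }
  w <- config$founder_haplogroup_weights
  hg <- sample(names(w), n, replace = TRUE, prob = w)
  list(A = A, A2 = matrix(NA_real_, n, nrow(slots)), hg = hg,
       slots = slots, mutations = 0L, allele_events = 0)
}

# one generation: paternal inheritance, then per-allele events
step_generation <- function(state, config) {
  n <- nrow(state$A)
  fathers <- sample.int(n, n, replace = TRUE)
  A <- state$A[fathers, , drop = FALSE]
  A2 <- state$A2[fathers, , drop = FALSE]
  hg <- state$hg[fathers]
  rates <- config$mutation_rates[state$slots$locus]
  rate_m <- matrix(rates, n, length(rates), byrow = TRUE)

  mutate <- function(M) {
    present <- !is.na(M)
    hit <- present & matrix(stats::runif(length(M)), n) < rate_m
    if (any(hit)) {
      step <- sample(c(-1, 1), sum(hit), replace = TRUE)
      M[hit] <- M[hit] + step
      low <- present & M < 1     # reflect at one repeat
      M[low] <- 2 - M[low]
    }
    list(M = M, n = sum(hit))
  }
  m1 <- mutate(A)
  m2 <- mutate(A2)
  expected_here <- sum(rate_m) + sum(rate_m[!is.na(A2)])
  A <- m1$M; A2 <- m2$M

  if (config$microvariant_rate > 0) {
    integerish <- abs(A - round(A)) < 1e-9
    mv <- integerish & matrix(stats::runif(length(A)), n) < config$microvariant_rate
    if (any(mv)) {
      # partial-repeat gain (+0.2) or loss (-0.8); both leave a ".2" allele
      off <- sample(c(0.2, -0.8), sum(mv), replace = TRUE)
      A[mv] <- pmax(A[mv] + off, 1.2)
    }
  }
  if (config$duplication_rate > 0) {
    dup <- is.na(A2) & matrix(stats::runif(length(A)), n) < config$duplication_rate
    A2[dup] <- A[dup]
  }
  state$A <- A; state$A2 <- A2; state$hg <- hg
  state$mutations <- state$mutations + m1$n + m2$n
  state$allele_events <- state$allele_events + expected_here
  state
}

state_to_profiles <- function(state, config, population, prefix) {
  n_keep <- config$n_sample
  idx <- sample.int(nrow(state$A), n_keep)
  slots <- state$slots
  ids <- sprintf("%s_%03d", prefix, seq_len(n_keep))
  df <- data.frame(sample_id = ids, population = population,
                   stringsAsFactors = FALSE)
  for (l in unique(slots$locus)) {
    cols <- which(slots$locus == l)
    df[[l]] <- lapply(idx, function(i) {
      a <- c(state$A[i, cols], state$A2[i, cols])
      sort(round(a[!is.na(a)], 1))
    })
  }
  str <- new_str_profiles(df)

  tree <- yhaplogroup_tree()
  tab <- tree$table
  snp <- data.frame(sample_id = ids, population = population,
                    stringsAsFactors = FALSE)
  for (m in tab$marker) snp[[m]] <- "A"
  for (i in seq_len(n_keep)) {
    cl <- state$hg[idx[i]]
    path <- c(tree_ancestors(tree, cl), cl)
    snp[i, tab$marker[match(path, tab$clade)]] <- "D"
  }
  snp <- structure(snp, class = c("snp_profiles", "data.frame"))
  list(str = str, snp = snp,
       true_haplogroups = stats::setNames(state$hg[idx], ids))
}

#' Simulate a male-lineage population
#'
#' Wright-Fisher reproduction over `n_generations`: each son draws a father
#' uniformly; every STR allele copy mutates with its per-locus rate by a
#' single repeat step (±1, reflecting at one repeat); rare events add a
#' heritable partial-repeat (".2") offset or duplicate an allele copy; the
#' Y-SNP haplogroup is inherited unchanged. Deterministic under the
#' config's seed.
#'
#' @param config a [sim_config()].
#' @param population population label for the sampled profiles.
#' @return list of class `"sim_output"`: `str` (`"str_profiles"`), `snp`
#'   (`"snp_profiles"`), `true_haplogroups` (named vector),
#'   `mutation_events` (STR mutations that occurred),
#'   `expected_mutations` (sum of per-allele rates over the run).
#' @export
simulate_population <- function(config, population = "pop1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  state <- init_state(config)
  for (g in seq_len(config$n_generations))
    state <- step_generation(state, config)
  out <- state_to_profiles(state, config, population, population)
  structure(c(out, list(mutation_events = state$mutations,
                        expected_mutations = state$allele_events,
                        config = config)),
            class = "sim_output")
}

#' Simulate a pair of diverging populations
#'
#' One ancestral population evolves for `n_generations`, is duplicated at
#' the split, and each daughter evolves independently for
#' `split_generations` more; `n_sample` males are then drawn from each.
#' With `split_generations = 0` both samples come from the same gene pool
#' and pairwise Rst is statistically indistinguishable from zero.
#'
#' @param config a [sim_config()].
#' @param populations length-2 character vector of population labels.
#' @return list with elements `popA` and `popB` (each a `"sim_output"`) and
#'   `str` (both sample sets combined into one `"str_profiles"` table).
#' @export
simulate_divergent_pair <- function(config,
                                    populations = c("popA", "popB")) {
  stopifnot(inherits(config, "sim_config"), length(populations) == 2)
  set.seed(config$seed)
  state <- init_state(config)
  for (g in seq_len(config$n_generations))
    state <- step_generation(state, config)
  stateA <- state; stateB <- state
  for (g in seq_len(config$split_generations)) {
    stateA <- step_generation(stateA, config)
    stateB <- step_generation(stateB, config)
  }
  outA <- state_to_profiles(stateA, config, populations[1], populations[1])
  outB <- state_to_profiles(stateB, config, populations[2], populations[2])
  mk <- function(o, s) structure(
    c(o, list(mutation_events = s$mutations,
              expected_mutations = s$allele_events, config = config)),
    class = "sim_output")
  combined <- new_str_profiles(rbind(as.data.frame(outA$str),
                                     as.data.frame(outB$str)))
  list(popA = mk(outA, stateA), popB = mk(outB, stateB), str = combined)
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("Simulated population: %d samples, %d STR mutations over the run\n",
              nrow(x$str), x$mutation_events))
  invisible(x)
}
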