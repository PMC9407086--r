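## Hierarchical Y-SNP haplogroup calling, frequency tables, clade
## aggregation and PCA of population haplogroup frequencies.

# 24-marker pedigree-tagging tree. Clade labels follow ISOGG nomenclature;
# each clade is defined by one binary marker. "Y" is the root (no marker).
.builtin_tree_df <- data.frame(
  clade = c("E", "D", "D1a1a1", "D1a2a", "C", "C2", "G",
            "IJK", "IJ", "I", "K", "N", "N1a1", "QR",
            "O", "O1a", "O1b", "O1b2", "O2", "O2a1", "O2a2",
            "O2a2a1a2", "O2a2b", "O2a2b1a1"),
  marker = c("M96", "JST021355", "N1", "P47", "M130", "M217", "M201",
             "M522", "M429", "M170", "M9", "M231", "M46", "M45",
             "P186", "M119", "M268", "M176", "M122", "KL1", "P201",
             "M7", "P164", "M117"),
  parent = c("Y", "Y", "D", "D", "Y", "C", "Y",
             "Y", "IJK", "IJ", "IJK", "K", "N", "K",
             "K", "O", "O", "O1b", "O", "O2", "O2",
             "O2a2", "O2a2", "O2a2b"),
  stringsAsFactors = FALSE)

new_haplogroup_tree <- function(df) {
  stopifnot(all(c("clade", "marker", "parent") %in% names(df)))
  if (anyDuplicated(df$clade)) stop("duplicated clade labels in tree")
  if (anyDuplicated(df$marker)) stop("duplicated defining markers in tree")
  roots <- setdiff(df$parent, df$clade)
  if (length(roots) != 1)
    stop("tree must have a single root; found: ", paste(roots, collapse = ", "))
  structure(list(table = df, root = roots), class = "haplogroup_tree")
}

#' The built-in 24-marker Y-SNP haplogroup tree
#'
#' Rooted clade hierarchy of the pedigree-tagging marker system: primary
#' haplogroups E-M96, D-JST021355, C-M130, G-M201 and IJK-M522 (splitting
#' into IJ-M429/I-M170 and K-M9, under which sit N-M231, O-P186 and QR-M45),
#' with the O subclades down to O2a2b1a1-M117.
#'
#' @param path optional TSV file with columns `clade, marker, parent` to load
#'   a custom tree instead of the built-in one.
#' @return an object of class `"haplogroup_tree"`.
#' @export
#' @examples
#' tr <- yhaplogroup_tree()
#' nrow(tr$table)  # 24 markers
yhaplogroup_tree <- function(path = NULL) {
  if (is.null(path)) return(new_haplogroup_tree(.builtin_tree_df))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  new_haplogroup_tree(df)
}

#' @rdname yhaplogroup_tree
#' @param tree a `"haplogroup_tree"`.
#' @export
write_haplogroup_tree <- function(tree, path) {
  utils::write.table(tree$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.haplogroup_tree <- function(x, ...) {
  cat(sprintf("Y-SNP haplogroup tree: %d clades, root '%s'\n",
              nrow(x$table), x$root))
  invisible(x)
}

# ancestors of a clade (exclusive), root-most first
tree_ancestors <- function(tree, clade) {
  tab <- tree$table
  anc <- character(0)
  cur <- clade
  repeat {
    p <- tab$parent[match(cur, tab$clade)]
    if (is.na(p) || p == tree$root) break
    anc <- c(p, anc)
    cur <- p
  }
  anc
}

tree_depth <- function(tree, clade) length(tree_ancestors(tree, clade)) + 1L

tree_descendants <- function(tree, clade) {
  tab <- tree$table
  out <- character(0)
  frontier <- clade
  while (length(frontier)) {
    kids <- tab$clade[tab$parent %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Call Y-SNP haplogroups
#'
#' Assigns each sample the deepest clade whose defining marker is derived
#' and whose typed ancestors are all derived. A no-call at an intermediate
#' marker does not block a deeper assignment: the derived state of a
#' descendant implies the ancestor, which is recorded as imputed. Samples
#' derived only at an internal marker (e.g. K-M9 with N/O/QR ancestral)
#' keep that internal label. Derived markers off the chosen root-to-label
#' path are reported as conflicts and clear `path_consistent`.
#'
#' @param profiles a `"snp_profiles"` table.
#' @param tree a `"haplogroup_tree"` (default: built-in 24-marker tree).
#' @return data frame with one row per sample: `sample_id`, `population`,
#'   `haplogroup` (`"unresolved"` when no marker supports any clade),
#'   `path_consistent`, `conflicts` and `imputed` (comma-separated marker
#'   lists, empty when none).
#' @export
call_haplogroup <- function(profiles, tree = yhaplogroup_tree()) {
  tab <- tree$table
  markers <- snp_markers(profiles)
  typed <- intersect(tab$marker, markers)
  if (!length(typed))
    stop("no tree marker is typed in the SNP table")
  depth <- vapply(tab$clade, function(cl) tree_depth(tree, cl), integer(1))

  one_call <- function(states) {
    der <- tab$clade[tab$marker %in% names(states)[states == "D"]]
    anc_state <- function(cl) {
      a <- tree_ancestors(tree, cl)
      m <- tab$marker[match(a, tab$clade)]
      s <- states[m]
      s[is.na(s)] <- "N"   # untyped ancestor treated as no-call
      stats::setNames(s, a)
    }
    # candidate clades: derived marker, no typed-ancestral ancestor
    ok <- vapply(der, function(cl) !any(anc_state(cl) == "A"), logical(1))
    cand <- der[ok]
    if (!length(cand))
      return(list(label = "unresolved", consistent = FALSE,
                  conflicts = "", imputed = ""))
    # deepest candidate; ties broken by tree (row) order
    d <- depth[match(cand, tab$clade)]
    cand <- cand[order(-d, match(cand, tab$clade))]
    label <- cand[1]
    path <- c(tree_ancestors(tree, label), label)
    off <- setdiff(der, path)
    imput <- names(which(anc_state(label) == "N"))
    imput_m <- tab$marker[match(imput, tab$clade)]
    imput_m <- imput_m[imput_m %in% names(states)]  # only typed no-calls
    list(label = label, consistent = length(off) == 0,
         conflicts = paste(sort(tab$marker[match(off, tab$clade)]),
                           collapse = ","),
         imputed = paste(sort(imput_m), collapse = ","))
  }

  res <- lapply(seq_len(nrow(profiles)), function(i) {
    st <- vapply(markers, function(m) profiles[[m]][i], character(1))
    one_call(st)
  })
  data.frame(sample_id = profiles$sample_id,
             population = profiles$population,
             haplogroup = vapply(res, `[[`, character(1), "label"),
             path_consistent = vapply(res, `[[`, logical(1), "consistent"),
             conflicts = vapply(res, `[[`, character(1), "conflicts"),
             imputed = vapply(res, `[[`, character(1), "imputed"),
             stringsAsFactors = FALSE)
}

#' Haplogroup frequency table
#'
#' Percent frequencies of terminal haplogroup calls per population.
#' Unresolved samples are excluded from the denominator (with a message).
#'
#' @param calls data frame from [call_haplogroup()].
#' @param digits display rounding for the `percent` column (half-up);
#'   `percent_raw` keeps full precision.
#' @return data frame `population, haplogroup, n, percent, percent_raw`.
#' @export
haplogroup_frequencies <- function(calls, digits = 2) {
  unres <- calls$haplogroup == "unresolved"
  if (any(unres))
    message(sum(unres), " unresolved sample(s) excluded from denominators")
  calls <- calls[!unres, , drop = FALSE]
  if (!nrow(calls)) stop("no resolved haplogroup calls")
  out <- do.call(rbind, lapply(split(calls, calls$population), function(d) {
    tab <- table(d$haplogroup)
    data.frame(population = d$population[1], haplogroup = names(tab),
               n = as.integer(tab),
               percent_raw = 100 * as.integer(tab) / nrow(d),
               stringsAsFactors = FALSE)
  }))
  out$percent <- round_half_up(out$percent_raw, digits)
  rownames(out) <- NULL
  out[, c("population", "haplogroup", "n", "percent", "percent_raw")]
}

#' Cumulative clade frequency
#'
#' Sums a population's frequencies over a clade and all of its descendants
#' present in the frequency vector (aggregation follows the tree structure,
#' not the observed labels, so e.g. "O2" aggregates O2a1, O2a2, O2a2b, ...).
#'
#' @param freqs either a named numeric vector (haplogroup -> percent) or the
#'   data frame from [haplogroup_frequencies()] (then `population` must
#'   identify one population unless only one is present).
#' @param clade clade label to aggregate.
#' @param tree a `"haplogroup_tree"`.
#' @param population population selector when `freqs` is a data frame.
#' @return cumulative percent (numeric scalar).
#' @export
#' @examples
#' v <- c(N = 9.06, N1a1 = 4.53, O1a = 29.62)
#' clade_frequency(v, "N")  # 13.59
clade_frequency <- function(freqs, clade, tree = yhaplogroup_tree(),
                            population = NULL) {
  if (is.data.frame(freqs)) {
    if (!is.null(population))
      freqs <- freqs[freqs$population == population, , drop = FALSE]
    if (length(unique(freqs$population)) > 1)
      stop("multiple populations in 'freqs'; give 'population'")
    freqs <- stats::setNames(freqs$percent, freqs$haplogroup)
  }
  if (!clade %in% c(tree$table$clade, tree$root))
    stop("unknown clade: ", clade)
  members <- c(clade, tree_descendants(tree, clade))
  if (clade == tree$root) members <- c(members, tree$table$clade)
  sum(freqs[names(freqs) %in% members])
}

#' PCA of population haplogroup frequencies
#'
#' Principal component analysis of a populations x clades frequency matrix,
#' by default in correlation mode (columns standardized). Constant columns
#' are dropped with a message. Component signs follow the convention that
#' each component's largest-magnitude loading is positive.
#'
#' @param freq_table numeric matrix or data frame, rows = populations
#'   (rownames), columns = haplogroup frequencies.
#' @param mode `"correlation"` (standardize columns) or `"covariance"`.
#' @return list with `scores` (populations x 2), `variance_explained`
#'   (percent per component, non-increasing), `loadings` and `mode`.
#' @export
haplogroup_pca <- function(freq_table, mode = c("correlation", "covariance")) {
  mode <- match.arg(mode)
  x <- as.matrix(freq_table)
  if (nrow(x) < 3 || ncol(x) < 2)
    stop("need at least 3 populations and 2 clades")
  const <- apply(x, 2, function(v) stats::var(v) < .Machine$double.eps)
  if (any(const)) {
    message("dropping constant column(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  p <- stats::prcomp(x, center = TRUE, scale. = (mode == "correlation"))
  # sign convention: largest |loading| positive
  for (j in seq_len(ncol(p$rotation))) {
    k <- which.max(abs(p$rotation[, j]))
    if (p$rotation[k, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  ve <- 100 * p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, 1:2, drop = FALSE],
       variance_explained = ve,
       loadings = p$rotation,
       mode = mode)
}
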