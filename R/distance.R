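## AMOVA-based Rst between populations, multidimensional scaling and
## distance-matrix I/O.

# Repeat-score matrix: rows = usable samples, columns = chosen loci.
# Single-copy integer loci only; samples with a null or duplicated call at
# a chosen locus are dropped; microvariant alleles enter with their decimal
# value.
repeat_scores <- function(profiles, loci, dys389ii = c("raw", "minus_389I")) {
  dys389ii <- match.arg(dys389ii)
  m <- matrix(NA_real_, nrow(profiles), length(loci),
              dimnames = list(profiles$sample_id, loci))
  for (j in seq_along(loci)) {
    a <- profiles[[loci[j]]]
    ok <- lengths(a) == 1L
    m[ok, j] <- unlist(a[ok])
  }
  if (dys389ii == "minus_389I" && "DYS389II" %in% loci &&
      "DYS389I" %in% names(profiles)) {
    i1 <- vapply(profiles$DYS389I, function(x)
      if (length(x) == 1) x else NA_real_, numeric(1))
    m[, "DYS389II"] <- m[, "DYS389II"] - i1
  }
  keep <- stats::complete.cases(m)
  m[keep, , drop = FALSE]
}

# variance components of a two-level AMOVA on squared Euclidean repeat-score
# distances
amova_components <- function(groups) {
  ss_pairs <- function(x) {
    # sum over i<j of squared distance, via column sums of squares
    n <- nrow(x)
    if (n < 2) return(0)
    sum(vapply(seq_len(ncol(x)), function(j) {
      v <- x[, j]
      n * sum(v^2) - sum(v)^2
    }, numeric(1)))  # = sum_{i<j} (v_i - v_j)^2 summed over loci... times 1
  }
  N <- sum(vapply(groups, nrow, integer(1)))
  K <- length(groups)
  total <- do.call(rbind, groups)
  ss_total <- ss_pairs(total) / N
  ss_within <- sum(vapply(groups, function(g) ss_pairs(g) / nrow(g),
                          numeric(1)))
  ms_among <- (ss_total - ss_within) / (K - 1)
  ms_within <- ss_within / (N - K)
  n_k <- vapply(groups, nrow, integer(1))
  n_c <- (N - sum(n_k^2) / N) / (K - 1)
  sigma_among <- (ms_among - ms_within) / n_c
  list(sigma_among = sigma_among, ms_within = ms_within)
}

#' Pairwise Rst between two populations
#'
#' Analysis of molecular variance on repeat scores: per-sample vectors of
#' repeat counts over single-copy loci, squared-difference distances
#' \eqn{d(i,j) = \sum_l (a_{il} - a_{jl})^2}, variance components
#' \eqn{\sigma^2_{among}} and mean squares within, and
#' \eqn{R_{st} = \sigma^2_{among} / (\sigma^2_{among} + MS_{within})}.
#' Slightly negative estimates are reported raw (attribute `"negative"`),
#' not truncated.
#'
#' @param popA,popB `"str_profiles"` objects.
#' @param loci single-copy loci to use; samples missing any are dropped.
#' @param dys389ii `"raw"` uses the DYS389II repeat count as typed;
#'   `"minus_389I"` subtracts DYS389I first.
#' @return Rst (numeric scalar, \eqn{\le 1}).
#' @export
pairwise_rst <- function(popA, popB, loci, dys389ii = "raw") {
  a <- repeat_scores(popA, loci, dys389ii)
  b <- repeat_scores(popB, loci, dys389ii)
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("fewer than 2 usable samples in a population")
  vc <- amova_components(list(a, b))
  denom <- vc$sigma_among + vc$ms_within
  r <- if (denom == 0) 0 else vc$sigma_among / denom
  if (r < 0) attr(r, "negative") <- TRUE
  r
}

#' Pairwise Rst matrix over several populations
#'
#' @param populations named list of `"str_profiles"` objects, or one
#'   `"str_profiles"` table split by its `population` column.
#' @inheritParams pairwise_rst
#' @return symmetric numeric matrix with zero diagonal, class
#'   `"rst_matrix"`.
#' @export
rst_matrix <- function(populations, loci, dys389ii = "raw") {
  if (inherits(populations, "str_profiles"))
    populations <- split_populations(populations)
  if (length(populations) < 3) stop("need at least 3 populations")
  labs <- names(populations)
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(labs)) for (j in seq_len(i - 1L)) {
    r <- pairwise_rst(populations[[i]], populations[[j]], loci, dys389ii)
    m[i, j] <- m[j, i] <- as.numeric(r)
  }
  structure(m, class = c("rst_matrix", "matrix", "array"))
}

#' Split a profile table by population
#' @param profiles a `"str_profiles"` object.
#' @return named list of single-population `"str_profiles"`.
#' @export
split_populations <- function(profiles) {
  lapply(split(seq_len(nrow(profiles)), profiles$population),
         function(idx) new_str_profiles(profiles[idx, , drop = FALSE]))
}

#' Read / write a square distance matrix
#'
#' Tab-separated square matrix with a leading label column and header row
#' (PHYLIP square matrices, which carry a count line first, are also read).
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (grepl("^\\s*[0-9]+\\s*$", first)) 1L else 0L
  header <- skip == 0L
  df <- utils::read.table(path, sep = "", header = header, skip = skip,
                          row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!header) colnames(m) <- rownames(m)
  storage.mode(m) <- "double"
  m
}

#' @rdname read_distance_matrix
#' @param m labeled square matrix.
#' @export
write_distance_matrix <- function(m, path) {
  df <- data.frame(population = rownames(m), unclass(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Kruskal stress-1 of a configuration
#'
#' \eqn{\sqrt{\sum (d_{ij} - \hat d_{ij})^2 / \sum d_{ij}^2}} where
#' \eqn{d_{ij}} are the input dissimilarities and \eqn{\hat d_{ij}} the
#' configuration distances (metric form; no monotone regression).
#'
#' @param d dissimilarity matrix.
#' @param coords configuration matrix (rows = points).
#' @return stress (fraction, \eqn{\ge 0}).
#' @export
stress1 <- function(d, coords) {
  d <- as.matrix(d)
  dhat <- as.matrix(stats::dist(coords))
  lo <- lower.tri(d)
  sqrt(sum((d[lo] - dhat[lo])^2) / sum(d[lo]^2))
}

#' Multidimensional scaling of an Rst matrix
#'
#' Classical (Torgerson) scaling — double-centering of \eqn{-D^2/2} and the
#' top-k eigenvectors scaled by the square roots of their eigenvalues —
#' optionally refined by Kruskal non-metric stress minimization
#' ([MASS::isoMDS()]) started from the classical configuration. Negative
#' dissimilarities (possible for near-identical populations under the raw
#' Rst estimator) are clamped to zero with a message.
#'
#' @param d symmetric dissimilarity matrix (e.g. from [rst_matrix()]).
#' @param k embedding dimension.
#' @param nonmetric run the non-metric refinement (skipped, with a message,
#'   when ties at zero make the dissimilarities degenerate).
#' @param maxit maximum isoMDS iterations.
#' @return list with `points` (n x k), `stress` (stress-1 of the returned
#'   configuration, as a fraction), `stress_classical` (stress-1 of the
#'   classical start), `eig` (classical eigenvalues) and `method`.
#' @export
mds_rst <- function(d, k = 2, nonmetric = TRUE, maxit = 200) {
  d <- as.matrix(d)
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (all(d == 0)) stop("degenerate all-zero distance matrix")
  if (any(d < 0)) {
    message("clamping ", sum(d < 0 & upper.tri(d)),
            " negative dissimilarit(ies) to 0")
    d[d < 0] <- 0
  }
  cs <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  pts <- cs$points
  method <- "classical"
  stress <- stress1(d, pts)
  if (nonmetric) {
    off <- d[lower.tri(d)]
    if (any(off <= 0)) {
      message("zero dissimilarities present; keeping the classical solution")
    } else {
      fit <- MASS::isoMDS(stats::as.dist(d), y = pts, k = k, maxit = maxit,
                          trace = FALSE)
      pts <- fit$points
      stress <- fit$stress / 100  # isoMDS reports percent
      method <- "nonmetric"
    }
  }
  rownames(pts) <- rownames(d)
  list(points = pts,
       stress = stress,
       stress_classical = stress1(d, cs$points),
       eig = cs$eig,
       method = method)
}
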