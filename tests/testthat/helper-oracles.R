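# Independent brute-force oracles, kept deliberately naive: they enumerate
# pairs/subsets explicitly and never reuse the package's computational
# shortcuts.

# two-group AMOVA Rst by explicit enumeration of all pairwise squared
# distances
amova_rst_oracle <- function(A, B) {
  X <- rbind(A, B)
  g <- rep(1:2, c(nrow(A), nrow(B)))
  N <- nrow(X); K <- 2
  d2 <- function(i, j) sum((X[i, ] - X[j, ])^2)
  ss_all <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) ss_all <- ss_all + d2(i, j)
  ss_total <- ss_all / N
  ss_within <- 0
  for (k in 1:2) {
    idx <- which(g == k)
    s <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx))
      if (a < b) s <- s + d2(idx[a], idx[b])
    ss_within <- ss_within + s / length(idx)
  }
  ms_among <- (ss_total - ss_within) / (K - 1)
  ms_within <- ss_within / (N - K)
  n_c <- (N - (nrow(A)^2 + nrow(B)^2) / N) / (K - 1)
  s2a <- (ms_among - ms_within) / n_c
  s2a / (s2a + ms_within)
}

# haplotype spectrum by naive group-by over pasted keys
spectrum_oracle <- function(profiles, loci) {
  keys <- sapply(seq_len(nrow(profiles)), function(i)
    paste(sapply(loci, function(l)
      paste(sort(profiles[[l]][[i]]), collapse = ",")), collapse = ";"))
  counts <- table(keys)
  table(as.integer(counts))
}

# weighted Manhattan distance, scalar
wdist <- function(x, y, w) sum(w * abs(x - y))

# MST total cost by Kruskal with explicit sorting (independent of Prim in
# the package)
mst_cost_oracle <- function(V, w) {
  m <- nrow(V)
  if (m < 2) return(0)
  edges <- NULL
  for (i in 1:(m - 1)) for (j in (i + 1):m)
    edges <- rbind(edges, c(i, j, wdist(V[i, ], V[j, ], w)))
  edges <- edges[order(edges[, 3]), , drop = FALSE]
  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  total <- 0; used <- 0
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) { parent[a] <- b; total <- total + edges[e, 3]; used <- used + 1 }
    if (used == m - 1) break
  }
  total
}

# greedy exhaustive Steiner-point search: repeatedly consider the
# component-wise medians of ALL node triples and add whichever lowers the
# spanning cost most, until no candidate helps; returns the final cost
steiner_cost_oracle <- function(V, w, max_add = 10) {
  repeat {
    base <- mst_cost_oracle(V, w)
    keys <- apply(V, 1, paste, collapse = "|")
    best_gain <- 0; best_m <- NULL; best_key <- NULL
    m <- nrow(V)
    if (m >= 3) for (i in 1:(m - 2)) for (j in (i + 1):(m - 1))
      for (k in (j + 1):m) {
        med <- apply(V[c(i, j, k), , drop = FALSE], 2,
                     function(a) sort(a)[2])
        kk <- paste(med, collapse = "|")
        if (kk %in% keys) next
        gain <- base - mst_cost_oracle(rbind(V, med), w)
        if (gain > best_gain + 1e-9 ||
            (abs(gain - best_gain) <= 1e-9 && !is.null(best_key) &&
             kk < best_key)) {
          best_gain <- gain; best_m <- med; best_key <- kk
        }
      }
    if (is.null(best_m) || best_gain <= 1e-9 || max_add == 0) return(base)
    V <- rbind(V, best_m)
    max_add <- max_add - 1
  }
}

# exhaustive weighted-medoid search over observed haplotypes
medoid_oracle <- function(V, counts, w) {
  scores <- sapply(seq_len(nrow(V)), function(i)
    sum(sapply(seq_len(nrow(V)), function(j)
      counts[j] * wdist(V[i, ], V[j, ], w))))
  best <- which(abs(scores - min(scores)) <= 1e-9)
  if (length(best) > 1) best <- best[counts[best] == max(counts[best])]
  if (length(best) > 1) {
    keys <- apply(V[best, , drop = FALSE], 1, function(v)
      paste(sprintf("%06d", v), collapse = ""))
    best <- best[order(keys)]
  }
  best[1]
}

# forensic parameters straight from raw per-haplotype counts
params_from_counts_oracle <- function(counts) {
  n <- sum(counts)
  list(FUH = sum(counts == 1) / n,
       MP = sum((counts / n)^2),
       HD = (n / (n - 1)) * (1 - sum((counts / n)^2)),
       DC = length(counts) / n)
}
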