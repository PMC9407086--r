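test_that("Rst vanishes without between-group variance; 1 at fixation", {
  # identical monomorphic populations: no variance anywhere, Rst = 0
  flat_a <- profiles_from_matrix(cbind(L1 = rep(10, 5)), "A")
  flat_b <- profiles_from_matrix(cbind(L1 = rep(10, 5)), "B")
  expect_equal(as.numeric(pairwise_rst(flat_a, flat_b, "L1")), 0,
               tolerance = 1e-12)

  # identical polymorphic multisets: the unbiased variance-component
  # estimator goes (slightly) negative, is flagged, and matches the oracle
  v <- c(10, 11, 12, 10, 11)
  a <- profiles_from_matrix(cbind(L1 = v), "A")
  b <- profiles_from_matrix(cbind(L1 = v), "B")
  r <- pairwise_rst(a, b, "L1")
  expect_equal(as.numeric(r), amova_rst_oracle(cbind(v), cbind(v)),
               tolerance = 1e-12)
  expect_lte(as.numeric(r), 0)
  expect_true(isTRUE(attr(r, "negative")))

  mono_a <- profiles_from_matrix(cbind(L1 = rep(10, 6)), "A")
  mono_b <- profiles_from_matrix(cbind(L1 = rep(14, 6)), "B")
  expect_equal(as.numeric(pairwise_rst(mono_a, mono_b, "L1")), 1)
})

test_that("Rst equals the brute-force AMOVA oracle on random instances", {
  set.seed(99)
  for (rep in 1:100) {
    nA <- sample(3:7, 1); nB <- sample(3:7, 1); L <- sample(2:4, 1)
    A <- matrix(sample(8:16, nA * L, replace = TRUE), nA,
                dimnames = list(NULL, paste0("L", 1:L)))
    B <- matrix(sample(8:16, nB * L, replace = TRUE), nB,
                dimnames = list(NULL, paste0("L", 1:L)))
    r_pkg <- as.numeric(pairwise_rst(profiles_from_matrix(A, "A"),
                                     profiles_from_matrix(B, "B"),
                                     paste0("L", 1:L)))
    r_orc <- amova_rst_oracle(A, B)
    expect_equal(r_pkg, r_orc, tolerance = 1e-10)
  }
})

test_that("Rst is symmetric, drops unusable samples, can be negative", {
  set.seed(3)
  A <- matrix(sample(10:14, 12, replace = TRUE), 6,
              dimnames = list(NULL, c("L1", "L2")))
  B <- matrix(sample(10:14, 12, replace = TRUE), 6,
              dimnames = list(NULL, c("L1", "L2")))
  pa <- profiles_from_matrix(A, "A"); pb <- profiles_from_matrix(B, "B")
  expect_equal(as.numeric(pairwise_rst(pa, pb, c("L1", "L2"))),
               as.numeric(pairwise_rst(pb, pa, c("L1", "L2"))),
               tolerance = 1e-12)
  # null and duplicated calls are excluded pairwise
  pa$L1[[1]] <- numeric(0)
  pa$L2[[2]] <- c(10, 12)
  r <- pairwise_rst(pa, pb, c("L1", "L2"))
  A_kept <- A[-(1:2), ]
  expect_equal(as.numeric(r), amova_rst_oracle(A_kept, B), tolerance = 1e-10)
  # near-identical groups can go slightly negative and are reported raw
  a2 <- profiles_from_matrix(cbind(L1 = c(10, 12, 10, 12)), "A")
  b2 <- profiles_from_matrix(cbind(L1 = c(10, 12, 11, 11)), "B")
  r2 <- pairwise_rst(a2, b2, "L1")
  if (as.numeric(r2) < 0) expect_true(isTRUE(attr(r2, "negative")))
})

test_that("rst_matrix is symmetric with zero diagonal and label-stable", {
  set.seed(17)
  mk <- function(pop) profiles_from_matrix(
    matrix(sample(10:15, 10, replace = TRUE), 5,
           dimnames = list(NULL, c("L1", "L2"))), pop)
  pops <- list(A = mk("A"), B = mk("B"), C = mk("C"))
  m <- rst_matrix(pops, c("L1", "L2"))
  expect_equal(unclass(m), t(unclass(m)), tolerance = 1e-12)
  expect_equal(unname(diag(m)), rep(0, 3))
  perm <- rst_matrix(pops[c("C", "A", "B")], c("L1", "L2"))
  expect_equal(unclass(perm[c("A", "B", "C"), c("A", "B", "C")]),
               unclass(m), tolerance = 1e-12)
  # identical populations: every off-diagonal entry equals the oracle's
  # (non-positive) value for duplicated multisets
  same <- list(A = pops$A,
               B = structure(transform(pops$A, population = "B"),
                             class = class(pops$A)),
               C = structure(transform(pops$A, population = "C"),
                             class = class(pops$A)))
  m0 <- rst_matrix(same, c("L1", "L2"))
  X <- cbind(sapply(pops$A$L1, identity), sapply(pops$A$L2, identity))
  r_dup <- amova_rst_oracle(X, X)
  expect_equal(unname(m0[upper.tri(m0)]), rep(r_dup, 3), tolerance = 1e-12)
  expect_true(all(m0[upper.tri(m0)] <= 0))
})

test_that("classical MDS recovers planar configurations", {
  set.seed(8)
  pts <- matrix(rnorm(10), 5, 2,
                dimnames = list(paste0("P", 1:5), NULL))
  d <- as.matrix(dist(pts))
  fit <- mds_rst(d, nonmetric = FALSE)
  # Procrustes: distances between embedded points match the input exactly
  expect_equal(as.matrix(dist(fit$points)), d, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(fit$stress_classical, 1e-8)
})

test_that("non-metric refinement never worsens stress over more iterations", {
  set.seed(21)
  d <- as.matrix(dist(matrix(rnorm(24), 8, 3)))
  d <- d + matrix(runif(64, 0, 0.3), 8); d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(paste0("P", 1:8), paste0("P", 1:8))
  one <- mds_rst(d, maxit = 1)
  many <- mds_rst(d, maxit = 100)
  expect_lte(many$stress, one$stress + 1e-9)
  expect_identical(many$method, "nonmetric")
})

test_that("duplicated populations embed at coincident coordinates", {
  d <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3,
              dimnames = list(c("A", "A2", "B"), c("A", "A2", "B")))
  fit <- quietly(mds_rst(d))   # zero off-diagonal keeps classical solution
  expect_lt(max(abs(fit$points["A", ] - fit$points["A2", ])), 1e-6)
  expect_error(mds_rst(matrix(0, 3, 3)), "degenerate")
})

test_that("NJ recovers additive trees exactly and matches ape", {
  set.seed(12)
  for (ntax in c(4, 5, 6, 8)) {
    tr0 <- ape::rtree(ntax)
    d <- ape::cophenetic.phylo(tr0)
    tr <- neighbor_joining(d)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
                 tolerance = 1e-10)
    ref <- ape::nj(d)
    expect_true(ape::all.equal.phylo(ape::unroot(tr), ape::unroot(ref),
                                     use.edge.length = FALSE))
  }
})

test_that("NJ three-taxon closed form and error handling", {
  d <- matrix(c(0, 3, 5, 3, 0, 4, 5, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  lens <- stats::setNames(tr$edge.length,
                          tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["A"]], (3 + 5 - 4) / 2)
  expect_equal(lens[["B"]], (3 + 4 - 5) / 2)
  expect_equal(lens[["C"]], (5 + 4 - 3) / 2)
  bad <- d; bad[1, 2] <- 9
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("NJ is deterministic under Q ties and stable to perturbation", {
  # perfectly symmetric distances: every Q entry ties
  d <- matrix(2, 4, 4); diag(d) <- 0
  dimnames(d) <- list(c("A", "B", "C", "D"), c("A", "B", "C", "D"))
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))

  set.seed(5)
  tr0 <- ape::rtree(6)
  d0 <- ape::cophenetic.phylo(tr0)
  base <- neighbor_joining(d0)
  eps <- matrix(runif(36, -1e-7, 1e-7), 6); eps <- (eps + t(eps)) / 2
  diag(eps) <- 0
  pert <- neighbor_joining(d0 + eps)
  expect_true(ape::all.equal.phylo(base, pert, use.edge.length = FALSE))
})

test_that("distance matrix files round-trip, including PHYLIP square", {
  m <- matrix(c(0, .1, .2, .1, 0, .3, .2, .3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tmp <- tempfile()
  write_distance_matrix(m, tmp)
  expect_equal(read_distance_matrix(tmp), m, ignore_attr = FALSE)
  phy <- tempfile()
  writeLines(c("3", "A 0 0.1 0.2", "B 0.1 0 0.3", "C 0.2 0.3 0"), phy)
  expect_equal(read_distance_matrix(phy), m)
})
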