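dist_mat <- function(m, bins = NULL) {
  attr(m, "bins") <- bins
  class(m) <- c("DistanceMatrix", class(m))
  m
}

test_that("shortest-path distances invert contact frequencies", {
  bins2 <- bin_fragments(tile_frag_map(build_toy_genome(
    n_chrom = 1, arm_lengths = list(c(20000, 20000)), rdna_chrom = NULL),
    20000), 1)
  # two bins, frequency 0.5 -> distance 2
  M <- contact_matrix(matrix(c(0, 0.5, 0.5, 0), 2), bins2)
  D <- contact_to_distance(M)
  expect_equal(D[1, 2], 2)

  # indirect path beats the direct edge: A-B-C = 10 + 1 < A-C = 20
  bins3 <- bin_fragments(tile_frag_map(build_toy_genome(
    n_chrom = 1, arm_lengths = list(c(20000, 40000)), rdna_chrom = NULL),
    20000), 1)
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.1
  m[2, 3] <- m[3, 2] <- 1
  m[1, 3] <- m[3, 1] <- 0.05
  D3 <- contact_to_distance(contact_matrix(m, bins3))
  expect_equal(D3[1, 3], 11)

  # disconnected graph is diagnosed
  md <- matrix(0, 3, 3); md[1, 2] <- md[2, 1] <- 1
  expect_error(contact_to_distance(contact_matrix(md, bins3)),
               "disconnected")
})

test_that("shortest paths match a Floyd-Warshall oracle on random instances", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    m <- matrix(0, n, n)
    ut <- upper.tri(m)
    vals <- ifelse(runif(sum(ut)) < 0.65, runif(sum(ut), 0.05, 2), 0)
    m[ut] <- vals
    m <- m + t(m)
    # ensure connectivity via a chain
    for (i in seq_len(n - 1)) if (m[i, i + 1] == 0) m[i, i + 1] <- m[i + 1, i] <- 0.5
    g <- build_toy_genome(n_chrom = 1,
                          arm_lengths = list(c(20000, (n - 1) * 20000)),
                          rdna_chrom = NULL)
    bins <- bead_bin_table(g)
    D <- contact_to_distance(contact_matrix(m, bins))
    W <- 1 / m
    W[m == 0] <- 0
    expect_equal(unclass(D), floyd_warshall(W), ignore_attr = TRUE)
    # triangle inequality
    for (k in 1:3) {
      ijk <- sample(n, 3)
      expect_lte(D[ijk[1], ijk[3]],
                 D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-9)
    }
  }
})

test_that("classical MDS recovers Euclidean configurations", {
  set.seed(17)
  X <- matrix(rnorm(30), 10, 3)
  D <- as.matrix(dist(X))
  st <- embed_3d(dist_mat(D))
  D2 <- as.matrix(dist(st[, c("x", "y", "z")]))
  expect_lt(max(abs(D2 - D)), 1e-6)

  # cross-check against stats::cmdscale as an independent implementation
  cmd <- cmdscale(D, k = 3)
  Dc <- as.matrix(dist(cmd))
  expect_lt(max(abs(D2 - Dc)), 1e-6)

  # unit square (rank 2): diagonals sqrt(2), third coordinate ~ 0
  sq <- matrix(c(0, 1, 1, sqrt(2),
                 1, 0, sqrt(2), 1,
                 1, sqrt(2), 0, 1,
                 sqrt(2), 1, 1, 0), 4)
  expect_warning(st2 <- embed_3d(dist_mat(sq)), "padding")
  expect_lt(max(abs(st2$z)), 1e-9)
  d2 <- as.matrix(dist(st2[, c("x", "y", "z")]))
  expect_equal(d2[1, 4], sqrt(2), tolerance = 1e-9)
  expect_equal(d2[2, 3], sqrt(2), tolerance = 1e-9)

  # duplicated point stays coincident
  Xd <- rbind(X, X[1, ])
  Dd <- as.matrix(dist(Xd))
  std <- embed_3d(dist_mat(Dd))
  expect_lt(sqrt(sum((std[11, c("x", "y", "z")] -
                        std[1, c("x", "y", "z")])^2)), 1e-8)
})

test_that("embedding is invariant to bin relabeling up to rigid motion", {
  set.seed(23)
  X <- matrix(rnorm(24), 8, 3)
  D <- as.matrix(dist(X))
  perm <- sample(8)
  s1 <- embed_3d(dist_mat(D))
  s2 <- embed_3d(dist_mat(D[perm, perm]))
  d1 <- as.matrix(dist(s1[, c("x", "y", "z")]))
  d2 <- as.matrix(dist(s2[, c("x", "y", "z")]))
  expect_equal(d2, d1[perm, perm], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("convex hull volume matches closed forms and Monte Carlo", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_hull_volume(cube), 1, tolerance = 1e-12)
  # regular tetrahedron of edge sqrt(2): volume 1/3
  tet <- matrix(c(0, 0, 0, 1, 1, 0, 1, 0, 1, 0, 1, 1), 4, 3, byrow = TRUE)
  expect_equal(convex_hull_volume(tet), 1 / 3, tolerance = 1e-12)
  # octahedron: volume 4/3
  oct <- rbind(diag(3), -diag(3))
  expect_equal(convex_hull_volume(oct), 4 / 3, tolerance = 1e-12)
  # interior points do not change the hull
  withpts <- rbind(cube, matrix(runif(30, 0.2, 0.8), 10, 3))
  expect_equal(convex_hull_volume(withpts), 1, tolerance = 1e-12)
  # degenerate (coplanar) cloud
  expect_equal(convex_hull_volume(cbind(runif(10), runif(10), 0)), 0)

  # Monte Carlo oracle on a random cloud
  set.seed(5)
  pts <- matrix(rnorm(150), 50, 3)
  v <- convex_hull_volume(pts)
  expect_equal(convex_hull_volume(pts * 1.7), v * 1.7^3, tolerance = 1e-9)
  # hit ratio inside the bounding box
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  probe <- cbind(runif(600, lo[1], hi[1]), runif(600, lo[2], hi[2]),
                 runif(600, lo[3], hi[3]))
  # a probe is inside the hull iff adding it leaves the volume unchanged
  inside <- vapply(seq_len(nrow(probe)), function(i) {
    convex_hull_volume(rbind(pts, probe[i, ])) <= v * (1 + 1e-9)
  }, TRUE)
  mc <- mean(inside) * prod(hi - lo)
  expect_lt(abs(mc - v) / v, 0.15)
})

test_that("structure rescaling matches hulls then nuclear volumes", {
  set.seed(41)
  mk <- function(X) {
    s <- data.frame(chrom = "A", bead = seq_len(nrow(X)) - 1,
                    x = X[, 1], y = X[, 2], z = X[, 3], label = "body")
    class(s) <- c("Structure3D", "data.frame")
    s
  }
  s_a <- mk(matrix(rnorm(60), 20, 3))
  s_b <- mk(matrix(rnorm(60) * 3, 20, 3))
  out <- rescale_structures(s_a, s_b, diam_a = 1.5, diam_b = 1.7)
  va <- convex_hull_volume(as.matrix(out$a[, c("x", "y", "z")]))
  vb <- convex_hull_volume(as.matrix(out$b[, c("x", "y", "z")]))
  sphere <- function(d) (4 / 3) * pi * (d * 100 / 2)^3
  expect_equal(va, sphere(1.5), tolerance = 1e-9)
  expect_equal(vb, sphere(1.7), tolerance = 1e-9)

  # pairwise-distance ratio in a equals (V_sphere(1.5)/V_hull_a)^(1/3)
  va0 <- convex_hull_volume(as.matrix(s_a[, c("x", "y", "z")]))
  f_expect <- (sphere(1.5) / va0)^(1 / 3)
  d0 <- dist(s_a[, c("x", "y", "z")])
  d1 <- dist(out$a[, c("x", "y", "z")])
  expect_equal(as.numeric(d1 / d0), rep(f_expect, length(d0)),
               tolerance = 1e-9)

  # idempotence: scaling input by 2 gives identical output distances
  s_a2 <- s_a; s_a2[, c("x", "y", "z")] <- s_a2[, c("x", "y", "z")] * 2
  out2 <- rescale_structures(s_a2, s_b, diam_a = 1.5, diam_b = 1.7)
  expect_equal(as.matrix(dist(out2$a[, c("x", "y", "z")])),
               as.matrix(dist(out$a[, c("x", "y", "z")])),
               tolerance = 1e-9)

  # commutes with global rotation
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  s_rot <- mk(as.matrix(s_a[, c("x", "y", "z")]) %*% Rz)
  out3 <- rescale_structures(s_rot, s_b, diam_a = 1.5, diam_b = 1.7)
  expect_equal(as.matrix(dist(out3$a[, c("x", "y", "z")])),
               as.matrix(dist(out$a[, c("x", "y", "z")])),
               tolerance = 1e-8)

  # degenerate hull
  flat <- mk(cbind(rnorm(10), rnorm(10), 0))
  expect_error(rescale_structures(flat, s_b), "degenerate")
})

test_that("noiseless round trip recovers planted pairwise distances", {
  # dense expected map f = c/d, direct edge always shortest (Euclidean
  # triangle inequality), so shortest-path + MDS is exact up to scale
  g <- toy3_genome()
  s <- simulate_structure(g, nucleus_config(mode = "uniform", seed = 51))
  xyz <- as.matrix(s[, c("x", "y", "z")])
  Dtrue <- as.matrix(dist(xyz))
  f <- 1 / Dtrue
  diag(f) <- 0
  bins <- bead_bin_table(g)
  D <- contact_to_distance(contact_matrix(f, bins))
  st <- embed_3d(D)
  Dhat <- as.matrix(dist(st[, c("x", "y", "z")]))
  # compare shapes after normalizing scale
  ratio <- Dhat[upper.tri(Dhat)] / Dtrue[upper.tri(Dtrue)]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
})

test_that("telomere distance matrices are arm-length ordered", {
  g <- build_toy_genome()
  s <- simulate_structure(g, nucleus_config(mode = "G0_hypercluster",
                                            seed = 61))
  td <- telomere_distance_matrix(s, g)
  expect_equal(dim(td), c(32, 32))
  expect_identical(unclass(td)[cbind(1:32, 1:32)], rep(0, 32))
  expect_equal(unclass(td), t(unclass(td)), ignore_attr = TRUE)
  telo <- attr(td, "telomeres")
  expect_true(all(diff(telo$arm_length) >= 0))

  # dropped chromosome -> fewer telomeres, with a warning
  s2 <- s[s$chrom != "XVI", ]
  class(s2) <- c("Structure3D", "data.frame")
  expect_warning(td2 <- telomere_distance_matrix(s2, g), "dropped")
  expect_equal(dim(td2), c(30, 30))

  # structure I/O round trip
  p <- withr::local_tempfile(fileext = ".tsv")
  write_structure(s, p)
  back <- read_structure(p)
  expect_equal(back$x, s$x, tolerance = 1e-9)
  expect_equal(back$label, s$label)
})
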