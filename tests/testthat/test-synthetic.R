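test_that("planted structures satisfy their mode's constraints", {
  g <- toy3_genome()

  cfg0 <- nucleus_config(mode = "G0_hypercluster", seed = 5)
  s0 <- simulate_structure(g, cfg0)
  term <- do.call(rbind, lapply(split(s0, s0$chrom),
                                function(d) d[c(1, nrow(d)), ]))
  # all terminal beads within one cluster diameter of each other
  expect_lte(max(dist(term[, c("x", "y", "z")])),
             2 * cfg0$cluster_radius * 100 + 1e-6)
  # cluster centroid well inside the nucleus (hypercluster is interior)
  expect_lt(sqrt(sum(colMeans(term[, c("x", "y", "z")])^2)),
            cfg0$radius * 100 / 3 + cfg0$cluster_radius * 100)

  cfg1 <- nucleus_config(mode = "G1_rabl", seed = 5)
  s1 <- simulate_structure(g, cfg1)
  term1 <- do.call(rbind, lapply(split(s1, s1$chrom),
                                 function(d) d[c(1, nrow(d)), ]))
  r <- sqrt(rowSums(term1[, c("x", "y", "z")]^2))
  R <- cfg1$radius * 100
  expect_true(all(r >= R - cfg1$tether_tolerance * 100 - 1e-6))
  expect_true(all(r <= R + 1e-6))
  # centromere beads tethered near the SPB-side point
  cen <- s1[s1$label == "centromere", ]
  spb_point <- 0.88 * R * cfg1$spb_direction
  dc <- sqrt(colSums((t(as.matrix(cen[, c("x", "y", "z")])) - spb_point)^2))
  expect_true(all(dc <= cfg1$tether_tolerance * 100 + 1e-6))

  # all beads inside the nucleus, bonds bounded, in both modes
  for (s in list(s0, s1)) {
    expect_true(all(sqrt(rowSums(s[, c("x", "y", "z")]^2)) <= R + 1e-6))
    for (d in split(s, s$chrom)) {
      step <- sqrt(rowSums(diff(as.matrix(d[, c("x", "y", "z")]))^2))
      expect_true(all(step <= 30 * (1 + 1e-6)))
    }
  }

  # determinism
  expect_identical(s0, simulate_structure(g, cfg0))

  # infeasible cluster radius
  expect_error(
    simulate_structure(g, nucleus_config(mode = "G0_hypercluster",
                                         cluster_radius = 1e-4, seed = 1)),
    "too small")
})

test_that("G0 terminal-bead centroid falls in the innermost nuclear zone", {
  g <- build_toy_genome()
  for (sd in 1:3) {
    s <- simulate_structure(g, nucleus_config(mode = "G0_hypercluster",
                                              seed = sd))
    term <- do.call(rbind, lapply(split(s, s$chrom),
                                  function(d) d[c(1, nrow(d)), ]))
    cen <- colMeans(term[, c("x", "y", "z")])
    zone <- zone_assay(cen[1], cen[2],
                       list(center = c(0, 0, 0), radius = 100))
    expect_equal(zone, 3L)
  }
})

test_that("contact sampling follows the inverse-distance law", {
  # 3 beads, d(1,2)=1, d(1,3)=2: expected N(1,2)/N(1,3) -> 2
  st <- data.frame(chrom = "A", bead = 0:2,
                   x = c(0, 1, 2), y = 0, z = 0, label = "body")
  class(st) <- c("Structure3D", "data.frame")
  bins <- bead_bin_table(build_toy_genome(
    n_chrom = 1, arm_lengths = list(c(20000, 40000)), rdna_chrom = NULL))
  M <- structure_to_contact_map(st, bins, n_contacts = 1e6, seed = 2)
  # p12 = (1/1)/(1+0.5+1) = 0.4, p13 = 0.2, p23 = 0.4
  n12 <- M$mat[1, 2]; n13 <- M$mat[1, 3]
  # ratio within 3 sigma of 2 (delta method on binomial counts)
  se <- sqrt(n12 + 4 * n13) / n13
  expect_lt(abs(n12 / n13 - 2), 3 * se)
  # symmetry and zero-contact edge cases
  expect_identical(M$mat, t(M$mat))
  M0 <- structure_to_contact_map(st, bins, n_contacts = 0, seed = 2)
  expect_true(all(M0$mat == 0))
  # determinism
  expect_identical(M$mat,
                   structure_to_contact_map(st, bins, 1e6, seed = 2)$mat)
  # degenerate structure rejected
  st2 <- st; st2$x <- 0
  class(st2) <- c("Structure3D", "data.frame")
  expect_error(structure_to_contact_map(st2, bins, 10, seed = 1),
               "degenerate")
})

test_that("empirical contact frequencies pass a goodness-of-fit test", {
  # 10-bead toy: chi-square against the c0/d law at n = 1e6
  set.seed(11)
  st <- data.frame(chrom = "A", bead = 0:9,
                   x = rnorm(10) * 30, y = rnorm(10) * 30,
                   z = rnorm(10) * 30, label = "body")
  class(st) <- c("Structure3D", "data.frame")
  g <- build_toy_genome(n_chrom = 1, arm_lengths = list(c(100000, 100000)),
                        rdna_chrom = NULL)
  bins <- bead_bin_table(g)
  M <- structure_to_contact_map(st, bins, n_contacts = 1e6, seed = 3)
  D <- as.matrix(dist(st[, c("x", "y", "z")]))
  ut <- upper.tri(D)
  p <- (1 / D[ut]) / sum(1 / D[ut])
  obs <- M$mat[ut]
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.001)
})

test_that("read-pair simulation round-trips and plants duplicates", {
  fx <- toy_pipeline_fixture(seed = 8)
  M <- structure_to_contact_map(fx$structure, fx$bins, 5000, seed = 9)
  P <- contact_matrix(M$mat / sum(M$mat), fx$bins)

  # clean round trip: recovered counts equal planted counts exactly
  sim <- simulate_read_pairs(P, fx$frag_map, n_pairs = 3000, seed = 10)
  pp <- preprocess_pairs(sim$pairs)
  raw <- build_contact_matrix(pp, fx$frag_map, fx$bins)
  expect_equal(raw$mat, sim$truth)
  expect_equal(attr(raw, "n_rejected"), 0)

  # duplicate planting: collapsed count within binomial 3 sigma
  sim2 <- simulate_read_pairs(P, fx$frag_map, n_pairs = 10000,
                              dup_fraction = 0.2, seed = 11)
  pp2 <- preprocess_pairs(sim2$pairs)
  n_dup <- attr(pp2, "n_dup")
  expect_lt(abs(n_dup - 2000), 3 * sqrt(10000 * 0.2 * 0.8))

  # determinism
  sim3 <- simulate_read_pairs(P, fx$frag_map, n_pairs = 3000, seed = 10)
  expect_identical(sim$pairs, sim3$pairs)

  expect_error(simulate_read_pairs(P, fx$frag_map, 10, dup_fraction = 1.2),
               "\\[0, 1\\]")
})

test_that("rendered images conserve planted intensity and are reproducible", {
  center <- c(1.56, 1.56, 1.6)
  # noiseless single focus: voxel sum above background matches planted
  img <- render_nucleus_image(
    data.frame(x = 1.5, y = 1.5, z = 1.6, intensity = 1e4),
    center = center, radius = 1.0, background = 20, noise = FALSE)
  # background voxel count from the renderer's own geometry
  bg_vox <- sum(render_nucleus_image(
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               intensity = numeric(0)),
    center = center, radius = 1.0, background = 1, noise = FALSE)$data)
  expect_lt(abs((sum(img$data) - 20 * bg_vox) - 1e4) / 1e4, 0.02)

  # zero foci, zero background -> all-zero image
  img0 <- render_nucleus_image(
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               intensity = numeric(0)),
    center = center, radius = 1.0, background = 0, noise = FALSE)
  expect_true(all(img0$data == 0))

  # determinism with noise
  f <- data.frame(x = 1.5, y = 1.6, z = 1.6, intensity = 2e4)
  i1 <- render_nucleus_image(f, center = center, radius = 1, seed = 4)
  i2 <- render_nucleus_image(f, center = center, radius = 1, seed = 4)
  expect_identical(i1$data, i2$data)

  # foci outside the nucleus are rejected
  expect_error(render_nucleus_image(
    data.frame(x = 3.0, y = 1.5, z = 1.6, intensity = 1e4),
    center = center, radius = 1.0), "inside the nucleus")
})

test_that("TIFF stacks round-trip voxel intensities", {
  img <- render_nucleus_image(
    data.frame(x = 1.5, y = 1.5, z = 1.6, intensity = 2e4),
    center = c(1.56, 1.56, 1.6), radius = 1, seed = 3)
  p <- withr::local_tempfile(fileext = ".tif")
  sc <- write_image_tiff(img, p)
  back <- read_image_tiff(p, voxel_size = img$voxel_size,
                          center = img$center, radius = img$radius,
                          scale = sc)
  expect_lt(max(abs(back$data - img$data)), 1e-3 * max(img$data))
  expect_equal(dim(back$data), dim(img$data))
})

test_that("foci spec sampler respects the separation constraint", {
  spec <- sample_foci_spec(4, center = c(1.5, 1.5, 1.5), radius = 1,
                           min_sep_sigma = 4, seed = 2)
  d <- as.matrix(dist(cbind(spec$x / spec$sigma_xy[1],
                            spec$y / spec$sigma_xy[1],
                            spec$z / spec$sigma_z[1])))
  expect_true(all(d[upper.tri(d)] >= 4))
  expect_identical(spec, sample_foci_spec(4, center = c(1.5, 1.5, 1.5),
                                          radius = 1, min_sep_sigma = 4,
                                          seed = 2))
})
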