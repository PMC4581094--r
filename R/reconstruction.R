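# Contact map -> 3D structure: shortest-path completion of inverse-frequency
# distances, classical multidimensional scaling, convex-hull rescaling to
# nuclear size, and telomere pairwise-distance extraction.

#' Distance matrix from a normalized contact map by shortest paths
#'
#' Builds the weighted graph whose nodes are retained bins and whose edges,
#' for every pair with nonzero contact frequency, carry weight
#' `1 / frequency`; the distance between two bins is the shortest-path
#' length on that graph. Frequent contacts thus translate into short
#' distances, and missing contacts are completed through intermediates.
#' Diagonal (intra-bin) entries are ignored.
#'
#' @param M A normalized (or at least symmetric nonnegative) `ContactMatrix`.
#' @return A `DistanceMatrix`: square symmetric matrix with zero diagonal
#'   and attribute `bins`.
#' @export
contact_to_distance <- function(M) {
  m <- M$mat
  n <- nrow(m)
  diag(m) <- 0
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    sizes <- paste(comp$csize, collapse = ", ")
    stop(sprintf(
      "contact graph is disconnected (%d components of sizes %s)",
      comp$no, sizes))
  }
  igraph::E(g)$weight <- 1 / igraph::E(g)$weight
  D <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(D) <- NULL
  attr(D, "bins") <- M$bins
  class(D) <- c("DistanceMatrix", class(D))
  D
}

#' Classical multidimensional scaling to 3D bead coordinates
#'
#' Torgerson scaling: the squared-distance matrix is double-centered to the
#' Gram matrix `B = -1/2 J D^2 J`, whose top three nonnegative eigenpairs
#' give the coordinates. Negative eigenvalues (non-Euclidean distances) are
#' clipped to zero; if fewer than three positive eigenvalues exist the
#' remaining coordinates are zero-padded with a warning.
#'
#' @param D A `DistanceMatrix` (square symmetric, zero diagonal).
#' @param bins Optional `BinTable` labelling the rows; defaults to
#'   `attr(D, "bins")`.
#' @return A `Structure3D` in input bin order (label `"body"`, or bead
#'   roles if `bins` carry them).
#' @export
embed_3d <- function(D, bins = attr(D, "bins")) {
  D <- unclass(D)
  n <- nrow(D)
  B <- -0.5 * scale(t(scale(t(D^2), center = TRUE, scale = FALSE)),
                    center = TRUE, scale = FALSE)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-12
  k <- min(3L, sum(pos))
  if (k < 3L) {
    warning(sprintf("only %d positive eigenvalue(s); padding with zeros", k))
  }
  xyz <- matrix(0, n, 3)
  if (k > 0) {
    xyz[, seq_len(k)] <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(e$values[seq_len(k)]), k)
  }
  st <- data.frame(
    chrom = if (!is.null(bins)) bins$chrom else NA_character_,
    bead = if (!is.null(bins)) stats::ave(seq_len(n), bins$chrom,
                                          FUN = seq_along) - 1L
           else seq_len(n) - 1L,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    label = "body", stringsAsFactors = FALSE
  )
  class(st) <- c("Structure3D", "data.frame")
  st
}

#' Rescale two reconstructed structures to their nuclear sizes
#'
#' Step 1 equalizes the convex-hull volumes of the two structures
#' (structure `b` is scaled isotropically onto `a`); step 2 scales each
#' structure so its hull volume equals the volume of a sphere of its stated
#' nuclear diameter, yielding coordinates in units of 10 nm. This makes
#' distances directly comparable between conditions with different nuclear
#' sizes (e.g. quiescent G0 nuclei of 1.5 um versus G1 daughters of 1.7 um).
#'
#' @param s_a,s_b `Structure3D` objects.
#' @param diam_a,diam_b Nuclear diameters in um.
#' @return List with elements `a` and `b`: rescaled structures (units of
#'   10 nm) with attribute `scale_factor`.
#' @export
rescale_structures <- function(s_a, s_b, diam_a = 1.5, diam_b = 1.7) {
  xa <- as.matrix(s_a[, c("x", "y", "z")])
  xb <- as.matrix(s_b[, c("x", "y", "z")])
  va <- convex_hull_volume(xa)
  vb <- convex_hull_volume(xb)
  if (va <= 0 || vb <= 0) stop("degenerate convex hull (zero volume)")
  # step 1: match b's hull volume to a's
  xb <- xb * (va / vb)^(1 / 3)
  # step 2: match each hull to its nuclear sphere (diameters in um -> 10 nm)
  sphere_vol <- function(diam_um) (4 / 3) * pi * (diam_um * 100 / 2)^3
  fa <- (sphere_vol(diam_a) / va)^(1 / 3)
  fb <- (sphere_vol(diam_b) / va)^(1 / 3)  # b now shares a's hull volume
  xa <- xa * fa
  xb <- xb * fb
  out_a <- s_a; out_a[, c("x", "y", "z")] <- xa
  out_b <- s_b; out_b[, c("x", "y", "z")] <- xb
  attr(out_a, "scale_factor") <- fa
  attr(out_b, "scale_factor") <- fb * (va / vb)^(1 / 3)
  list(a = out_a, b = out_b)
}

#' Pairwise 3D distances between telomere-proximal beads
#'
#' The terminal bead of each chromosome arm (first and last retained bead of
#' the chromosome) represents its telomere. Distances are Euclidean in the
#' structure's units; rows and columns are ordered by increasing arm length
#' (ties broken by chromosome name), the ordering used to reveal arm-length
#' dependence of telomere pairing.
#'
#' @param s A `Structure3D`.
#' @param genome The [GenomeModel] the structure derives from.
#' @return A `TelomereDistanceMatrix`: symmetric matrix with zero diagonal,
#'   dimnames `chrom_arm`, and attribute `telomeres` (the ordered table).
#' @export
telomere_distance_matrix <- function(s, genome) {
  telo <- genome$telomeres  # already ordered by arm length
  present <- unique(s$chrom)
  missing <- setdiff(genome$chromosomes$name, present)
  if (length(missing)) {
    warning("chromosome(s) with no retained beads dropped: ",
            paste(missing, collapse = ", "))
    telo <- telo[telo$chrom %in% present, , drop = FALSE]
  }
  coords <- t(vapply(seq_len(nrow(telo)), function(i) {
    sc <- s[s$chrom == telo$chrom[i], , drop = FALSE]
    sc <- sc[order(sc$bead), , drop = FALSE]
    row <- if (telo$arm[i] == "L") sc[1L, ] else sc[nrow(sc), ]
    c(row$x, row$y, row$z)
  }, numeric(3)))
  D <- as.matrix(stats::dist(coords))
  dimnames(D) <- list(paste0(telo$chrom, "_", telo$arm),
                      paste0(telo$chrom, "_", telo$arm))
  attr(D, "telomeres") <- telo
  class(D) <- c("TelomereDistanceMatrix", class(D))
  D
}

#' Full reconstruction from a raw contact map
#'
#' Convenience wrapper: filter bins, SCN-normalize, shortest-path distances,
#' and 3D embedding.
#'
#' @param M Raw `ContactMatrix`.
#' @param min_coverage_quantile Passed to [filter_bins()].
#' @param tol,max_iter Passed to [scn_normalize()].
#' @return List with `normalized` (`ContactMatrix`), `distances`
#'   (`DistanceMatrix`) and `structure` (`Structure3D`).
#' @export
reconstruct_structure <- function(M, min_coverage_quantile = 0.01,
                                  tol = 1e-6, max_iter = 200L) {
  Mf <- filter_bins(M, min_coverage_quantile)
  Mn <- scn_normalize(Mf, tol = tol, max_iter = max_iter)
  D <- contact_to_distance(Mn)
  s <- embed_3d(D)
  list(normalized = Mn, distances = D, structure = s)
}
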