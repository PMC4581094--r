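# Bead-chain nuclear structures with planted organization. One bead = 20 kb;
# coordinates are in units of 10 nm (1 um = 100 units) with the nucleus
# centered at the origin.

#' Nucleus configuration for structure simulation
#'
#' @param radius Nuclear radius in um.
#' @param mode One of `"G1_rabl"` (clustered centromeres at the spindle pole
#'   body side, telomeres tethered to the nuclear envelope), `"G0_hypercluster"`
#'   (all telomeres gathered in a single interior cluster), or `"uniform"`
#'   (unconstrained chains).
#' @param spb_direction Unit vector pointing from the nuclear center toward
#'   the spindle pole body; centromeres cluster on that side in G1, and the
#'   rDNA is confined to the opposite sector.
#' @param cluster_radius Radius (um) of the telomere hypercluster in G0 mode.
#' @param tether_tolerance Tolerance (um) for envelope/centromere tethering.
#' @param seed Integer seed; the structure is deterministic given the seed.
#' @return A list of class `NucleusConfig`.
#' @export
nucleus_config <- function(radius = 1.0,
                           mode = c("G1_rabl", "G0_hypercluster", "uniform"),
                           spb_direction = c(1, 0, 0),
                           cluster_radius = 0.1,
                           tether_tolerance = 0.1,
                           seed = 1L) {
  mode <- match.arg(mode)
  if (radius <= 0) stop("radius must be > 0")
  if (cluster_radius >= radius) stop("cluster_radius must be < radius")
  structure(list(radius = radius, mode = mode,
                 spb_direction = unit3(spb_direction),
                 cluster_radius = cluster_radius,
                 tether_tolerance = tether_tolerance,
                 seed = as.integer(seed)),
            class = "NucleusConfig")
}

#' Simulate a bead-chain genome structure in a spherical nucleus
#'
#' Generates one chain of 20-kb beads per chromosome by a constrained random
#' walk (Brownian bridges between anchor points, followed by iterative
#' projection onto the constraints). In `G1_rabl` mode centromere beads are
#' tethered near a peripheral spindle-pole-body point and terminal beads to
#' the nuclear envelope, with the envelope anchor of each telomere placed at
#' an angular distance from the pole that grows with arm length (the Rabl
#' configuration). In `G0_hypercluster` mode every terminal bead lies within
#' `cluster_radius` of a single interior point closer than `radius/3` to the
#' nuclear center. rDNA beads are confined to a peripheral sector opposite
#' the pole in both organized modes.
#'
#' @param genome A [GenomeModel].
#' @param config A [nucleus_config()].
#' @param bead_bp Bead size in bp (default 20 kb).
#' @param bond Maximum distance between consecutive beads, in units of 10 nm.
#' @return A `Structure3D`: data.frame with columns `chrom`, `bead` (0-based
#'   index within chromosome), `x`, `y`, `z` (units of 10 nm) and `label`
#'   in `{"centromere", "subtelomere", "rdna", "body"}`.
#' @export
simulate_structure <- function(genome, config, bead_bp = 20000, bond = 30) {
  stopifnot(inherits(genome, "GenomeModel"), inherits(config, "NucleusConfig"))
  R <- config$radius * 100           # 10-nm units
  cr <- config$cluster_radius * 100
  tt <- config$tether_tolerance * 100
  spb <- config$spb_direction
  chrom <- genome$chromosomes
  n_tel <- 2L * nrow(chrom)
  if (config$mode == "G0_hypercluster" &&
      (4 / 3) * pi * cr^3 < n_tel * 0.01) {
    stop(sprintf(
      "cluster_radius %.3g um is too small to host %d terminal beads",
      config$cluster_radius, n_tel))
  }

  with_seed(config$seed, {
    # shared anchors for the whole nucleus
    spb_point <- 0.88 * R * spb
    cluster_center <- if (config$mode == "G0_hypercluster") {
      runif_ball(1, max(R / 3 - cr - 1, 0), c(0, 0, 0))[1, ]
    } else NULL
    rdna_dir <- -spb
    max_arm <- max(genome$telomeres$arm_length)

    chains <- lapply(seq_len(nrow(chrom)), function(ci) {
      len <- chrom$length[ci]
      n <- as.integer(ceiling(len / bead_bp))
      cb <- min(n, as.integer(floor(chrom$centromere_pos[ci] / bead_bp)) + 1L)
      # bead role labels
      label <- rep("body", n)
      if (!is.na(chrom$rdna_start[ci])) {
        b0 <- (seq_len(n) - 1) * bead_bp
        b1 <- pmin(b0 + bead_bp, len)
        label[b1 > chrom$rdna_start[ci] & b0 < chrom$rdna_end[ci]] <- "rdna"
      }
      label[c(1L, n)] <- "subtelomere"
      label[cb] <- "centromere"

      sim_one_chain(n, cb, chrom$centromere_pos[ci],
                    len - chrom$centromere_pos[ci], label,
                    mode = config$mode, R = R, cr = cr, tt = tt,
                    spb_point = spb_point, spb = spb,
                    cluster_center = cluster_center, rdna_dir = rdna_dir,
                    max_arm = max_arm, bond = bond,
                    chrom_name = chrom$name[ci])
    })
    st <- do.call(rbind, chains)
    rownames(st) <- NULL
    class(st) <- c("Structure3D", "data.frame")
    st
  })
}

# one chromosome chain: anchors + Brownian bridge + projection repair
sim_one_chain <- function(n, cb, arm_l, arm_r, label, mode, R, cr, tt,
                          spb_point, spb, cluster_center, rdna_dir,
                          max_arm, bond, chrom_name) {
  anchor <- vector("list", n)  # each: list(center, radius) or NULL
  if (mode == "G1_rabl") {
    cen <- runif_ball(1, 0.9 * tt, spb_point)[1, ]
    anchor[[cb]] <- list(center = spb_point, radius = tt)
    tel1 <- rabl_envelope_point(arm_l, max_arm, R, tt, spb)
    teln <- rabl_envelope_point(arm_r, max_arm, R, tt, spb)
    anchor[[1L]] <- list(center = c(0, 0, 0), radius = R,
                         min_radius = R - tt)   # envelope shell
    anchor[[n]] <- anchor[[1L]]
  } else if (mode == "G0_hypercluster") {
    cen <- runif_ball(1, 0.7 * R, c(0, 0, 0))[1, ]
    tel1 <- runif_ball(1, 0.9 * cr, cluster_center)[1, ]
    teln <- runif_ball(1, 0.9 * cr, cluster_center)[1, ]
    anchor[[1L]] <- list(center = cluster_center, radius = cr)
    anchor[[n]] <- anchor[[1L]]
  } else {
    cen <- runif_ball(1, 0.8 * R, c(0, 0, 0))[1, ]
    tel1 <- runif_ball(1, 0.9 * R, c(0, 0, 0))[1, ]
    teln <- runif_ball(1, 0.9 * R, c(0, 0, 0))[1, ]
  }

  pts <- matrix(0, n, 3)
  pts[1, ] <- tel1
  pts[n, ] <- teln
  pts[cb, ] <- cen
  if (cb > 1L) pts[1:cb, ] <- bridge(tel1, cen, cb, bond)
  if (cb < n)  pts[cb:n, ] <- bridge(cen, teln, n - cb + 1L, bond)
  if (n == 1L) pts[1, ] <- if (mode == "G0_hypercluster") tel1 else cen

  rdna_idx <- which(label == "rdna")
  pts <- repair_chain(pts, anchor, R, bond, rdna_idx, rdna_dir)

  viol <- chain_violations(pts, anchor, R, bond, rdna_idx, rdna_dir)
  if (length(viol)) {
    stop(sprintf("infeasible constraints for chromosome %s: %s",
                 chrom_name, paste(viol, collapse = "; ")))
  }
  data.frame(chrom = chrom_name, bead = seq_len(n) - 1L,
             x = pts[, 1], y = pts[, 2], z = pts[, 3],
             label = label, stringsAsFactors = FALSE)
}

# envelope anchor whose polar angle from the SPB grows with arm length
rabl_envelope_point <- function(arm, max_arm, R, tt, spb) {
  frac <- arm / max_arm
  theta <- pi * (0.15 + 0.7 * frac) + stats::rnorm(1, 0, 0.15)
  theta <- min(max(theta, 0.05), pi - 0.05)
  phi <- stats::runif(1, 0, 2 * pi)
  # orthonormal frame around spb
  a <- unit3(if (abs(spb[1]) < 0.9) pracma_cross(spb, c(1, 0, 0)) else
    pracma_cross(spb, c(0, 1, 0)))
  b <- pracma_cross(spb, a)
  dirv <- cos(theta) * spb + sin(theta) * (cos(phi) * a + sin(phi) * b)
  (R - 0.5 * tt) * dirv
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Brownian bridge between two anchors with m beads (inclusive)
bridge <- function(a, b, m, bond) {
  if (m == 1L) return(matrix(a, 1, 3))
  steps <- matrix(stats::rnorm(3 * (m - 1), 0, bond / 2.2), ncol = 3)
  walk <- rbind(0, apply(steps, 2, cumsum))
  drift <- outer(seq(0, 1, length.out = m), walk[m, ])
  bb <- walk - drift
  line <- outer(seq(0, 1, length.out = m), b - a)
  sweep(bb + line, 2, a, `+`)
}

# iterative projection onto anchor balls / envelope shell / nucleus /
# bond-length / rDNA sector constraints
repair_chain <- function(pts, anchor, R, bond, rdna_idx, rdna_dir,
                         max_iter = 500L) {
  n <- nrow(pts)
  project_all <- function(pts) {
    for (k in seq_len(n)) {
      a <- anchor[[k]]
      if (!is.null(a)) pts[k, ] <- project_anchor(pts[k, ], a)
    }
    for (k in rdna_idx) pts[k, ] <- project_sector(pts[k, ], rdna_dir, R)
    rad <- sqrt(rowSums(pts^2))
    out <- rad > R - 0.25
    if (any(out)) {
      pts[out, ] <- pts[out, , drop = FALSE] * ((R - 0.25) / rad[out])
    }
    pts
  }
  for (it in seq_len(max_iter)) {
    pts <- project_all(pts)
    if (n > 1L) {
      # FABRIK-style: forward sweep pinned at bead 1, then re-pin bead n
      # and sweep backward; alternation converges for reachable anchors
      for (k in 2:n) {
        d <- pts[k, ] - pts[k - 1, ]
        nd <- sqrt(sum(d^2))
        if (nd > bond) pts[k, ] <- pts[k - 1, ] + d * (bond / nd)
      }
      pts <- project_all(pts)  # re-pin end and interior anchors
      for (k in (n - 1):1) {
        d <- pts[k, ] - pts[k + 1, ]
        nd <- sqrt(sum(d^2))
        if (nd > bond) pts[k, ] <- pts[k + 1, ] + d * (bond / nd)
      }
      if (!is.null(anchor[[1L]])) {
        pts[1, ] <- project_anchor(pts[1, ], anchor[[1L]])
      }
    }
    if (!length(chain_violations(pts, anchor, R, bond, rdna_idx, rdna_dir))) {
      break
    }
  }
  pts
}

project_anchor <- function(p, a) {
  d <- p - a$center
  nd <- sqrt(sum(d^2))
  if (nd > a$radius) {
    p <- a$center + (if (nd > 0) d * (a$radius / nd) else c(a$radius, 0, 0))
    nd <- a$radius
  }
  if (!is.null(a$min_radius) && nd < a$min_radius) {
    p <- a$center + (if (nd > 0) d * (a$min_radius / nd)
                     else c(a$min_radius, 0, 0))
  }
  p
}

# peripheral sector: within 60 degrees of rdna_dir, radius in [0.55R, R)
project_sector <- function(p, dirv, R) {
  nd <- sqrt(sum(p^2))
  if (nd < 1e-9) p <- dirv * 0.7 * R
  u <- unit3(p)
  cosang <- sum(u * dirv)
  if (cosang < 0.5) {
    # rotate toward dirv until 60 degrees
    perp <- u - cosang * dirv
    np <- sqrt(sum(perp^2))
    u <- if (np < 1e-9) dirv else 0.5 * dirv + sqrt(0.75) * perp / np
  }
  nd <- min(max(sqrt(sum(p^2)), 0.55 * R), R - 0.25)
  nd * u
}

chain_violations <- function(pts, anchor, R, bond, rdna_idx, rdna_dir,
                             tol = 1e-6) {
  v <- character()
  n <- nrow(pts)
  if (n > 1L) {
    d <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-n, , drop = FALSE])^2))
    if (any(d > bond * (1 + tol))) v <- c(v, "bond length exceeded")
  }
  if (any(sqrt(rowSums(pts^2)) > R + tol)) v <- c(v, "bead outside nucleus")
  for (k in seq_len(n)) {
    a <- anchor[[k]]
    if (is.null(a)) next
    nd <- sqrt(sum((pts[k, ] - a$center)^2))
    if (nd > a$radius * (1 + tol) + tol) {
      v <- c(v, sprintf("anchor violated at bead %d", k))
    }
    if (!is.null(a$min_radius) && nd < a$min_radius - tol) {
      v <- c(v, sprintf("envelope tether violated at bead %d", k))
    }
  }
  if (length(rdna_idx)) {
    for (k in rdna_idx) {
      u <- unit3(pts[k, ])
      if (sum(u * rdna_dir) < 0.5 - tol ||
          sqrt(sum(pts[k, ]^2)) < 0.55 * R - tol) {
        v <- c(v, "rDNA sector violated")
        break
      }
    }
  }
  unique(v)
}

#' @export
print.Structure3D <- function(x, ...) {
  cat(sprintf("Structure3D: %d beads on %d chromosomes (units of 10 nm)\n",
              nrow(x), length(unique(x$chrom))))
  invisible(NextMethod())
}

#' Write / read a bead-chain structure as a tab-separated table
#'
#' Columns: chrom, bead, x, y, z, label.
#' @param s A `Structure3D`.
#' @param path File path.
#' @export
write_structure <- function(s, path) {
  utils::write.table(as.data.frame(s), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_structure
#' @export
read_structure <- function(path) {
  s <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  class(s) <- c("Structure3D", "data.frame")
  s
}
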