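# Exact 3D convex hull volume via randomized incremental construction.
# Used for structure rescaling; no installed package in this stack provides
# a 3D hull, so it is implemented here and validated against closed-form
# solids and Monte Carlo integration in the tests.

#' Volume of the convex hull of a 3D point cloud
#'
#' Incremental convex hull (beneath-beyond): starting from a tetrahedron of
#' extreme points, each remaining point outside the current hull replaces
#' its visible faces with a cone of new faces over the horizon. The volume
#' is the sum of signed tetrahedra from the centroid over the final faces.
#'
#' @param pts Numeric matrix with 3 columns (x, y, z), >= 4 rows.
#' @return Hull volume (0 for degenerate/coplanar input).
#' @export
convex_hull_volume <- function(pts) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3)
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 4) return(0)

  init <- hull_initial_tetra(pts)
  if (is.null(init)) return(0)  # degenerate (collinear/coplanar)

  faces <- init$faces           # list of integer triples, outward-oriented
  interior <- init$interior     # a point strictly inside the tetrahedron
  eps <- 1e-12 * max(abs(pts)) ^ 0  # scale-aware below
  scale <- max(apply(pts, 2, function(v) diff(range(v))))
  eps <- 1e-10 * max(scale, 1)^3

  remaining <- setdiff(seq_len(n), unique(unlist(faces)))
  for (p in remaining) {
    vis <- vapply(faces, function(f) {
      signed_vol(pts[f[1], ], pts[f[2], ], pts[f[3], ], pts[p, ]) > eps
    }, TRUE)
    if (!any(vis)) next  # inside current hull
    # horizon = edges shared by exactly one visible face
    edges <- do.call(rbind, lapply(faces[vis], function(f) {
      rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])
    }))
    key <- paste(pmin(edges[, 1], edges[, 2]),
                 pmax(edges[, 1], edges[, 2]))
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    faces <- faces[!vis]
    for (e in seq_len(nrow(horizon))) {
      f <- c(horizon[e, 1], horizon[e, 2], p)
      # orient outward: interior point must be on the negative side
      if (signed_vol(pts[f[1], ], pts[f[2], ], pts[f[3], ], interior) > 0) {
        f <- f[c(2, 1, 3)]
      }
      faces <- c(faces, list(f))
    }
  }
  vol <- 0
  for (f in faces) {
    vol <- vol + signed_vol(interior, pts[f[1], ], pts[f[2], ], pts[f[3], ])
  }
  abs(vol)
}

signed_vol <- function(a, b, c, d) {
  # 6V of tetra (a,b,c,d); positive if d on the positive side of (a,b,c)
  det(rbind(b - a, c - a, d - a)) / 6
}

hull_initial_tetra <- function(pts) {
  n <- nrow(pts)
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (isTRUE(all.equal(pts[i1, ], pts[i2, ]))) return(NULL)
  # farthest from line (i1, i2)
  v <- pts[i2, ] - pts[i1, ]
  d2 <- vapply(seq_len(n), function(k) {
    w <- pts[k, ] - pts[i1, ]
    cr <- c(v[2] * w[3] - v[3] * w[2],
            v[3] * w[1] - v[1] * w[3],
            v[1] * w[2] - v[2] * w[1])
    sum(cr^2)
  }, 0)
  i3 <- which.max(d2)
  if (d2[i3] <= 1e-20) return(NULL)
  # farthest from plane (i1, i2, i3)
  vols <- vapply(seq_len(n), function(k) {
    abs(signed_vol(pts[i1, ], pts[i2, ], pts[i3, ], pts[k, ]))
  }, 0)
  i4 <- which.max(vols)
  if (vols[i4] <= 1e-20) return(NULL)
  tet <- c(i1, i2, i3, i4)
  interior <- colMeans(pts[tet, ])
  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- lapply(faces, function(f) {
    if (signed_vol(pts[f[1], ], pts[f[2], ], pts[f[3], ], interior) > 0) {
      f[c(2, 1, 3)]
    } else f
  })
  list(faces = faces, interior = interior)
}
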