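# Planar polygon toolkit. Polygons are open rings: an n x 2 matrix of
# (x, y) vertices in counterclockwise order. A "mosaic" is a list of convex
# CCW rings with pairwise-disjoint interiors; unions, intersections and
# area queries on arbitrary shapes reduce to convex-convex clipping of the
# pieces, which keeps every area computation exact (no sampling).

as_ring <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2 || nrow(p) < 3)
    mim_abort("polygon must be a matrix with >= 3 rows and 2 columns",
              "invalid_argument")
  storage.mode(p) <- "double"
  dimnames(p) <- NULL
  if (poly_area_cpp(p) < 0) p <- p[nrow(p):1, , drop = FALSE]
  p
}

ring_area <- function(p) poly_area_cpp(p)

#' Create a mosaic of disjoint convex pieces
#'
#' Internal geometry container: a list of convex counterclockwise rings with
#' disjoint interiors whose union represents an arbitrary (multi)polygon.
#' @param pieces list of n x 2 vertex matrices.
#' @return object of class `mosaic`.
#' @keywords internal
new_mosaic <- function(pieces) {
  pieces <- Filter(function(p) nrow(p) >= 3 && poly_area_cpp(p) > 1e-12,
                   pieces)
  structure(pieces, class = "mosaic")
}

mosaic_area <- function(m) mosaic_area_cpp(unclass(m))

mosaic_bbox <- function(m) {
  xy <- do.call(rbind, unclass(m))
  c(xmin = min(xy[, 1]), xmax = max(xy[, 1]),
    ymin = min(xy[, 2]), ymax = max(xy[, 2]))
}

is_mosaic <- function(x) inherits(x, "mosaic")

as_mosaic <- function(x) {
  if (is_mosaic(x)) return(x)
  ring <- as_ring(x)
  if (is_convex(ring)) new_mosaic(list(ring))
  else new_mosaic(ear_triangulate(ring))
}

is_convex <- function(p, tol = 1e-12) {
  n <- nrow(p)
  i <- seq_len(n)
  j <- c(2:n, 1)
  k <- c(3:n, 1, 2)
  cr <- (p[j, 1] - p[i, 1]) * (p[k, 2] - p[j, 2]) -
        (p[j, 2] - p[i, 2]) * (p[k, 1] - p[j, 1])
  all(cr >= -tol)
}

# One Sutherland-Hodgman step in R: keep the part of `poly` on the given
# side of the directed line a -> b ("left" keeps counterclockwise interior).
clip_halfplane_r <- function(poly, a, b, side = "left") {
  if (side == "right") { tmp <- a; a <- b; b <- tmp }
  n <- nrow(poly)
  if (n == 0) return(poly)
  e <- b - a
  s <- e[1] * (poly[, 2] - a[2]) - e[2] * (poly[, 1] - a[1])
  inside <- s >= -1e-12
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(0, 2 * n, 2)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    if (inside[j] != inside[i]) {
      t <- s[j] / (s[j] - s[i])
      k <- k + 1L
      out[k, ] <- poly[j, ] + t * (poly[i, ] - poly[j, ])
    }
    if (inside[i]) {
      k <- k + 1L
      out[k, ] <- poly[i, ]
    }
  }
  out[seq_len(k), , drop = FALSE]
}

# P \ Q for convex P, Q as a list of disjoint convex pieces: walk the edges
# of Q, peeling off the part of P outside each successive edge.
convex_difference <- function(P, Q) {
  # quick reject: disjoint bounding boxes leave P untouched
  if (max(P[, 1]) < min(Q[, 1]) || min(P[, 1]) > max(Q[, 1]) ||
      max(P[, 2]) < min(Q[, 2]) || min(P[, 2]) > max(Q[, 2]))
    return(list(P))
  out <- list()
  cur <- P
  n <- nrow(Q)
  for (i in seq_len(n)) {
    if (nrow(cur) < 3) break
    j <- if (i == 1) n else i - 1
    piece <- clip_halfplane_r(cur, Q[j, ], Q[i, ], side = "right")
    if (nrow(piece) >= 3 && poly_area_cpp(piece) > 1e-12)
      out[[length(out) + 1]] <- piece
    cur <- clip_halfplane_r(cur, Q[j, ], Q[i, ], side = "left")
  }
  out
}

# Union of possibly-overlapping convex polygons as a disjoint mosaic.
mosaic_union_convex <- function(polys) {
  pieces <- list()
  for (p in polys) {
    p <- as_ring(p)
    frags <- list(p)
    for (q in pieces) {
      frags <- unlist(lapply(frags, convex_difference, Q = q),
                      recursive = FALSE)
      if (length(frags) == 0) break
    }
    pieces <- c(pieces, frags)
  }
  new_mosaic(pieces)
}

# Intersection of two mosaics (pairwise convex clipping keeps disjointness).
mosaic_intersect <- function(m1, m2) {
  out <- list()
  for (p in unclass(m1)) {
    for (q in unclass(m2)) {
      r <- clip_convex_cpp(p, q)
      if (nrow(r) >= 3 && poly_area_cpp(r) > 1e-12)
        out[[length(out) + 1]] <- r
    }
  }
  new_mosaic(out)
}

point_in_convex <- function(pts, poly, tol = 1e-9) {
  n <- nrow(poly)
  ok <- rep(TRUE, nrow(pts))
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    e <- poly[i, ] - poly[j, ]
    s <- e[1] * (pts[, 2] - poly[j, 2]) - e[2] * (pts[, 1] - poly[j, 1])
    ok <- ok & (s >= -tol)
  }
  ok
}

point_in_mosaic <- function(pts, m, tol = 1e-9) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  hit <- rep(FALSE, nrow(pts))
  for (p in unclass(m)) {
    todo <- which(!hit)
    if (length(todo) == 0) break
    hit[todo] <- point_in_convex(pts[todo, , drop = FALSE], p, tol)
  }
  hit
}

# Ear-clipping triangulation of a simple CCW ring.
ear_triangulate <- function(poly) {
  poly <- as_ring(poly)
  idx <- seq_len(nrow(poly))
  tris <- list()
  guard <- 0
  while (length(idx) > 3) {
    n <- length(idx)
    found <- FALSE
    for (k in seq_len(n)) {
      i <- idx[if (k == 1) n else k - 1]
      j <- idx[k]
      l <- idx[if (k == n) 1 else k + 1]
      a <- poly[i, ]; b <- poly[j, ]; c <- poly[l, ]
      cr <- (b[1] - a[1]) * (c[2] - b[2]) - (b[2] - a[2]) * (c[1] - b[1])
      if (cr <= 1e-14) next # reflex or degenerate corner
      tri <- rbind(a, b, c)
      others <- setdiff(idx, c(i, j, l))
      # a vertex on the candidate triangle's boundary blocks the ear too
      if (length(others) > 0 &&
          any(point_in_convex(poly[others, , drop = FALSE], tri,
                              tol = 1e-9)))
        next
      tris[[length(tris) + 1]] <- tri
      idx <- idx[-k]
      found <- TRUE
      break
    }
    if (!found) {
      guard <- guard + 1
      if (guard > 2) mim_abort("polygon could not be triangulated",
                               "degenerate_geometry")
      # drop a degenerate (collinear) corner and retry
      drop <- NULL
      for (k in seq_along(idx)) {
        n <- length(idx)
        i <- idx[if (k == 1) n else k - 1]
        j <- idx[k]
        l <- idx[if (k == n) 1 else k + 1]
        a <- poly[i, ]; b <- poly[j, ]; c <- poly[l, ]
        cr <- (b[1] - a[1]) * (c[2] - b[2]) - (b[2] - a[2]) * (c[1] - b[1])
        if (abs(cr) <= 1e-12) { drop <- k; break }
      }
      if (is.null(drop)) mim_abort("polygon could not be triangulated",
                                   "degenerate_geometry")
      idx <- idx[-drop]
    }
  }
  if (length(idx) == 3) {
    tri <- poly[idx, , drop = FALSE]
    if (poly_area_cpp(tri) > 1e-14) tris[[length(tris) + 1]] <- tri
  }
  tris
}

convex_hull_poly <- function(points) {
  points <- as.matrix(points)
  h <- grDevices::chull(points[, 1], points[, 2])
  as_ring(points[h, , drop = FALSE])
}

circle_polygon <- function(center, radius, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
            c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-14) return(list(center = c(NA, NA), r = Inf))
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  list(center = c(ux, uy), r = sqrt((a[1] - ux)^2 + (a[2] - uy)^2))
}

# Bowyer-Watson Delaunay triangulation. Returns vertex-index triples and
# the circumradius of each triangle (used by the alpha-complex filter).
delaunay_triangulation <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) mim_abort("need >= 3 points", "degenerate_geometry")
  rng <- apply(points, 2, range)
  span <- max(rng[2, ] - rng[1, ], 1e-9)
  mid <- colMeans(rng)
  big <- 50 * span
  sup <- rbind(mid + c(-big, -big), mid + c(big, -big), mid + c(0, big))
  pts <- rbind(points, sup)
  tris <- list(c(n + 1, n + 2, n + 3))
  cc <- list(circumcircle(sup[1, ], sup[2, ], sup[3, ]))
  for (ip in seq_len(n)) {
    p <- pts[ip, ]
    bad <- vapply(seq_along(tris), function(k) {
      ck <- cc[[k]]
      is.finite(ck$r) &&
        (p[1] - ck$center[1])^2 + (p[2] - ck$center[2])^2 < ck$r^2 + 1e-12
    }, logical(1))
    if (!any(bad)) next
    edges <- do.call(rbind, lapply(tris[bad], function(t)
      rbind(sort(t[c(1, 2)]), sort(t[c(2, 3)]), sort(t[c(1, 3)]))))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), ,
                      drop = FALSE]
    tris <- tris[!bad]
    cc <- cc[!bad]
    for (e in seq_len(nrow(boundary))) {
      t <- c(boundary[e, ], ip)
      tris[[length(tris) + 1]] <- t
      cc[[length(cc) + 1]] <- circumcircle(pts[t[1], ], pts[t[2], ],
                                           pts[t[3], ])
    }
  }
  keep <- vapply(tris, function(t) all(t <= n), logical(1))
  tris <- tris[keep]
  cc <- cc[keep]
  if (length(tris) == 0)
    mim_abort("points are collinear: no triangulation exists",
              "degenerate_geometry")
  list(
    triangles = do.call(rbind, tris),
    circumradius = vapply(cc, function(x) x$r, numeric(1))
  )
}

# Uniform sampling inside a mosaic via area-weighted fan triangles.
sample_in_mosaic <- function(n, m, seed = NULL) {
  tris <- list()
  for (p in unclass(m)) {
    np <- nrow(p)
    for (k in 2:(np - 1))
      tris[[length(tris) + 1]] <- p[c(1, k, k + 1), , drop = FALSE]
  }
  areas <- vapply(tris, poly_area_cpp, numeric(1))
  areas <- pmax(areas, 0)
  if (sum(areas) <= 0) mim_abort("degenerate region", "degenerate_geometry")
  with_seed(seed, {
    ti <- sample.int(length(tris), n, replace = TRUE, prob = areas)
    u <- stats::runif(n)
    v <- stats::runif(n)
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]
    v[flip] <- 1 - v[flip]
    out <- t(vapply(seq_len(n), function(i) {
      tr <- tris[[ti[i]]]
      tr[1, ] + u[i] * (tr[2, ] - tr[1, ]) + v[i] * (tr[3, ] - tr[1, ])
    }, numeric(2)))
    colnames(out) <- c("lon", "lat")
    out
  })
}

#' Jitter a record uniformly within a polygon
#'
#' Places a point uniformly at random inside a polygon. Used for occurrence
#' records that carry only a municipality/state of collection rather than
#' coordinates: the record is assigned a random position within the
#' political boundary before range construction.
#'
#' @param record optional `c(lon, lat)` of the original (unused) coordinate;
#'   retained so occurrence tables can be row-mapped through this function.
#' @param polygon an n x 2 matrix of polygon vertices (lon, lat), or a
#'   mosaic.
#' @param seed integer seed; the same seed always returns the same point.
#' @return named numeric vector `c(lon, lat)` inside `polygon`.
#' @export
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' jitter_within_polygon(NULL, sq, seed = 1)
jitter_within_polygon <- function(record = NULL, polygon, seed = NULL) {
  m <- as_mosaic(polygon)
  if (mosaic_area(m) <= 0)
    mim_abort("polygon is degenerate (zero area)", "invalid_argument")
  pt <- sample_in_mosaic(1, m, seed = seed)
  c(lon = pt[1, 1], lat = pt[1, 2])
}
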