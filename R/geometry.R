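# Planar polygon utilities.
#
# Polygons are lists of rings; each ring is list(x =, y =) without a repeated
# closing vertex (the polyclip convention). Outer rings are positively
# oriented, holes negatively, so signed ring areas sum to the net area.

ring_area_signed <- function(ring) {
  x <- ring$x; y <- ring$y
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

ring_perimeter <- function(ring) {
  dx <- diff(c(ring$x, ring$x[1]))
  dy <- diff(c(ring$y, ring$y[1]))
  sum(sqrt(dx^2 + dy^2))
}

#' Net area of a multi-ring polygon (holes subtract)
#' @noRd
rings_area <- function(rings) {
  if (length(rings) == 0) return(0)
  abs(sum(vapply(rings, ring_area_signed, numeric(1))))
}

rings_perimeter <- function(rings) {
  if (length(rings) == 0) return(0)
  sum(vapply(rings, ring_perimeter, numeric(1)))
}

#' Union of many polygons via pairwise clipping
#' @noRd
rings_union <- function(polys) {
  polys <- polys[lengths(polys) > 0]
  if (length(polys) == 0) return(list())
  acc <- polys[[1]]
  for (p in polys[-1]) acc <- polyclip::polyclip(acc, p, op = "union")
  acc
}

rings_intersect <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(list())
  polyclip::polyclip(a, b, op = "intersection")
}

#' Buffer (positive) or shrink (negative) a polygon
#' @noRd
rings_offset <- function(rings, delta) {
  if (length(rings) == 0) return(list())
  if (delta == 0) return(rings)
  polyclip::polyoffset(rings, delta, jointype = "round")
}

rings_bbox <- function(rings) {
  xs <- unlist(lapply(rings, `[[`, "x"))
  ys <- unlist(lapply(rings, `[[`, "y"))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

rings_translate <- function(rings, dx, dy) {
  lapply(rings, function(r) list(x = r$x + dx, y = r$y + dy))
}

#' Even-odd point-in-polygon over a set of rings, boundary-inclusive
#'
#' Vectorised over points. Crossing-number parity over all rings gives
#' even-odd containment; points within `tol` of any edge count as inside.
#' @noRd
points_in_rings <- function(px, py, rings, tol = 1e-9) {
  n <- length(px)
  if (length(rings) == 0 || n == 0) return(logical(n))
  crossings <- integer(n)
  on_edge <- logical(n)
  for (ring in rings) {
    x <- ring$x; y <- ring$y
    m <- length(x)
    x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
    for (e in seq_len(m)) {
      x1e <- x[e]; y1e <- y[e]; x2e <- x2[e]; y2e <- y2[e]
      # ray casting: horizontal ray to +x
      cond <- ((y1e > py) != (y2e > py))
      if (any(cond)) {
        xint <- x1e + (py[cond] - y1e) * (x2e - x1e) / (y2e - y1e)
        hit <- xint > px[cond]
        idx <- which(cond)[hit]
        crossings[idx] <- crossings[idx] + 1L
      }
      # distance to segment for boundary inclusion
      ex <- x2e - x1e; ey <- y2e - y1e
      len2 <- ex^2 + ey^2
      if (len2 == 0) {
        d2 <- (px - x1e)^2 + (py - y1e)^2
      } else {
        tt <- pmin(1, pmax(0, ((px - x1e) * ex + (py - y1e) * ey) / len2))
        d2 <- (px - (x1e + tt * ex))^2 + (py - (y1e + tt * ey))^2
      }
      on_edge <- on_edge | d2 <= tol^2
    }
  }
  (crossings %% 2L == 1L) | on_edge
}

#' Convex hull of a point set as a positively oriented ring
#'
#' Returns NULL for fewer than 3 distinct non-collinear points.
#' @noRd
convex_ring <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(NULL)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3) return(NULL)
  ring <- list(x = pts[h, 1], y = pts[h, 2])
  if (ring_area_signed(ring) < 0) ring <- list(x = rev(ring$x), y = rev(ring$y))
  if (abs(ring_area_signed(ring)) == 0) return(NULL)
  ring
}

#' Boundary-inclusive test against a single convex ring, vectorised
#' @noRd
points_in_convex <- function(px, py, ring, tol = 1e-9) {
  x <- ring$x; y <- ring$y
  m <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  inside <- rep(TRUE, length(px))
  for (e in seq_len(m)) {
    # positive orientation: interior is to the left, cross >= -tol*scale
    cr <- (x2[e] - x[e]) * (py - y[e]) - (y2[e] - y[e]) * (px - x[e])
    edge_len <- sqrt((x2[e] - x[e])^2 + (y2[e] - y[e])^2)
    inside <- inside & (cr >= -tol * max(edge_len, 1))
    if (!any(inside)) break
  }
  inside
}

#' Assemble flat ring lists into GeoJSON-style nested polygons
#'
#' Each negatively oriented ring is assigned as a hole of the smallest
#' positive ring that contains its first vertex.
#' @noRd
rings_to_polygons <- function(rings) {
  if (length(rings) == 0) return(list())
  sa <- vapply(rings, ring_area_signed, numeric(1))
  outers <- which(sa > 0)
  holes <- which(sa < 0)
  polys <- lapply(outers, function(i) list(rings[[i]]))
  if (length(holes) > 0 && length(outers) > 0) {
    areas <- sa[outers]
    for (h in holes) {
      px <- rings[[h]]$x[1]; py <- rings[[h]]$y[1]
      contains <- vapply(seq_along(outers), function(k) {
        points_in_rings(px, py, list(rings[[outers[k]]]))
      }, logical(1))
      if (any(contains)) {
        k <- which(contains)[which.min(areas[contains])]
        polys[[k]] <- c(polys[[k]], list(rings[[h]]))
      }
    }
  }
  polys
}
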