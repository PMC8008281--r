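#' Per-vertex sulcal depth
#'
#' Sulcal depth at a vertex is the Euclidean distance from the vertex to
#' the nearest point of the hemisphere's convex hull surface (exact
#' point-to-triangle distance minimised over all hull facets).  Vertices on
#' gyral crowns touch the hull and have depth ~0; vertices at sulcal fundi
#' are deepest.
#'
#' @param mesh A [surface_mesh()] (gray-white junction surface, mm).
#' @param hull Convex hull of the same hemisphere, from [build_hull()].
#' @return Numeric vector of nonnegative depths (mm), one per mesh vertex.
#' @export
sulcal_depth <- function(mesh, hull) {
  if (is.null(hull$faces) || nrow(hull$faces) == 0L)
    stopf("hull has no facets")
  .min_dist_to_mesh(mesh$vertices, hull$vertices, hull$faces)
}

#' Per-vertex local gyrification index
#'
#' The local gyrification index (LGI) at a vertex is the ratio between the
#' area of a circular region of the surface around the vertex and the
#' corresponding area on the convex hull: the surface/hull area within a
#' Euclidean ball of the given radius centred at the vertex.  On a convex
#' surface LGI is ~1; folding pushes it above 1 as sulcal walls add
#' surface area the hull does not have.
#'
#' Triangles are attributed to the ball by the configured inclusion rule:
#' `"centroid"` (default) counts a triangle's full area when its centroid
#' lies inside the ball; `"clip"` adaptively subdivides boundary-crossing
#' triangles (to `clip_depth` levels) so only the area actually inside the
#' ball is counted, and exists mainly to validate the centroid rule.
#'
#' @param mesh A [surface_mesh()].
#' @param hull Convex hull of the same hemisphere, from [build_hull()].
#' @param radius Patch radius in mm (default 10, fetal-brain scale); should
#'   exceed the typical edge length.
#' @param inclusion `"centroid"` or `"clip"`.
#' @param clip_depth Maximum subdivision depth for `"clip"`.
#' @return Numeric vector of LGI values; `NA` where the ball captures zero
#'   hull area (undefined; excluded from aggregates).
#' @export
local_gi <- function(mesh, hull, radius = 10,
                     inclusion = c("centroid", "clip"), clip_depth = 4L) {
  inclusion <- match.arg(inclusion)
  if (radius <= 0) stopf("radius must be positive")
  pts <- mesh$vertices
  if (inclusion == "centroid") {
    # refine coarse facets first: hull facets bridge whole sulci, so raw
    # centroid membership would quantise the hull area in the ball badly
    gs <- refined_face_geometry(mesh, radius / 4)
    gh <- refined_face_geometry(hull, radius / 4)
    surf <- .ball_area_sum(pts, gs$centroids, gs$areas, radius)
    hl <- .ball_area_sum(pts, gh$centroids, gh$areas, radius)
  } else {
    surf <- clipped_ball_areas(mesh, pts, radius, clip_depth)
    hl <- clipped_ball_areas(hull, pts, radius, clip_depth)
  }
  lgi <- surf / hl
  undef <- hl <= 0
  if (any(undef)) {
    warnf("%d vertex/vertices with zero hull area in ball flagged NA",
          sum(undef))
    lgi[undef] <- NA_real_
  }
  lgi
}

# Triangle soup (centroids + areas) with every triangle 4-split until its
# longest edge is at most max_edge; topology is irrelevant for area sums.
refined_face_geometry <- function(mesh, max_edge, max_iter = 8L) {
  v <- mesh$vertices
  f <- mesh$faces
  A <- v[f[, 1L], , drop = FALSE]
  B <- v[f[, 2L], , drop = FALSE]
  C <- v[f[, 3L], , drop = FALSE]
  for (it in seq_len(max_iter)) {
    e <- pmax(rowSums((A - B)^2), rowSums((B - C)^2), rowSums((C - A)^2))
    big <- e > max_edge^2
    if (!any(big)) break
    a <- A[big, , drop = FALSE]
    b <- B[big, , drop = FALSE]
    cc <- C[big, , drop = FALSE]
    ab <- (a + b) / 2; bc <- (b + cc) / 2; ca <- (cc + a) / 2
    A <- rbind(A[!big, , drop = FALSE], a, b, cc, ab)
    B <- rbind(B[!big, , drop = FALSE], ab, bc, ca, bc)
    C <- rbind(C[!big, , drop = FALSE], ca, ab, bc, ca)
  }
  ux <- B - A; vx <- C - A
  cx <- ux[, 2L] * vx[, 3L] - ux[, 3L] * vx[, 2L]
  cy <- ux[, 3L] * vx[, 1L] - ux[, 1L] * vx[, 3L]
  cz <- ux[, 1L] * vx[, 2L] - ux[, 2L] * vx[, 1L]
  list(centroids = (A + B + C) / 3,
       areas = 0.5 * sqrt(cx^2 + cy^2 + cz^2))
}

# Area of each ball/surface intersection by adaptive triangle subdivision:
# triangles wholly inside count fully, wholly outside count zero, and
# boundary-crossing triangles are split into 4 until `depth` is exhausted
# (then the centroid rule decides).
clipped_ball_areas <- function(mesh, centers, radius, depth) {
  v <- mesh$vertices
  f <- mesh$faces
  tri_a <- v[f[, 1L], , drop = FALSE]
  tri_b <- v[f[, 2L], , drop = FALSE]
  tri_c <- v[f[, 3L], , drop = FALSE]
  vapply(seq_len(nrow(centers)), function(i) {
    ctr <- centers[i, ]
    tot <- 0
    for (j in seq_len(nrow(f)))
      tot <- tot + clip_tri_area(tri_a[j, ], tri_b[j, ], tri_c[j, ],
                                 ctr, radius, depth)
    tot
  }, numeric(1L))
}

clip_tri_area <- function(a, b, cc, ctr, r, depth) {
  da <- sqrt(sum((a - ctr)^2))
  db <- sqrt(sum((b - ctr)^2))
  dc <- sqrt(sum((cc - ctr)^2))
  area <- 0.5 * sqrt(sum(crossv(b - a, cc - a)^2))
  if (max(da, db, dc) <= r) return(area)
  # circumradius upper bound: no part of the triangle can be closer to the
  # centre than the nearest vertex minus the triangle's diameter
  diam <- max(sqrt(sum((a - b)^2)), sqrt(sum((b - cc)^2)),
              sqrt(sum((cc - a)^2)))
  if (min(da, db, dc) - diam > r) return(0)
  if (depth <= 0L) {
    cen <- (a + b + cc) / 3
    return(if (sqrt(sum((cen - ctr)^2)) <= r) area else 0)
  }
  ab <- (a + b) / 2; bc <- (b + cc) / 2; ca <- (cc + a) / 2
  clip_tri_area(a, ab, ca, ctr, r, depth - 1L) +
    clip_tri_area(ab, b, bc, ctr, r, depth - 1L) +
    clip_tri_area(ca, bc, cc, ctr, r, depth - 1L) +
    clip_tri_area(ab, bc, ca, ctr, r, depth - 1L)
}

#' Aggregate per-vertex metrics by region
#'
#' Mean of a per-vertex metric within each labelled region, either
#' area-weighted (default; weights are barycentric vertex areas, so the
#' mean is a surface integral divided by region area) or unweighted.
#' `NA` metric values (e.g. undefined LGI) are excluded; regions with no
#' usable vertices are omitted with a warning.
#'
#' @param values Numeric per-vertex metric.
#' @param vertex_labels Region label per vertex.
#' @param mesh The [surface_mesh()] the metric lives on (needed for area
#'   weighting).
#' @param mode `"area"` (default) or `"vertex"`.
#' @return Named numeric vector of per-region means.
#' @export
aggregate_by_region <- function(values, vertex_labels, mesh = NULL,
                                mode = c("area", "vertex")) {
  mode <- match.arg(mode)
  if (length(values) != length(vertex_labels))
    stopf("values and vertex_labels must have equal length")
  w <- if (mode == "area") {
    if (is.null(mesh)) stopf("area weighting needs the mesh")
    vertex_areas(mesh)
  } else rep(1, length(values))
  ok <- !is.na(values)
  labs <- vertex_labels[ok]
  out <- tapply(values[ok] * w[ok], labs, sum) / tapply(w[ok], labs, sum)
  empty <- setdiff(unique(vertex_labels), names(out))
  if (length(empty))
    warnf("region(s) with no usable vertices omitted: %s",
          paste(empty, collapse = ", "))
  setNames(as.numeric(out), names(out))
}

#' Full folding morphometry for one surface
#'
#' Convenience wrapper: builds the hull, computes per-vertex sulcal depth
#' and LGI, and aggregates both by the mesh's vertex labels.
#'
#' @param mesh A labelled [surface_mesh()].
#' @param lgi_radius LGI patch radius (mm).
#' @param inclusion Inclusion rule passed to [local_gi()].
#' @param mode Aggregation mode passed to [aggregate_by_region()].
#' @return List with `vertex` (data frame of per-vertex `lgi`, `depth`),
#'   `region` (data frame of per-region means), `mean_lgi`, `mean_depth`
#'   (surface-wide aggregates), and the `hull`.
#' @export
surface_morphometry <- function(mesh, lgi_radius = 10,
                                inclusion = "centroid", mode = "area") {
  hull <- build_hull(mesh)
  depth <- sulcal_depth(mesh, hull)
  lgi <- local_gi(mesh, hull, radius = lgi_radius, inclusion = inclusion)
  labs <- mesh$vertex_labels
  if (is.null(labs)) labs <- rep(1L, nrow(mesh$vertices))
  reg_lgi <- aggregate_by_region(lgi, labs, mesh, mode)
  reg_dep <- aggregate_by_region(depth, labs, mesh, mode)
  regions <- sort(unique(labs))
  region <- data.frame(region = regions,
                       lgi = as.numeric(reg_lgi[as.character(regions)]),
                       depth = as.numeric(reg_dep[as.character(regions)]))
  all_lab <- rep(1L, length(labs))
  list(vertex = data.frame(lgi = lgi, depth = depth, region = labs),
       region = region,
       mean_lgi = as.numeric(aggregate_by_region(lgi, all_lab, mesh, mode)),
       mean_depth = as.numeric(aggregate_by_region(depth, all_lab, mesh,
                                                   mode)),
       hull = hull)
}
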