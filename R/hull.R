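#' Convex hull of a 3D point set
#'
#' Incremental convex hull with outward-oriented triangular facets.
#' Degenerate configurations (cospherical rings, coplanar facets such as
#' cube faces) are resolved by a deterministic symbolic-perturbation
#' jitter of relative magnitude 1e-10 applied only during facet
#' construction; the returned hull carries the original, unperturbed
#' coordinates, so containment holds to well within 1e-6 mm at brain scale.
#'
#' @param points Numeric n x 3 matrix (n >= 4, not all coplanar).
#' @return A list of class `hull_mesh`: `vertices` (hull-vertex
#'   coordinates), `faces` (1-based triples, outward orientation),
#'   `vertex_index` (row of `points` each hull vertex came from).
#' @export
convex_hull3d <- function(points) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) stopf("points must be n x 3")
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 4L) stopf("convex hull needs at least 4 distinct points")
  scale <- max(apply(pts, 2L, function(z) diff(range(z))))
  if (scale <= 0) stopf("degenerate input: all points coincide")

  # reject (near-)coplanar input before any perturbation
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr), nu = 0, nv = 0)$d
  if (sv[3L] < sv[1L] * 1e-9)
    stopf("degenerate input: points are (nearly) coplanar")

  # deterministic jitter to break ties; original coords kept for output
  jit <- with_seed(783901L,
                   matrix(runif(3L * n, -1, 1), n, 3L)) * scale * 1e-10
  p <- pts + jit
  eps <- scale * 1e-12

  # --- initial tetrahedron from extreme points -----------------------------
  i1 <- which.min(p[, 1L]); i2 <- which.max(p[, 1L])
  d12 <- p[i2, ] - p[i1, ]
  rel <- sweep(p, 2L, p[i1, ])
  cr <- cbind(rel[, 2L] * d12[3L] - rel[, 3L] * d12[2L],
              rel[, 3L] * d12[1L] - rel[, 1L] * d12[3L],
              rel[, 1L] * d12[2L] - rel[, 2L] * d12[1L])
  i3 <- which.max(rowSums(cr^2))
  nrm0 <- crossv(p[i2, ] - p[i1, ], p[i3, ] - p[i1, ])
  dist0 <- abs(rel %*% nrm0)
  i4 <- which.max(dist0)
  if (dist0[i4] <= eps * sqrt(sum(nrm0^2)) * 10)
    stopf("degenerate input: points are (nearly) coplanar")
  base <- c(i1, i2, i3, i4)
  c0 <- colMeans(p[base, ])

  cap <- 1024L
  Fm <- matrix(0L, cap, 3L)      # facet vertex indices (into p)
  Nm <- matrix(0, cap, 3L)       # outward unit normals
  Dv <- numeric(cap)             # plane offsets: N . x = D
  alive <- logical(cap)
  nf <- 0L

  add_face <- function(a, b, cc) {
    nrm <- crossv(p[b, ] - p[a, ], p[cc, ] - p[a, ])
    nl <- sqrt(sum(nrm^2))
    if (nl <= 0) return(invisible())          # degenerate sliver; skip
    nrm <- nrm / nl
    d <- sum(nrm * p[a, ])
    if (sum(nrm * c0) - d > 0) {              # flip to outward
      tmp <- b; b <- cc; cc <- tmp
      nrm <- -nrm; d <- -d
    }
    if (nf == cap) {
      cap <<- cap * 2L
      Fm2 <- matrix(0L, cap, 3L); Fm2[seq_len(nf), ] <- Fm[seq_len(nf), ]
      Nm2 <- matrix(0, cap, 3L); Nm2[seq_len(nf), ] <- Nm[seq_len(nf), ]
      Fm <<- Fm2; Nm <<- Nm2
      length(Dv) <<- cap; length(alive) <<- cap
    }
    nf <<- nf + 1L
    Fm[nf, ] <<- c(a, b, cc)
    Nm[nf, ] <<- nrm
    Dv[nf] <<- d
    alive[nf] <<- TRUE
    invisible()
  }

  add_face(base[1L], base[2L], base[3L])
  add_face(base[1L], base[2L], base[4L])
  add_face(base[1L], base[3L], base[4L])
  add_face(base[2L], base[3L], base[4L])

  for (i in setdiff(seq_len(n), base)) {
    act <- which(alive[seq_len(nf)])
    d <- Nm[act, , drop = FALSE] %*% p[i, ] - Dv[act]
    vis <- act[d > eps]
    if (!length(vis)) next                      # interior point
    # horizon: directed edges of visible facets whose twin is not visible
    fv <- Fm[vis, , drop = FALSE]
    ed <- rbind(fv[, c(1L, 2L)], fv[, c(2L, 3L)], fv[, c(3L, 1L)])
    fwd <- paste(ed[, 1L], ed[, 2L])
    rev <- paste(ed[, 2L], ed[, 1L])
    horizon <- ed[!(fwd %in% rev), , drop = FALSE]
    alive[vis] <- FALSE
    for (k in seq_len(nrow(horizon)))
      add_face(horizon[k, 1L], horizon[k, 2L], i)
  }

  keep <- which(alive[seq_len(nf)])
  fm <- Fm[keep, , drop = FALSE]
  used <- sort(unique(as.vector(fm)))
  remap <- integer(n)
  remap[used] <- seq_along(used)
  structure(list(vertices = pts[used, , drop = FALSE],
                 faces = matrix(remap[fm], ncol = 3L),
                 vertex_index = used),
            class = c("hull_mesh", "surface_mesh"))
}

crossv <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Convex hull of a brain surface
#'
#' Builds the convex hull of a hemisphere's gray-white junction surface.
#' The hull is the outer reference against which sulcal depth and the
#' local gyrification index are measured: it touches the gyral crowns and
#' spans the sulci.
#'
#' @param mesh A [surface_mesh()] with at least 4 non-coplanar vertices.
#' @return A `hull_mesh` (also a valid [surface_mesh()]).
#' @export
build_hull <- function(mesh) {
  h <- convex_hull3d(mesh$vertices)
  h$hemisphere <- mesh$hemisphere
  h
}

#' Signed offset of points from a hull
#'
#' Maximum signed distance of each point to the hull's facet planes:
#' <= 0 inside, > 0 outside.  Used to verify hull containment.
#'
#' @param hull A `hull_mesh` from [build_hull()].
#' @param points Numeric n x 3 matrix.
#' @return Numeric vector of signed offsets (mm).
#' @export
hull_offset <- function(hull, points) {
  v <- hull$vertices
  f <- hull$faces
  a <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - a
  e2 <- v[f[, 3L], , drop = FALSE] - a
  nrm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
               e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
               e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  ctr <- colMeans(v)
  s <- sign(rowSums(nrm * sweep(a, 2L, ctr)))   # ensure outward
  nrm <- nrm * s
  d <- rowSums(nrm * a)
  off <- tcrossprod(as.matrix(points), nrm) - rep(d, each = nrow(points))
  apply(off, 1L, max)
}
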