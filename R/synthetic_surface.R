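#' Folded-surface generator parameters
#'
#' Controls for the synthetic gray-white junction surface: an icosphere of
#' `base_radius` mm perturbed radially by a seeded band-limited
#' spherical-harmonic field scaled to `amplitude` mm RMS.  `amplitude = 0`
#' yields an exactly convex sphere (the analytic limit where the local
#' gyrification index is 1 and sulcal depth 0); increasing the amplitude
#' monotonically deepens the folds.
#'
#' @param base_radius Hemisphere radius, mm (fetal scale, default 30).
#' @param amplitude RMS radial fold depth, mm (>= 0).
#' @param max_degree Spherical-harmonic band limit (>= 2); higher degrees
#'   give finer folds.
#' @param subdivisions Icosphere refinement level (>= 1); the mesh has
#'   `10 * 4^subdivisions + 2` vertices.
#' @param seed Integer seed; `NULL` inherits the session RNG stream.
#' @return Validated list of class `folding_params`.
#' @export
folding_params <- function(base_radius = 30, amplitude = 2.5,
                           max_degree = 8, subdivisions = 4, seed = NULL) {
  if (base_radius <= 0) stopf("base_radius must be positive")
  if (amplitude < 0) stopf("amplitude must be nonnegative")
  if (!is_count(max_degree) || max_degree < 2)
    stopf("max_degree must be an integer >= 2")
  if (!is_count(subdivisions)) stopf("subdivisions must be an integer >= 1")
  structure(list(base_radius = base_radius, amplitude = amplitude,
                 max_degree = as.integer(max_degree),
                 subdivisions = as.integer(subdivisions), seed = seed),
            class = "folding_params")
}

#' Unit icosphere
#'
#' Icosahedron subdivided `subdivisions` times with vertices projected to
#' the unit sphere: `10 * 4^s + 2` vertices, `20 * 4^s` faces.
#'
#' @param subdivisions Refinement level (>= 0).
#' @return A [surface_mesh()] on the unit sphere.
#' @export
icosphere <- function(subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    env <- new.env(hash = TRUE, size = 4L * nrow(f))
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- env[[key]]
      if (!is.null(hit)) return(hit)
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- p
      env[[key]] <- nv
      nv
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; cc <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4L * i - 3L, ] <- c(a, ab, ca)
      nf[4L * i - 2L, ] <- c(b, bc, ab)
      nf[4L * i - 1L, ] <- c(cc, ca, bc)
      nf[4L * i, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, c(list(v), vlist[-1L]))
    f <- nf
  }
  surface_mesh(v, f)
}

# Real spherical-harmonic field of degrees 2..lmax with N(0,1) coefficients,
# evaluated at unit directions; returns one value per direction.
sh_random_field <- function(u, lmax) {
  theta <- acos(pmin(1, pmax(-1, u[, 3L])))
  phi <- atan2(u[, 2L], u[, 1L])
  x <- cos(theta)
  f <- numeric(nrow(u))
  for (l in 2:lmax) {
    P <- pracma::legendre(l, x)          # (l+1) x n, rows m = 0..l
    a <- rnorm(2L * l + 1L)
    for (m in 0:l) {
      nlm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      if (m == 0L) {
        f <- f + a[1L] * nlm * P[1L, ]
      } else {
        f <- f + sqrt(2) * nlm * P[m + 1L, ] *
          (a[2L * m] * cos(m * phi) + a[2L * m + 1L] * sin(m * phi))
      }
    }
  }
  f
}

#' Generate a synthetic folded brain surface
#'
#' Closed triangulated surface standing in for a hemisphere's gray-white
#' junction: an icosphere displaced radially by a seeded band-limited
#' spherical-harmonic field normalised to zero mean and unit RMS over the
#' vertices, then scaled by `amplitude`.  Vertices carry one of four
#' region labels assigned by spatial quadrant around the z axis
#' (`"frontal"`, `"parietal"`, `"temporal"`, `"occipital"`) as stand-ins
#' for lobes.
#'
#' @param params A [folding_params()].
#' @return A labelled [surface_mesh()] (mm coordinates).
#' @export
generate_folded_surface <- function(params = folding_params()) {
  stopifnot(inherits(params, "folding_params"))
  mesh <- icosphere(params$subdivisions)
  u <- mesh$vertices
  r <- rep(params$base_radius, nrow(u))
  if (params$amplitude > 0) {
    f <- with_seed(params$seed, sh_random_field(u, params$max_degree))
    f <- (f - mean(f)) / sd(f)
    r <- r + params$amplitude * f
    if (any(r <= 0))
      stopf("amplitude too large: displaced radius became nonpositive")
  }
  v <- u * r
  quad <- 1L + (u[, 1L] < 0) + 2L * (u[, 2L] < 0)
  labels <- c("frontal", "parietal", "temporal", "occipital")[quad]
  surface_mesh(v, mesh$faces, vertex_labels = labels, hemisphere = "left")
}
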