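test_that("hull of a convex mesh reproduces the mesh", {
  m <- icosphere(3)
  h <- build_hull(m)
  expect_equal(nrow(h$vertices), 642L)
  a_mesh <- oracle_mesh_area(m$vertices, m$faces)
  a_hull <- oracle_mesh_area(h$vertices, h$faces)
  expect_equal(a_hull, a_mesh, tolerance = 0.01)
  expect_lt(max(hull_offset(h, m$vertices)), 1e-6)
})

test_that("hull of a cube corner cloud is the 12-triangle cube surface", {
  side <- 2.5
  pts <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  h <- convex_hull3d(pts)
  expect_equal(nrow(h$vertices), 8L)
  expect_equal(nrow(h$faces), 12L)
  expect_equal(oracle_mesh_area(h$vertices, h$faces), 6 * side^2,
               tolerance = 1e-9)
})

test_that("interior points do not enter the hull; degenerate input errors", {
  set.seed(3)
  inner <- matrix(runif(60, -0.4, 0.4), ncol = 3)
  pts <- rbind(as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))), inner)
  h <- convex_hull3d(pts)
  expect_equal(nrow(h$vertices), 8L)
  expect_true(all(hull_offset(h, pts) < 1e-6))
  flat <- cbind(runif(10), runif(10), 0)
  expect_error(convex_hull3d(flat), "coplanar")
  expect_error(convex_hull3d(matrix(1:9, 3, 3)), "at least 4")
})

test_that("a dimpled sphere loses hull area but not containment", {
  m <- dented_sphere(3, dent = 0.3, radius = 20)
  h <- build_hull(m)
  expect_lt(oracle_mesh_area(h$vertices, h$faces),
            oracle_mesh_area(m$vertices, m$faces))
  expect_lt(max(hull_offset(h, m$vertices)), 1e-6)
})

test_that("sulcal depth vanishes on a convex surface", {
  m <- generate_folded_surface(folding_params(amplitude = 0,
                                              subdivisions = 3))
  d <- sulcal_depth(m, build_hull(m))
  expect_true(all(d >= 0))
  expect_lt(max(d), 1e-6)
})

test_that("depth of a dented vertex matches the dent size", {
  radius <- 20; dent <- 0.15
  m <- dented_sphere(3, dent = dent, vertex = 5L, radius = radius)
  h <- build_hull(m)
  d <- sulcal_depth(m, h)
  # the hull facets bridge the dented vertex's neighbours, so the true
  # hull distance is the dent minus at most the facet sagitta ~ e^2 / 2R
  edges <- m$vertices[m$faces[, 1], ] - m$vertices[m$faces[, 2], ]
  e_max <- sqrt(max(rowSums(edges^2)))
  expect_lte(d[5L], radius * dent + 1e-9)
  expect_gte(d[5L], radius * dent - e_max^2 / (2 * radius) - 1e-9)
  expect_true(all(d[-5L] < radius * dent))
})

test_that("exact point-to-hull distance is consistent with dense sampling", {
  set.seed(11)
  m <- generate_folded_surface(folding_params(amplitude = 3,
                                              subdivisions = 2, seed = 8))
  h <- build_hull(m)
  pts <- m$vertices[sample(nrow(m$vertices), 25L), ]
  d_exact <- fetalmorph:::.min_dist_to_mesh(pts, h$vertices, h$faces)
  # oracle: nearest of many random points on the hull surface (area-
  # weighted barycentric samples); an upper bound on the true distance
  areas <- oracle_mesh_area_by_face <- vapply(seq_len(nrow(h$faces)),
    function(i) oracle_mesh_area(h$vertices, h$faces[i, , drop = FALSE]),
    numeric(1))
  nsamp <- 2e5
  fidx <- sample.int(nrow(h$faces), nsamp, replace = TRUE,
                     prob = areas / sum(areas))
  r1 <- sqrt(runif(nsamp)); r2 <- runif(nsamp)
  w <- cbind(1 - r1, r1 * (1 - r2), r1 * r2)
  samp <- w[, 1] * h$vertices[h$faces[fidx, 1], ] +
    w[, 2] * h$vertices[h$faces[fidx, 2], ] +
    w[, 3] * h$vertices[h$faces[fidx, 3], ]
  for (i in seq_len(nrow(pts))) {
    d_orc <- sqrt(min(rowSums(sweep(samp, 2, pts[i, ])^2)))
    expect_lte(d_exact[i], d_orc + 1e-9)
    expect_lt(d_orc - d_exact[i], 0.5)   # sampling resolution slack
  }
})

test_that("LGI is ~1 on a convex surface and undefined balls are flagged", {
  m <- generate_folded_surface(folding_params(amplitude = 0,
                                              subdivisions = 3))
  h <- build_hull(m)
  g <- local_gi(m, h, radius = 10)
  expect_true(all(is.finite(g)))
  expect_gt(mean(g), 0.95)
  expect_lt(mean(g), 1.05)
  expect_error(local_gi(m, h, radius = -1), "positive")
})

test_that("doubling fold amplitude raises mean LGI and mean depth", {
  for (seed in c(2, 3)) {
    a1 <- generate_folded_surface(folding_params(amplitude = 1.5,
                                                 subdivisions = 3,
                                                 seed = seed))
    a2 <- generate_folded_surface(folding_params(amplitude = 3,
                                                 subdivisions = 3,
                                                 seed = seed))
    # deep folds may put a few ball centres out of reach of the hull;
    # those vertices are flagged NA and excluded, which is the tested rule
    m1 <- suppressWarnings(surface_morphometry(a1))
    m2 <- suppressWarnings(surface_morphometry(a2))
    expect_gt(m2$mean_lgi, m1$mean_lgi)
    expect_gt(m2$mean_depth, m1$mean_depth)
  }
})

test_that("centroid-inclusion patch areas agree with adaptive clipping", {
  m <- generate_folded_surface(folding_params(amplitude = 2.5,
                                              subdivisions = 4, seed = 6))
  h <- build_hull(m)
  set.seed(1)
  probe <- m$vertices[sample(nrow(m$vertices), 12L), ]
  r <- 10
  gm <- fetalmorph:::refined_face_geometry(m, r / 4)
  gh <- fetalmorph:::refined_face_geometry(h, r / 4)
  cent_m <- fetalmorph:::.ball_area_sum(probe, gm$centroids, gm$areas, r)
  cent_h <- fetalmorph:::.ball_area_sum(probe, gh$centroids, gh$areas, r)
  clip_m <- fetalmorph:::clipped_ball_areas(m, probe, r, 4L)
  clip_h <- fetalmorph:::clipped_ball_areas(h, probe, r, 4L)
  expect_equal(cent_m / cent_h, clip_m / clip_h, tolerance = 0.05)
})

test_that("metrics are rigid-motion invariant and scale-covariant", {
  m <- generate_folded_surface(folding_params(amplitude = 2.5,
                                              subdivisions = 3, seed = 5))
  h <- build_hull(m)
  d0 <- sulcal_depth(m, h)
  g0 <- local_gi(m, h, radius = 10)
  # rigid motion: rotation about z by 30 deg then a translation
  th <- pi / 6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  vr <- m$vertices %*% t(R) + matrix(c(5, -3, 11), nrow(m$vertices), 3,
                                     byrow = TRUE)
  mr <- surface_mesh(vr, m$faces, m$vertex_labels)
  hr <- build_hull(mr)
  expect_equal(sulcal_depth(mr, hr), d0, tolerance = 1e-6)
  expect_equal(local_gi(mr, hr, radius = 10), g0, tolerance = 1e-6)
  # uniform scale s: depth scales by s, LGI (at radius 10 s) is unchanged
  s <- 2.5
  ms <- surface_mesh(m$vertices * s, m$faces, m$vertex_labels)
  hs <- build_hull(ms)
  expect_equal(sulcal_depth(ms, hs), s * d0, tolerance = 1e-6)
  expect_equal(local_gi(ms, hs, radius = 10 * s), g0, tolerance = 1e-6)
})

test_that("regional aggregation recovers constants and area weighting", {
  m <- generate_folded_surface(folding_params(amplitude = 2,
                                              subdivisions = 2, seed = 3))
  labs <- m$vertex_labels
  const <- rep(3.7, nrow(m$vertices))
  agg <- aggregate_by_region(const, labs, m)
  expect_equal(unname(agg), rep(3.7, 4), tolerance = 1e-12)
  # two-region field with known values
  vals <- ifelse(labs == "frontal", 2, 5)
  agg2 <- aggregate_by_region(vals, labs, m)
  expect_equal(unname(agg2["frontal"]), 2)
  expect_equal(unname(agg2["parietal"]), 5)
  # area-weighted mean matches the explicit weighted-sum oracle
  set.seed(8)
  x <- rnorm(nrow(m$vertices))
  va <- numeric(nrow(m$vertices))
  for (i in seq_len(nrow(m$faces))) {
    a3 <- oracle_mesh_area(m$vertices, m$faces[i, , drop = FALSE]) / 3
    for (k in 1:3) va[m$faces[i, k]] <- va[m$faces[i, k]] + a3
  }
  for (rg in unique(labs)) {
    sel <- labs == rg
    expect_equal(unname(aggregate_by_region(x, labs, m)[rg]),
                 sum(x[sel] * va[sel]) / sum(va[sel]), tolerance = 1e-9)
  }
  # vertex mode is the plain mean
  expect_equal(unname(aggregate_by_region(x, labs, mode = "vertex")[
    "temporal"]), mean(x[labs == "temporal"]))
})

test_that("PLY round trip preserves geometry and region labels", {
  m <- generate_folded_surface(folding_params(amplitude = 2,
                                              subdivisions = 2, seed = 12))
  m$vertex_labels <- as.integer(factor(m$vertex_labels))
  path <- tempfile(fileext = ".ply")
  write_ply(m, path)
  m2 <- read_ply(path)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(m2$faces, m$faces)
  expect_identical(m2$vertex_labels, m$vertex_labels)
  unlink(path)
})
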