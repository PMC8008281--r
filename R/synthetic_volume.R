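#' Generate a synthetic labelled segmentation volume
#'
#' Builds an integer label grid from a region specification.  Two region
#' modes are supported, per entry:
#' \itemize{
#'   \item count mode: `list(label =, count =)` places exactly `count`
#'     voxels of that label as a compact blob grown outward (in world
#'     distance) from a random unoccupied seed voxel;
#'   \item ellipsoid mode: `list(label =, center =, semiaxes =)` (mm,
#'     world coordinates) labels every voxel whose center falls inside the
#'     ellipsoid, exact up to rasterisation.
#' }
#' Regions may not overlap: count-mode blobs only claim free voxels (an
#' error is raised if the grid runs out), and an ellipsoid touching an
#' already-labelled voxel is a specification error.
#'
#' @param region_spec List of region entries as above; empty list gives an
#'   all-background grid.
#' @param dim Grid dimensions, e.g. `c(64, 64, 48)`.
#' @param affine 4x4 voxel-to-world matrix (mm); voxel index `(i,j,k)`
#'   (0-based) maps to the voxel-center world coordinate.
#' @param seed Integer seed for the blob seeds; `NULL` inherits the
#'   session RNG stream.
#' @return A [label_volume()].
#' @export
generate_label_volume <- function(region_spec, dim = c(64, 64, 48),
                                  affine = diag(4), seed = NULL) {
  if (length(dim) != 3L) stopf("dim must have length 3")
  grid <- array(0L, dim = dim)
  idx <- as.matrix(expand.grid(i = seq_len(dim[1L]) - 1L,
                               j = seq_len(dim[2L]) - 1L,
                               k = seq_len(dim[3L]) - 1L))
  world <- idx %*% t(affine[1:3, 1:3]) +
    matrix(affine[1:3, 4L], nrow(idx), 3L, byrow = TRUE)
  with_seed(seed, {
    for (spec in region_spec) {
      lab <- as.integer(spec$label)
      if (is.na(lab) || lab <= 0L)
        stopf("region labels must be positive integers")
      if (!is.null(spec$count)) {
        count <- as.integer(spec$count)
        free <- which(grid == 0L)
        if (count > length(free))
          stopf("label %d: %d voxels requested but only %d free (overlap)",
                lab, count, length(free))
        if (count > 0L) {
          seed_vox <- free[sample.int(length(free), 1L)]
          d2 <- rowSums(sweep(world[free, , drop = FALSE], 2L,
                              world[seed_vox, ])^2)
          grid[free[order(d2)][seq_len(count)]] <- lab
        }
      } else if (!is.null(spec$ellipsoid) || !is.null(spec$center)) {
        ell <- if (!is.null(spec$ellipsoid)) spec$ellipsoid else spec
        u <- sweep(world, 2L, ell$center) %*% diag(1 / ell$semiaxes)
        inside <- rowSums(u^2) <= 1
        if (any(grid[inside] != 0L))
          stopf("label %d: ellipsoid overlaps label(s) %s", lab,
                paste(unique(grid[inside][grid[inside] != 0L]),
                      collapse = ", "))
        grid[inside] <- lab
      } else {
        stopf("region entry needs either count or center/semiaxes")
      }
    }
  })
  label_volume(grid, affine)
}
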