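#' Labelled segmentation volume
#'
#' A 3D integer label grid together with the 4x4 voxel-to-world affine
#' (mm) and an optional label map.  Label code 0 is reserved for
#' background.  All volume computations use the world geometry (the
#' absolute determinant of the affine's 3x3 block), never an isotropic
#' voxel assumption; grids are 0-indexed in voxel space.
#'
#' @param grid 3D integer array of label codes (nonnegative).
#' @param affine 4x4 voxel-to-world matrix (mm); must be invertible.
#' @param label_map Optional named list/vector mapping region names to
#'   label codes.
#' @return Object of class `label_volume`.
#' @export
label_volume <- function(grid, affine = diag(4), label_map = NULL) {
  if (length(dim(grid)) != 3L) stopf("grid must be a 3D array")
  if (any(grid < 0)) stopf("label codes must be nonnegative")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stopf("affine must be 4x4")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stopf("affine is singular")
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, affine = affine, label_map = label_map),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("label_volume: %s grid, voxel %.4g mm^3, %d label(s)\n",
              paste(dim(x$grid), collapse = "x"), voxel_volume(x),
              length(setdiff(unique(as.vector(x$grid)), 0L))))
  invisible(x)
}

#' Voxel volume in mm^3
#'
#' @param lv A [label_volume()].
#' @return Scalar |det(affine[1:3,1:3])| in mm^3.
#' @export
voxel_volume <- function(lv) {
  abs(det(lv$affine[1:3, 1:3]))
}

#' Volume of a set of labels
#'
#' Volume is the number of voxels carrying any of the given codes times
#' the world voxel volume, reported in cm^3.
#'
#' @param lv A [label_volume()].
#' @param codes Integer label codes (an empty set gives 0 cm^3).  When the
#'   volume carries a `label_map`, all codes must be listed in it.
#' @return Volume in cm^3.
#' @export
region_volume <- function(lv, codes) {
  codes <- as.integer(codes)
  if (!is.null(lv$label_map)) {
    known <- as.integer(unlist(lv$label_map))
    bad <- setdiff(codes, known)
    if (length(bad))
      stopf("unknown label code(s): %s", paste(bad, collapse = ", "))
  }
  if (!length(codes)) return(0)
  n <- sum(lv$grid %in% codes)
  n * voxel_volume(lv) / 1000
}

#' Tissue, lobe and whole-brain volume table
#'
#' Combines a tissue segmentation and a regional parcellation of the same
#' scan into one row of volumes (cm^3).  Tissues (cortical gray matter,
#' white matter, deep gray matter, cerebellum, brainstem, ventricles, ...)
#' come from the segmentation volume; lobes come from the parcellation,
#' optionally restricted to a tissue mask in the segmentation (default
#' restriction: white matter, so "frontal lobe volume" is frontal WM).
#' The whole-brain volume is the sum of a configurable subset of tissues
#' (default: all tissues except the ventricles, since ventricular CSF is
#' not brain tissue).
#'
#' @param lv_seg [label_volume()] with tissue labels.
#' @param lv_parc [label_volume()] with parcellation labels; must share
#'   grid shape and affine with `lv_seg`.
#' @param mapping List with elements `tissues` (named list: tissue ->
#'   segmentation codes), `lobes` (named list: lobe -> parcellation codes),
#'   optional `lobe_mask` (segmentation codes the lobes are restricted to;
#'   `NULL` = full lobe), and `whole_brain` (character vector of tissue
#'   names to sum).
#' @return One-row data frame of volumes in cm^3 (tissues, lobes,
#'   `whole_brain`).
#' @export
tissue_table <- function(lv_seg, lv_parc, mapping) {
  if (!identical(dim(lv_seg$grid), dim(lv_parc$grid)))
    stopf("segmentation and parcellation grid shapes differ")
  if (max(abs(lv_seg$affine - lv_parc$affine)) > 1e-9)
    stopf("segmentation and parcellation affines differ")
  if (is.null(mapping$tissues)) stopf("mapping$tissues is required")
  vv <- voxel_volume(lv_seg) / 1000
  out <- list()
  for (tn in names(mapping$tissues))
    out[[tn]] <- region_volume(lv_seg, mapping$tissues[[tn]])
  wb <- mapping$whole_brain
  if (is.null(wb)) wb <- setdiff(names(mapping$tissues), "ventricles")
  miss <- setdiff(wb, names(out))
  if (length(miss))
    stopf("whole_brain names unknown tissue(s): %s",
          paste(miss, collapse = ", "))
  out$whole_brain <- sum(unlist(out[wb]))
  if (!is.null(mapping$lobes)) {
    mask <- mapping$lobe_mask
    in_mask <- if (is.null(mask)) TRUE else
      lv_seg$grid %in% as.integer(mask)
    for (ln in names(mapping$lobes)) {
      sel <- lv_parc$grid %in% as.integer(mapping$lobes[[ln]]) & in_mask
      out[[ln]] <- sum(sel) * vv
    }
  }
  as.data.frame(out)
}

#' Read a labelled volume from NIfTI
#'
#' @param path Path to a `.nii` or `.nii.gz` file of integer labels.
#' @param label_map Optional label map to attach.
#' @return A [label_volume()] with the file's voxel-to-world affine.
#' @export
read_label_volume <- function(path, label_map = NULL) {
  img <- RNifti::readNifti(path)
  grid <- array(as.integer(round(img)), dim = dim(img))
  label_volume(grid, structure(RNifti::xform(img), dimnames = NULL),
               label_map)
}

#' Write a labelled volume as NIfTI
#'
#' @param lv A [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_label_volume <- function(lv, path) {
  img <- RNifti::asNifti(lv$grid)
  RNifti::sform(img) <- structure(lv$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}
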