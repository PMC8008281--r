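#' Triangulated surface mesh
#'
#' Lightweight container for a triangulated brain surface: vertex
#' coordinates in mm, 1-based triangular faces, and an optional per-vertex
#' region label (e.g. lobe membership on a gray-white junction surface).
#'
#' @param vertices Numeric n x 3 matrix of coordinates (mm).
#' @param faces Integer m x 3 matrix of 1-based vertex indices.
#' @param vertex_labels Optional integer/character vector, one label per
#'   vertex.
#' @param hemisphere `"left"`, `"right"`, or `NA` when not applicable.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, vertex_labels = NULL,
                         hemisphere = NA_character_) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stopf("vertices must be n x 3")
  if (ncol(faces) != 3L) stopf("faces must be m x 3")
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stopf("face indices out of range 1..%d", nrow(vertices))
  if (!is.null(vertex_labels) && length(vertex_labels) != nrow(vertices))
    stopf("vertex_labels must have one entry per vertex")
  structure(list(vertices = vertices, faces = faces,
                 vertex_labels = vertex_labels, hemisphere = hemisphere),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces%s%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$vertex_labels)) "" else
                sprintf(", %d regions", length(unique(x$vertex_labels))),
              if (is.na(x$hemisphere)) "" else paste0(" (", x$hemisphere, ")")))
  invisible(x)
}

# Per-face areas via the cross-product formula; always > 0 for valid meshes.
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1L], , drop = FALSE] + v[f[, 2L], , drop = FALSE] +
     v[f[, 3L], , drop = FALSE]) / 3
}

#' Per-vertex area weights
#'
#' Barycentric vertex areas: one third of the total area of the faces
#' incident to each vertex.  They partition the surface area and serve as
#' weights for area-weighted regional summaries.
#'
#' @param mesh A [surface_mesh()].
#' @return Numeric vector, one area (mm^2) per vertex.
#' @export
vertex_areas <- function(mesh) {
  fa <- face_areas(mesh) / 3
  va <- numeric(nrow(mesh$vertices))
  for (k in 1:3) {
    s <- tapply(fa, mesh$faces[, k], sum)
    idx <- as.integer(names(s))
    va[idx] <- va[idx] + as.numeric(s)
  }
  va
}

#' Validate mesh topology
#'
#' Checks that every edge is shared by exactly two faces (closed,
#' manifold surface) and that all face areas are positive.
#'
#' @param mesh A [surface_mesh()].
#' @return `TRUE` invisibly; otherwise an error describing the defect.
#' @export
validate_mesh <- function(mesh) {
  if (any(face_areas(mesh) <= 0)) stopf("mesh has zero-area faces")
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  tab <- table(key)
  if (any(tab != 2L))
    stopf("mesh is not closed: %d edge(s) not shared by exactly 2 faces",
          sum(tab != 2L))
  invisible(TRUE)
}

#' Write a surface mesh as ASCII PLY
#'
#' Vertex coordinates are written as `x y z` float properties; per-vertex
#' region labels, when present, as an integer `region` property.
#'
#' @param mesh A [surface_mesh()].
#' @param path Output file path.
#' @export
write_ply <- function(mesh, path) {
  n <- nrow(mesh$vertices)
  m <- nrow(mesh$faces)
  has_lab <- !is.null(mesh$vertex_labels)
  hdr <- c("ply", "format ascii 1.0",
           "comment fetalmorph surface mesh (mm)",
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z",
           if (has_lab) "property int region",
           sprintf("element face %d", m),
           "property list uchar int vertex_indices",
           "end_header")
  vtx <- apply(format(mesh$vertices, digits = 9, trim = TRUE,
                      scientific = FALSE), 1L, paste, collapse = " ")
  if (has_lab) vtx <- paste(vtx, as.integer(mesh$vertex_labels))
  fac <- paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
               mesh$faces[, 3L] - 1L)
  writeLines(c(hdr, vtx, fac), path)
  invisible(path)
}

#' Read an ASCII PLY surface mesh
#'
#' Supports the subset written by [write_ply()]: ASCII format, float
#' x/y/z vertex properties, optional integer `region` property, triangular
#' faces.
#'
#' @param path PLY file path.
#' @return A [surface_mesh()].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1L] != "ply" || !grepl("ascii", lines[2L]))
    stopf("%s is not an ASCII PLY file", path)
  end <- match("end_header", lines)
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr,
                                                   value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr,
                                                 value = TRUE)))
  vprops <- sub("^property \\S+ ", "",
                hdr[grep("^property (float|double|int|uchar|uint) ", hdr)])
  vlines <- lines[(end + 1L):(end + nv)]
  vdat <- matrix(scan(text = vlines, quiet = TRUE), nrow = nv, byrow = TRUE)
  colnames(vdat) <- vprops[seq_len(ncol(vdat))]
  flines <- lines[(end + nv + 1L):(end + nv + nf)]
  fdat <- matrix(scan(text = flines, quiet = TRUE), nrow = nf, byrow = TRUE)
  if (any(fdat[, 1L] != 3L)) stopf("only triangular faces are supported")
  labs <- if ("region" %in% colnames(vdat)) as.integer(vdat[, "region"])
  surface_mesh(vdat[, c("x", "y", "z")], fdat[, 2:4] + 1L, labs)
}
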