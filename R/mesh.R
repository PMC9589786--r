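#' Construct a triangle mesh
#'
#' A `sm_trimesh` holds vertex positions in 3-space and a triangle
#' connectivity table. Meshes built from spectrogram surfaces are graph
#' surfaces over a planar grid: they are manifold, have a single boundary
#' loop (disk topology), and every triangle is counterclockwise in the
#' `(x, y)` projection.
#'
#' @param vertices numeric `n x 3` matrix of `(x, y, z)` positions.
#' @param triangles integer `m x 3` matrix of 1-based vertex indices.
#' @return An object of class `sm_trimesh` with fields `V` and `F`.
#' @export
sm_trimesh <- function(vertices, triangles) {
  V <- as.matrix(vertices); storage.mode(V) <- "double"
  F <- as.matrix(triangles); storage.mode(F) <- "integer"
  dimnames(V) <- NULL; dimnames(F) <- NULL
  if (ncol(V) != 3L) stop("vertices must be n x 3")
  if (ncol(F) != 3L) stop("triangles must be m x 3")
  if (!all(is.finite(V))) stop("vertex positions must be finite")
  if (min(F) < 1L || max(F) > nrow(V)) stop("triangle index out of range")
  if (any(F[, 1] == F[, 2] | F[, 2] == F[, 3] | F[, 1] == F[, 3])) {
    stop("triangle with repeated vertex index")
  }
  structure(list(V = V, F = F), class = "sm_trimesh")
}

#' @export
print.sm_trimesh <- function(x, ...) {
  cat(sprintf("<sm_trimesh: %d vertices, %d triangles>\n",
              nrow(x$V), nrow(x$F)))
  invisible(x)
}

#' Per-triangle quantities of a mesh
#'
#' `triangle_areas()` returns the 3D (surface) area of every triangle;
#' `triangle_areas_projected()` the signed area of its `(x, y)` projection
#' (positive for counterclockwise triangles); `triangle_fcg()` the frequency
#' of each triangle's centre of gravity, i.e. the mean of its three vertices'
#' y (frequency) coordinates.
#'
#' @param mesh a [sm_trimesh].
#' @return Numeric vector, one value per triangle.
#' @export
triangle_areas <- function(mesh) {
  V <- mesh$V; F <- mesh$F
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname triangle_areas
#' @export
triangle_areas_projected <- function(mesh) {
  V <- mesh$V; F <- mesh$F
  e1 <- V[F[, 2], 1:2, drop = FALSE] - V[F[, 1], 1:2, drop = FALSE]
  e2 <- V[F[, 3], 1:2, drop = FALSE] - V[F[, 1], 1:2, drop = FALSE]
  0.5 * (e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' @rdname triangle_areas
#' @export
triangle_fcg <- function(mesh) {
  V <- mesh$V; F <- mesh$F
  (V[F[, 1], 2] + V[F[, 2], 2] + V[F[, 3], 2]) / 3
}

#' Triangulate a spectrogram surface into a mesh
#'
#' Lifts the uniform `N x N` surface grid to vertices `(x_i, y_j, z_ij)` and
#' connects them by the Delaunay triangulation of the planar `(x, y)` grid.
#' On a uniform rectangular grid every cell's four corners are co-circular,
#' so the Delaunay diagonal is a tie; the tie is broken deterministically
#' toward the "/" diagonal (connecting the lower-right and upper-left cell
#' corners), making connectivity reproducible across runs and platforms.
#' Connectivity depends only on `(x, y)`: heights move vertices but never
#' change the triangle set. For an `N x N` grid the mesh has `N^2` vertices
#' and `2 (N - 1)^2` counterclockwise triangles.
#'
#' @param surface a [sm_surface].
#' @return A [sm_trimesh].
#' @export
build_mesh <- function(surface) {
  stopifnot(inherits(surface, "sm_surface"))
  tx <- surface$times; fy <- surface$freqs
  nt <- length(tx); nf <- length(fy)
  if (nt < 2L || nf < 2L) stop("surface grid must be at least 2 x 2")
  if (anyDuplicated(tx) || anyDuplicated(fy)) {
    stop("degenerate grid: repeated coordinates")
  }
  # vertex k = (j - 1) * nt + i  for grid point (i, j)
  V <- cbind(rep(tx, times = nf),
             rep(fy, each = nt),
             as.vector(surface$z))
  vid <- function(i, j) (j - 1L) * nt + i
  i <- rep(seq_len(nt - 1L), times = nf - 1L)
  j <- rep(seq_len(nf - 1L), each = nt - 1L)
  a <- vid(i, j); b <- vid(i + 1L, j); c <- vid(i, j + 1L); d <- vid(i + 1L, j + 1L)
  # "/" diagonal b--c splits each cell into (a,b,c) and (b,d,c), both CCW
  F <- rbind(cbind(a, b, c), cbind(b, d, c))
  colnames(F) <- NULL
  sm_trimesh(V, F)
}

#' Ordered boundary loop of a disk-topology mesh
#'
#' Returns the single cycle of vertices along edges incident to exactly one
#' triangle, ordered counterclockwise (interior on the left, matching the
#' triangles' counterclockwise orientation). Non-manifold edges (incident to
#' more than two triangles) or multiple boundary loops raise a topology
#' error.
#'
#' @param mesh a [sm_trimesh].
#' @return Integer vector of boundary vertex indices in cycle order (first
#'   vertex not repeated at the end).
#' @export
boundary_loop <- function(mesh) {
  F <- mesh$F
  # directed half-edges in triangle orientation
  he_tail <- c(F[, 1], F[, 2], F[, 3])
  he_head <- c(F[, 2], F[, 3], F[, 1])
  key <- paste(pmin(he_tail, he_head), pmax(he_tail, he_head))
  cnt <- table(key)
  if (any(cnt > 2L)) stop("topology error: non-manifold edge (in > 2 triangles)")
  on_boundary <- cnt[key] == 1L
  bt <- he_tail[on_boundary]; bh <- he_head[on_boundary]
  if (length(bt) == 0L) stop("topology error: mesh has no boundary")
  if (anyDuplicated(bt)) stop("topology error: boundary is not a simple loop")
  nxt <- integer(max(mesh$F))
  nxt[bt] <- bh
  start <- bt[1L]
  loop <- integer(length(bt))
  v <- start
  for (k in seq_along(loop)) {
    loop[k] <- v
    v <- nxt[v]
    if (v == 0L) stop("topology error: broken boundary chain")
    if (v == start && k < length(loop)) {
      stop("topology error: more than one boundary loop")
    }
  }
  if (v != start) stop("topology error: boundary does not close")
  loop
}

#' Mesh file I/O (OFF and OBJ)
#'
#' Plain-text mesh exchange. OFF stores 0-based face indices; OBJ stores
#' 1-based indices and optionally per-vertex texture coordinates (`vt`
#' records), used here to carry a planar embedding alongside the mesh.
#'
#' @param mesh a [sm_trimesh].
#' @param path file path.
#' @param uv optional `n x 2` matrix of planar positions written as `vt`
#'   records (OBJ only).
#' @return Writers return `path` invisibly. `read_off()` returns a
#'   [sm_trimesh]; `read_obj()` a list with elements `mesh` and `uv` (NULL
#'   when absent).
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$V), nrow(mesh$F)), con)
  utils::write.table(format(mesh$V, digits = 17, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$F - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_off
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (trimws(lines[1L]) != "OFF") stop("not an OFF file")
  hdr <- as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  nv <- hdr[1L]; nf <- hdr[2L]
  vl <- lines[3:(2L + nv)]
  fl <- lines[(3L + nv):(2L + nv + nf)]
  V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  F <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"),
                             function(x) as.integer(x[2:4]) + 1L))
  sm_trimesh(V, F)
}

#' @rdname write_off
#' @export
write_obj <- function(mesh, path, uv = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g",
                     mesh$V[, 1], mesh$V[, 2], mesh$V[, 3]), con)
  if (!is.null(uv)) {
    writeLines(sprintf("vt %.17g %.17g", uv[, 1], uv[, 2]), con)
    writeLines(sprintf("f %d/%d %d/%d %d/%d",
                       mesh$F[, 1], mesh$F[, 1], mesh$F[, 2], mesh$F[, 2],
                       mesh$F[, 3], mesh$F[, 3]), con)
  } else {
    writeLines(sprintf("f %d %d %d", mesh$F[, 1], mesh$F[, 2], mesh$F[, 3]),
               con)
  }
  invisible(path)
}

#' @rdname write_off
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  tok <- strsplit(trimws(lines), "\\s+")
  tag <- vapply(tok, function(x) x[1L] %||% "", "")
  V <- do.call(rbind, lapply(tok[tag == "v"],
                             function(x) as.numeric(x[2:4])))
  uv <- if (any(tag == "vt")) {
    do.call(rbind, lapply(tok[tag == "vt"], function(x) as.numeric(x[2:3])))
  } else NULL
  F <- do.call(rbind, lapply(tok[tag == "f"], function(x) {
    as.integer(vapply(strsplit(x[2:4], "/"), `[`, "", 1L))
  }))
  list(mesh = sm_trimesh(V, F), uv = uv)
}
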