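#' Triangulated surface meshes
#'
#' A `surface_mesh` holds vertex positions (mm), triangle faces with
#' consistent winding, and the ordered boundary loops that bound each hole
#' in the surface (anatomical cavities such as valve orifices or vein
#' ostia, or the outer rim of an open sheet).
#'
#' @param vertices numeric matrix, n x 3, positions in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices with a
#'   consistent (outward) winding.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces` and `boundary_loops` (a list of ordered vertex cycles; the
#'   ordering follows the face winding, so loops run counterclockwise
#'   around a hole as seen from outside the surface).
#' @examples
#' m <- mesh_sheet(10, 10, dx = 1)
#' length(m$boundary_loops)  # the outer rim
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  n <- nrow(vertices)
  if (any(faces < 1L) || any(faces > n))
    stop("face references a vertex outside 1..", n)
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
          faces[, 1] == faces[, 3]))
    stop("degenerate face (repeated vertex)")
  # manifoldness: every undirected edge in at most two faces, and shared
  # edges traversed in opposite directions (consistent winding)
  he <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  cnt <- table(key)
  if (any(cnt > 2L))
    stop("non-manifold mesh: an edge is shared by more than two faces")
  dkey <- paste(he[, 1], he[, 2])
  if (anyDuplicated(dkey))
    stop("inconsistent face winding: a directed edge appears twice")
  loops <- .boundary_loops(he[key %in% names(cnt)[cnt == 1L], , drop = FALSE])
  structure(list(vertices = vertices, faces = faces, boundary_loops = loops),
            class = "surface_mesh")
}

# assemble boundary half-edges (each belonging to exactly one face) into
# ordered cycles following the face winding
.boundary_loops <- function(bedges) {
  if (nrow(bedges) == 0L) return(list())
  nxt <- setNames(bedges[, 2], as.character(bedges[, 1]))
  if (length(nxt) != length(unique(names(nxt))))
    stop("boundary edges do not form simple loops")
  loops <- list()
  remaining <- setNames(rep(TRUE, nrow(bedges)), names(nxt))
  while (any(remaining)) {
    s <- as.integer(names(remaining)[remaining][1])
    loop <- s
    v <- nxt[[as.character(s)]]
    remaining[as.character(s)] <- FALSE
    while (v != s) {
      loop <- c(loop, v)
      remaining[as.character(v)] <- FALSE
      v <- nxt[[as.character(v)]]
      if (length(loop) > length(nxt)) stop("boundary edges do not close")
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, %d boundary loop(s)\n",
              nrow(x$vertices), nrow(x$faces), length(x$boundary_loops)))
  invisible(x)
}

#' Flat triangulated sheet fixture, optionally with a circular hole
#'
#' Builds a regular grid in the xy-plane (z = 0), split into right
#' triangles with a consistent counterclockwise winding (outward normal
#' +z). With a hole, vertices strictly inside the disc are removed and the
#' rim becomes an interior boundary loop (an anatomical cavity stand-in).
#'
#' @param width,height extents in mm.
#' @param dx grid spacing in mm.
#' @param hole_center optional c(x, y) in mm.
#' @param hole_radius hole radius in mm.
#' @return A [surface_mesh()].
#' @export
mesh_sheet <- function(width = 40, height = 40, dx = 0.5,
                       hole_center = NULL, hole_radius = 5) {
  nx <- as.integer(round(width / dx)) + 1L
  ny <- as.integer(round(height / dx)) + 1L
  xs <- rep((seq_len(nx) - 1L) * dx, times = ny)
  ys <- rep((seq_len(ny) - 1L) * dx, each = nx)
  keep <- rep(TRUE, nx * ny)
  if (!is.null(hole_center)) {
    d2 <- (xs - hole_center[1])^2 + (ys - hole_center[2])^2
    keep <- d2 >= hole_radius^2
  }
  newid <- cumsum(keep)
  newid[!keep] <- NA_integer_
  vid <- function(i, j) newid[(j - 1L) * nx + i]
  faces <- vector("list", 2L * (nx - 1L) * (ny - 1L))
  k <- 0L
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      a <- vid(i, j); b <- vid(i + 1L, j)
      c_ <- vid(i + 1L, j + 1L); d <- vid(i, j + 1L)
      if (!anyNA(c(a, b, d))) { k <- k + 1L; faces[[k]] <- c(a, b, d) }
      if (!anyNA(c(b, c_, d))) { k <- k + 1L; faces[[k]] <- c(b, c_, d) }
    }
  }
  faces <- do.call(rbind, faces[seq_len(k)])
  verts <- cbind(xs[keep], ys[keep], 0)
  surface_mesh(verts, faces)
}

#' Triangulated sphere fixture (subdivided icosahedron)
#'
#' Closed surface with no boundary loops; used to exercise the
#' index-theorem conservation law, which requires a closed surface.
#'
#' @param radius sphere radius in mm.
#' @param subdiv number of 4-to-1 subdivision passes (0 = icosahedron).
#' @return A [surface_mesh()] with outward-facing winding.
#' @export
mesh_sphere <- function(radius = 20, subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid <- new.env()
    getmid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid[[key]])) return(mid[[key]])
      p <- (v[a, ] + v[b, ]) / 2
      v <<- rbind(v, p)
      mid[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- vector("list", nrow(f) * 4L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- getmid(a, b); bc <- getmid(b, c_); ca <- getmid(c_, a)
      nf[[4 * i - 3]] <- c(a, ab, ca)
      nf[[4 * i - 2]] <- c(b, bc, ab)
      nf[[4 * i - 1]] <- c(c_, ca, bc)
      nf[[4 * i]] <- c(ab, bc, ca)
    }
    f <- do.call(rbind, nf)
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  surface_mesh(v, f)
}

# unique undirected edges with lengths
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  d <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  list(edges = e, lengths = d)
}

# symmetric CSR (0-based) adjacency over mesh vertices, edge-length weights
mesh_csr <- function(mesh) {
  ed <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  from <- c(ed$edges[, 1], ed$edges[, 2])
  to <- c(ed$edges[, 2], ed$edges[, 1])
  w <- c(ed$lengths, ed$lengths)
  o <- order(from, to)
  from <- from[o]; to <- to[o]; w <- w[o]
  ptr <- c(0L, cumsum(tabulate(from, nbins = n)))
  list(ptr = as.integer(ptr), idx = as.integer(to - 1L), w = w, n = n)
}

# area-weighted vertex normals from face winding
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    idx <- f[, k]
    acc <- rowsum(fn, idx)
    rows <- as.integer(rownames(acc))
    nrm[rows, ] <- nrm[rows, ] + acc
  }
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- NA_real_  # degenerate: flagged downstream
  nrm / len
}

# cotangent Laplacian weights for monodomain diffusion on a triangulated
# surface; returns CSR with w_ij = D * (cot a + cot b) / (2 * A_i).
# With a fiber direction, each edge weight is scaled by
# cos^2(theta) + cv_frac^2 sin^2(theta) (theta = angle edge/fiber), which
# reduces transverse CV to cv_frac of the longitudinal value.
cotan_csr <- function(mesh, D, fiber = NULL, cv_frac = 0.5) {
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(v)
  cot3 <- function(a, b, c_) {
    # cotangent of the angle at vertex a in triangle (a,b,c)
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w_ <- v[c_, , drop = FALSE] - v[a, , drop = FALSE]
    dot <- rowSums(u * w_)
    crs <- cbind(u[, 2] * w_[, 3] - u[, 3] * w_[, 2],
                 u[, 3] * w_[, 1] - u[, 1] * w_[, 3],
                 u[, 1] * w_[, 2] - u[, 2] * w_[, 1])
    dot / sqrt(rowSums(crs^2))
  }
  # half-weight contributions: edge (b,c) opposite vertex a gets cot(a)/2
  ct1 <- cot3(f[, 1], f[, 2], f[, 3])
  ct2 <- cot3(f[, 2], f[, 3], f[, 1])
  ct3v <- cot3(f[, 3], f[, 1], f[, 2])
  ei <- rbind(f[, c(2, 3)], f[, c(3, 1)], f[, c(1, 2)])
  cw <- c(ct1, ct2, ct3v) / 2
  # vertex areas: one third of incident triangle areas
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  crs <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  fa <- sqrt(rowSums(crs^2)) / 2
  area <- rep(0, n)
  for (k in 1:3) {
    acc <- rowsum(fa, f[, k])
    area[as.integer(rownames(acc))] <- area[as.integer(rownames(acc))] + acc / 3
  }
  key <- paste(pmin(ei[, 1], ei[, 2]), pmax(ei[, 1], ei[, 2]))
  wsum <- tapply(cw, key, sum)
  ek <- do.call(rbind, strsplit(names(wsum), " "))
  ea <- as.integer(ek[, 1]); eb <- as.integer(ek[, 2])
  wv <- pmax(as.numeric(wsum), 0)   # clamp obtuse-negative weights
  if (!is.null(fiber)) {
    fiber <- fiber / sqrt(sum(fiber^2))
    ev <- v[eb, , drop = FALSE] - v[ea, , drop = FALSE]
    ev <- ev / sqrt(rowSums(ev^2))
    c2 <- as.numeric((ev %*% fiber))^2
    wv <- wv * (c2 + cv_frac^2 * (1 - c2))
  }
  from <- c(ea, eb); to <- c(eb, ea)
  w <- c(wv, wv) * D / area[from]
  o <- order(from, to)
  from <- from[o]; to <- to[o]; w <- w[o]
  ptr <- c(0L, cumsum(tabulate(from, nbins = n)))
  list(ptr = as.integer(ptr), idx = as.integer(to - 1L), w = w, n = n)
}

#' Read a triangulated surface mesh from an ASCII file
#'
#' Supports ASCII PLY, OFF, and legacy VTK polydata. Lengths are taken as
#' millimetres.
#'
#' @param path file path.
#' @param format `"auto"` (from extension) or one of `"ply"`, `"off"`, `"vtk"`.
#' @return A [surface_mesh()].
#' @export
read_surface_mesh <- function(path, format = c("auto", "ply", "off", "vtk")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", off = "off", vtk = "vtk",
                     stop("cannot infer mesh format from extension: ", ext))
  }
  lines <- readLines(path, warn = FALSE)
  switch(format,
    ply = .read_ply(lines),
    off = .read_off(lines),
    vtk = .read_vtk(lines))
}

.read_ply <- function(lines) {
  stopifnot(trimws(lines[1]) == "ply")
  hdr_end <- which(trimws(lines) == "end_header")[1]
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format\\s+ascii", hdr))) stop("only ASCII PLY supported")
  nv <- as.integer(sub("^element\\s+vertex\\s+", "", grep("^element\\s+vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element\\s+face\\s+", "", grep("^element\\s+face", hdr, value = TRUE)[1]))
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vl <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"), as.numeric))
  fl <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"), as.numeric))
  if (any(fl[, 1] != 3)) stop("non-triangular face in PLY")
  surface_mesh(vl[, 1:3, drop = FALSE], fl[, 2:4, drop = FALSE] + 1L)
}

.read_off <- function(lines) {
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  stopifnot(trimws(lines[1]) == "OFF")
  hd <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- hd[1]; nf <- hd[2]
  vl <- do.call(rbind, lapply(strsplit(trimws(lines[2 + seq_len(nv)]), "\\s+"), as.numeric))
  fl <- do.call(rbind, lapply(strsplit(trimws(lines[2 + nv + seq_len(nf)]), "\\s+"), as.numeric))
  if (any(fl[, 1] != 3)) stop("non-triangular face in OFF")
  surface_mesh(vl[, 1:3, drop = FALSE], fl[, 2:4, drop = FALSE] + 1L)
}

.read_vtk <- function(lines) {
  pts_i <- grep("^POINTS", lines)[1]
  np <- as.integer(strsplit(trimws(lines[pts_i]), "\\s+")[[1]][2])
  nums <- numeric(0)
  i <- pts_i + 1L
  while (length(nums) < 3 * np) {
    nums <- c(nums, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1L
  }
  verts <- matrix(nums[seq_len(3 * np)], ncol = 3, byrow = TRUE)
  poly_i <- grep("^POLYGONS", lines)[1]
  nf <- as.integer(strsplit(trimws(lines[poly_i]), "\\s+")[[1]][2])
  ints <- integer(0)
  i <- poly_i + 1L
  while (i <= length(lines) && length(ints) < 4 * nf) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) break
    ints <- c(ints, as.integer(strsplit(ln, "\\s+")[[1]]))
    i <- i + 1L
  }
  fl <- matrix(ints[seq_len(4 * nf)], ncol = 4, byrow = TRUE)
  if (any(fl[, 1] != 3)) stop("non-triangular polygon in VTK")
  surface_mesh(verts, fl[, 2:4, drop = FALSE] + 1L)
}

#' Write a surface mesh to ASCII PLY
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(path)
}
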