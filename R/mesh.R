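#' Triangle meshes
#'
#' Minimal triangle-mesh container for epicardial shell geometry: an
#' `n x 3` vertex matrix (mm) and an `m x 3` face matrix of 1-based vertex
#' indices.  Degenerate (zero-area) faces are dropped at construction with
#' a message reporting the count.
#'
#' @param vertices numeric matrix, one vertex per row, columns x/y/z in mm.
#' @param faces integer matrix, one triangle per row, 1-based indices.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be n x 3", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must be m x 3", call. = FALSE)
  if (!all(is.finite(vertices)))
    stop("vertex coordinates must be finite", call. = FALSE)
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  areas <- face_areas(vertices, faces)
  degen <- areas <= .Machine$double.eps * 100
  if (any(degen)) {
    message(sum(degen), " degenerate (zero-area) face(s) dropped")
    faces <- faces[!degen, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

face_areas <- function(vertices, faces) {
  if (nrow(faces) == 0L) return(numeric(0))
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c <- vertices[faces[, 3L], , drop = FALSE]
  cr <- cross3(b - a, c - a)
  0.5 * sqrt(rowSums(cr^2))
}

cross3 <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

# undirected edge table with face incidence counts
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  key <- paste(e[, 1L], e[, 2L])
  tab <- table(key)
  u <- !duplicated(key)
  data.frame(v1 = e[u, 1L], v2 = e[u, 2L],
             n_faces = as.integer(tab[key[u]]))
}

#' Euler characteristic of a triangle mesh
#'
#' `V - E + F`; 2 for closed genus-0 surfaces, 0 for a torus.
#'
#' @param mesh a [triangle_mesh()].
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

#' Read a surface mesh from STL, OBJ or PLY
#'
#' Supports ASCII and binary (little-endian) STL, Wavefront OBJ
#' (triangulated; `v`/`f` records, `f` may carry `/`-separated texture and
#' normal indices) and ASCII PLY.  Binary PLY is rejected with a parse
#' error.  Faces with more than three vertices are fan-triangulated.
#' Vertex coordinates are preserved as stored (up to the 32-bit float
#' precision binary STL itself uses).
#'
#' @param path file path.
#' @param format one of `"stl"`, `"obj"`, `"ply"`; default inferred from
#'   the file extension.
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("stl", "obj", "ply"))
  switch(format,
         stl = read_stl(path),
         obj = read_obj(path),
         ply = read_ply(path))
}

read_stl <- function(path) {
  # binary STL: 80-byte header, uint32 count, 50-byte records
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 80L)
  nf <- if (sz >= 84) readBin(con, "integer", n = 1L, size = 4L,
                              endian = "little") else -1L
  if (sz == 84 + 50 * max(nf, 0L) && nf >= 0L) {
    rec <- readBin(con, "raw", n = 50L * nf)
    dim(rec) <- c(50L, nf)
    tri <- apply(rec[1:48, , drop = FALSE], 2L, function(r)
      readBin(r, "double", n = 12L, size = 4L, endian = "little"))
    v <- t(tri[4:12, , drop = FALSE])           # nf x 9, normals dropped
    verts <- matrix(as.vector(t(v)), ncol = 3L, byrow = TRUE)
    return(index_soup(verts))
  }
  close(con)
  on.exit()
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^\\s*solid", lines[1L]))
    stop("STL parse error: file is neither a well-formed binary STL ",
         "nor an ASCII STL starting with 'solid'", call. = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl))
    stop("STL parse error: no 'vertex' records found", call. = FALSE)
  vals <- lapply(vl, function(l) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1L]][2:4]))
    if (anyNA(x)) stop("STL parse error at record: ", trimws(l),
                       call. = FALSE)
    x
  })
  verts <- do.call(rbind, vals)
  if (nrow(verts) %% 3L != 0L)
    stop("STL parse error: vertex count ", nrow(verts),
         " is not a multiple of 3 (truncated facet?)", call. = FALSE)
  index_soup(verts)
}

# triangle soup (3 rows per face) -> indexed mesh, merging exact duplicates
index_soup <- function(verts) {
  key <- apply(verts, 1L, function(p)
    paste(sprintf("%.17g", p), collapse = " "))
  uid <- match(key, unique(key))
  uv <- verts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  triangle_mesh(uv, faces)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "\\s+")
  verts <- list(); faces <- list()
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (!length(tk) || tk[1L] == "" || startsWith(tk[1L], "#")) next
    if (tk[1L] == "v") {
      xyz <- suppressWarnings(as.numeric(tk[2:4]))
      if (anyNA(xyz))
        stop("OBJ parse error at line ", i, ": ", lines[i], call. = FALSE)
      verts[[length(verts) + 1L]] <- xyz
    } else if (tk[1L] == "f") {
      idx <- suppressWarnings(
        as.integer(vapply(tk[-1L], function(s)
          strsplit(s, "/", fixed = TRUE)[[1L]][1L], "")))
      if (anyNA(idx) || length(idx) < 3L)
        stop("OBJ parse error at line ", i, ": ", lines[i], call. = FALSE)
      idx[idx < 0L] <- length(verts) + 1L + idx[idx < 0L]
      for (j in seq_len(length(idx) - 2L))   # fan triangulation
        faces[[length(faces) + 1L]] <- idx[c(1L, j + 1L, j + 2L)]
    }
  }
  if (!length(verts)) stop("OBJ parse error: no vertices", call. = FALSE)
  if (!length(faces)) stop("OBJ parse error: no faces", call. = FALSE)
  triangle_mesh(do.call(rbind, verts), do.call(rbind, faces))
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1L]) != "ply")
    stop("PLY parse error: missing 'ply' magic line", call. = FALSE)
  hdr_end <- which(trimws(lines) == "end_header")[1L]
  if (is.na(hdr_end))
    stop("PLY parse error: no end_header", call. = FALSE)
  hdr <- trimws(lines[seq_len(hdr_end)])
  fmt <- grep("^format", hdr, value = TRUE)
  if (!length(fmt) || !grepl("ascii", fmt[1L]))
    stop("PLY parse error: only ASCII PLY is supported (format line: ",
         fmt[1L], ")", call. = FALSE)
  elems <- grep("^element", hdr)
  get_count <- function(what) {
    l <- grep(paste0("^element\\s+", what), hdr, value = TRUE)
    if (!length(l)) stop("PLY parse error: no '", what, "' element",
                         call. = FALSE)
    as.integer(strsplit(l[1L], "\\s+")[[1L]][3L])
  }
  nv <- get_count("vertex"); nf <- get_count("face")
  body <- lines[(hdr_end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf)
    stop("PLY parse error: truncated body (expected ", nv + nf,
         " records, found ", length(body), ")", call. = FALSE)
  vt <- do.call(rbind, lapply(body[seq_len(nv)], function(l) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1L]][1:3]))
    if (anyNA(x)) stop("PLY parse error at vertex record: ", l,
                       call. = FALSE)
    x
  }))
  faces <- list()
  for (l in body[nv + seq_len(nf)]) {
    x <- suppressWarnings(as.integer(strsplit(trimws(l), "\\s+")[[1L]]))
    if (anyNA(x[1L]) || length(x) < x[1L] + 1L || x[1L] < 3L)
      stop("PLY parse error at face record: ", l, call. = FALSE)
    idx <- x[1L + seq_len(x[1L])] + 1L          # PLY is 0-based
    for (j in seq_len(length(idx) - 2L))
      faces[[length(faces) + 1L]] <- idx[c(1L, j + 1L, j + 2L)]
  }
  triangle_mesh(vt, do.call(rbind, faces))
}

#' Write a triangle mesh as ASCII STL, OBJ or ASCII PLY
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param format inferred from extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("stl", "obj", "ply"))
  v <- mesh$vertices; f <- mesh$faces
  out <- switch(format,
    stl = {
      n <- face_normals(mesh)
      c("solid epimap",
        unlist(lapply(seq_len(nrow(f)), function(i) c(
          sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
          "    outer loop",
          sprintf("      vertex %.9g %.9g %.9g",
                  v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
          "    endloop", "  endfacet"))),
        "endsolid epimap")
    },
    obj = c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
            sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])),
    ply = c("ply", "format ascii 1.0",
            sprintf("element vertex %d", nrow(v)),
            "property float x", "property float y", "property float z",
            sprintf("element face %d", nrow(f)),
            "property list uchar int vertex_indices", "end_header",
            sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
            sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)))
  writeLines(out, path)
  invisible(path)
}

face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  cr <- cross3(v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE],
               v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE])
  cr / pmax(sqrt(rowSums(cr^2)), .Machine$double.eps)
}

#' Parametric mesh generators
#'
#' Closed and open fixture meshes used for curvature validation and demos:
#' an icosahedron, a subdivided icosphere (vertices projected to radius
#' `radius_mm`), a flat triangulated plane grid, and a torus.
#'
#' @param radius_mm sphere radius, mm.
#' @param subdivisions icosphere subdivision depth (0 = icosahedron).
#' @param nx,ny plane grid vertex counts.
#' @param spacing_mm plane grid spacing, mm.
#' @param R_mm,r_mm torus major/minor radii, mm.
#' @param nu,nv torus discretisation along the major/minor circles.
#' @return A [triangle_mesh()].
#' @name mesh_generators
NULL

#' @rdname mesh_generators
#' @export
mesh_icosahedron <- function(radius_mm = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2)) * radius_mm
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  triangle_mesh(v, f)
}

#' @rdname mesh_generators
#' @export
mesh_icosphere <- function(radius_mm = 1, subdivisions = 3L) {
  m <- mesh_icosahedron(radius_mm)
  for (s in seq_len(subdivisions)) {
    v <- m$vertices; f <- m$faces
    ed <- mesh_edges(m)
    ekey <- paste(ed$v1, ed$v2)
    mid <- (v[ed$v1, , drop = FALSE] + v[ed$v2, , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2)) * radius_mm
    midx <- nrow(v) + seq_len(nrow(ed))
    names(midx) <- ekey
    mkey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    m12 <- midx[mkey(f[, 1L], f[, 2L])]
    m23 <- midx[mkey(f[, 2L], f[, 3L])]
    m31 <- midx[mkey(f[, 3L], f[, 1L])]
    nf <- rbind(cbind(f[, 1L], m12, m31), cbind(f[, 2L], m23, m12),
                cbind(f[, 3L], m31, m23), cbind(m12, m23, m31))
    m <- triangle_mesh(rbind(v, mid), nf)
  }
  m
}

#' @rdname mesh_generators
#' @export
mesh_plane_grid <- function(nx = 5L, ny = 5L, spacing_mm = 1) {
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  v <- cbind((g$x - 1) * spacing_mm, (g$y - 1) * spacing_mm, 0)
  id <- function(i, j) (j - 1L) * nx + i
  f <- list()
  for (j in seq_len(ny - 1L)) for (i in seq_len(nx - 1L)) {
    f[[length(f) + 1L]] <- c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L))
    f[[length(f) + 1L]] <- c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
  }
  triangle_mesh(v, do.call(rbind, f))
}

#' @rdname mesh_generators
#' @export
mesh_torus <- function(R_mm = 3, r_mm = 1, nu = 24L, nv = 12L) {
  iu <- seq_len(nu) - 1L; iv <- seq_len(nv) - 1L
  g <- expand.grid(u = iu, v = iv)
  th <- 2 * pi * g$u / nu; ph <- 2 * pi * g$v / nv
  vtx <- cbind((R_mm + r_mm * cos(ph)) * cos(th),
               (R_mm + r_mm * cos(ph)) * sin(th),
               r_mm * sin(ph))
  id <- function(u, v) (v %% nv) * nu + (u %% nu) + 1L
  f <- list()
  for (v0 in iv) for (u0 in iu) {
    a <- id(u0, v0); b <- id(u0 + 1L, v0)
    c <- id(u0 + 1L, v0 + 1L); d <- id(u0, v0 + 1L)
    f[[length(f) + 1L]] <- c(a, b, c)
    f[[length(f) + 1L]] <- c(a, c, d)
  }
  triangle_mesh(vtx, do.call(rbind, f))
}
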