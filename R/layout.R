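#' Electrode layouts
#'
#' An `electrode_layout` describes the geometry of a multichannel mapping
#' array: one row per electrode with a unique integer channel id, a 3-D
#' position in millimetres, optional regular-grid indices, and an active
#' flag.  Layouts are shared by the wavefront simulator, conduction-velocity
#' estimation and spatial interpolation.
#'
#' @param channel_id integer vector of unique channel labels.
#' @param x_mm,y_mm,z_mm numeric electrode coordinates, mm.
#' @param row,col optional integer grid indices (1-based); `(row, col)`
#'   pairs must be unique when present.
#' @param active logical contact flag, default all `TRUE`.
#' @return A data frame of class `electrode_layout` with columns
#'   `channel_id, x_mm, y_mm, z_mm, row, col, active`.
#' @examples
#' lay <- grid_layout(4, 4, 3.5)
#' nrow(lay)
#' @export
electrode_layout <- function(channel_id, x_mm, y_mm, z_mm = 0,
                             row = NA_integer_, col = NA_integer_,
                             active = TRUE) {
  n <- length(channel_id)
  lay <- data.frame(
    channel_id = as.integer(channel_id),
    x_mm = as.numeric(x_mm), y_mm = as.numeric(y_mm),
    z_mm = rep_len(as.numeric(z_mm), n),
    row = rep_len(as.integer(row), n), col = rep_len(as.integer(col), n),
    active = rep_len(as.logical(active), n)
  )
  class(lay) <- c("electrode_layout", "data.frame")
  validate_layout(lay)
  lay
}

validate_layout <- function(lay) {
  stopifnot(is.data.frame(lay))
  if (nrow(lay) < 2L)
    stop("an electrode layout needs at least 2 channels", call. = FALSE)
  if (anyDuplicated(lay$channel_id))
    stop("channel ids must be unique", call. = FALSE)
  pos <- layout_positions(lay)
  if (!all(is.finite(pos)))
    stop("electrode positions must be finite", call. = FALSE)
  d <- stats::dist(pos)
  if (any(d <= 0))
    stop("electrode positions must be pairwise distinct", call. = FALSE)
  if (has_grid(lay)) {
    if (anyDuplicated(lay[, c("row", "col")]))
      stop("grid (row, col) pairs must be unique", call. = FALSE)
  }
  invisible(lay)
}

has_grid <- function(layout) {
  !anyNA(layout$row) && !anyNA(layout$col)
}

layout_positions <- function(layout) {
  m <- as.matrix(layout[, c("x_mm", "y_mm", "z_mm")])
  rownames(m) <- layout$channel_id
  m
}

#' Regular planar electrode grid
#'
#' Builds the default high-density mapping array: a planar `rows x cols`
#' grid of unipolar electrodes with uniform spacing.  The package default
#' mirrors a 16 x 16 (256-channel) flexible epicardial array with 3.5 mm
#' interelectrode spacing.  Channel ids are row-major consecutive integers
#' starting at 1.
#'
#' @param rows,cols grid dimensions, each >= 1 (with `rows * cols >= 2`).
#' @param spacing_mm interelectrode spacing, mm, > 0.
#' @return An [electrode_layout()].
#' @examples
#' lay <- grid_layout()          # 16 x 16, 3.5 mm: 256 channels
#' grid_layout(3, 3, 2)$x_mm
#' @export
grid_layout <- function(rows = 16L, cols = 16L, spacing_mm = 3.5) {
  if (length(rows) != 1L || length(cols) != 1L || rows < 1 || cols < 1 ||
      rows != round(rows) || cols != round(cols))
    stop("rows and cols must be positive integers", call. = FALSE)
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    stop("spacing_mm must be a positive number", call. = FALSE)
  rc <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  electrode_layout(
    channel_id = seq_len(rows * cols),
    x_mm = (rc$col - 1L) * spacing_mm,
    y_mm = (rc$row - 1L) * spacing_mm,
    z_mm = 0,
    row = rc$row, col = rc$col
  )
}

#' Read / write electrode layout tables
#'
#' Layout files are plain CSV with the header
#' `channel_id,x_mm,y_mm,z_mm,row,col,active`.
#'
#' @param path file path.
#' @param layout an [electrode_layout()].
#' @return `read_layout_csv` returns an [electrode_layout()];
#'   `write_layout_csv` returns `path` invisibly.
#' @export
read_layout_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("channel_id", "x_mm", "y_mm", "z_mm", "row", "col", "active")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("layout file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  electrode_layout(df$channel_id, df$x_mm, df$y_mm, df$z_mm,
                   df$row, df$col, df$active)
}

#' @rdname read_layout_csv
#' @export
write_layout_csv <- function(layout, path) {
  validate_layout(layout)
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Spatial adjacency graph over an electrode layout
#'
#' Builds the undirected neighbour graph used as the substrate for geodesic
#' wavefront simulation, local conduction-velocity fits and spatial
#' interpolation.  Edge lengths are Euclidean distances in mm.  Inactive
#' channels are excluded.
#'
#' Modes: `"grid8"` connects each electrode to its (up to) 8 row/column
#' neighbours including diagonals and requires grid indices; `"knn"`
#' connects each electrode to its `k` nearest neighbours (symmetrised);
#' `"radius"` connects all pairs closer than `radius_mm`.
#'
#' @param layout an [electrode_layout()].
#' @param mode `"grid8"` (default), `"knn"` or `"radius"`.
#' @param k neighbour count for `"knn"`.
#' @param radius_mm cutoff for `"radius"`.
#' @return An object of class `adjacency_graph`: a list with the `igraph`
#'   graph (`graph`, vertex name = channel id, edge attribute `length_mm`)
#'   and an edge table `edges` (`from, to, length_mm`).
#' @examples
#' g <- build_adjacency(grid_layout(3, 3, 2))
#' igraph::degree(g$graph)   # centre electrode has degree 8
#' @export
build_adjacency <- function(layout, mode = c("grid8", "knn", "radius"),
                            k = 4L, radius_mm = NULL) {
  mode <- match.arg(mode)
  validate_layout(layout)
  lay <- layout[layout$active, , drop = FALSE]
  if (nrow(lay) < 2L)
    stop("fewer than 2 active channels", call. = FALSE)
  pos <- layout_positions(lay)
  n <- nrow(lay)

  pairs <- switch(mode,
    grid8 = {
      if (!has_grid(lay))
        stop("grid8 adjacency requires grid (row, col) indices; ",
             "use mode = 'knn' or 'radius' for non-grid layouts",
             call. = FALSE)
      idx <- which(
        outer(lay$row, lay$row, function(a, b) abs(a - b) <= 1L) &
        outer(lay$col, lay$col, function(a, b) abs(a - b) <= 1L),
        arr.ind = TRUE)
      idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    },
    knn = {
      if (k < 1L) stop("k must be >= 1", call. = FALSE)
      dm <- as.matrix(stats::dist(pos))
      diag(dm) <- Inf
      nb <- t(apply(dm, 1L, function(d) order(d)[seq_len(min(k, n - 1L))]))
      idx <- cbind(rep(seq_len(n), ncol(nb)), as.vector(nb))
      idx <- t(apply(idx, 1L, sort))
      unique(idx)
    },
    radius = {
      if (is.null(radius_mm) || radius_mm <= 0)
        stop("radius mode needs a positive radius_mm", call. = FALSE)
      dm <- as.matrix(stats::dist(pos))
      idx <- which(dm <= radius_mm & upper.tri(dm), arr.ind = TRUE)
      idx[, c(1L, 2L), drop = FALSE]
    })

  if (nrow(pairs) == 0L)
    stop("adjacency graph has no edges under mode '", mode, "'",
         call. = FALSE)
  len <- sqrt(rowSums((pos[pairs[, 1L], , drop = FALSE] -
                       pos[pairs[, 2L], , drop = FALSE])^2))
  edges <- data.frame(from = lay$channel_id[pairs[, 1L]],
                      to   = lay$channel_id[pairs[, 2L]],
                      length_mm = len)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to),
               length_mm = edges$length_mm),
    directed = FALSE,
    vertices = data.frame(name = as.character(lay$channel_id)))
  structure(list(graph = g, edges = edges, mode = mode),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("<adjacency_graph: %d nodes, %d edges, mode '%s'>\n",
              igraph::vcount(x$graph), nrow(x$edges), x$mode))
  invisible(x)
}

# named list: channel id -> integer vector of neighbour channel ids
adjacency_neighbors <- function(graph) {
  g <- graph$graph
  ids <- igraph::V(g)$name
  nb <- lapply(igraph::adjacent_vertices(g, igraph::V(g)),
               function(v) as.integer(v$name))
  names(nb) <- ids
  nb
}
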