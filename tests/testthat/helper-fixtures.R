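# Shared fixtures and independent oracles, all built in code.

# ---- brute-force shortest-path oracle -------------------------------------
# Exhaustive simple-path enumeration, independent of the Dijkstra engine.
# edges: data.frame(from, to, cost); returns min cost from any source
# (+ onset) to every node, Inf where unreachable.
bf_arrival <- function(node_ids, edges, sources, onsets = 0) {
  onsets <- rep_len(onsets, length(sources))
  adj <- lapply(stats::setNames(seq_along(node_ids), node_ids),
                function(i) integer(0))
  costs <- list()
  for (k in seq_len(nrow(edges))) {
    a <- as.character(edges$from[k]); b <- as.character(edges$to[k])
    adj[[a]] <- c(adj[[a]], match(edges$to[k], node_ids))
    adj[[b]] <- c(adj[[b]], match(edges$from[k], node_ids))
    costs[[paste(a, b)]] <- edges$cost[k]
    costs[[paste(b, a)]] <- edges$cost[k]
  }
  best <- rep(Inf, length(node_ids))
  names(best) <- node_ids
  # exhaustive DFS over simple paths; pruning a branch only when its
  # cost strictly exceeds the best known cost at the node is exact for
  # positive edge costs (every prefix of an optimal path is optimal)
  dfs <- function(i, acc, visited) {
    if (acc > best[i]) return(invisible())
    if (acc < best[i]) best[i] <<- acc
    for (j in adj[[i]]) {
      if (visited[j]) next
      c_ij <- costs[[paste(node_ids[i], node_ids[j])]]
      visited[j] <- TRUE
      dfs(j, acc + c_ij, visited)
      visited[j] <- FALSE
    }
  }
  for (s in seq_along(sources)) {
    i <- match(as.character(sources[s]), node_ids)
    visited <- rep(FALSE, length(node_ids))
    visited[i] <- TRUE
    dfs(i, onsets[s], visited)
  }
  best
}

# random connected graph on n nodes with random positive edge costs
random_graph_fixture <- function(n, p_extra = 0.3) {
  pos <- cbind(stats::runif(n, 0, 10), stats::runif(n, 0, 10), 0)
  # spanning tree: connect each node to a random earlier node
  from <- to <- integer(0)
  for (i in 2:n) {
    from <- c(from, sample.int(i - 1L, 1L))
    to <- c(to, i)
  }
  extra <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  have <- paste(pmin(from, to), pmax(from, to))
  extra <- extra[!(paste(extra[, 1], extra[, 2]) %in% have), , drop = FALSE]
  if (nrow(extra) > 0) {
    pick <- stats::runif(nrow(extra)) < p_extra
    from <- c(from, extra[pick, 1]); to <- c(to, extra[pick, 2])
  }
  len <- sqrt(rowSums((pos[from, , drop = FALSE] -
                       pos[to, , drop = FALSE])^2))
  len <- pmax(len, 0.1)
  cv <- stats::runif(n, 0.3, 2)
  list(ids = seq_len(n), pos = pos, cv = cv,
       edges = data.frame(from = from, to = to, length_mm = len,
                          cost = len * (1 / cv[from] + 1 / cv[to]) / 2))
}

# wrap an arbitrary edge list as the package's adjacency_graph class
graph_from_edges <- function(ids, edges) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from),
               to = as.character(edges$to),
               length_mm = edges$length_mm),
    directed = FALSE,
    vertices = data.frame(name = as.character(ids)))
  structure(list(graph = g,
                 edges = edges[, c("from", "to", "length_mm")],
                 mode = "custom"),
            class = "adjacency_graph")
}

# layout with arbitrary positions (no grid indices)
free_layout <- function(pos) {
  electrode_layout(seq_len(nrow(pos)), pos[, 1], pos[, 2], pos[, 3])
}

# scenario with an explicit per-channel CV vector
cv_scenario <- function(sources, cv_vec, lesions = integer(0),
                        onsets = 0) {
  onsets <- rep_len(onsets, length(sources))
  src <- mapply(function(ch, on) list(channel = ch, onset_ms = on),
                sources, onsets, SIMPLIFY = FALSE)
  propagation_scenario(src, cv_mps = cv_vec, lesions = lesions,
                       rhythm = "focal")
}

# ---- mesh helpers ---------------------------------------------------------
write_binary_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  nrm <- epimap:::face_normals(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(c(nrm[i, ], t(v[f[i, ], ]))), con, size = 4L,
             endian = "little")
    writeBin(as.integer(0), con, size = 2L, endian = "little")
  }
  invisible(path)
}

mesh_tetrahedron <- function() {
  triangle_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
}

# plane grid with a height field applied (for saddle fixtures)
warped_plane <- function(nx, ny, spacing, zfun) {
  m <- mesh_plane_grid(nx, ny, spacing)
  v <- m$vertices
  ctr <- colMeans(v)
  v[, 3] <- zfun(v[, 1] - ctr[1], v[, 2] - ctr[2])
  triangle_mesh(v, m$faces)
}

# ---- signal helpers -------------------------------------------------------
# pure far-field-only recording: shared template, per-channel scale
farfield_only_recording <- function(n_channels = 9, sample_rate = 2048,
                                    duration_s = 3, beat_times = NULL,
                                    seed = 11) {
  set.seed(seed)
  n <- as.integer(duration_s * sample_rate)
  t_ms <- (seq_len(n) - 1L) / sample_rate * 1000
  if (is.null(beat_times)) beat_times <- c(500, 1300, 2100)
  ff <- rowSums(vapply(beat_times, function(b)
    farfield_template(t_ms, b), numeric(n)))
  scl <- stats::runif(n_channels, 0.5, 1.5)
  rec <- electrogram_recording(outer(scl, ff), sample_rate,
                               reference = ff)
  list(rec = rec, beat_times = beat_times, scale = scl)
}

expect_rms <- function(x) sqrt(mean(x^2))
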