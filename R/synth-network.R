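#' Generate a planar grid street network
#'
#' Surrogate for a county street-centerline layer: streets are the edges of a
#' rectangular grid with node spacing equal to the street length, enumerated
#' deterministically (horizontal row-major, then vertical), truncated to
#' `n_streets`. Total length therefore matches `n_streets * street_length_m`
#' exactly (within one street when the grid is truncated).
#'
#' @param n_streets number of streets (>= 1).
#' @param street_length_m length of each street, meters.
#' @return street tibble (`street_id`, `x0`, `y0`, `x1`, `y1`, `length_m`).
#' @examples
#' make_street_network(4, 100)
#' @export
make_street_network <- function(n_streets, street_length_m = 100) {
  if (n_streets < 1) stopf("n_streets must be >= 1")
  # smallest square-ish node grid with enough edges
  k <- 2L
  edge_count <- function(k) 2L * k * (k - 1L)
  while (edge_count(k) < n_streets) k <- k + 1L
  nx <- ny <- k
  rows <- list()
  add <- function(x0, y0, x1, y1) {
    rows[[length(rows) + 1]] <<- c(x0, y0, x1, y1)
  }
  for (j in seq_len(ny)) {           # horizontal edges
    for (i in seq_len(nx - 1)) {
      add((i - 1) * street_length_m, (j - 1) * street_length_m,
          i * street_length_m, (j - 1) * street_length_m)
    }
  }
  for (j in seq_len(ny - 1)) {       # vertical edges
    for (i in seq_len(nx)) {
      add((i - 1) * street_length_m, (j - 1) * street_length_m,
          (i - 1) * street_length_m, j * street_length_m)
    }
  }
  m <- do.call(rbind, rows)[seq_len(n_streets), , drop = FALSE]
  streets <- tibble::tibble(
    street_id = sprintf("S%03d", seq_len(n_streets)),
    x0 = m[, 1], y0 = m[, 2], x1 = m[, 3], y1 = m[, 4]
  )
  streets$length_m <- sqrt((streets$x1 - streets$x0)^2 + (streets$y1 - streets$y0)^2)
  attr(streets, "crs") <- "planar_m"
  streets
}

# adjacency of grid nodes, keyed by "x|y"
street_graph <- function(streets) {
  key <- function(x, y) paste(round(x, 6), round(y, 6), sep = "|")
  edges <- tibble::tibble(
    street_id = streets$street_id,
    from = key(streets$x0, streets$y0),
    to = key(streets$x1, streets$y1)
  )
  nodes <- unique(c(edges$from, edges$to))
  xy <- do.call(rbind, strsplit(nodes, "\\|"))
  list(
    nodes = tibble::tibble(node = nodes,
                           x = as.numeric(xy[, 1]), y = as.numeric(xy[, 2])),
    edges = edges
  )
}

# random non-backtracking walk over the network; returns a vertex polyline
# (matrix) and the streets traversed. Uses the current RNG stream.
sample_route <- function(streets, n_edges) {
  g <- street_graph(streets)
  # indices of edges touching each node
  incident <- lapply(g$nodes$node, function(nd) {
    which(g$edges$from == nd | g$edges$to == nd)
  })
  names(incident) <- g$nodes$node
  node <- sample(g$nodes$node, 1)
  prev_edge <- 0L
  verts <- g$nodes[g$nodes$node == node, c("x", "y")]
  ids <- character(0)
  for (step in seq_len(n_edges)) {
    cand <- incident[[node]]
    if (length(cand) > 1 && prev_edge %in% cand) cand <- setdiff(cand, prev_edge)
    e <- if (length(cand) == 1) cand else sample(cand, 1)
    nxt <- if (g$edges$from[e] == node) g$edges$to[e] else g$edges$from[e]
    verts <- rbind(verts, g$nodes[g$nodes$node == nxt, c("x", "y")])
    ids <- c(ids, g$edges$street_id[e])
    prev_edge <- e
    node <- nxt
  }
  list(vertices = as.matrix(verts), street_ids = ids)
}

# cumulative arc length of a polyline (matrix of vertices)
polyline_arcs <- function(v) {
  seg <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  c(0, cumsum(seg))
}

# position at arc distance s along polyline
polyline_point <- function(v, s) {
  arcs <- polyline_arcs(v)
  s <- pmin(pmax(s, 0), max(arcs))
  x <- approx(arcs, v[, 1], xout = s, rule = 2)$y
  y <- approx(arcs, v[, 2], xout = s, rule = 2)$y
  cbind(x, y)
}

# arc position of the closest approach of a polyline to a point, with distance
polyline_nearest_arc <- function(v, px, py) {
  arcs <- polyline_arcs(v)
  best <- list(dist = Inf, arc = NA_real_)
  for (k in seq_len(nrow(v) - 1)) {
    pd <- point_segment_distance(px, py, v[k, 1], v[k, 2], v[k + 1, 1], v[k + 1, 2])
    if (pd$dist_end < best$dist) {
      best <- list(dist = pd$dist_end, arc = arcs[k] + pd$t_m)
    }
  }
  best
}
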