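# Road network construction and snapping.
#
# Networks are undirected planar graphs in projected (meter) coordinates.
# Edge travel times are derived from segment length and posted speed limit;
# routing is symmetric (no one-way restrictions, turn penalties or traffic).

#' Travel time of a road segment
#'
#' Converts a segment length and speed limit into a drive time in minutes:
#' `(length_m / 1000) / speed_kmh * 60`.
#'
#' @param length_m Segment length in meters (>= 0). Vectorised.
#' @param speed_kmh Speed limit in km/h (> 0). Vectorised.
#' @return Travel time in minutes.
#' @examples
#' edge_travel_time(1000, 60) # 1 minute
#' @export
edge_travel_time <- function(length_m, speed_kmh) {
  if (any(length_m < 0)) stop("length_m must be nonnegative")
  if (any(speed_kmh <= 0)) stop("speed_kmh must be positive")
  (length_m / 1000) / speed_kmh * 60
}

#' Construct a road network object
#'
#' @param nodes data.frame with columns `node_id` (integer), `x`, `y`
#'   (planar meters).
#' @param edges data.frame with columns `from`, `to` (node ids), `length_m`,
#'   `speed_kmh`. Travel minutes are (re)computed from length and speed.
#'   Self-loops are dropped; duplicate undirected edges are collapsed keeping
#'   the minimum travel time.
#' @return A `road_network` object: list with `nodes` and `edges`
#'   data.frames; `edges` gains a `travel_min` column.
#' @export
road_network <- function(nodes, edges) {
  stopifnot(all(c("node_id", "x", "y") %in% names(nodes)),
            all(c("from", "to", "length_m", "speed_kmh") %in% names(edges)))
  nodes$node_id <- as.integer(nodes$node_id)
  if (anyDuplicated(nodes$node_id)) stop("duplicate node_id")
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  if (!all(c(edges$from, edges$to) %in% nodes$node_id)) {
    stop("edge endpoint references unknown node_id")
  }
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  if (nrow(edges) > 0 && any(edges$length_m <= 0)) stop("length_m must be positive")
  edges$travel_min <- edge_travel_time(edges$length_m, edges$speed_kmh)
  # canonical undirected orientation, dedup keeping fastest
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges$from <- a
  edges$to <- b
  edges <- edges[order(edges$from, edges$to, edges$travel_min), , drop = FALSE]
  edges <- edges[!duplicated(edges[, c("from", "to")]), , drop = FALSE]
  rownames(edges) <- NULL
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d nodes, %d edges, %.1f km total\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length_m) / 1000))
  invisible(x)
}

#' Convert a road network to an igraph graph
#'
#' Vertices are named by `node_id`; edge attribute `weight` is `travel_min`.
#'
#' @param network A `road_network`.
#' @return An undirected `igraph` graph.
#' @export
network_graph <- function(network) {
  stopifnot(inherits(network, "road_network"))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(network$edges$from),
                   to = as.character(network$edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(network$nodes$node_id))
  )
  igraph::E(g)$weight <- network$edges$travel_min
  g
}

#' Snap a point to the closest network junction
#'
#' Returns the node minimising Euclidean distance to the point; ties are
#' broken by the lowest `node_id` so snapping is deterministic.
#'
#' @param point Numeric length-2 vector `(x, y)` in meters.
#' @param network A `road_network`.
#' @return The snapped `node_id` (integer).
#' @export
snap_to_junction <- function(point, network) {
  stopifnot(inherits(network, "road_network"))
  if (nrow(network$nodes) == 0) stop("cannot snap to an empty network")
  d2 <- (network$nodes$x - point[1])^2 + (network$nodes$y - point[2])^2
  cand <- network$nodes$node_id[d2 <= min(d2) + 1e-12]
  min(cand)
}

#' Population-weighted centroid of an area
#'
#' The centroid is the population-weighted mean of the centers of the grid
#' cells belonging to the area. When no populated cell is available the
#' geometric centroid of the polygon is used instead and the result is
#' flagged unweighted.
#'
#' @param polygon data.frame or matrix with columns `x`, `y`: polygon
#'   vertices (unclosed ring).
#' @param cells data.frame with columns `x`, `y`, `count`: centers and
#'   population counts of the grid cells intersecting the area (may have
#'   zero rows).
#' @param area_id Identifier carried through to the result.
#' @return list with `area_id`, `point` (named numeric x, y), `weighted`
#'   (logical).
#' @export
weighted_centroid <- function(polygon, cells, area_id = NA_character_) {
  polygon <- as.data.frame(polygon)
  if (nrow(polygon) < 3) stop("degenerate polygon: fewer than 3 vertices")
  if (abs(.polygon_area(polygon$x, polygon$y)) < 1e-12) {
    stop("degenerate polygon: zero area")
  }
  total <- if (is.null(cells) || nrow(cells) == 0) 0 else sum(cells$count)
  if (total > 0) {
    pt <- c(x = sum(cells$x * cells$count) / total,
            y = sum(cells$y * cells$count) / total)
    weighted <- TRUE
  } else {
    pt <- .polygon_centroid(polygon$x, polygon$y)
    weighted <- FALSE
  }
  list(area_id = area_id, point = pt, weighted = weighted)
}

# Shoelace area (signed).
.polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# Geometric centroid of a simple polygon.
.polygon_centroid <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  cross <- x[j] * y - x * y[j]
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) { # degenerate: fall back to vertex mean
    return(c(x = mean(x), y = mean(y)))
  }
  c(x = sum((x[j] + x) * cross) / (6 * a),
    y = sum((y[j] + y) * cross) / (6 * a))
}

#' Build a road network from line segments
#'
#' Creates a node at every segment endpoint, merging endpoints that lie
#' within `tol` meters of each other; duplicate edges between the same node
#' pair are collapsed keeping the fastest. Optional buffer segments (roads
#' outside the reporting region, kept to avoid border effects in routing)
#' are included in the graph and their edges flagged `buffer = TRUE`.
#'
#' @param segments data.frame with columns `x1`, `y1`, `x2`, `y2`,
#'   `length_m`, `speed_kmh`; optionally `node_a`, `node_b` with explicit
#'   node ids (then no tolerance merging is done).
#' @param buffer_segments Optional data.frame with the same columns.
#' @param tol Endpoint merge tolerance in meters (default 1).
#' @return A `road_network`; `edges$buffer` marks buffer edges,
#'   `nodes$buffer` marks nodes only touched by buffer edges.
#' @export
build_network <- function(segments, buffer_segments = NULL, tol = 1) {
  req <- c("x1", "y1", "x2", "y2", "length_m", "speed_kmh")
  miss <- setdiff(req, names(segments))
  if (length(miss) > 0) {
    stop("segment table missing attribute(s): ", paste(miss, collapse = ", "))
  }
  segments$buffer <- FALSE
  if (!is.null(buffer_segments) && nrow(buffer_segments) > 0) {
    miss <- setdiff(req, names(buffer_segments))
    if (length(miss) > 0) {
      stop("buffer segment table missing attribute(s): ",
           paste(miss, collapse = ", "))
    }
    buffer_segments$buffer <- TRUE
    keep <- intersect(names(segments), names(buffer_segments))
    segments <- rbind(segments[, keep, drop = FALSE],
                      buffer_segments[, keep, drop = FALSE])
  }
  if (any(is.na(segments$length_m)) || any(is.na(segments$speed_kmh))) {
    bad <- which(is.na(segments$length_m) | is.na(segments$speed_kmh))[1]
    stop("segment ", bad, " has missing length_m/speed_kmh")
  }

  if (all(c("node_a", "node_b") %in% names(segments))) {
    ends <- data.frame(id = c(segments$node_a, segments$node_b),
                       x = c(segments$x1, segments$x2),
                       y = c(segments$y1, segments$y2))
    ends <- ends[!duplicated(ends$id), ]
    nodes <- data.frame(node_id = as.integer(ends$id), x = ends$x, y = ends$y)
    nodes <- nodes[order(nodes$node_id), ]
    from <- as.integer(segments$node_a)
    to <- as.integer(segments$node_b)
  } else {
    pts <- rbind(cbind(segments$x1, segments$y1), cbind(segments$x2, segments$y2))
    id <- .merge_endpoints(pts, tol)
    n_nodes <- max(id)
    xs <- tapply(pts[, 1], id, mean)
    ys <- tapply(pts[, 2], id, mean)
    nodes <- data.frame(node_id = seq_len(n_nodes),
                        x = as.numeric(xs), y = as.numeric(ys))
    m <- nrow(segments)
    from <- id[seq_len(m)]
    to <- id[m + seq_len(m)]
  }

  edges <- data.frame(from = from, to = to,
                      length_m = segments$length_m,
                      speed_kmh = segments$speed_kmh,
                      buffer = segments$buffer)
  net <- road_network(nodes, edges)
  touched <- unique(c(net$edges$from[!net$edges$buffer],
                      net$edges$to[!net$edges$buffer]))
  net$nodes$buffer <- !(net$nodes$node_id %in% touched)
  net
}

# Cluster 2-d points whose pairwise distance is <= tol into shared ids.
# Grid hashing with neighborhood lookup; adequate for endpoint merging where
# tol is far below typical segment length.
.merge_endpoints <- function(pts, tol) {
  n <- nrow(pts)
  if (tol <= 0) {
    key <- paste(pts[, 1], pts[, 2])
    return(as.integer(factor(key, levels = unique(key))))
  }
  gx <- floor(pts[, 1] / tol)
  gy <- floor(pts[, 2] / tol)
  id <- integer(n)
  next_id <- 0L
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    assigned <- 0L
    for (dx in -1:1) {
      for (dy in -1:1) {
        key <- paste(gx[i] + dx, gy[i] + dy)
        js <- seen[[key]]
        if (!is.null(js)) {
          for (j in js) {
            if ((pts[i, 1] - pts[j, 1])^2 + (pts[i, 2] - pts[j, 2])^2 <= tol^2) {
              assigned <- id[j]
              break
            }
          }
        }
        if (assigned > 0L) break
      }
      if (assigned > 0L) break
    }
    if (assigned == 0L) {
      next_id <- next_id + 1L
      assigned <- next_id
      key <- paste(gx[i], gy[i])
      seen[[key]] <- c(seen[[key]], i)
    }
    id[i] <- assigned
  }
  id
}

#' Create a facility (ambulance station or emergency department)
#'
#' Facilities are snapped to the closest junction so routes always traverse
#' whole segments.
#'
#' @param facility_id Character id.
#' @param kind One of `"ambulance_station"`, `"emergency_department"`.
#' @param location Numeric `(x, y)` raw location in meters.
#' @param network A `road_network` used for snapping.
#' @return list with `facility_id`, `kind`, `raw_location`, `snapped_node`.
#' @export
facility <- function(facility_id, kind, location, network) {
  kind <- match.arg(kind, c("ambulance_station", "emergency_department"))
  list(facility_id = as.character(facility_id), kind = kind,
       raw_location = c(x = location[1], y = location[2]),
       snapped_node = snap_to_junction(location, network))
}
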