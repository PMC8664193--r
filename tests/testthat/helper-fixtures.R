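# Shared fixtures and independent oracles.

# Small path network A(1)-B(2)-C(3) with travel times 2 and 3 minutes.
path_network <- function() {
  road_network(
    nodes = data.frame(node_id = 1:3, x = c(0, 2000, 5000), y = 0),
    edges = data.frame(from = c(1, 2), to = c(2, 3),
                       length_m = c(2000, 3000), speed_kmh = 60)
  )
}

# Random connected-ish undirected graph as a road_network (nodes on a plane,
# random edges; may be disconnected, which is part of what the oracle checks).
random_network <- function(n_nodes, p_edge = 0.12) {
  nodes <- data.frame(node_id = seq_len(n_nodes),
                      x = runif(n_nodes, 0, 10000),
                      y = runif(n_nodes, 0, 10000))
  pairs <- utils::combn(n_nodes, 2)
  take <- runif(ncol(pairs)) < p_edge
  if (!any(take)) take[1] <- TRUE
  ee <- pairs[, take, drop = FALSE]
  edges <- data.frame(
    from = ee[1, ], to = ee[2, ],
    length_m = runif(ncol(ee), 100, 5000),
    speed_kmh = sample(c(50, 70, 90, 110), ncol(ee), replace = TRUE)
  )
  road_network(nodes, edges)
}

# Independent all-pairs shortest-path oracle (Floyd-Warshall on the travel
# time matrix). O(n^3); for small graphs only.
floyd_warshall <- function(network) {
  n <- nrow(network$nodes)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(nrow(network$edges))) {
    a <- network$edges$from[i]
    b <- network$edges$to[i]
    w <- network$edges$travel_min[i]
    d[a, b] <- min(d[a, b], w)
    d[b, a] <- min(d[b, a], w)
  }
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, dk)
  }
  d
}

# Textbook Pearson correlation, written out by hand.
pearson_by_hand <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Small region config used across tests (fast to generate, all stages work).
tiny_region_config <- function(seed = 7) {
  region_config(seed = seed, n_nodes = 144, n_areas = 60, n_stations = 4,
                n_hospitals = 2, extent_km = 50)
}

# Study-scale region (2,520 areas, 118 stations, 25 emergency departments),
# generated once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())
paper_scale_region <- function() {
  if (is.null(.fixture_cache$region2520)) {
    .fixture_cache$region2520 <- generate_region(
      region_config(seed = 404, n_areas = 2520, n_stations = 118,
                    n_hospitals = 25))
  }
  .fixture_cache$region2520
}
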