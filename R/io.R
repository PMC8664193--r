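# Region serialization: GeoJSON for geometry, CSV for tables.
#
# Only the GeoJSON subset the pipeline needs is handled (Point, LineString,
# Polygon features with flat properties), via jsonlite. Extra properties in
# foreign files are ignored; files written here carry node/area ids so
# read/write round-trips are exact.

.feature <- function(type, coordinates, properties) {
  list(type = "Feature",
       geometry = list(type = type, coordinates = coordinates),
       properties = properties)
}

.write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
}

.read_geojson <- function(path) {
  if (!file.exists(path)) stop("GeoJSON file not found: ", path)
  jsonlite::read_json(path, simplifyVector = FALSE)
}

.prop <- function(f, name, default = NA) {
  v <- f$properties[[name]]
  if (is.null(v)) default else v
}

#' Write a synthetic region to disk
#'
#' Emits `network.geojson` (LineString features with `length_m`,
#' `speed_kmh` and node ids), `stations.geojson` / `hospitals.geojson`
#' (Point features with `facility_id`), `areas.geojson` (Polygon features
#' with `area_id` and centroid metadata), `covariates.csv`, `popgrid.csv`
#' and `truth.json`. The file set round-trips losslessly through
#' [read_region()].
#'
#' @param region A `synthetic_region`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of paths written.
#' @export
write_region <- function(region, dir) {
  stopifnot(inherits(region, "synthetic_region"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- region$network$nodes
  ed <- region$network$edges

  net_f <- lapply(seq_len(nrow(ed)), function(i) {
    a <- match(ed$from[i], nodes$node_id)
    b <- match(ed$to[i], nodes$node_id)
    .feature("LineString",
             list(c(nodes$x[a], nodes$y[a]), c(nodes$x[b], nodes$y[b])),
             list(length_m = ed$length_m[i], speed_kmh = ed$speed_kmh[i],
                  node_a = ed$from[i], node_b = ed$to[i]))
  })
  .write_geojson(net_f, file.path(dir, "network.geojson"))

  fac_features <- function(fac) {
    lapply(seq_len(nrow(fac)), function(i) {
      .feature("Point", c(fac$x[i], fac$y[i]),
               list(facility_id = fac$facility_id[i], kind = fac$kind[i],
                    snapped_node = fac$snapped_node[i]))
    })
  }
  .write_geojson(fac_features(region$stations), file.path(dir, "stations.geojson"))
  .write_geojson(fac_features(region$hospitals), file.path(dir, "hospitals.geojson"))

  ar <- region$areas
  area_f <- lapply(seq_len(nrow(ar)), function(i) {
    p <- region$polygons[[i]]
    ring <- lapply(c(seq_len(nrow(p)), 1L), function(j) c(p$x[j], p$y[j]))
    .feature("Polygon", list(ring),
             list(area_id = ar$area_id[i],
                  seed_x = ar$seed_x[i], seed_y = ar$seed_y[i],
                  centroid_x = ar$centroid_x[i], centroid_y = ar$centroid_y[i],
                  weighted = ar$weighted[i],
                  snapped_node = ar$snapped_node[i],
                  municipality = ar$municipality[i],
                  population = ar$population[i]))
  })
  .write_geojson(area_f, file.path(dir, "areas.geojson"))

  cov_cols <- c("area_id", "older_share", "high_edu_share", "median_income",
                "area_type", "region", "has_station")
  cov_cols <- intersect(cov_cols, names(ar))
  utils::write.csv(ar[, cov_cols], file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(region$population_grid, file.path(dir, "popgrid.csv"),
                   row.names = FALSE)
  jsonlite::write_json(region$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, c("network.geojson", "stations.geojson",
                             "hospitals.geojson", "areas.geojson",
                             "covariates.csv", "popgrid.csv", "truth.json")))
}

.read_facilities <- function(path, what) {
  fc <- .read_geojson(path)
  if (length(fc$features) == 0) stop("no facilities in ", path)
  data.frame(
    facility_id = vapply(fc$features, .prop, "", "facility_id"),
    kind = vapply(fc$features, function(f) .prop(f, "kind", what), ""),
    x = vapply(fc$features, function(f) f$geometry$coordinates[[1]], 0),
    y = vapply(fc$features, function(f) f$geometry$coordinates[[2]], 0),
    snapped_node = vapply(fc$features, function(f)
      as.integer(.prop(f, "snapped_node", NA_integer_)), 0L),
    stringsAsFactors = FALSE
  )
}

#' Read road-network segments from GeoJSON
#'
#' Each LineString feature becomes one segment between its first and last
#' coordinate; `length_m` and `speed_kmh` properties are required, node ids
#' (`node_a`, `node_b`) are used when present.
#'
#' @param path Path to a GeoJSON FeatureCollection of LineStrings.
#' @return Segment data.frame suitable for [build_network()].
#' @export
read_network_segments <- function(path) {
  fc <- .read_geojson(path)
  feats <- fc$features
  if (length(feats) == 0) stop("no line features in ", path)
  seg <- data.frame(
    x1 = vapply(feats, function(f) f$geometry$coordinates[[1]][[1]], 0),
    y1 = vapply(feats, function(f) f$geometry$coordinates[[1]][[2]], 0),
    x2 = vapply(feats, function(f) {
      cc <- f$geometry$coordinates; cc[[length(cc)]][[1]]
    }, 0),
    y2 = vapply(feats, function(f) {
      cc <- f$geometry$coordinates; cc[[length(cc)]][[2]]
    }, 0),
    length_m = vapply(feats, function(f) {
      v <- .prop(f, "length_m")
      if (is.na(v)) stop("feature missing length_m property")
      as.numeric(v)
    }, 0),
    speed_kmh = vapply(feats, function(f) {
      v <- .prop(f, "speed_kmh")
      if (is.na(v)) stop("feature missing speed_kmh property")
      as.numeric(v)
    }, 0)
  )
  ids_a <- vapply(feats, function(f) as.integer(.prop(f, "node_a", NA_integer_)), 0L)
  ids_b <- vapply(feats, function(f) as.integer(.prop(f, "node_b", NA_integer_)), 0L)
  if (!anyNA(ids_a) && !anyNA(ids_b)) {
    seg$node_a <- ids_a
    seg$node_b <- ids_b
  }
  seg
}

#' Read a region file set written by [write_region()]
#'
#' @param dir Directory containing the region files.
#' @return A `synthetic_region` (with `truth` as read from `truth.json`).
#' @export
read_region <- function(dir) {
  seg <- read_network_segments(file.path(dir, "network.geojson"))
  network <- build_network(seg)
  network$nodes$buffer <- NULL
  network$edges$buffer <- NULL

  stations <- .read_facilities(file.path(dir, "stations.geojson"),
                               "ambulance_station")
  hospitals <- .read_facilities(file.path(dir, "hospitals.geojson"),
                                "emergency_department")

  fc <- .read_geojson(file.path(dir, "areas.geojson"))
  feats <- fc$features
  polygons <- lapply(feats, function(f) {
    ring <- f$geometry$coordinates[[1]]
    ring <- ring[-length(ring)] # drop closing vertex
    data.frame(x = vapply(ring, function(p) p[[1]], 0),
               y = vapply(ring, function(p) p[[2]], 0))
  })
  geo <- data.frame(
    area_id = vapply(feats, .prop, "", "area_id"),
    seed_x = vapply(feats, function(f) as.numeric(.prop(f, "seed_x")), 0),
    seed_y = vapply(feats, function(f) as.numeric(.prop(f, "seed_y")), 0),
    centroid_x = vapply(feats, function(f) as.numeric(.prop(f, "centroid_x")), 0),
    centroid_y = vapply(feats, function(f) as.numeric(.prop(f, "centroid_y")), 0),
    weighted = vapply(feats, function(f) isTRUE(.prop(f, "weighted", FALSE)), TRUE),
    snapped_node = vapply(feats, function(f)
      as.integer(.prop(f, "snapped_node", NA_integer_)), 0L),
    municipality = vapply(feats, function(f)
      as.integer(.prop(f, "municipality", NA_integer_)), 0L),
    population = vapply(feats, function(f) as.numeric(.prop(f, "population", 0)), 0),
    stringsAsFactors = FALSE
  )
  cov <- utils::read.csv(file.path(dir, "covariates.csv"),
                         stringsAsFactors = FALSE)
  areas <- merge(geo, cov, by = "area_id", sort = FALSE)
  areas <- areas[order(areas$area_id), ]
  areas$reportable <- TRUE
  canonical <- c("area_id", "seed_x", "seed_y", "centroid_x", "centroid_y",
                 "weighted", "snapped_node", "area_type", "region",
                 "municipality", "population", "has_station", "reportable")
  areas <- areas[, c(intersect(canonical, names(areas)),
                     setdiff(names(areas), canonical))]
  rownames(areas) <- NULL
  grid <- utils::read.csv(file.path(dir, "popgrid.csv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(network = network, stations = stations,
                 hospitals = hospitals, areas = areas, polygons = polygons,
                 population_grid = grid, truth = truth),
            class = "synthetic_region")
}
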