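# Closest-facility accessibility measures.
#
# RT  = travel time from the nearest ambulance station + activation constant
# TT  = travel time to the nearest emergency department (no constants)
# TPT = RT + TT + on-scene constant
#
# Activation and on-scene constants differ between urban/densely-populated
# and rural areas and attach to the area's own type classification.

#' Prehospital time constants
#'
#' Fixed dispatch-activation and on-scene components of the prehospital
#' timeline, in minutes, by area type, plus the golden-hour threshold.
#' Defaults: activation 1.4 (urban/dense) and 2.9 (rural); on-scene 13.5
#' (urban/dense) and 15.1 (rural); golden hour 60.
#'
#' @param activation_urban_dense,activation_rural Activation minutes.
#' @param onscene_urban_dense,onscene_rural On-scene minutes.
#' @param golden_hour Threshold in minutes; areas with TPT strictly below it
#'   count as served within the golden hour.
#' @return A `time_constants` list.
#' @export
time_constants <- function(activation_urban_dense = 1.4,
                           activation_rural = 2.9,
                           onscene_urban_dense = 13.5,
                           onscene_rural = 15.1,
                           golden_hour = 60) {
  vals <- c(activation_urban_dense, activation_rural,
            onscene_urban_dense, onscene_rural, golden_hour)
  if (any(vals < 0)) stop("time constants must be nonnegative")
  structure(list(activation_urban_dense = activation_urban_dense,
                 activation_rural = activation_rural,
                 onscene_urban_dense = onscene_urban_dense,
                 onscene_rural = onscene_rural,
                 golden_hour = golden_hour),
            class = "time_constants")
}

.is_rural <- function(area_type) {
  if (!all(area_type %in% c("urban", "densely_populated", "rural"))) {
    stop("unknown area type; expected urban / densely_populated / rural")
  }
  area_type == "rural"
}

activation_constant <- function(area_type, constants) {
  ifelse(.is_rural(area_type),
         constants$activation_rural, constants$activation_urban_dense)
}

onscene_constant <- function(area_type, constants) {
  ifelse(.is_rural(area_type),
         constants$onscene_rural, constants$onscene_urban_dense)
}

#' Closest-facility travel times
#'
#' Multi-source shortest-path query: for each target node, the minimum
#' travel time (minutes) over all facilities and the facility achieving it.
#' Ties are broken by the lowest `facility_id`. Unreachable targets get
#' `NA` time and facility.
#'
#' @param network A `road_network`.
#' @param facilities data.frame with columns `facility_id`, `snapped_node`
#'   (or a list of [facility()] objects).
#' @param target_nodes Integer vector of node ids.
#' @return data.frame with `node`, `facility_id`, `travel_min`.
#' @export
closest_facility <- function(network, facilities, target_nodes) {
  if (is.list(facilities) && !is.data.frame(facilities)) {
    facilities <- data.frame(
      facility_id = vapply(facilities, `[[`, "", "facility_id"),
      snapped_node = vapply(facilities, `[[`, 0L, "snapped_node")
    )
  }
  if (nrow(facilities) == 0) stop("facility set is empty")
  if (!all(target_nodes %in% network$nodes$node_id)) {
    stop("target node not in network")
  }
  # sort so which.min's first-match rule implements the lowest-id tie-break
  facilities <- facilities[order(facilities$facility_id), , drop = FALSE]
  g <- network_graph(network)
  usrc <- unique(facilities$snapped_node)
  utgt <- unique(target_nodes)
  du <- igraph::distances(g,
                          v = as.character(usrc),
                          to = as.character(utgt),
                          weights = igraph::E(g)$weight,
                          algorithm = "dijkstra")
  d <- du[match(facilities$snapped_node, usrc),
          match(target_nodes, utgt), drop = FALSE]
  idx <- apply(d, 2, function(col) {
    if (all(!is.finite(col))) NA_integer_ else which.min(col)
  })
  travel <- d[cbind(ifelse(is.na(idx), 1L, idx), seq_along(target_nodes))]
  travel[is.na(idx) | !is.finite(travel)] <- NA_real_
  data.frame(node = target_nodes,
             facility_id = ifelse(is.na(idx), NA_character_,
                                  facilities$facility_id[idx]),
             travel_min = travel)
}

#' Response time: nearest station travel plus activation
#'
#' @param travel_min Travel minutes from the closest ambulance station.
#' @param area_type `"urban"`, `"densely_populated"` or `"rural"` (vectorised).
#' @param constants A [time_constants()] object.
#' @return RT in minutes.
#' @export
compute_rt <- function(travel_min, area_type, constants = time_constants()) {
  if (any(travel_min < 0, na.rm = TRUE)) stop("travel_min must be nonnegative")
  travel_min + activation_constant(area_type, constants)
}

#' Transportation time: nearest emergency department travel
#'
#' TT is strictly the travel time to the closest emergency department; no
#' activation or on-scene component is added.
#'
#' @inheritParams compute_rt
#' @return TT in minutes.
#' @export
compute_tt <- function(travel_min, area_type = NULL, constants = NULL) {
  if (any(travel_min < 0, na.rm = TRUE)) stop("travel_min must be nonnegative")
  travel_min
}

#' Total prehospital time
#'
#' TPT = RT + TT + on-scene constant for the area's type.
#'
#' @param rt,tt RT and TT in minutes (vectorised).
#' @inheritParams compute_rt
#' @return TPT in minutes.
#' @export
compute_tpt <- function(rt, tt, area_type, constants = time_constants()) {
  if (any(rt < 0, na.rm = TRUE) || any(tt < 0, na.rm = TRUE)) {
    stop("rt and tt must be nonnegative")
  }
  rt + tt + onscene_constant(area_type, constants)
}

#' Golden-hour classification
#'
#' TRUE when TPT is strictly below the golden-hour threshold ("below one
#' hour"); exactly 60 minutes counts as outside.
#'
#' @param tpt TPT in minutes.
#' @param constants A [time_constants()] object.
#' @return Logical vector.
#' @export
golden_hour_flag <- function(tpt, constants = time_constants()) {
  if (any(tpt < 0, na.rm = TRUE)) stop("tpt must be nonnegative")
  tpt < constants$golden_hour
}

#' Rank-based quintiles
#'
#' Splits values into `k` groups by rank; group `k` holds the longest times
#' (the most underserviced areas). Ties are resolved by stable original
#' order, so group sizes differ by at most one.
#'
#' @param values Numeric vector (length >= k).
#' @param k Number of groups (default 5).
#' @return Integer labels in `1..k`.
#' @export
assign_quintiles <- function(values, k = 5) {
  n <- length(values)
  if (n < k) stop("need at least ", k, " values to form ", k, " groups")
  ord <- order(values, seq_len(n)) # stable: ties by original position
  lab <- integer(n)
  lab[ord] <- ceiling(k * seq_len(n) / n)
  lab
}

#' Per-area accessibility records
#'
#' Runs the closest-facility analysis for ambulance stations and emergency
#' departments against the snapped area centroids and composes RT, TT, TPT,
#' golden-hour flags and per-measure quintiles.
#'
#' Areas unreachable from all facilities are excluded with a warning;
#' quintiles are computed over the remaining (reportable) areas only.
#'
#' @param network A `road_network`.
#' @param stations,hospitals Facility data.frames (`facility_id`,
#'   `snapped_node`) or lists of [facility()] objects.
#' @param areas data.frame with columns `area_id`, `snapped_node`,
#'   `area_type`, and optionally `reportable` (buffer areas get FALSE).
#' @param constants A [time_constants()] object.
#' @return data.frame of access records: `area_id`, `rt_min`, `tt_min`,
#'   `tpt_min`, `nearest_station`, `nearest_hospital`, `within_golden_hour`,
#'   `quintile_rt`, `quintile_tt`, `quintile_tpt`.
#' @export
compute_access <- function(network, stations, hospitals, areas,
                           constants = time_constants()) {
  stopifnot(all(c("area_id", "snapped_node", "area_type") %in% names(areas)))
  reportable <- if ("reportable" %in% names(areas)) areas$reportable else TRUE
  areas <- areas[rep_len(reportable, nrow(areas)), , drop = FALSE]

  st <- closest_facility(network, stations, areas$snapped_node)
  ho <- closest_facility(network, hospitals, areas$snapped_node)

  unreach <- is.na(st$travel_min) | is.na(ho$travel_min)
  if (any(unreach)) {
    warning(sum(unreach), " area(s) unreachable from all facilities; excluded: ",
            paste(utils::head(areas$area_id[unreach], 5), collapse = ", "),
            if (sum(unreach) > 5) ", ...")
    areas <- areas[!unreach, , drop = FALSE]
    st <- st[!unreach, , drop = FALSE]
    ho <- ho[!unreach, , drop = FALSE]
  }

  rt <- compute_rt(st$travel_min, areas$area_type, constants)
  tt <- compute_tt(ho$travel_min)
  tpt <- compute_tpt(rt, tt, areas$area_type, constants)

  data.frame(
    area_id = areas$area_id,
    rt_min = rt,
    tt_min = tt,
    tpt_min = tpt,
    nearest_station = st$facility_id,
    nearest_hospital = ho$facility_id,
    within_golden_hour = golden_hour_flag(tpt, constants),
    quintile_rt = assign_quintiles(rt),
    quintile_tt = assign_quintiles(tt),
    quintile_tpt = assign_quintiles(tpt),
    stringsAsFactors = FALSE
  )
}
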