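test_that("closest facility returns the minimum over sources with id tie-break", {
  net <- path_network()
  fac <- data.frame(facility_id = c("f_a"), snapped_node = 1L)
  # facility at the target node -> zero time
  r <- closest_facility(net, fac, 1L)
  expect_equal(r$travel_min, 0)
  expect_equal(r$facility_id, "f_a")
  # path A-B-C with times 2, 3: target C gets 5
  expect_equal(closest_facility(net, fac, 3L)$travel_min, 5)
  # tie between two facilities at equal distance -> lowest facility_id
  fac2 <- data.frame(facility_id = c("f_b", "f_a"), snapped_node = c(1L, 3L))
  r2 <- closest_facility(net, fac2, 2L)
  expect_equal(r2$travel_min, 2) # wait: A-B is 2, C-B is 3
  net_sym <- road_network(
    nodes = data.frame(node_id = 1:3, x = c(0, 1, 2), y = 0),
    edges = data.frame(from = c(1, 2), to = c(2, 3), length_m = 1000,
                       speed_kmh = 60))
  r3 <- closest_facility(net_sym, fac2, 2L)
  expect_equal(r3$facility_id, "f_a") # equal times, alphabetical id wins
  expect_error(closest_facility(net, fac[0, ], 1L), "empty")
})

test_that("closest facility equals the all-pairs brute-force minimum", {
  set.seed(97)
  for (rep in 1:20) {
    net <- random_network(sample(10:30, 1))
    d <- floyd_warshall(net)
    n <- nrow(net$nodes)
    fnodes <- sample(n, 3)
    fac <- data.frame(facility_id = sprintf("f%02d", 1:3), snapped_node = fnodes)
    res <- closest_facility(net, fac, seq_len(n))
    brute <- apply(d[fnodes, , drop = FALSE], 2, min)
    brute[!is.finite(brute)] <- NA_real_
    expect_equal(res$travel_min, unname(brute), tolerance = 1e-12)
  }
})

test_that("RT, TT and TPT compose with the urban/rural constants", {
  k <- time_constants()
  expect_equal(compute_rt(10, "rural", k), 12.9)
  expect_equal(compute_rt(0, "urban", k), 1.4)
  # densely populated and urban share the activation constant
  expect_equal(compute_rt(6, "densely_populated", k), compute_rt(6, "urban", k))
  expect_equal(compute_tt(20), 20)
  expect_equal(compute_tt(0), 0)
  expect_equal(compute_tpt(12.9, 20, "rural", k), 48.0)
  expect_equal(compute_tpt(1.4, 0, "urban", k), 14.9)
  # algebraic identity: TPT - RT - TT is the on-scene constant
  for (ty in c("urban", "densely_populated", "rural")) {
    rt <- runif(1, 0, 30); tt <- runif(1, 0, 50)
    expect_equal(compute_tpt(rt, tt, ty, k) - rt - tt,
                 if (ty == "rural") 15.1 else 13.5)
  }
  expect_error(compute_tpt(-1, 0, "urban", k), "nonnegative")
  expect_error(compute_rt(5, "suburban", k), "unknown area type")
})

test_that("golden hour is a strict below-60 threshold", {
  expect_true(golden_hour_flag(48.0))
  expect_false(golden_hour_flag(60.0))
  expect_false(golden_hour_flag(108.8))
  expect_true(golden_hour_flag(59.999))
})

test_that("quintiles split by rank with stable tie handling", {
  expect_equal(assign_quintiles(1:10), rep(1:5, each = 2))
  # all equal: stable order resolves into balanced groups
  expect_equal(assign_quintiles(rep(3, 10)), rep(1:5, each = 2))
  # 2520 values -> exactly 504 per quintile
  set.seed(2)
  q <- assign_quintiles(rnorm(2520))
  expect_equal(as.integer(table(q)), rep(504L, 5))
  expect_error(assign_quintiles(1:4), "at least 5")
  # quintile 5 holds the longest times
  v <- c(1, 100, 2, 99, 3, 98, 4, 97, 5, 96)
  expect_equal(sort(v[assign_quintiles(v) == 5]), c(99, 100))
})

test_that("access records satisfy the composition and threshold invariants", {
  region <- generate_region(tiny_region_config())
  rec <- compute_access(region$network, region$stations, region$hospitals,
                        region$areas)
  expect_equal(nrow(rec), nrow(region$areas))
  onscene <- ifelse(region$areas$area_type == "rural", 15.1, 13.5)
  activation <- ifelse(region$areas$area_type == "rural", 2.9, 1.4)
  expect_equal(rec$tpt_min - rec$rt_min - rec$tt_min, onscene,
               tolerance = 1e-12)
  expect_true(all(rec$rt_min >= activation))
  expect_true(all(rec$tt_min >= 0))
  expect_equal(rec$within_golden_hour, rec$tpt_min < 60)
  expect_true(all(rec$quintile_rt %in% 1:5))
})

test_that("unreachable areas are dropped with a warning", {
  # disconnected network: facility on one component, one area on the other
  net <- road_network(
    nodes = data.frame(node_id = 1:4, x = c(0, 1000, 50000, 51000), y = 0),
    edges = data.frame(from = c(1, 3), to = c(2, 4), length_m = 1000,
                       speed_kmh = 60))
  stations <- data.frame(facility_id = "st", snapped_node = 1L)
  hospitals <- data.frame(facility_id = "ho", snapped_node = 2L)
  areas <- data.frame(area_id = sprintf("a%d", 1:6),
                      snapped_node = c(1L, 2L, 3L, 1L, 2L, 1L),
                      area_type = "urban")
  expect_warning(rec <- compute_access(net, stations, hospitals, areas),
                 "unreachable")
  expect_equal(nrow(rec), 5)
  expect_false("a3" %in% rec$area_id)
})

test_that("adding a facility never increases RT or TT", {
  set.seed(123)
  region <- generate_region(tiny_region_config(seed = 21))
  net <- region$network
  areas <- region$areas
  st <- region$stations
  ho <- region$hospitals
  base <- compute_access(net, st, ho, areas)
  for (i in 1:5) {
    new_node <- sample(net$nodes$node_id, 1)
    st2 <- rbind(st, data.frame(facility_id = "st_new", kind = "ambulance_station",
                                x = NA, y = NA, snapped_node = new_node))
    ho2 <- rbind(ho, data.frame(facility_id = "hosp_new",
                                kind = "emergency_department",
                                x = NA, y = NA, snapped_node = new_node))
    more <- compute_access(net, st2, ho2, areas)
    expect_true(all(more$rt_min <= base$rt_min + 1e-12))
    expect_true(all(more$tt_min <= base$tt_min + 1e-12))
  }
})
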