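# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

YEAR <- as.Date(c("2019-01-01", "2020-01-01"))

# assignment tibble straight from (user, place) pairs, one event each,
# timestamps mid-period unless given
make_assignment <- function(user_id, place_id,
                            timestamp = as.POSIXct("2019-06-01", tz = "UTC")) {
  tibble::tibble(user_id = user_id,
                 timestamp = rep_len(timestamp, length(user_id)),
                 place_id = place_id)
}

# a random incidence fixture: n_users users each visiting 1..max_visits
# distinct places out of n_places
random_assignment <- function(n_places, n_users, seed, max_visits = 4) {
  set.seed(seed)
  places <- sprintf("p%03d", seq_len(n_places))
  rows <- lapply(seq_len(n_users), function(u) {
    k <- sample.int(max_visits, 1)
    tibble::tibble(user_id = sprintf("u%04d", u),
                   place_id = sample(places, min(k, n_places)))
  })
  asn <- dplyr::bind_rows(rows)
  asn$timestamp <- as.POSIXct("2019-06-01", tz = "UTC")
  asn[, c("user_id", "timestamp", "place_id")]
}

# Independent brute-force connectivity oracle: materialize per-place user
# sets and intersect every pair with base R. Deliberately avoids the joins
# the implementation uses.
brute_force_pci <- function(assignment, period) {
  ts <- as.POSIXct(assignment$timestamp, tz = "UTC")
  keep <- ts >= as.POSIXct(as.character(period[1]), tz = "UTC") &
    ts < as.POSIXct(as.character(period[2]), tz = "UTC")
  asn <- assignment[keep, ]
  sets <- tapply(asn$user_id, asn$place_id, unique, simplify = FALSE)
  ids <- sort(names(sets))
  out <- list()
  for (ii in seq_along(ids)) {
    for (jj in seq_along(ids)) {
      if (ii >= jj) next
      s_ij <- length(intersect(sets[[ids[ii]]], sets[[ids[jj]]]))
      if (s_ij == 0) next
      out[[length(out) + 1]] <- data.frame(
        place_i = ids[ii], place_j = ids[jj],
        s_ij = s_ij,
        pci = s_ij / sqrt(length(sets[[ids[ii]]]) * length(sets[[ids[jj]]]))
      )
    }
  }
  list(
    edges = if (length(out)) do.call(rbind, out)
            else data.frame(place_i = character(), place_j = character(),
                            s_ij = integer(), pci = double()),
    user_counts = data.frame(place_id = ids,
                             user_count = vapply(sets[ids], length, 1L))
  )
}

# unit-square grid layer written as GeoJSON text, returned as a path
grid_geojson <- function(nx, ny, parent = NULL, path = tempfile(fileext = ".geojson")) {
  feats <- character()
  k <- 0
  for (r in seq_len(ny)) {
    for (c in seq_len(nx)) {
      k <- k + 1
      x0 <- c - 1; y0 <- r - 1
      props <- sprintf('"id":"sq%02d","name":"sq%02d"', k, k)
      if (!is.null(parent)) props <- paste0(props, sprintf(',"parent":"%s"', parent[k]))
      feats <- c(feats, sprintf(
        '{"type":"Feature","properties":{%s},"geometry":{"type":"Polygon","coordinates":[[[%d,%d],[%d,%d],[%d,%d],[%d,%d],[%d,%d]]]}}',
        props, x0, y0, x0 + 1, y0, x0 + 1, y0 + 1, x0, y0 + 1, x0, y0))
    }
  }
  writeLines(sprintf('{"type":"FeatureCollection","features":[%s]}',
                     paste(feats, collapse = ",")), path)
  path
}

# small synthetic world run through the full pipeline up to a pci_matrix
pipeline_pci <- function(seed, grid = 6, states = 4, users = 500, gamma = 3,
                         beta = 1.7) {
  w <- make_world(grid_rows = grid, grid_cols = grid, states = states,
                  seed = seed)
  sim <- simulate_events(w, n_users = users, same_state_boost = gamma,
                         decay_exponent = beta, seed = seed + 10000)
  asn <- assign_points(sim$events, w$layer)
  inc <- build_incidence(asn, YEAR)
  list(world = w, sim = sim, assignment = asn, incidence = inc,
       pci = compute_pci(inc))
}

# per-origin decay exponents from a gravity world, measured on cross-state
# person-day movements over the full pair universe (absent pairs count 0)
end_to_end_decay <- function(world_seed, sim_seed, grid = 8, states = 4,
                             users = 5000, beta = 1.7, gamma = 3) {
  w <- make_world(grid_rows = grid, grid_cols = grid, states = states,
                  seed = world_seed)
  sim <- simulate_events(w, n_users = users, decay_exponent = beta,
                         same_state_boost = gamma, seed = sim_seed)
  asn <- assign_points(sim$events, w$layer)
  home <- infer_home(asn)
  mv <- compute_person_day_movements(asn, YEAR, "home_based", home)
  dist <- centroid_distance(w$layer)
  parents <- setNames(w$parent_map$parent_id, w$parent_map$child_id)
  tab <- dplyr::left_join(
    dplyr::select(dist, "place_i", "place_j", distance_miles = "value"),
    dplyr::select(mv, "place_i", "place_j", "value"),
    by = c("place_i", "place_j"))
  tab$value[is.na(tab$value)] <- 0
  tab <- tab[parents[tab$place_i] != parents[tab$place_j], ]
  origins <- unique(c(tab$place_i, tab$place_j))
  vapply(origins, function(o) {
    g <- tab[tab$place_i == o | tab$place_j == o, ]
    fit_distance_decay(g, response = "value")$exponent
  }, double(1))
}

adjusted_rand <- function(a, b) {
  skip_if_not_installed("mclust")
  mclust::adjustedRandIndex(a, b)
}
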