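#' Generate a synthetic world of gridded places
#'
#' Builds a rectangular grid of square lon/lat cells (sized in statute miles
#' at the equator, where one degree spans ~69.1 miles), tiles it into
#' `states` parent regions, and draws a population for every cell uniformly
#' from `population_range`. This is the stage on which the gravity mobility
#' generator operates; grids are centered on the equator so centroid
#' distances match the nominal cell size.
#'
#' @param grid_rows,grid_cols Grid dimensions (`rows * cols >= 2`).
#' @param cell_size_miles Cell edge length in miles at the equator.
#' @param states Number of parent regions; must tile the grid evenly (there
#'   must be a factorization `states = r * c` with `r | grid_rows` and
#'   `c | grid_cols`).
#' @param population_range Length-2 integer range for cell populations.
#' @param seed RNG seed; the same seed reproduces the world exactly.
#' @return A list with `layer` (a `place_layer` tibble, `parent_id` holding
#'   state ids, plus cell bounds columns used by the simulator), `summary`
#'   (tibble `place_id`, `population`), and `parent_map`
#'   (tibble `child_id`, `parent_id`).
#' @export
make_world <- function(grid_rows = 8, grid_cols = 8, cell_size_miles = 69.09,
                       states = 4, population_range = c(5000, 50000),
                       seed = 1) {
  stopifnot(grid_rows * grid_cols >= 2, length(population_range) == 2,
            population_range[1] <= population_range[2])
  tile <- state_tiling(grid_rows, grid_cols, states)
  deg <- cell_size_miles / (pi * 3958.8 / 180)
  lat0 <- -grid_rows * deg / 2
  set.seed(seed)
  cells <- tidyr::expand_grid(row = seq_len(grid_rows), col = seq_len(grid_cols))
  npad <- nchar(as.character(grid_rows * grid_cols))
  cells <- cells |>
    dplyr::mutate(
      place_id = sprintf(paste0("C%0", npad, "d"),
                         (.data$row - 1) * grid_cols + .data$col),
      parent_id = sprintf("S%02d",
                          ((.data$row - 1) %/% tile[1]) * (grid_cols %/% tile[2]) +
                            ((.data$col - 1) %/% tile[2]) + 1),
      lon_min = (.data$col - 1) * deg, lon_max = .data$col * deg,
      lat_min = lat0 + (.data$row - 1) * deg, lat_max = lat0 + .data$row * deg
    )
  geometry <- purrr::pmap(
    list(cells$lon_min, cells$lon_max, cells$lat_min, cells$lat_max),
    function(x0, x1, y0, y1) {
      ring <- cbind(lon = c(x0, x1, x1, x0, x0), lat = c(y0, y0, y1, y1, y0))
      list(list(ring))
    }
  )
  layer <- new_place_layer(tibble::tibble(
    place_id = cells$place_id,
    name = cells$place_id,
    parent_id = cells$parent_id,
    geometry = geometry,
    centroid_lon = (cells$lon_min + cells$lon_max) / 2,
    centroid_lat = (cells$lat_min + cells$lat_max) / 2,
    lon_min = cells$lon_min, lon_max = cells$lon_max,
    lat_min = cells$lat_min, lat_max = cells$lat_max
  ))
  pop <- sample(population_range[1]:population_range[2],
                nrow(cells), replace = TRUE)
  list(
    layer = layer,
    summary = tibble::tibble(place_id = cells$place_id, population = pop),
    parent_map = tibble::tibble(child_id = cells$place_id,
                                parent_id = cells$parent_id)
  )
}

state_tiling <- function(rows, cols, states) {
  divs <- divisors(states)
  ok <- divs[rows %% divs == 0 & states %% divs == 0 &
               cols %% (states / divs) == 0]
  if (length(ok) == 0) {
    stop("states = ", states, " does not tile a ", rows, "x", cols, " grid",
         call. = FALSE)
  }
  best <- ok[which.min(abs(log((rows / ok) / (cols / (states / ok)))))]
  c(rows / best, cols / (states / best))  # tile height, tile width (cells)
}

divisors <- function(n) which(n %% seq_len(n) == 0)

#' Simulate a year of geotagged events from a gravity model
#'
#' Emulates the data-generating process behind shared-user connectivity:
#' users get home places with probability proportional to population; each
#' user posts a Poisson number of events; each event is at home with
#' probability `1 - trip_fraction`, otherwise at a destination drawn with
#' probability proportional to
#' `population_j * d(home, j)^(-decay_exponent) * same_state_boost^[same state]`
#' (home excluded from the trip kernel). Event coordinates are uniform
#' inside the destination cell and timestamps uniform over the period, so
#' the stream exercises point-in-polygon assignment, incidence building and
#' every downstream statistic with known ground truth: distance decay with
#' exponent `decay_exponent`, a same-state connectivity boost, and
#' population-proportional user counts.
#'
#' @param world Output of [make_world()].
#' @param n_users Total user count; default `users_per_capita` times total
#'   population.
#' @param users_per_capita Used when `n_users` is `NULL`.
#' @param events_per_user_mean Poisson mean of events per user over the period.
#' @param trip_fraction Probability an event is away from home, in `[0, 1]`.
#' @param decay_exponent Gravity distance-decay exponent (>= 0).
#' @param same_state_boost Multiplier (>= 1) on destinations in the home state.
#' @param period Length-2 `[start, end)` (dates or date strings, UTC).
#' @param seed RNG seed.
#' @return List with `events` (tibble `user_id`, `timestamp`, `lon`, `lat`),
#'   `homes` (tibble `user_id`, `home`), `visits` (ground-truth realized
#'   user-place sets, tibble `user_id`, `place_id`), and `flows`
#'   (tibble `home`, `destination`, `trips`).
#' @export
simulate_events <- function(world, n_users = NULL, users_per_capita = 0.01,
                            events_per_user_mean = 50, trip_fraction = 0.2,
                            decay_exponent = 1.7, same_state_boost = 3,
                            period = c("2019-01-01", "2020-01-01"),
                            seed = 1) {
  stopifnot(trip_fraction >= 0, trip_fraction <= 1,
            decay_exponent >= 0, same_state_boost >= 1)
  layer <- world$layer
  pop <- world$summary$population[match(layer$place_id, world$summary$place_id)]
  n_places <- nrow(layer)
  period <- as_utc_instant(period)
  set.seed(seed)
  if (is.null(n_users)) n_users <- max(1L, round(users_per_capita * sum(pop)))

  user_id <- sprintf(paste0("u%0", nchar(n_users), "d"), seq_len(n_users))
  home_idx <- sample.int(n_places, n_users, replace = TRUE, prob = pop)
  n_events <- stats::rpois(n_users, events_per_user_mean)

  # pairwise centroid distances (miles) for the trip kernel
  pts <- cbind(layer$centroid_lon, layer$centroid_lat)
  dmat <- matrix(0, n_places, n_places)
  for (i in seq_len(n_places)) {
    dmat[i, ] <- geosphere::distHaversine(pts[i, , drop = FALSE], pts,
                                          r = 3958.8)
  }
  same_state <- outer(layer$parent_id, layer$parent_id, "==")

  ev_user <- rep(seq_len(n_users), n_events)
  n_total <- length(ev_user)
  is_trip <- stats::runif(n_total) < trip_fraction
  dest <- home_idx[ev_user]
  # draw trip destinations home-by-home from the gravity kernel
  trip_rows <- which(is_trip)
  if (length(trip_rows) > 0 && n_places > 1) {
    trip_home <- home_idx[ev_user[trip_rows]]
    for (h in unique(trip_home)) {
      w <- pop * dmat[h, ]^(-decay_exponent) *
        ifelse(same_state[h, ], same_state_boost, 1)
      w[h] <- 0
      rows <- trip_rows[trip_home == h]
      dest[rows] <- sample.int(n_places, length(rows), replace = TRUE, prob = w)
    }
  }
  lon <- stats::runif(n_total, layer$lon_min[dest], layer$lon_max[dest])
  lat <- stats::runif(n_total, layer$lat_min[dest], layer$lat_max[dest])
  ts <- as.POSIXct(stats::runif(n_total, as.numeric(period[1]),
                                as.numeric(period[2])),
                   origin = "1970-01-01", tz = "UTC")
  events <- tibble::tibble(user_id = user_id[ev_user], timestamp = ts,
                           lon = lon, lat = lat) |>
    dplyr::arrange(.data$user_id, .data$timestamp)

  visits <- dplyr::distinct(tibble::tibble(
    user_id = user_id[ev_user], place_id = layer$place_id[dest]
  )) |> dplyr::arrange(.data$user_id, .data$place_id)

  flows <- tibble::tibble(
    home = layer$place_id[home_idx[ev_user[trip_rows]]],
    destination = layer$place_id[dest[trip_rows]]
  ) |> dplyr::count(.data$home, .data$destination, name = "trips")

  list(events = events,
       homes = tibble::tibble(user_id = user_id,
                              home = layer$place_id[home_idx]),
       visits = visits, flows = flows)
}

#' Block-structured connectivity fixture with planted communities
#'
#' Builds a symmetric connectivity matrix whose within-block pairs have mean
#' `intra_pci` and cross-block pairs mean `inter_pci`, plus Gaussian noise
#' truncated to `[0, 1]` — the planted-partition ground truth for testing
#' regionalization.
#'
#' @param n_blocks,block_size Community structure (total places =
#'   `n_blocks * block_size`).
#' @param intra_pci,inter_pci Block means; requires
#'   `0 <= inter_pci < intra_pci <= 1`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @param user_count Unique-user count assigned to every place in the
#'   summary (all places pass the default min-user filter).
#' @return List with `pci_matrix` (a `pci_matrix`; `shared_users` is `NULL`
#'   since the fixture plants the index directly) and `labels`
#'   (tibble `place_id`, `block`).
#' @export
make_block_pci <- function(n_blocks, block_size, intra_pci, inter_pci,
                           noise_sd = 0, seed = 1, user_count = 100) {
  if (!(inter_pci >= 0 && inter_pci < intra_pci && intra_pci <= 1)) {
    stop("need 0 <= inter_pci < intra_pci <= 1", call. = FALSE)
  }
  n <- n_blocks * block_size
  npad <- nchar(as.character(n))
  ids <- sprintf(paste0("P%0", npad, "d"), seq_len(n))
  block <- rep(seq_len(n_blocks), each = block_size)
  set.seed(seed)
  pairs <- utils::combn(n, 2)
  mu <- ifelse(block[pairs[1, ]] == block[pairs[2, ]], intra_pci, inter_pci)
  v <- pmin(1, pmax(0, mu + stats::rnorm(ncol(pairs), 0, noise_sd)))
  keep <- v > 0
  pm <- structure(
    list(
      pci = edge_list(ids[pairs[1, keep]], ids[pairs[2, keep]], v[keep],
                      kind = "pci"),
      shared_users = NULL,
      place_summary = tibble::tibble(place_id = ids, user_count = user_count)
    ),
    class = "pci_matrix"
  )
  list(pci_matrix = pm, labels = tibble::tibble(place_id = ids, block = block))
}
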