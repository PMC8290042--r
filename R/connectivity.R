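#' Build the user-place incidence set for a time period
#'
#' The incidence set is the object all connectivity quantities derive from:
#' for a half-open period `[start, end)` it records, per user, the set of
#' places the user was observed in (at least one assigned event inside the
#' period), and per place the number of unique observed users.
#'
#' @param assignment Tibble from [assign_points()] (or [map_to_level()]).
#' @param period Length-2 vector (`Date` or `POSIXct`) giving `[start, end)`;
#'   timestamps are compared in UTC.
#' @return An object of class `incidence_set`: a list with `user_places`
#'   (tibble `user_id`, `place_id`, one row per observed pair), `place_users`
#'   (tibble `place_id`, `user_count`), and `period`.
#' @export
build_incidence <- function(assignment, period) {
  period <- as_utc_instant(period)
  if (length(period) != 2 || !(period[1] < period[2])) {
    stop("period must be two instants with start < end", call. = FALSE)
  }
  ts <- as_utc_instant(assignment$timestamp)
  keep <- ts >= period[1] & ts < period[2]
  user_places <- dplyr::distinct(
    tibble::tibble(user_id = assignment$user_id[keep],
                   place_id = assignment$place_id[keep])
  )
  place_users <- dplyr::count(user_places, .data$place_id, name = "user_count")
  structure(
    list(user_places = dplyr::arrange(user_places, .data$user_id, .data$place_id),
         place_users = dplyr::arrange(place_users, .data$place_id),
         period = period),
    class = "incidence_set"
  )
}

as_utc_instant <- function(x) {
  if (inherits(x, "Date")) as.POSIXct(as.character(x), tz = "UTC")
  else if (inherits(x, "POSIXct")) x
  else if (is.character(x)) parse_utc(x)
  else stop("cannot interpret as instant: ", class(x)[1], call. = FALSE)
}

#' @export
print.incidence_set <- function(x, ...) {
  cat("<incidence_set> ", format(x$period[1]), " to ", format(x$period[2]),
      " (UTC, half-open)\n", sep = "")
  cat("  users:  ", dplyr::n_distinct(x$user_places$user_id), "\n", sep = "")
  cat("  places: ", nrow(x$place_users), "\n", sep = "")
  invisible(x)
}

#' Compute the place connectivity index
#'
#' For places i and j with `S_i`, `S_j` unique observed users and `S_ij`
#' shared users (users observed in both), the connectivity index is
#' `S_ij / sqrt(S_i * S_j)` — the shared-user count normalized by the
#' geometric mean of the two user counts, giving a value in `[0, 1]`.
#' Pairs with no shared user (index 0) are not stored; self-pairs are
#' identically 1 and are omitted from the edge list.
#'
#' @param incidence An `incidence_set` from [build_incidence()].
#' @return An object of class `pci_matrix`: list with `pci` (edge list of
#'   kind `pci`), `shared_users` (edge list of kind `shared_users`), and
#'   `place_summary` (tibble `place_id`, `user_count`).
#' @examples
#' asn <- tibble::tibble(
#'   user_id = c("u1", "u1", "u2"),
#'   timestamp = as.POSIXct("2019-06-01", tz = "UTC"),
#'   place_id = c("A", "B", "A")
#' )
#' inc <- build_incidence(asn, as.Date(c("2019-01-01", "2020-01-01")))
#' compute_pci(inc)$pci  # S_A=2, S_B=1, S_AB=1 -> 1/sqrt(2)
#' @export
compute_pci <- function(incidence) {
  stopifnot(inherits(incidence, "incidence_set"))
  up <- incidence$user_places
  if (nrow(up) == 0) stop("incidence set is empty", call. = FALSE)
  shared <- up |>
    dplyr::inner_join(up, by = "user_id", relationship = "many-to-many",
                      suffix = c("_i", "_j")) |>
    dplyr::filter(.data$place_id_i < .data$place_id_j) |>
    dplyr::count(.data$place_id_i, .data$place_id_j, name = "s_ij")
  pu <- incidence$place_users
  s <- stats::setNames(pu$user_count, pu$place_id)
  pci_val <- shared$s_ij / sqrt(s[shared$place_id_i] * s[shared$place_id_j])
  structure(
    list(
      pci = edge_list(shared$place_id_i, shared$place_id_j,
                      unname(pci_val), kind = "pci"),
      shared_users = edge_list(shared$place_id_i, shared$place_id_j,
                               as.double(shared$s_ij), kind = "shared_users"),
      place_summary = tibble::tibble(place_id = pu$place_id,
                                     user_count = pu$user_count)
    ),
    class = "pci_matrix"
  )
}

#' @export
print.pci_matrix <- function(x, ...) {
  cat("<pci_matrix> ", nrow(x$place_summary), " places, ",
      nrow(x$pci), " connected pairs\n", sep = "")
  if (nrow(x$pci) > 0) {
    q <- stats::quantile(x$pci$value, c(0, .5, 1))
    cat(sprintf("  pci range: %.4g (median %.4g) to %.4g\n", q[1], q[2], q[3]))
  }
  invisible(x)
}

#' Directional connectivity
#'
#' The directional index from i to j is `S_ij / S_i`: the share of i's users
#' also observed in j. It is stored for both directions, and its geometric
#' mean over the two directions reproduces the symmetric index exactly:
#' `sqrt(S_ij/S_i * S_ij/S_j) = S_ij / sqrt(S_i S_j)`.
#'
#' @inheritParams compute_pci
#' @return An edge list of kind `pci_directional` with one row per ordered
#'   pair that shares at least one user.
#' @export
compute_directional_pci <- function(incidence) {
  stopifnot(inherits(incidence, "incidence_set"))
  sym <- compute_pci(incidence)
  sh <- sym$shared_users
  s <- stats::setNames(sym$place_summary$user_count, sym$place_summary$place_id)
  tibble::tibble(
    place_i = c(sh$place_i, sh$place_j),
    place_j = c(sh$place_j, sh$place_i),
    kind = "pci_directional",
    value = c(sh$value / unname(s[sh$place_i]),
              sh$value / unname(s[sh$place_j]))
  ) |>
    dplyr::arrange(.data$place_i, .data$place_j)
}

#' Infer each user's home place
#'
#' Home is the user's modal place by assigned-event count; ties are broken by
#' the earliest first observation among the tied places, then by
#' lexicographic place id.
#'
#' @param assignment Tibble from [assign_points()].
#' @return Tibble (`user_id`, `home`).
#' @export
infer_home <- function(assignment) {
  assignment |>
    dplyr::group_by(.data$user_id, .data$place_id) |>
    dplyr::summarise(n_events = dplyr::n(),
                     first_seen = min(.data$timestamp), .groups = "drop") |>
    dplyr::group_by(.data$user_id) |>
    dplyr::arrange(dplyr::desc(.data$n_events), .data$first_seen,
                   .data$place_id, .by_group = TRUE) |>
    dplyr::summarise(home = dplyr::first(.data$place_id))
}

#' Person-day movement matrix
#'
#' Counts (user, UTC calendar day) movement units between place pairs, the
#' quantity mobility panels report. Two modes:
#' * `home_based` (default): a user-day with at least one event in a place
#'   `j` different from the user's home contributes 1 to the pair
#'   `(home, j)` — one unit per distinct destination visited that day.
#' * `copresence`: a user-day with events in `m >= 2` distinct places
#'   contributes 1 to each of the `choose(m, 2)` unordered pairs.
#'
#' @param assignment Tibble from [assign_points()].
#' @param period Half-open `[start, end)` interval, as in [build_incidence()].
#' @param mode `"home_based"` or `"copresence"`.
#' @param home Tibble from [infer_home()]; required for `home_based`.
#' @return An edge list of kind `person_days` (integer-valued).
#' @export
compute_person_day_movements <- function(assignment, period,
                                         mode = c("home_based", "copresence"),
                                         home = NULL) {
  mode <- match.arg(mode)
  period <- as_utc_instant(period)
  ts <- as_utc_instant(assignment$timestamp)
  keep <- ts >= period[1] & ts < period[2]
  ud <- dplyr::distinct(tibble::tibble(
    user_id = assignment$user_id[keep],
    day = as.Date(ts[keep], tz = "UTC"),
    place_id = assignment$place_id[keep]
  ))
  if (mode == "home_based") {
    if (is.null(home)) stop("home_based mode requires a home table", call. = FALSE)
    moves <- ud |>
      dplyr::inner_join(home, by = "user_id") |>
      dplyr::filter(.data$place_id != .data$home) |>
      dplyr::mutate(a = pmin(.data$home, .data$place_id),
                    b = pmax(.data$home, .data$place_id)) |>
      dplyr::count(.data$a, .data$b, name = "n")
  } else {
    moves <- ud |>
      dplyr::inner_join(ud, by = c("user_id", "day"),
                        relationship = "many-to-many", suffix = c("_i", "_j")) |>
      dplyr::filter(.data$place_id_i < .data$place_id_j) |>
      dplyr::count(.data$place_id_i, .data$place_id_j, name = "n") |>
      dplyr::rename(a = "place_id_i", b = "place_id_j")
  }
  if (nrow(moves) == 0) {
    return(tibble::tibble(place_i = character(), place_j = character(),
                          kind = character(), value = double()))
  }
  edge_list(moves$a, moves$b, as.double(moves$n), kind = "person_days")
}

#' Drop thinly-observed places from a connectivity matrix
#'
#' Places observed by fewer than `min_users` unique users are removed along
#' with all their edges. The default threshold of 5 matches the convention of
#' ignoring places with fewer than five users when mapping or regionalizing.
#'
#' @param pci_matrix A `pci_matrix` from [compute_pci()].
#' @param min_users Minimum unique-user count to retain a place.
#' @return A filtered `pci_matrix`.
#' @export
filter_min_users <- function(pci_matrix, min_users = 5) {
  stopifnot(inherits(pci_matrix, "pci_matrix"), min_users >= 0)
  keep_ids <- pci_matrix$place_summary$place_id[
    pci_matrix$place_summary$user_count >= min_users
  ]
  keep_edge <- function(e) {
    if (is.null(e)) return(NULL)
    e[e$place_i %in% keep_ids & e$place_j %in% keep_ids, ]
  }
  structure(
    list(
      pci = keep_edge(pci_matrix$pci),
      shared_users = keep_edge(pci_matrix$shared_users),
      place_summary = pci_matrix$place_summary[
        pci_matrix$place_summary$place_id %in% keep_ids, ]
    ),
    class = "pci_matrix"
  )
}
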