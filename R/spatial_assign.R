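#' Assign point events to places
#'
#' Point-in-polygon spatial join of geotagged events onto a place layer.
#' "Covers" semantics: a point on a polygon's boundary belongs to that
#' polygon, so a point on the shared edge of two places is covered by both —
#' the tie is broken deterministically to the lexicographically smallest
#' place id, with a warning. Events covered by no place are excluded from the
#' output and tallied.
#'
#' @param events Tibble of events (`user_id`, `timestamp`, `lon`, `lat`),
#'   as returned by [read_events()] or [simulate_events()].
#' @param layer A `place_layer` tibble.
#' @return A tibble (`user_id`, `timestamp`, `place_id`) with attribute
#'   `unassigned_count`.
#' @export
assign_points <- function(events, layer) {
  if (nrow(layer) == 0) stop("place layer is empty", call. = FALSE)
  n <- nrow(events)
  # candidate matches per event; places scanned in id order so the first
  # match is the lexicographic-min tie winner
  ord <- order(layer$place_id)
  assigned <- rep(NA_character_, n)
  multi <- rep(FALSE, n)
  for (r in ord) {
    polys <- layer$geometry[[r]]
    bb <- place_bbox(polys)
    cand <- which(events$lon >= bb[1] & events$lon <= bb[2] &
                    events$lat >= bb[3] & events$lat <= bb[4])
    if (length(cand) == 0) next
    inside <- rep(FALSE, length(cand))
    for (poly in polys) {
      outer <- poly[[1]]
      hit <- sp::point.in.polygon(events$lon[cand], events$lat[cand],
                                  outer[, 1], outer[, 2]) > 0
      if (length(poly) > 1) {
        for (hole in poly[-1]) {
          # strictly interior to a hole -> not covered; hole boundary stays in
          inhole <- sp::point.in.polygon(events$lon[cand], events$lat[cand],
                                         hole[, 1], hole[, 2]) == 1
          hit <- hit & !inhole
        }
      }
      inside <- inside | hit
    }
    idx <- cand[inside]
    fresh <- is.na(assigned[idx])
    assigned[idx[fresh]] <- layer$place_id[r]
    multi[idx[!fresh]] <- TRUE
  }
  if (any(multi)) {
    warning(sum(multi), " event(s) covered by more than one place; ",
            "assigned to the smallest place id", call. = FALSE)
  }
  keep <- !is.na(assigned)
  out <- tibble::tibble(
    user_id = events$user_id[keep],
    timestamp = events$timestamp[keep],
    place_id = assigned[keep]
  )
  attr(out, "unassigned_count") <- sum(!keep)
  out
}

place_bbox <- function(polys) {
  xs <- unlist(purrr::map(polys, ~ purrr::map(.x, ~ .x[, 1])))
  ys <- unlist(purrr::map(polys, ~ purrr::map(.x, ~ .x[, 2])))
  c(min(xs), max(xs), min(ys), max(ys))
}

#' Re-key an assignment to a coarser geographic level
#'
#' Maps each assigned place id to its parent (county to state, subdivision to
#' country, ...). Multi-scale connectivity is computed by re-keying the event
#' assignment and recounting unique users at the coarser level — not by
#' summing child-level shared counts, which would double-count users observed
#' in several children of one parent.
#'
#' @param assignment Output of [assign_points()].
#' @param mapping Tibble or data frame with columns `child_id`, `parent_id`.
#' @return An assignment tibble keyed by parent ids; `unassigned_count` is
#'   carried over unchanged.
#' @export
map_to_level <- function(assignment, mapping) {
  stopifnot(all(c("child_id", "parent_id") %in% names(mapping)))
  idx <- match(assignment$place_id, mapping$child_id)
  if (anyNA(idx)) {
    orphan <- unique(assignment$place_id[is.na(idx)])
    stop("no parent for place id(s): ", paste(orphan, collapse = ", "),
         call. = FALSE)
  }
  out <- assignment
  out$place_id <- mapping$parent_id[idx]
  attr(out, "unassigned_count") <- attr(assignment, "unassigned_count") %||% 0L
  out
}

#' Great-circle centroid distances between all place pairs
#'
#' Haversine distance between place centroids in statute miles
#' (Earth radius 3958.8 mi), one row per unordered pair.
#'
#' @param layer A `place_layer` tibble with populated centroids.
#' @return An edge list of kind `distance_miles`.
#' @export
centroid_distance <- function(layer) {
  n <- nrow(layer)
  if (n < 2) stop("need at least two places", call. = FALSE)
  ord <- order(layer$place_id)
  ids <- layer$place_id[ord]
  pts <- cbind(layer$centroid_lon[ord], layer$centroid_lat[ord])
  pairs <- utils::combn(n, 2)
  d <- geosphere::distHaversine(pts[pairs[1, ], , drop = FALSE],
                                pts[pairs[2, ], , drop = FALSE],
                                r = 3958.8)
  edge_list(ids[pairs[1, ]], ids[pairs[2, ]], d, kind = "distance_miles")
}
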