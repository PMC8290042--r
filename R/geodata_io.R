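#' Read geotagged events from delimited text
#'
#' Reads one row per geotagged post (user id, timestamp, longitude, latitude)
#' from CSV or TSV (autodetected by extension). Rows violating the coordinate
#' bounds, with an unparseable timestamp, or with an empty user id are dropped
#' and tallied; identical duplicate rows are kept (deduplication is not the
#' reader's job — unique-user logic downstream is unaffected).
#'
#' @param path Delimited text file with a header.
#' @param columns Named character vector mapping the canonical names
#'   `user_id`, `timestamp`, `lon`, `lat` to the file's column names.
#' @return A tibble with columns `user_id` (character), `timestamp`
#'   (POSIXct, UTC), `lon`, `lat`; the number of rejected rows is attached as
#'   attribute `n_rejected` and reported via a message when non-zero.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("u,t,x,y", "a,2019-01-01,10,50", "b,2019-06-01,11,95"), f)
#' ev <- read_events(f, c(user_id = "u", timestamp = "t", lon = "x", lat = "y"))
#' attr(ev, "n_rejected")  # the lat=95 row
#' @export
read_events <- function(path,
                        columns = c(user_id = "user_id", timestamp = "timestamp",
                                    lon = "lon", lat = "lat")) {
  required <- c("user_id", "timestamp", "lon", "lat")
  if (!all(required %in% names(columns))) {
    stop("`columns` must name all of: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  reader <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  raw <- suppressWarnings(
    reader(path, col_types = readr::cols(.default = readr::col_character()))
  )
  missing <- setdiff(unname(columns[required]), names(raw))
  if (length(missing) > 0) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ev <- tibble::tibble(
    user_id = raw[[columns[["user_id"]]]],
    timestamp = parse_utc(raw[[columns[["timestamp"]]]]),
    lon = suppressWarnings(as.double(raw[[columns[["lon"]]]])),
    lat = suppressWarnings(as.double(raw[[columns[["lat"]]]]))
  )
  ok <- !is.na(ev$user_id) & nzchar(ev$user_id) &
    !is.na(ev$timestamp) &
    !is.na(ev$lon) & ev$lon >= -180 & ev$lon <= 180 &
    !is.na(ev$lat) & ev$lat >= -90 & ev$lat <= 90
  out <- ev[ok, ]
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    message(n_rejected, " event row(s) rejected (bounds/parse failures)")
  }
  attr(out, "n_rejected") <- n_rejected
  out
}

# ISO 8601 with date resolution at minimum; timezone-naive strings are UTC.
# strptime (unlike as.POSIXct) yields NA per element instead of erroring.
parse_utc <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out
}

#' Read a polygon place layer from GeoJSON
#'
#' Parses a WGS84 FeatureCollection of Polygon/MultiPolygon features into the
#' package's place-layer tibble: one row per place with its id, name, optional
#' parent-region id, polygon rings as a list-column, and the area-weighted
#' polygon centroid.
#'
#' @param path GeoJSON file.
#' @param id_field Property holding the unique place id.
#' @param name_field Property holding a display name (defaults to the id).
#' @param parent_field Optional property holding the parent-region id (e.g.
#'   the state of a county).
#' @return A tibble of class `place_layer` with columns `place_id`, `name`,
#'   `parent_id`, `geometry` (list of polygons, each a list of ring matrices
#'   with lon/lat columns), `centroid_lon`, `centroid_lat`.
#' @export
read_place_layer <- function(path, id_field = "id", name_field = NULL,
                             parent_field = NULL) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  feats <- gj$features
  rows <- purrr::imap(feats, function(f, idx) {
    geom <- f$geometry
    if (is.null(geom$type) || !geom$type %in% c("Polygon", "MultiPolygon")) {
      stop("feature ", idx, " has non-polygon geometry (",
           geom$type %||% "missing", ")", call. = FALSE)
    }
    props <- f$properties
    id <- props[[id_field]]
    if (is.null(id) || !nzchar(as.character(id))) {
      stop("feature ", idx, " lacks id field '", id_field, "'", call. = FALSE)
    }
    polys <- if (geom$type == "Polygon") list(geom$coordinates) else geom$coordinates
    polys <- purrr::map(polys, function(poly) {
      purrr::map(poly, function(ring) {
        m <- do.call(rbind, purrr::map(ring, ~ c(.x[[1]], .x[[2]])))
        colnames(m) <- c("lon", "lat")
        m
      })
    })
    tibble::tibble(
      place_id = as.character(id),
      name = as.character(
        if (!is.null(name_field) && !is.null(props[[name_field]]))
          props[[name_field]] else id
      ),
      parent_id = if (!is.null(parent_field) && !is.null(props[[parent_field]]))
        as.character(props[[parent_field]]) else NA_character_,
      geometry = list(polys)
    )
  })
  layer <- dplyr::bind_rows(rows)
  dup <- layer$place_id[duplicated(layer$place_id)]
  if (length(dup) > 0) {
    stop("duplicate place id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  cent <- purrr::map(layer$geometry, multipolygon_centroid)
  layer$centroid_lon <- purrr::map_dbl(cent, 1)
  layer$centroid_lat <- purrr::map_dbl(cent, 2)
  new_place_layer(layer)
}

new_place_layer <- function(df) {
  structure(df, class = c("place_layer", class(tibble::tibble())))
}

# area-weighted centroid over outer rings (shoelace); holes are rare in the
# layers this package targets and are ignored for the centroid
multipolygon_centroid <- function(polys) {
  acc <- c(0, 0)
  area <- 0
  for (poly in polys) {
    ring <- poly[[1]]
    x <- ring[, 1]; y <- ring[, 2]
    n <- nrow(ring)
    j <- c(2:n, 1)
    cr <- x * y[j] - x[j] * y
    a <- sum(cr) / 2
    if (abs(a) < .Machine$double.eps) next
    cx <- sum((x + x[j]) * cr) / (6 * a)
    cy <- sum((y + y[j]) * cr) / (6 * a)
    acc <- acc + abs(a) * c(cx, cy)
    area <- area + abs(a)
  }
  if (area == 0) c(mean(polys[[1]][[1]][, 1]), mean(polys[[1]][[1]][, 2]))
  else acc / area
}

#' Write a place layer to GeoJSON
#'
#' @param layer A `place_layer` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_place_layer <- function(layer, path) {
  feats <- purrr::pmap(
    list(layer$place_id, layer$name, layer$parent_id, layer$geometry),
    function(id, nm, parent, polys) {
      coords <- purrr::map(polys, function(poly) {
        purrr::map(poly, function(ring) {
          purrr::map(seq_len(nrow(ring)), ~ c(ring[.x, 1], ring[.x, 2]))
        })
      })
      props <- list(id = id, name = nm)
      if (!is.na(parent)) props$parent <- parent
      single <- length(polys) == 1
      list(
        type = "Feature",
        properties = props,
        geometry = list(
          type = if (single) "Polygon" else "MultiPolygon",
          coordinates = if (single) coords[[1]] else coords
        )
      )
    }
  )
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write per-place summaries
#'
#' A place summary carries the unique-user count per place (the denominator
#' terms of the connectivity index) plus any covariates (population, outcome
#' rates) joined for downstream models.
#'
#' @param path CSV path.
#' @return A tibble with `place_id`, `user_count`, and any extra columns.
#' @export
read_place_summary <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    place_id = readr::col_character(),
    .default = readr::col_double()
  ))
  if (!all(c("place_id", "user_count") %in% names(out))) {
    stop("place summary needs place_id and user_count columns", call. = FALSE)
  }
  if (any(out$user_count < 0)) stop("user_count must be >= 0", call. = FALSE)
  out
}

#' @rdname read_place_summary
#' @param summary A place-summary tibble.
#' @export
write_place_summary <- function(summary, path) {
  readr::write_csv(summary, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
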