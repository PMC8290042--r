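#' Log-transform connectivity or movement values
#'
#' Base-10 logarithm used to tame the heavy right skew of pairwise
#' connectivity and movement distributions. For `kind = "pci"` values are
#' first multiplied by 1000 so that typical indices map to non-negative
#' logs; `kind = "plain"` takes the log directly. Non-positive inputs cannot
#' be logged and are dropped with a reported tally.
#'
#' @param values Numeric vector.
#' @param kind `"pci"` (log10 of 1000 x value) or `"plain"` (log10).
#' @return Transformed vector with attribute `n_dropped`; errors if every
#'   value is dropped.
#' @examples
#' log_transform(c(1, 0.001), kind = "pci")  # 3, 0
#' @export
log_transform <- function(values, kind = c("pci", "plain")) {
  kind <- match.arg(kind)
  scaled <- if (kind == "pci") 1000 * values else values
  ok <- is.finite(scaled) & scaled > 0
  if (!any(ok)) stop("no positive values to log-transform", call. = FALSE)
  if (any(!ok)) {
    message(sum(!ok), " non-positive value(s) dropped before log transform")
  }
  out <- log10(scaled[ok])
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Join two edge lists on unordered place pairs
#'
#' Inner join: only pairs present (i.e. nonzero) in both inputs are kept,
#' mirroring how external comparison streams are aligned ("pairs that have
#' both values"). The dropped count is attached. Optional decorations add a
#' centroid distance column and a same-parent indicator.
#'
#' @param A,B Edge lists; their values become columns `x` and `y`.
#' @param distances Optional edge list of kind `distance_miles`.
#' @param parent_map Optional tibble (`child_id`, `parent_id`); adds
#'   `same_parent` = 1 when both places share a parent.
#' @return Tibble (`place_i`, `place_j`, `x`, `y`[, `distance_miles`]
#'   [, `same_parent`]) with attribute `n_dropped` (pairs in exactly one
#'   input).
#' @export
pair_edges <- function(A, B, distances = NULL, parent_map = NULL) {
  a <- dplyr::select(A, "place_i", "place_j", x = "value")
  b <- dplyr::select(B, "place_i", "place_j", y = "value")
  out <- dplyr::inner_join(a, b, by = c("place_i", "place_j"))
  attr_drop <- (nrow(a) - nrow(out)) + (nrow(b) - nrow(out))
  if (!is.null(distances)) {
    d <- dplyr::select(distances, "place_i", "place_j",
                       distance_miles = "value")
    out <- dplyr::left_join(out, d, by = c("place_i", "place_j"))
  }
  if (!is.null(parent_map)) {
    pm <- stats::setNames(as.character(parent_map$parent_id),
                          parent_map$child_id)
    out$same_parent <- as.integer(
      !is.na(pm[out$place_i]) & !is.na(pm[out$place_j]) &
        pm[out$place_i] == pm[out$place_j]
    )
  }
  attr(out, "n_dropped") <- attr_drop
  out
}

#' Pearson correlation of a paired edge table
#'
#' @param table A paired edge table from [pair_edges()].
#' @param transform_x,transform_y `"none"`, `"pci"`, or `"plain"`; the latter
#'   two apply [log_transform()] (rows where either transform drops a value
#'   are removed pairwise).
#' @return Tibble (`pearson_r`, `n`).
#' @export
correlate <- function(table, transform_x = "none", transform_y = "none") {
  xy <- apply_transforms(table, transform_x, transform_y)
  if (nrow(xy) < 3) stop("need at least 3 records to correlate", call. = FALSE)
  tibble::tibble(pearson_r = stats::cor(xy$x, xy$y), n = nrow(xy))
}

apply_transforms <- function(table, transform_x, transform_y) {
  x <- table$x
  y <- table$y
  ok <- rep(TRUE, length(x))
  if (transform_x != "none") ok <- ok & transform_ok(x, transform_x)
  if (transform_y != "none") ok <- ok & transform_ok(y, transform_y)
  x <- x[ok]; y <- y[ok]
  if (transform_x != "none") x <- log10(if (transform_x == "pci") 1000 * x else x)
  if (transform_y != "none") y <- log10(if (transform_y == "pci") 1000 * y else y)
  tibble::tibble(x = x, y = y)
}

transform_ok <- function(v, kind) {
  s <- if (kind == "pci") 1000 * v else v
  is.finite(s) & s > 0
}

#' Per-origin correlation and slope
#'
#' Restricts the paired table to each place's incident pairs and reports the
#' Pearson correlation and the simple-regression slope of `y` on `x` from
#' that place to all others — the per-county comparison the connectivity
#' index is validated with. Slopes can then be associated with a covariate
#' (e.g. log population) via [correlate()].
#'
#' @param table Paired edge table; transforms as in [correlate()].
#' @inheritParams correlate
#' @return Tibble (`origin`, `pearson_r`, `ols_slope`, `n`), one row per
#'   origin with at least 3 incident pairs; the omitted-origin count is
#'   attached as attribute `n_omitted`.
#' @export
per_origin_stats <- function(table, transform_x = "none", transform_y = "none") {
  long <- dplyr::bind_rows(
    dplyr::mutate(table, origin = .data$place_i),
    dplyr::mutate(table, origin = .data$place_j)
  )
  by_origin <- split(long, long$origin)
  rows <- purrr::map(by_origin, function(g) {
    xy <- apply_transforms(g, transform_x, transform_y)
    if (nrow(xy) < 3 || stats::sd(xy$x) == 0) return(NULL)
    fit <- stats::lm.fit(cbind(1, xy$x), xy$y)
    tibble::tibble(origin = g$origin[1],
                   pearson_r = stats::cor(xy$x, xy$y),
                   ols_slope = unname(fit$coefficients[2]),
                   n = nrow(xy))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_omitted") <- length(by_origin) - nrow(out)
  out
}

#' Fit a distance-decay power law
#'
#' Fits `y = a * d^(-b)` to a paired table of connectivity (`x` treated as
#' the response when `response = "x"`, default `y`) against
#' `distance_miles`, by nonlinear least squares on the raw scale,
#' initialized from the log-log ordinary-least-squares solution over the
#' positive responses. Zero responses stay in the raw-scale fit — a pair
#' with no observed interaction is an informative low value, and excluding
#' it would flatten the tail. The coefficient of determination is reported
#' on the raw scale. If the nonlinear fit fails to converge the closed-form
#' log-log fit is returned, flagged as a fallback.
#'
#' @param table Tibble with a response column and `distance_miles > 0`;
#'   typically one origin's incident pairs.
#' @param response Name of the response column (default `"y"`; pass `"value"`
#'   to fit an edge list joined with distances).
#' @return An object of class `decay_fit` with fields `amplitude`,
#'   `exponent`, `r_squared`, `n_pairs`, `fallback`, and the fitting data.
#' @examples
#' d <- seq(10, 500, length.out = 50)
#' tab <- tibble::tibble(y = 5 * d^-1.7, distance_miles = d)
#' fit_distance_decay(tab)  # recovers exponent 1.7 exactly
#' @export
fit_distance_decay <- function(table, response = "y") {
  stopifnot("distance_miles" %in% names(table), response %in% names(table))
  dat <- tibble::tibble(y = table[[response]], d = table$distance_miles)
  dat <- dat[is.finite(dat$y) & dat$y >= 0 & is.finite(dat$d) & dat$d > 0, ]
  pos <- dat[dat$y > 0, ]
  if (nrow(pos) < 3) stop("need at least 3 positive pairs", call. = FALSE)
  # closed-form log-log start values from the positive responses; the
  # raw-scale fit itself keeps zero responses (they are informative lows)
  lf <- stats::lm.fit(cbind(1, log(pos$d)), log(pos$y))
  a0 <- exp(unname(lf$coefficients[1]))
  b0 <- -unname(lf$coefficients[2])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * d^(-b), data = dat,
                      start = list(a = a0, b = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    a <- unname(a0); b <- unname(b0); fallback <- TRUE
  } else {
    cf <- stats::coef(fit)
    a <- unname(cf["a"]); b <- unname(cf["b"]); fallback <- FALSE
  }
  yhat <- a * dat$d^(-b)
  ss_res <- sum((dat$y - yhat)^2)
  ss_tot <- sum((dat$y - mean(dat$y))^2)
  structure(
    list(amplitude = a, exponent = b,
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
         n_pairs = nrow(dat), fallback = fallback, data = dat),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> y = a * d^(-b)", if (x$fallback) " [log-log fallback]", "\n",
      sep = "")
  cat(sprintf("  a = %.6g, b = %.4f, R^2 (raw scale) = %.3f, n = %d\n",
              x$amplitude, x$exponent, x$r_squared, x$n_pairs))
  invisible(x)
}

#' Administrative boundary-effect regression
#'
#' Ordinary least squares of pairwise connectivity on an intercept, a
#' same-parent indicator (e.g. both counties in one state) and centroid
#' distance — the design used to test whether, at fixed distance, places
#' sharing an administrative parent are more connected. Conventional
#' standard errors, two-sided t p-values.
#'
#' @param table Paired edge table with `same_parent` and `distance_miles`
#'   columns and the response in `y` (use `response` to override).
#' @param response Response column name (default `"y"`).
#' @return A `conn_lm` regression summary (see [tidy.conn_lm()]).
#' @export
boundary_regression <- function(table, response = "y") {
  stopifnot(all(c("same_parent", "distance_miles") %in% names(table)))
  if (nrow(table) < 10) stop("need at least 10 records", call. = FALSE)
  df <- data.frame(y = table[[response]],
                   same_parent = table$same_parent,
                   distance = table$distance_miles)
  if (stats::sd(df$same_parent) == 0 || stats::sd(df$distance) == 0) {
    stop("collinear design: a regressor is constant", call. = FALSE)
  }
  fit <- stats::lm(y ~ same_parent + distance, data = df)
  if (any(is.na(stats::coef(fit)))) {
    stop("collinear design: coefficients not estimable", call. = FALSE)
  }
  as_conn_lm(fit, response = response)
}

#' Focal-place association model
#'
#' Regresses a per-place outcome (an infection rate, an evacuee count, ...)
#' on each place's connectivity to one focal place, optionally controlling
#' for distance to the focal place. The connectivity index is multiplied by
#' `scale` (default 1000) so coefficients are presented on a convenient
#' magnitude.
#'
#' @param outcomes Tibble with `place_id` and an `outcome` column.
#' @param connectivity_to_focal Edge list restricted to pairs involving the
#'   focal place (either column may hold the focal id).
#' @param focal Id of the focal place.
#' @param distances Optional edge list of kind `distance_miles`; adds a
#'   distance control.
#' @param scale Multiplier applied to connectivity before fitting.
#' @param outcome Name of the outcome column in `outcomes`.
#' @return A `conn_lm` regression summary.
#' @export
focal_association <- function(outcomes, connectivity_to_focal, focal,
                              distances = NULL, scale = 1000,
                              outcome = "outcome") {
  stopifnot(outcome %in% names(outcomes))
  conn <- focal_edges(connectivity_to_focal, focal, "connectivity")
  df <- dplyr::inner_join(
    dplyr::select(outcomes, "place_id", y = dplyr::all_of(outcome)),
    conn, by = "place_id"
  )
  df$connectivity <- scale * df$connectivity
  rhs <- "connectivity"
  if (!is.null(distances)) {
    d <- focal_edges(distances, focal, "distance")
    df <- dplyr::inner_join(df, d, by = "place_id")
    rhs <- c(rhs, "distance")
  }
  if (nrow(df) < 10) stop("fewer than 10 joined rows", call. = FALSE)
  fit <- stats::lm(stats::reformulate(rhs, response = "y"), data = df)
  as_conn_lm(fit, response = outcome)
}

focal_edges <- function(edges, focal, value_name) {
  e <- edges[edges$place_i == focal | edges$place_j == focal, ]
  tibble::tibble(
    place_id = ifelse(e$place_i == focal, e$place_j, e$place_i),
    !!value_name := e$value
  )
}

# wrap an lm into the package's regression-summary contract
as_conn_lm <- function(fit, response) {
  sm <- summary(fit)
  co <- sm$coefficients
  structure(
    list(
      terms = tibble::tibble(
        term = rownames(co),
        coefficient = unname(co[, "Estimate"]),
        standard_error = unname(co[, "Std. Error"]),
        p_value = unname(co[, "Pr(>|t|)"])
      ),
      adjusted_r_squared = sm$adj.r.squared,
      n_observations = length(fit$residuals),
      response = response,
      model = fit
    ),
    class = "conn_lm"
  )
}

signif_stars <- function(p) {
  dplyr::case_when(p < 0.01 ~ "***", p < 0.05 ~ "**", p < 0.1 ~ "*",
                   .default = "")
}

#' @export
print.conn_lm <- function(x, ...) {
  cat("Linear model: ", x$response, "\n", sep = "")
  w <- max(nchar(x$terms$term))
  for (i in seq_len(nrow(x$terms))) {
    cat(sprintf("  %-*s  % .5g%-3s  (SE %.5g)\n", w, x$terms$term[i],
                x$terms$coefficient[i], signif_stars(x$terms$p_value[i]),
                x$terms$standard_error[i]))
  }
  cat(sprintf("  Adjusted R-squared: %.2f   Observations: %d\n",
              x$adjusted_r_squared, x$n_observations))
  cat("  *p<0.1, **p<0.05, ***p<0.01\n")
  invisible(x)
}
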