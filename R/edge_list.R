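#' Pairwise edge lists
#'
#' An edge list is the package's sparse pairwise container: one row per place
#' pair carrying a non-negative value of a declared `kind`. Symmetric kinds
#' (`shared_users`, `pci`, `person_days`, `distance_miles`) store one row per
#' unordered pair with `place_i < place_j` under lexicographic id order;
#' `pci_directional` stores both directions. Zero-valued pairs are implicit:
#' they are simply absent, which keeps county-scale matrices sparse.
#'
#' @param place_i,place_j Character vectors of place ids.
#' @param value Numeric vector of non-negative values (`pci` additionally
#'   must not exceed 1).
#' @param kind One of `"shared_users"`, `"pci"`, `"pci_directional"`,
#'   `"person_days"`, `"distance_miles"`.
#' @return A tibble with columns `place_i`, `place_j`, `kind`, `value`,
#'   canonically ordered for symmetric kinds.
#' @examples
#' edge_list(c("b", "a"), c("a", "c"), c(0.2, 0.1), kind = "pci")
#' @export
edge_list <- function(place_i, place_j, value, kind) {
  kind <- match.arg(kind, edge_kinds())
  place_i <- as.character(place_i)
  place_j <- as.character(place_j)
  value <- as.double(value)
  stopifnot(length(place_i) == length(place_j), length(place_i) == length(value))
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("edge values must be finite and non-negative", call. = FALSE)
  }
  if (kind == "pci" && any(value > 1)) {
    stop("pci values must lie in [0, 1]", call. = FALSE)
  }
  if (kind != "pci_directional") {
    swap <- place_i > place_j
    tmp <- place_i[swap]
    place_i[swap] <- place_j[swap]
    place_j[swap] <- tmp
  }
  if (any(place_i == place_j)) {
    stop("self-pairs are not stored in edge lists", call. = FALSE)
  }
  out <- tibble::tibble(place_i = place_i, place_j = place_j,
                        kind = kind, value = value)
  if (anyDuplicated(paste(out$place_i, out$place_j))) {
    stop("duplicate place pair in edge list", call. = FALSE)
  }
  out
}

edge_kinds <- function() {
  c("shared_users", "pci", "pci_directional", "person_days", "distance_miles")
}

#' Write an edge list to CSV
#'
#' Serializes with 17 significant digits so that `read_edge_list()` round-trips
#' bit-exactly, including record order.
#'
#' @param edges An edge list tibble (see [edge_list()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(all(c("place_i", "place_j", "kind", "value") %in% names(edges)))
  lines <- c("place_i,place_j,kind,value",
             sprintf("%s,%s,%s,%.17g",
                     edges$place_i, edges$place_j, edges$kind, edges$value))
  writeLines(lines, path)
  invisible(path)
}

#' Read an edge list from CSV
#'
#' Validates the `kind` column against the known vocabulary and re-checks the
#' container invariants (non-negative values, `pci` within `[0, 1]`,
#' `place_i < place_j` for symmetric kinds).
#'
#' @param path CSV path written by [write_edge_list()] or matching its schema.
#' @return An edge list tibble.
#' @export
read_edge_list <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    place_i = readr::col_character(),
    place_j = readr::col_character(),
    kind = readr::col_character(),
    value = readr::col_double()
  ))
  if (nrow(raw) == 0) {
    return(tibble::tibble(place_i = character(), place_j = character(),
                          kind = character(), value = double()))
  }
  bad <- setdiff(unique(raw$kind), edge_kinds())
  if (length(bad) > 0) {
    stop("unknown edge kind: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(raw$value < 0)) stop("negative edge value on read", call. = FALSE)
  if (any(raw$kind == "pci" & raw$value > 1)) {
    stop("pci value above 1 on read", call. = FALSE)
  }
  sym <- raw$kind != "pci_directional"
  if (any(raw$place_i[sym] >= raw$place_j[sym])) {
    stop("symmetric edge rows must satisfy place_i < place_j", call. = FALSE)
  }
  raw
}
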