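#' Inverse-connectivity dissimilarity matrix
#'
#' For regionalization the "distance" between two places is the reciprocal
#' of their connectivity index: weakly connected pairs are far apart. Pairs
#' with no shared users (index 0, absent from the sparse edge list) receive
#' a finite sentinel of 10 times the largest finite dissimilarity so that
#' they merge last without breaking the arithmetic; the diagonal is 0.
#' Apply [filter_min_users()] first (default threshold 5) so thinly-observed
#' places do not distort the communities.
#'
#' @param pci_matrix A `pci_matrix`, normally already min-user filtered.
#' @return A symmetric base matrix of dissimilarities with place ids as
#'   dimnames.
#' @export
pci_to_distance <- function(pci_matrix) {
  stopifnot(inherits(pci_matrix, "pci_matrix"))
  ids <- sort(pci_matrix$place_summary$place_id)
  n <- length(ids)
  if (n < 2) stop("need at least 2 retained places", call. = FALSE)
  e <- pci_matrix$pci
  d <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  i <- match(e$place_i, ids)
  j <- match(e$place_j, ids)
  d[cbind(i, j)] <- 1 / e$value
  d[cbind(j, i)] <- 1 / e$value
  finite_max <- max(d[upper.tri(d)], na.rm = TRUE)
  sentinel <- 10 * finite_max
  d[is.na(d)] <- sentinel
  d
}

#' Agglomerative average-linkage regionalization
#'
#' Groups places into communities by unweighted average-linkage (UPGMA-style)
#' agglomeration of a dissimilarity matrix: starting from singleton
#' communities, the two closest communities are merged and the dissimilarity
#' of the merged community to every other is the mean over all cross-pair
#' dissimilarities (Lance-Williams size-weighted update). Merging stops when
#' the requested number of communities remains; several cut levels are
#' extracted from one merge sequence, so assignments at coarser `k` are
#' exact coarsenings of finer ones.
#'
#' Ties in the minimum linkage are broken deterministically: each community
#' is represented by its smallest member id, and the candidate pair whose
#' (smaller, larger) representative-id tuple is lexicographically least is
#' merged.
#'
#' @param dissimilarity Symmetric numeric matrix with place-id dimnames
#'   (e.g. from [pci_to_distance()]).
#' @param k_list Integer vector of community counts to cut at.
#' @return An object of class `region_clust`: list with `merges` (tibble
#'   `step`, `community_a`, `community_b`, `linkage_distance`, `new_size`)
#'   and `assignments` (tibble `place_id`, `k`, `label` with labels
#'   `0..k-1` ordered by each community's smallest member id).
#' @export
cluster_regions <- function(dissimilarity, k_list) {
  d <- as.matrix(dissimilarity)
  n <- nrow(d)
  ids <- rownames(d)
  stopifnot(!is.null(ids), all(ids == colnames(d)), isSymmetric(unname(d)))
  k_list <- sort(unique(as.integer(k_list)), decreasing = TRUE)
  if (any(k_list > n) || any(k_list < 1)) {
    stop("every k must lie in [1, number of places]", call. = FALSE)
  }
  ord <- order(ids)
  d <- d[ord, ord, drop = FALSE]
  ids <- ids[ord]

  active <- rep(TRUE, n)
  size <- rep(1L, n)
  members <- as.list(seq_len(n))   # indices into ids
  rep_id <- ids                    # smallest member id per community
  cur <- d
  diag(cur) <- Inf

  merges <- vector("list", n - 1)
  assignments <- vector("list", length(k_list))
  names(assignments) <- as.character(k_list)
  snapshot <- function(k) {
    act <- which(active)
    lab_order <- order(rep_id[act])
    out <- vector("list", length(act))
    for (li in seq_along(lab_order)) {
      comm <- act[lab_order[li]]
      out[[li]] <- tibble::tibble(place_id = ids[members[[comm]]],
                                  k = k, label = li - 1L)
    }
    dplyr::bind_rows(out)
  }
  if (n %in% k_list) assignments[[as.character(n)]] <- snapshot(n)

  for (step in seq_len(n - 1)) {
    act <- which(active)
    sub <- cur[act, act, drop = FALSE]
    m <- min(sub)
    hits <- which(sub == m, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # deterministic tie-break on representative-id tuples
    keys_a <- rep_id[act[hits[, 1]]]
    keys_b <- rep_id[act[hits[, 2]]]
    lo <- pmin(keys_a, keys_b)
    hi <- pmax(keys_a, keys_b)
    pick <- order(lo, hi)[1]
    a <- act[hits[pick, 1]]
    b <- act[hits[pick, 2]]

    merges[[step]] <- tibble::tibble(
      step = step,
      community_a = min(rep_id[a], rep_id[b]),
      community_b = max(rep_id[a], rep_id[b]),
      linkage_distance = m,
      new_size = size[a] + size[b]
    )
    # Lance-Williams average-linkage update into slot a
    others <- setdiff(act, c(a, b))
    cur[a, others] <- (size[a] * cur[a, others] + size[b] * cur[b, others]) /
      (size[a] + size[b])
    cur[others, a] <- cur[a, others]
    members[[a]] <- c(members[[a]], members[[b]])
    size[a] <- size[a] + size[b]
    rep_id[a] <- min(rep_id[a], rep_id[b])
    active[b] <- FALSE
    cur[b, ] <- Inf
    cur[, b] <- Inf

    k_now <- n - step
    if (k_now %in% k_list) assignments[[as.character(k_now)]] <- snapshot(k_now)
  }

  structure(
    list(merges = dplyr::bind_rows(merges),
         assignments = dplyr::bind_rows(assignments)),
    class = "region_clust"
  )
}

#' @export
print.region_clust <- function(x, ...) {
  ks <- sort(unique(x$assignments$k))
  cat("<region_clust> ", nrow(x$merges) + 1, " places, cuts at k = ",
      paste(ks, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract the community assignment at one cut level
#'
#' @param clust A `region_clust` from [cluster_regions()].
#' @param k Community count (must be one of the requested cuts).
#' @return Tibble (`place_id`, `label`).
#' @export
region_assignment <- function(clust, k) {
  sub <- clust$assignments[clust$assignments$k == k, ]
  if (nrow(sub) == 0) stop("no cut stored at k = ", k, call. = FALSE)
  dplyr::select(sub, "place_id", "label")
}
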