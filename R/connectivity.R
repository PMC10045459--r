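#' Pairwise patch distance matrix in kilometres
#'
#' @param patches An `mrr_patches` data frame.
#' @param mode `"centroid"` (geodesic distance between polygon centroids,
#'   the default) or `"edge"` (minimum boundary-to-boundary distance;
#'   overlapping or touching patches get 0 with a warning).
#' @return Symmetric matrix (km) with zero diagonal, dimnames = patch ids.
#' @export
pairwise_patch_distance_km <- function(patches, mode = c("centroid", "edge")) {
  mode <- match.arg(mode)
  n <- nrow(patches)
  if (n < 1L) stop("need at least one patch")
  D <- matrix(0, n, n, dimnames = list(patches$patch_id, patches$patch_id))
  if (n == 1L) return(D)
  if (mode == "centroid") {
    cen <- cbind(patches$centroid_lon, patches$centroid_lat)
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      d <- geodesic_distance_m(matrix(cen[i, ], length(j), 2, byrow = TRUE),
                               cen[j, , drop = FALSE]) / 1000
      D[i, j] <- d; D[j, i] <- d
    }
  } else {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- edge_distance_km(patches$ring[[i]], patches$ring[[j]])
      if (d == 0) warning("patches ", patches$patch_id[i], " and ",
                          patches$patch_id[j], " overlap; edge distance 0")
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

edge_distance_km <- function(ring_a, ring_b) {
  ring_a <- close_ring(ring_a); ring_b <- close_ring(ring_b)
  if (any(points_in_ring(ring_a, ring_b)) || any(points_in_ring(ring_b, ring_a)))
    return(0)
  da <- min(geosphere::dist2Line(ring_a, ring_b)[, "distance"])
  db <- min(geosphere::dist2Line(ring_b, ring_a)[, "distance"])
  min(da, db) / 1000
}

#' Connectivity parameters
#'
#' @param alpha Inverse of the average dispersal distance, in 1/km.
#' @param xi Area scaling exponent of immigration (default 0.5).
#' @param buffer_km Neighbourhood radius; patches beyond it contribute
#'   nothing (default 3 km).
#' @param distance_mode `"centroid"` or `"edge"`.
#' @return A list of class `connectivity_params`.
#' @export
connectivity_params <- function(alpha, xi = 0.5, buffer_km = 3,
                                distance_mode = c("centroid", "edge")) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (xi < 0 || xi > 1) stop("xi must lie in [0, 1]")
  if (buffer_km <= 0) stop("buffer_km must be > 0")
  structure(list(alpha = alpha, xi = xi, buffer_km = buffer_km,
                 distance_mode = match.arg(distance_mode)),
            class = "connectivity_params")
}

#' Patch connectivity index
#'
#' For each patch j, S_j = sum over neighbouring patches k (k != j, within
#' `buffer_km`) of exp(-alpha * d_jk) * A_k^xi, with d_jk in km and A_k the
#' patch area in m^2. Patches with no neighbour inside the buffer have
#' S_j = 0.
#'
#' @param patches An `mrr_patches` data frame.
#' @param params A [connectivity_params()] object.
#' @param dist_km Optional precomputed distance matrix (km); computed with
#'   `params$distance_mode` when omitted.
#' @return Data frame `patch_id`, `S_j`, `n_neighbours`.
#' @export
connectivity <- function(patches, params, dist_km = NULL) {
  if (is.null(dist_km))
    dist_km <- pairwise_patch_distance_km(patches, params$distance_mode)
  W <- exp(-params$alpha * dist_km) *
    matrix(patches$area_m2^params$xi, nrow(dist_km), ncol(dist_km), byrow = TRUE)
  keep <- dist_km <= params$buffer_km
  diag(keep) <- FALSE
  W[!keep] <- 0
  data.frame(patch_id = patches$patch_id,
             S_j = rowSums(W),
             n_neighbours = rowSums(keep),
             stringsAsFactors = FALSE)
}

#' Dispersal-ability parameter from observed movements
#'
#' alpha = 1 / (mean observed dispersal distance in km), the package default
#' when no alpha is supplied.
#'
#' @param movements Data frame from [classify_movements()].
#' @return alpha in 1/km.
#' @export
alpha_from_movements <- function(movements) {
  d <- movements$distance_m[movements$kind == "dispersal"]
  if (!length(d)) stop("no dispersal events; cannot derive alpha")
  1 / (mean(d) / 1000)
}
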