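#' Gray-level zone-size matrix of a quantized VOI
#'
#' Zones are maximal 3D connected components of equal gray level inside the
#' VOI, using 26-connectivity. Unlike GLCM/GLRLM the zone matrix has no
#' direction. Connected components are found on a voxel-adjacency graph
#' (same-level 26-neighbors) with igraph.
#'
#' @param q A `quantized_voi`.
#' @return Object of class `zs_matrix`: list with `Z` (G x Smax count
#'   matrix), `n_zones`, `n_voxels`, `zones` (tibble level/size per zone).
#' @export
glzsm <- function(q) {
  stopifnot(inherits(q, "quantized_voi"))
  L <- q$levels
  L[is.na(L)] <- 0L
  dims <- dim(L)
  n <- prod(dims)
  ids <- which(q$mask)  # linear indices of VOI voxels
  # the 13 lexicographically-positive offsets of the 26-neighborhood
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[offs$dk > 0 | (offs$dk == 0 & (offs$dj > 0 |
            (offs$dj == 0 & offs$di > 0))), ]
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    di <- offs$di[r]; dj <- offs$dj[r]; dk <- offs$dk[r]
    i_rng <- seq.int(max(1L, 1L - di), min(dims[1], dims[1] - di))
    j_rng <- seq.int(max(1L, 1L - dj), min(dims[2], dims[2] - dj))
    k_rng <- seq.int(max(1L, 1L - dk), min(dims[3], dims[3] - dk))
    A <- L[i_rng, j_rng, k_rng, drop = FALSE]
    B <- L[i_rng + di, j_rng + dj, k_rng + dk, drop = FALSE]
    ok <- A > 0L & A == B
    if (!any(ok)) next
    # linear index of the source voxel of each matching pair
    src <- array(FALSE, dims)
    src[i_rng, j_rng, k_rng] <- ok
    from <- which(src)
    to <- from + di + dj * dims[1] + dk * dims[1] * dims[2]
    edges[[r]] <- cbind(from, to)
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  if (!is.null(el) && nrow(el) > 0) {
    # remap linear voxel indices to 1..n_voxels vertex ids
    vid <- integer(n)
    vid[ids] <- seq_along(ids)
    g <- igraph::add_edges(g, t(cbind(vid[el[, 1]], vid[el[, 2]])))
  }
  comp <- igraph::components(g)
  lev_vox <- L[ids]
  zone_level <- tapply(lev_vox, comp$membership, function(v) v[1])
  zone_size <- as.integer(comp$csize)
  G <- q$G
  Smax <- max(zone_size)
  Z <- matrix(0, G, Smax)
  tab <- tabulate((as.integer(zone_level) - 1L) * Smax + zone_size,
                  nbins = G * Smax)
  Z <- matrix(tab, G, Smax, byrow = TRUE)
  structure(list(Z = Z, n_zones = comp$no, n_voxels = length(ids),
                 zones = tibble::tibble(level = as.integer(zone_level),
                                        size = zone_size)),
            class = "zs_matrix")
}

#' GLZSM texture features
#'
#' Four zone features normalized by the number of zones: high/low intensity
#' (gray-level) emphasis and their large-area counterparts. High-intensity
#' emphasis (HIE) weights zones by squared gray level; high-intensity large
#' area emphasis (HILAE) additionally weights by squared zone size.
#'
#' @param m A `zs_matrix` from [glzsm()].
#' @return Named numeric vector of length 4, in registry order.
#' @export
glzsm_features <- function(m) {
  stopifnot(inherits(m, "zs_matrix"))
  Z <- m$Z
  Nz <- m$n_zones
  G <- nrow(Z); Smax <- ncol(Z)
  g2 <- matrix(seq_len(G)^2, G, Smax)
  s2 <- matrix(seq_len(Smax)^2, G, Smax, byrow = TRUE)
  c(high_intensity_emphasis = sum(Z * g2) / Nz,
    high_intensity_large_area_emphasis = sum(Z * g2 * s2) / Nz,
    low_intensity_emphasis = sum(Z / g2) / Nz,
    low_intensity_large_area_emphasis = sum(Z * s2 / g2) / Nz)
}
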