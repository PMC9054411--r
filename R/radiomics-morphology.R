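#' Morphological features of a VOI
#'
#' Seven shape/size features of the tumor mask in physical units:
#' \describe{
#'   \item{volume}{voxel count times voxel volume, mm^3.}
#'   \item{surface_area}{total area of exposed voxel faces (faces between a
#'     mask voxel and background or the grid boundary), mm^2.}
#'   \item{density}{mean in-mask raw intensity.}
#'   \item{maximum_diameter}{largest pairwise distance between surface-voxel
#'     centers, mm.}
#'   \item{sphericity}{\eqn{\pi^{1/3} (6V)^{2/3} / A}; 1 for a perfect
#'     sphere, smaller for irregular shapes.}
#'   \item{compactness}{\eqn{V / (\sqrt{\pi} A^{3/2})}, dimensionless.}
#'   \item{surface_to_volume_ratio}{\eqn{A / V}, 1/mm.}
#' }
#'
#' @param mask A [voi_mask] (or 3D array) with at least one foreground voxel.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param raw_intensities In-mask raw intensities (mask order), used for
#'   `density`.
#' @return Named numeric vector of length 7, in registry order.
#' @export
morphology_features <- function(mask, spacing = c(1, 1, 1), raw_intensities) {
  if (!inherits(mask, "voi_mask")) mask <- voi_mask(mask)
  if (!any(mask)) stop("empty mask: VOI has no foreground voxel", call. = FALSE)
  spacing <- as.numeric(spacing)
  dims <- dim(mask)
  n <- sum(mask)
  vol <- n * prod(spacing)

  # exposed faces per axis: pad with background so grid-boundary faces count
  face_area <- c(spacing[2] * spacing[3],
                 spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  exposed <- numeric(3)
  m <- array(mask, dims)
  for (ax in 1:3) {
    pd <- dims; pd[ax] <- pd[ax] + 2L
    pad <- array(FALSE, pd)
    idx <- lapply(seq_len(3), function(a) seq_len(dims[a]) +
                    (if (a == ax) 1L else 0L))
    pad[idx[[1]], idx[[2]], idx[[3]]] <- m
    # neighbor comparison along the axis
    take <- function(shift) {
      r <- lapply(seq_len(3), function(a) {
        if (a == ax) seq_len(pd[a] - 1L) + shift else seq_len(pd[a])
      })
      pad[r[[1]], r[[2]], r[[3]], drop = FALSE]
    }
    a1 <- take(0L); a2 <- take(1L)
    exposed[ax] <- sum(a1 != a2)  # each TRUE/FALSE boundary is one face
  }
  area <- sum(exposed * face_area)

  surf <- surface_voxels(m)
  coords <- which(surf, arr.ind = TRUE)
  xyz <- sweep(coords - 1, 2, spacing, `*`)
  dmax <- max_pairwise_distance(xyz)

  c(volume = vol,
    surface_area = area,
    density = mean(raw_intensities),
    maximum_diameter = dmax,
    sphericity = pi^(1 / 3) * (6 * vol)^(2 / 3) / area,
    compactness = vol / (sqrt(pi) * area^1.5),
    surface_to_volume_ratio = area / vol)
}

# mask voxels with at least one of the 6 face neighbors outside the mask or
# outside the grid
surface_voxels <- function(m) {
  dims <- dim(m)
  interior <- array(TRUE, dims)
  shifts <- list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                 c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  for (s in shifts) {
    nb <- array(FALSE, dims)
    src <- lapply(1:3, function(a) {
      r <- seq_len(dims[a])
      r[r + s[a] >= 1L & r + s[a] <= dims[a]]
    })
    dst <- lapply(1:3, function(a) src[[a]] + s[a])
    nb[src[[1]], src[[2]], src[[3]]] <- m[dst[[1]], dst[[2]], dst[[3]]]
    interior <- interior & nb
  }
  m & !interior
}

# exact max pairwise Euclidean distance, chunked to bound memory
max_pairwise_distance <- function(xyz) {
  np <- nrow(xyz)
  if (np < 2) return(0)
  best <- 0
  chunk <- 512L
  sq <- rowSums(xyz^2)
  for (s in seq(1L, np, by = chunk)) {
    e <- min(np, s + chunk - 1L)
    d2 <- outer(sq[s:e], sq, `+`) - 2 * tcrossprod(xyz[s:e, , drop = FALSE],
                                                   xyz)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}
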