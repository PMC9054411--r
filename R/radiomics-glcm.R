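# In-plane (axial-slice) offset for a GLCM/GLRLM direction in degrees.
# Array axes: [i, j, k] with (i, j) the axial plane, k the slice index.
direction_offset <- function(direction, distance = 1L) {
  d <- as.integer(distance)
  if (d < 1L) stop("`distance` must be a positive integer", call. = FALSE)
  switch(as.character(direction),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("direction must be one of 0, 45, 90, 135", call. = FALSE))
}

#' Gray-level co-occurrence matrix of a quantized VOI
#'
#' Counts pairs of gray levels separated by the given in-plane offset.
#' Pairs are enumerated per axial slice and accumulated over all slices
#' before normalization (2.5D convention matching the four in-plane angles
#' 0/45/90/135 degrees); both orders of each pair are counted, so the
#' matrix is symmetric. Voxels outside the VOI never contribute.
#'
#' @param q A `quantized_voi`.
#' @param direction Angle in degrees: 0, 45, 90 or 135.
#' @param distance Offset length in voxels (default 1).
#' @return Object of class `glc_matrix`: list with `P` (G x G matrix,
#'   normalized to sum 1 when any pair exists, all zero otherwise),
#'   `counts`, `n_pairs`, `direction`, `distance`.
#' @export
glcm <- function(q, direction = 0, distance = 1L) {
  stopifnot(inherits(q, "quantized_voi"))
  off <- direction_offset(direction, distance)
  L <- q$levels
  L[is.na(L)] <- 0L
  dims <- dim(L)
  di <- off[1]; dj <- off[2]
  i_rng <- seq.int(max(1L, 1L - di), min(dims[1], dims[1] - di))
  j_rng <- seq.int(max(1L, 1L - dj), min(dims[2], dims[2] - dj))
  G <- q$G
  counts <- matrix(0, G, G)
  if (length(i_rng) > 0 && length(j_rng) > 0) {
    A <- L[i_rng, j_rng, , drop = FALSE]
    B <- L[i_rng + di, j_rng + dj, , drop = FALSE]
    ok <- A > 0L & B > 0L
    if (any(ok)) {
      idx <- (A[ok] - 1L) * G + B[ok]
      tab <- tabulate(idx, nbins = G * G)
      counts <- matrix(tab, G, G, byrow = TRUE)
    }
  }
  sym <- counts + t(counts)
  n_pairs <- sum(counts)
  P <- if (n_pairs > 0) sym / sum(sym) else sym
  structure(list(P = P, counts = sym, n_pairs = n_pairs,
                 direction = direction, distance = distance),
            class = "glc_matrix")
}

#' GLCM texture features
#'
#' Nine features of a normalized co-occurrence matrix: energy (angular
#' second moment), contrast, correlation, entropy (log2), homogeneity
#' (inverse difference moment), dissimilarity, sum entropy, cluster shade
#' and cluster prominence. When the matrix holds no pair (degenerate VOI or
#' direction) the degenerate-limit values of a one-state distribution are
#' returned; a zero-variance marginal gives correlation 1 by convention.
#'
#' @param m A `glc_matrix` from [glcm()].
#' @return Named numeric vector of length 9, in registry order.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "glc_matrix"))
  P <- m$P
  G <- nrow(P)
  if (m$n_pairs == 0 || sum(P) == 0) {
    return(c(energy = 1, contrast = 0, correlation = 1, entropy = 0,
             homogeneity = 1, dissimilarity = 0, sum_entropy = 0,
             cluster_shade = 0, cluster_prominence = 0))
  }
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  px <- rowSums(P)
  mu_x <- sum(seq_len(G) * px)      # symmetric: mu_x == mu_y
  sd_x <- sqrt(sum((seq_len(G) - mu_x)^2 * px))
  dif <- i - j
  pp <- P[P > 0]
  # distribution of i + j for sum entropy
  psum <- vapply(2:(2 * G), function(k) sum(P[i + j == k]), numeric(1))
  psum <- psum[psum > 0]
  corr <- if (sd_x > 0) sum((i - mu_x) * (j - mu_x) * P) / sd_x^2 else 1
  c(energy = sum(P^2),
    contrast = sum(dif^2 * P),
    correlation = corr,
    entropy = -sum(pp * log2(pp)),
    homogeneity = sum(P / (1 + dif^2)),
    dissimilarity = sum(abs(dif) * P),
    sum_entropy = -sum(psum * log2(psum)),
    cluster_shade = sum((i + j - 2 * mu_x)^3 * P),
    cluster_prominence = sum((i + j - 2 * mu_x)^4 * P))
}
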