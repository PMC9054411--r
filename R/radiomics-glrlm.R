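# Extract the level sequences ("lines") of one axial slice along a GLRLM
# direction. Out-of-mask voxels carry level 0 and break runs.
slice_lines <- function(M, direction) {
  switch(as.character(direction),
    "0"   = lapply(seq_len(nrow(M)), function(i) M[i, ]),
    "90"  = lapply(seq_len(ncol(M)), function(j) M[, j]),
    "45"  = split(M, row(M) + col(M)),   # anti-diagonals
    "135" = split(M, row(M) - col(M)),   # main diagonals
    stop("direction must be one of 0, 45, 90, 135", call. = FALSE))
}

#' Gray-level run-length matrix of a quantized VOI
#'
#' Counts maximal runs of equal gray level along straight lines of one
#' in-plane direction, per axial slice, accumulated over slices. A run is
#' broken by the slice edge and by out-of-mask voxels, so every in-mask
#' voxel belongs to exactly one run per direction.
#'
#' @param q A `quantized_voi`.
#' @param direction Angle in degrees: 0, 45, 90 or 135.
#' @return Object of class `rl_matrix`: list with `R` (G x Lmax count
#'   matrix), `n_runs`, `n_voxels`, `direction`.
#' @export
glrlm <- function(q, direction = 0) {
  stopifnot(inherits(q, "quantized_voi"))
  L <- q$levels
  L[is.na(L)] <- 0L
  dims <- dim(L)
  # concatenate all lines of all slices with a 0 separator: a single rle
  # then yields every maximal run; level-0 runs (mask gaps, separators)
  # are discarded.
  seqs <- unlist(lapply(seq_len(dims[3]), function(k) {
    M <- L[, , k, drop = FALSE]
    dim(M) <- dims[1:2]
    lines <- slice_lines(M, direction)
    unlist(lapply(lines, function(v) c(v, 0L)), use.names = FALSE)
  }), use.names = FALSE)
  r <- rle(seqs)
  keep <- r$values > 0L
  lev <- r$values[keep]
  len <- r$lengths[keep]
  G <- q$G
  Lmax <- if (length(len)) max(len) else 1L
  R <- matrix(0, G, Lmax)
  if (length(len)) {
    tab <- tabulate((lev - 1L) * Lmax + len, nbins = G * Lmax)
    R <- matrix(tab, G, Lmax, byrow = TRUE)
  }
  structure(list(R = R, n_runs = sum(R), n_voxels = sum(q$mask),
                 direction = direction),
            class = "rl_matrix")
}

#' GLRLM texture features
#'
#' The eleven classical run-length features, normalized by the number of
#' runs: short/long run emphasis, gray-level and run-length non-uniformity
#' (the latter is the "run inhomogeneity" of the multiphase analysis), run
#' percentage, low/high gray-level run emphasis and the four joint
#' short/long x low/high emphases.
#'
#' @param m An `rl_matrix` from [glrlm()].
#' @return Named numeric vector of length 11, in registry order.
#' @export
glrlm_features <- function(m) {
  stopifnot(inherits(m, "rl_matrix"))
  R <- m$R
  Nr <- m$n_runs
  if (Nr == 0) {
    # unreachable for a nonempty mask (every voxel lies in some run);
    # defined for completeness
    z <- feature_registry("glrlm")
    return(stats::setNames(rep(0, length(z)), z))
  }
  G <- nrow(R); Lmax <- ncol(R)
  g <- seq_len(G); l <- seq_len(Lmax)
  gl2 <- matrix(g^2, G, Lmax)        # g^2 by row
  rl2 <- matrix(l^2, G, Lmax, byrow = TRUE)
  rg <- rowSums(R)  # per-level run counts
  rl <- colSums(R)  # per-length run counts
  c(short_run_emphasis = sum(R / rl2) / Nr,
    long_run_emphasis = sum(R * rl2) / Nr,
    gray_level_nonuniformity = sum(rg^2) / Nr,
    run_length_nonuniformity = sum(rl^2) / Nr,
    run_percentage = Nr / m$n_voxels,
    low_gray_run_emphasis = sum(R / gl2) / Nr,
    high_gray_run_emphasis = sum(R * gl2) / Nr,
    short_run_low_gray_emphasis = sum(R / (gl2 * rl2)) / Nr,
    short_run_high_gray_emphasis = sum(R * gl2 / rl2) / Nr,
    long_run_low_gray_emphasis = sum(R * rl2 / gl2) / Nr,
    long_run_high_gray_emphasis = sum(R * gl2 * rl2) / Nr)
}
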