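#' Per-phase feature block: 12 + 24 + 7 = 43 features
#'
#' Extracts the full feature block of one contrast phase: 12 first-order
#' features, 24 texture features averaged over the four in-plane directions
#' (0/45/90/135 degrees; 24 x 4 = 96 directional evaluations feed the
#' average), and 7 morphological features. The zone-size matrix has no
#' direction; its 4 features are computed once and replicated across the
#' four directions, so averaging leaves them unchanged while the 96-count
#' accounting holds.
#'
#' @param stack A [voi_stack].
#' @param phase_id One of [tace_phases].
#' @param G Gray levels for quantization (default 64).
#' @param distance GLCM offset in voxels (default 1).
#' @return One-row tibble with `phase_id` and the 43 registry features, in
#'   registry order. The pre-averaging 24 x 4 directional values are
#'   attached as attribute `"directional"` (matrix, feature x direction).
#' @export
phase_block <- function(stack, phase_id, G = 64L, distance = 1L) {
  stopifnot(inherits(stack, "voi_stack"))
  phase_id <- match.arg(phase_id, tace_phases)
  vol <- stack$volumes[[phase_id]]
  q <- tryCatch(
    quantize(vol, stack$mask, G = G),
    error = function(e) stop("phase ", phase_id, " (case ", stack$case_id,
                             "): ", conditionMessage(e), call. = FALSE))
  fo <- first_order_features(q)

  zf <- glzsm_features(glzsm(q))
  dir_vals <- vapply(tace_directions, function(d) {
    gf <- glcm_features(glcm(q, d, distance))
    rf <- glrlm_features(glrlm(q, d))
    c(stats::setNames(gf, paste0("glcm_", names(gf))),
      stats::setNames(rf, paste0("glrlm_", names(rf))),
      stats::setNames(zf, paste0("glzsm_", names(zf))))
  }, numeric(24))
  colnames(dir_vals) <- paste0("deg", tace_directions)
  texture <- rowMeans(dir_vals)

  morph <- morphology_features(stack$mask, vol$spacing, q$raw)

  vals <- c(fo, texture[feature_registry("texture")], morph)
  stopifnot(identical(names(vals), feature_registry("block")))
  out <- tibble::as_tibble(as.list(vals))
  out <- tibble::add_column(out, phase_id = phase_id, .before = 1)
  attr(out, "directional") <- dir_vals
  out
}

#' Extract per-phase features for every case of a cohort
#'
#' Runs [phase_block()] on all four phases of every case, returning a tidy
#' per-phase feature table (one row per case x phase).
#'
#' @param cohort A `rad_cohort` from [generate_cohort()], or a list of
#'   [voi_stack]s.
#' @param G,distance Passed to [phase_block()].
#' @return Tibble with columns `case_id`, `recist`, `phase_id` and the 43
#'   block features.
#' @export
extract_features <- function(cohort, G = 64L, distance = 1L) {
  stacks <- if (inherits(cohort, "rad_cohort")) cohort$cases else cohort
  purrr::map_dfr(stacks, function(st) {
    purrr::map_dfr(tace_phases, function(p) {
      blk <- phase_block(st, p, G = G, distance = distance)
      tibble::add_column(blk, case_id = st$case_id, recist = st$recist,
                         .before = 1)
    })
  })
}
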