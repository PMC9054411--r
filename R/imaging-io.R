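#' Construct a single-phase image volume
#'
#' A `phase_volume` couples a 3D intensity grid with its voxel spacing and a
#' contrast-phase identifier. Intensities are HU-like arbitrary units.
#'
#' @param voxels 3D numeric array of intensities.
#' @param spacing Numeric length-3, mm per voxel along each axis; all
#'   strictly positive.
#' @param phase_id One of [tace_phases].
#' @return An object of class `phase_volume`.
#' @export
phase_volume <- function(voxels, spacing = c(1, 1, 1), phase_id) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array", call. = FALSE)
  }
  if (any(dim(voxels) < 1L)) {
    stop("grid dimensions must be >= 1 along each axis", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive numbers (mm)", call. = FALSE)
  }
  phase_id <- match.arg(phase_id, tace_phases)
  structure(list(voxels = voxels, spacing = spacing, phase_id = phase_id),
            class = "phase_volume")
}

#' Construct a binary volume-of-interest mask
#'
#' Any nonzero voxel is foreground. The mask must match the shape of the
#' volumes it is paired with; it is consumed as given, with no morphological
#' cleanup.
#'
#' @param mask 3D array; nonzero means inside the VOI.
#' @return Logical 3D array of class `voi_mask`.
#' @export
voi_mask <- function(mask) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array", call. = FALSE)
  m <- array(mask != 0, dim = dim(mask))
  structure(m, class = c("voi_mask", "array"))
}

#' Bundle four aligned phase volumes, a VOI mask and a RECIST label
#'
#' @param volumes Named list of four [phase_volume]s keyed by phase id; all
#'   shapes must match the mask.
#' @param mask A [voi_mask] (or 3D array coerced to one).
#' @param recist RECIST category, one of `"CR"`, `"PR"`, `"SD"`, `"PD"`, or
#'   `NA` when unknown.
#' @param case_id Character scalar.
#' @return Object of class `voi_stack`.
#' @export
voi_stack <- function(volumes, mask, recist = NA_character_,
                      case_id = "case") {
  if (!inherits(mask, "voi_mask")) mask <- voi_mask(mask)
  missing <- setdiff(tace_phases, names(volumes))
  if (length(missing) > 0) {
    stop("missing phase(s): ", paste(missing, collapse = ", "),
         "; required phase ids are ", paste(tace_phases, collapse = ", "),
         call. = FALSE)
  }
  volumes <- volumes[tace_phases]
  shp <- dim(mask)
  for (p in tace_phases) {
    v <- volumes[[p]]
    if (!inherits(v, "phase_volume")) {
      stop("volume for phase ", p, " is not a `phase_volume`", call. = FALSE)
    }
    if (!identical(dim(v$voxels), shp)) {
      stop("shape mismatch between mask [", paste(shp, collapse = "x"),
           "] and phase ", p, " volume [",
           paste(dim(v$voxels), collapse = "x"), "]", call. = FALSE)
    }
  }
  if (!is.na(recist)) recist <- match.arg(recist, c("CR", "PR", "SD", "PD"))
  structure(list(volumes = volumes, mask = mask, recist = recist,
                 case_id = case_id),
            class = "voi_stack")
}

#' @export
print.voi_stack <- function(x, ...) {
  cat("<voi_stack> case", x$case_id, "| grid",
      paste(dim(x$mask), collapse = "x"), "|", sum(x$mask),
      "VOI voxels | RECIST", x$recist, "\n")
  invisible(x)
}

#' Read one case from NIfTI files
#'
#' Loads the four phase volumes and the binary mask of a case from disk and
#' validates their alignment. Voxel spacing is taken from the NIfTI header
#' (`pixdim`).
#'
#' @param volume_paths Named character vector of NIfTI paths, names drawn
#'   from [tace_phases]; all four phases required.
#' @param mask_path NIfTI path of the mask volume (nonzero = foreground).
#' @param recist,case_id Passed through to [voi_stack()].
#' @return A [voi_stack].
#' @export
load_case <- function(volume_paths, mask_path, recist = NA_character_,
                      case_id = "case") {
  missing <- setdiff(tace_phases, names(volume_paths))
  if (length(missing) > 0) {
    stop("missing phase(s): ", paste(missing, collapse = ", "),
         "; required phase ids are ", paste(tace_phases, collapse = ", "),
         call. = FALSE)
  }
  for (f in c(volume_paths, mask_path)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  mask_img <- RNifti::readNifti(mask_path)
  mask <- voi_mask(array(as.numeric(mask_img), dim = dim(mask_img)))
  vols <- lapply(tace_phases, function(p) {
    img <- RNifti::readNifti(volume_paths[[p]])
    phase_volume(array(as.numeric(img), dim = dim(img)),
                 spacing = RNifti::pixdim(img)[1:3], phase_id = p)
  })
  names(vols) <- tace_phases
  voi_stack(vols, mask, recist = recist, case_id = case_id)
}

#' Write one case to NIfTI files
#'
#' Inverse of [load_case()]; file names are `<case_id>_<phase>.nii.gz` and
#' `<case_id>_mask.nii.gz` under `dir`.
#'
#' @param stack A [voi_stack].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list with `volume_paths` and `mask_path`.
#' @export
write_case <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vpaths <- vapply(tace_phases, function(p) {
    f <- file.path(dir, paste0(stack$case_id, "_", p, ".nii.gz"))
    v <- stack$volumes[[p]]
    img <- RNifti::asNifti(v$voxels)
    RNifti::pixdim(img) <- v$spacing
    RNifti::writeNifti(img, f)
    f
  }, character(1))
  mpath <- file.path(dir, paste0(stack$case_id, "_mask.nii.gz"))
  mimg <- RNifti::asNifti(array(as.integer(stack$mask),
                                dim = dim(stack$mask)))
  RNifti::pixdim(mimg) <- stack$volumes[[1]]$spacing
  RNifti::writeNifti(mimg, mpath)
  invisible(list(volume_paths = vpaths, mask_path = mpath))
}

#' Quantize in-mask intensities to G gray levels
#'
#' Equal-width bins over the in-mask intensity range `[min, max]`, the
#' standard fixed-bin-count radiomics discretization that all texture-matrix
#' features are computed from. A constant (zero-range) region maps entirely
#' to level 1 so that downstream features stay defined (entropy 0, energy 1).
#'
#' @param volume A [phase_volume] (or bare 3D array).
#' @param mask A [voi_mask] with at least one foreground voxel.
#' @param G Number of gray levels, integer >= 2. Default 64.
#' @return Object of class `quantized_voi` with fields `levels` (3D integer
#'   array, `NA` outside the mask, values in `1..G`), `G`, `bin_edges`,
#'   `mask`, `raw` (in-mask raw intensities, mask order) and `spacing`.
#' @export
quantize <- function(volume, mask, G = 64L) {
  if (inherits(volume, "phase_volume")) {
    vox <- volume$voxels
    spacing <- volume$spacing
  } else {
    vox <- as.array(volume)
    spacing <- c(1, 1, 1)
  }
  if (!inherits(mask, "voi_mask")) mask <- voi_mask(mask)
  if (!identical(dim(vox), dim(mask))) {
    stop("mask shape does not match volume shape", call. = FALSE)
  }
  if (!any(mask)) stop("empty mask: VOI has no foreground voxel", call. = FALSE)
  G <- as.integer(G)
  if (is.na(G) || G < 2L) stop("`G` must be an integer >= 2", call. = FALSE)

  raw <- vox[mask]
  if (any(!is.finite(raw))) stop("non-finite intensities inside VOI",
                                 call. = FALSE)
  lo <- min(raw); hi <- max(raw)
  levels <- array(NA_integer_, dim = dim(vox))
  if (hi == lo) {
    # zero-range convention: whole VOI at level 1
    levels[mask] <- 1L
    edges <- c(lo, lo + 1)
  } else {
    edges <- seq(lo, hi, length.out = G + 1L)
    lv <- findInterval(raw, edges, rightmost.closed = TRUE)
    lv[lv > G] <- G  # guard against floating rounding at the top edge
    levels[mask] <- as.integer(lv)
  }
  structure(list(levels = levels, G = G, bin_edges = edges, mask = mask,
                 raw = raw, spacing = spacing),
            class = "quantized_voi")
}
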