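#' Configuration of the synthetic multiphase tumor-phantom cohort
#'
#' The generator emulates a balanced two-class TACE-response cohort of
#' four-phase contrast-enhanced tumor volumes. Each case is an ellipsoidal
#' VOI on a cubic grid; in-mask intensity is a phase- and class-dependent
#' mean plus spatially correlated Gaussian texture (Gaussian-filtered white
#' noise). The two classes differ in three planted properties:
#' \itemize{
#'   \item enhancement dynamics: responders (ease) show strong arterial
#'     enhancement followed by washout, non-responders (relief) a flat
#'     profile — this drives the change-rate (delta) features;
#'   \item heterogeneity: the relief class has a larger noise amplitude
#'     (`sigma_mult`), raising variance/entropy-type features;
#'   \item texture grain: the classes have different spatial correlation
#'     lengths, separating co-occurrence, run-length and zone features.
#' }
#'
#' @param n_per_class Cases per class. Default 24 (a balanced 24 vs 24
#'   cohort).
#' @param grid Cubic grid side in voxels. Default 48.
#' @param spacing Voxel spacing, mm. Default c(1, 1, 1).
#' @param radius_range Ellipsoid semi-axis range, mm. Default c(8, 16).
#' @param mu Named list of per-phase mean intensity profiles (length-4
#'   numeric) for `ease` and `relief`.
#' @param sigma Base texture noise SD (HU-like). Default 12.
#' @param intensity_scale_sd SD of the per-case log-normal intensity gain,
#'   emulating scanner/injection gain variability; one factor per case,
#'   shared by all four phases, so change-rate features are unaffected
#'   while absolute per-phase intensities jitter. Default 0.1.
#' @param sigma_mult Class noise multipliers. Default ease 1, relief 2.
#' @param corr_length Class spatial correlation lengths of the texture, in
#'   voxels (SD of the Gaussian filter). Default ease 2, relief 1.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return List of class `phantom_config`.
#' @export
phantom_config <- function(n_per_class = 24L, grid = 48L,
                           spacing = c(1, 1, 1),
                           radius_range = c(8, 16),
                           mu = list(ease = c(110, 160, 135, 95),
                                     relief = c(110, 125, 120, 112)),
                           sigma = 12,
                           sigma_mult = c(ease = 1, relief = 2),
                           corr_length = c(ease = 2, relief = 1),
                           intensity_scale_sd = 0.1,
                           seed = 1L) {
  if (n_per_class < 2) stop("need at least 2 cases per class", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  grid <- as.integer(grid)
  # a radius_range[2] ellipsoid with center jitter of 1/8 grid must fit
  max_extent <- 2 * radius_range[2] / min(spacing) + grid / 4
  if (max_extent > grid) {
    stop("tumor radius range does not fit inside the grid", call. = FALSE)
  }
  structure(list(n_per_class = as.integer(n_per_class), grid = grid,
                 spacing = as.numeric(spacing),
                 radius_range = radius_range, mu = mu, sigma = sigma,
                 sigma_mult = sigma_mult, corr_length = corr_length,
                 intensity_scale_sd = intensity_scale_sd,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# separable Gaussian smoothing of a 3D array via banded-matrix products
smooth_gaussian_3d <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  dims <- dim(arr)
  band <- function(n) {
    r <- ceiling(3 * sigma_vox)
    i <- matrix(seq_len(n), n, n)
    d <- abs(i - t(i))
    B <- exp(-d^2 / (2 * sigma_vox^2)) * (d <= r)
    B / rowSums(B)
  }
  # axis 1
  out <- band(dims[1]) %*% matrix(arr, dims[1], dims[2] * dims[3])
  out <- array(out, dims)
  # axis 2
  p <- aperm(out, c(2, 1, 3))
  p <- array(band(dims[2]) %*% matrix(p, dims[2], dims[1] * dims[3]),
             dim(p))
  out <- aperm(p, c(2, 1, 3))
  # axis 3
  p <- aperm(out, c(3, 1, 2))
  p <- array(band(dims[3]) %*% matrix(p, dims[3], dims[1] * dims[2]),
             dim(p))
  aperm(p, c(2, 3, 1))
}

# one standardized correlated-noise field
texture_field <- function(dims, corr_length) {
  f <- smooth_gaussian_3d(array(stats::rnorm(prod(dims)), dims), corr_length)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic multiphase phantom cohort
#'
#' See [phantom_config()] for what the phantoms emulate. RECIST labels are
#' drawn consistently with class: responders get CR or PR, non-responders
#' SD or PD. The same seed always yields a bit-identical cohort.
#'
#' @param config A [phantom_config()].
#' @return Object of class `rad_cohort`: `cases` (list of [voi_stack]),
#'   `manifest` (tibble: case_id, recist, group), `truth` (tibble of the
#'   generating parameters per case) and `config`.
#' @export
generate_cohort <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  dims <- rep(config$grid, 3)
  classes <- rep(c("ease", "relief"), each = config$n_per_class)
  n <- length(classes)
  case_ids <- sprintf("case%03d", seq_len(n))
  cases <- vector("list", n)
  truth <- vector("list", n)
  for (ci in seq_len(n)) {
    cl <- classes[ci]
    radii <- stats::runif(3, config$radius_range[1], config$radius_range[2])
    center <- dims / 2 + stats::runif(3, -config$grid / 8, config$grid / 8)
    mask <- ellipsoid_mask(dims, center, radii, config$spacing)
    recist <- if (cl == "ease") {
      sample(c("CR", "PR"), 1, prob = c(0.3, 0.7))
    } else {
      sample(c("SD", "PD"), 1, prob = c(0.6, 0.4))
    }
    sdev <- config$sigma * config$sigma_mult[[cl]]
    gain <- exp(stats::rnorm(1, 0, config$intensity_scale_sd))
    vols <- lapply(seq_along(tace_phases), function(p) {
      field <- texture_field(dims, config$corr_length[[cl]])
      phase_volume(gain * (config$mu[[cl]][p] + sdev * field),
                   spacing = config$spacing, phase_id = tace_phases[p])
    })
    names(vols) <- tace_phases
    cases[[ci]] <- voi_stack(vols, mask, recist = recist,
                             case_id = case_ids[ci])
    truth[[ci]] <- tibble::tibble(case_id = case_ids[ci], class = cl,
                                  recist = recist,
                                  radius_x = radii[1], radius_y = radii[2],
                                  radius_z = radii[3], sigma = sdev,
                                  corr_length = config$corr_length[[cl]])
  }
  manifest <- tibble::tibble(case_id = case_ids,
                             recist = vapply(cases, function(s) s$recist,
                                             character(1)),
                             group = map_recist(vapply(cases,
                                                       function(s) s$recist,
                                                       character(1))))
  structure(list(cases = cases, manifest = manifest,
                 truth = dplyr::bind_rows(truth), config = config),
            class = "rad_cohort")
}

ellipsoid_mask <- function(dims, center, radii_mm, spacing) {
  co <- lapply(1:3, function(a) ((seq_len(dims[a]) - center[a]) *
                                   spacing[a] / radii_mm[a])^2)
  d2 <- outer(outer(co[[1]], co[[2]], `+`), co[[3]], `+`)
  voi_mask(array(d2 <= 1, dims))
}

#' @export
print.rad_cohort <- function(x, ...) {
  cat("<rad_cohort>", length(x$cases), "cases |",
      paste(table(x$manifest$group), collapse = " vs "),
      "| grid", x$config$grid, "^3\n")
  invisible(x)
}

#' Write / read a phantom cohort as NIfTI + manifest CSV
#'
#' `write_cohort()` lays the cohort out as one NIfTI file per phase volume
#' and mask plus a long-format manifest CSV (`case_id`, `phase_id`,
#' `volume_path`, `mask_path`, `recist`); `load_cohort()` reads that layout
#' back into a `rad_cohort`.
#'
#' @param cohort A `rad_cohort`.
#' @param dir Output directory.
#' @return `write_cohort()`: the manifest path, invisibly;
#'   `load_cohort()`: a `rad_cohort` (without `truth`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (st in cohort$cases) {
    paths <- write_case(st, dir)
    rows[[st$case_id]] <- tibble::tibble(
      case_id = st$case_id, phase_id = tace_phases,
      volume_path = unname(paths$volume_paths),
      mask_path = paths$mask_path, recist = st$recist)
  }
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(dplyr::bind_rows(rows), manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' @rdname write_cohort
#' @param manifest_path Path to a manifest CSV.
#' @export
load_cohort <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("case_id", "phase_id", "volume_path", "mask_path", "recist")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  cases <- lapply(split(man, man$case_id), function(df) {
    vp <- stats::setNames(df$volume_path, df$phase_id)
    load_case(vp, df$mask_path[1], recist = df$recist[1],
              case_id = df$case_id[1])
  })
  ids <- unique(man$case_id)
  cases <- cases[ids]
  recist <- unname(vapply(cases, function(s) s$recist, character(1)))
  structure(list(cases = unname(cases),
                 manifest = tibble::tibble(case_id = ids, recist = recist,
                                           group = map_recist(recist)),
                 truth = NULL, config = NULL),
            class = "rad_cohort")
}

#' Generate a tabular feature simulation for selection / classifier tests
#'
#' A direct tabular analogue of the cohort: balanced binary labels,
#' `informative` columns drawn as class-shifted unit normals at the given
#' standardized effect size, `noise` pure N(0, 1) columns, and optionally
#' exact duplicates of the first informative columns to exercise the
#' correlation filter.
#'
#' @param n Total cases (split evenly; must be >= 4). Default 48.
#' @param informative Number of signal columns. Default 5.
#' @param noise Number of noise columns. Default 200.
#' @param effect Standardized mean shift between classes. Default 1.5.
#' @param n_duplicate Number of informative columns to duplicate. Default 0.
#' @param seed Integer seed.
#' @return List: `X` (tibble), `y` (+1/-1), `informative` (column names),
#'   `duplicates` (named character: duplicate -> source).
#' @export
generate_feature_table <- function(n = 48L, informative = 5L, noise = 200L,
                                   effect = 1.5, n_duplicate = 0L,
                                   seed = 1L) {
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (informative + noise < 1) stop("need at least one column", call. = FALSE)
  set.seed(seed)
  n1 <- floor(n / 2)
  y <- c(rep(1, n1), rep(-1, n - n1))
  Xi <- if (informative > 0) {
    sapply(seq_len(informative), function(j) {
      stats::rnorm(n, mean = ifelse(y > 0, effect / 2, -effect / 2))
    })
  } else NULL
  Xn <- if (noise > 0) {
    matrix(stats::rnorm(n * noise), n, noise)
  } else NULL
  X <- cbind(Xi, Xn)
  colnames(X) <- c(if (informative > 0) paste0("info_", seq_len(informative)),
                   if (noise > 0) paste0("noise_", seq_len(noise)))
  dup <- character(0)
  if (n_duplicate > 0) {
    n_duplicate <- min(n_duplicate, informative)
    src <- paste0("info_", seq_len(n_duplicate))
    dup_names <- paste0("dup_", seq_len(n_duplicate))
    D <- X[, src, drop = FALSE]
    colnames(D) <- dup_names
    X <- cbind(X, D)
    dup <- stats::setNames(src, dup_names)
  }
  list(X = tibble::as_tibble(as.data.frame(X)), y = y,
       informative = if (informative > 0)
         paste0("info_", seq_len(informative)) else character(0),
       duplicates = dup)
}
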