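#' Relative change rate of a feature between two adjacent phases
#'
#' The delta-radiomics primitive: \eqn{\tilde x_{l-r} = (x_l - x_r) / x_r},
#' the relative change of feature value \eqn{x} from the earlier phase
#' \eqn{r} to the later phase \eqn{l}. When the reference value is (numerically)
#' zero the change rate is undefined; the pipeline convention returns 0 with
#' a warning so the design matrix stays finite — zero references only arise
#' from degenerate phantoms.
#'
#' @param x_r Feature value at the earlier (reference) phase.
#' @param x_l Feature value at the later phase.
#' @param eps Magnitudes of `x_r` below this count as zero. Default 1e-12.
#' @return `(x_l - x_r) / x_r`, vectorized over both arguments.
#' @export
#' @examples
#' change_rate(2, 3) # 0.5
change_rate <- function(x_r, x_l, eps = 1e-12) {
  if (any(!is.finite(x_r)) || any(!is.finite(x_l))) {
    stop("change_rate: non-finite feature value", call. = FALSE)
  }
  out <- (x_l - x_r) / x_r
  zero <- abs(x_r) < eps
  if (any(zero)) {
    warning(sum(zero), " zero-reference change rate(s) set to 0",
            call. = FALSE)
    out[zero] <- 0
  }
  out
}

# adjacent phase transitions, earlier -> later
phase_transitions <- function() {
  list(c("arterial_early", "arterial_mid"),
       c("arterial_mid", "arterial_late"),
       c("arterial_late", "hepatobiliary"))
}

#' Assemble a case's multiphase feature vector (115 static + 108 delta)
#'
#' Combines the four per-phase blocks of one case into the multiphase
#' feature vector: the static part holds the 36 dynamic (first-order +
#' texture) features of each of the three arterial phases plus the 7
#' morphological features (36 x 3 + 7 = 115; tumor geometry is
#' phase-invariant, so morphology enters once, taken from the
#' arterial-early block); the delta part holds the change rate of every
#' dynamic feature over the three adjacent phase transitions
#' (36 x 3 = 108). The hepatobiliary block contributes through the
#' late-to-hepatobiliary transition.
#'
#' Naming: `<feature>__<phase>` for static dynamic features, bare registry
#' names for morphology, and `<feature>__delta_<earlier>_<later>` for change
#' rates.
#'
#' @param blocks Tibble of the case's four phase blocks as returned by
#'   [extract_features()] filtered to one case (or by row-binding four
#'   [phase_block()] results).
#' @return One-row tibble with 223 feature columns (115 static, then 108
#'   delta).
#' @export
assemble_case <- function(blocks) {
  blocks <- tibble::as_tibble(blocks)
  missing <- setdiff(tace_phases, blocks$phase_id)
  if (length(missing) > 0) {
    stop("missing phase block(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dyn <- dynamic_registry()
  row_of <- function(p) blocks[match(p, blocks$phase_id), , drop = FALSE]

  static <- list()
  for (p in static_phases()) {
    v <- as.numeric(row_of(p)[1, dyn])
    static[[p]] <- stats::setNames(v, paste0(dyn, "__", p))
  }
  morph <- as.numeric(row_of("arterial_early")[1, feature_registry("morphology")])
  names(morph) <- feature_registry("morphology")

  delta <- list()
  for (tr in phase_transitions()) {
    xr <- as.numeric(row_of(tr[1])[1, dyn])
    xl <- as.numeric(row_of(tr[2])[1, dyn])
    d <- suppressWarnings(change_rate(xr, xl))
    delta[[paste(tr, collapse = "_")]] <-
      stats::setNames(d, paste0(dyn, "__delta_", tr[1], "_", tr[2]))
  }
  vals <- c(unlist(static, use.names = TRUE) |> unname_outer(),
            morph,
            unlist(delta, use.names = TRUE) |> unname_outer())
  tibble::as_tibble(as.list(vals))
}

# unlist() prefixes list names; strip them, keeping inner names
unname_outer <- function(x) {
  nm <- sub("^[^.]*\\.", "", names(x))
  stats::setNames(as.numeric(x), nm)
}

#' Assemble the cohort-level multiphase feature table
#'
#' @param per_phase Per-phase feature tibble from [extract_features()].
#' @return Tibble with `case_id`, `recist`, `group` (+1 ease / -1 relief
#'   when RECIST is known) and the 223 multiphase feature columns.
#' @export
assemble_features <- function(per_phase) {
  per_phase |>
    dplyr::group_by(.data$case_id) |>
    dplyr::group_modify(function(df, key) {
      out <- assemble_case(df)
      tibble::add_column(out, recist = df$recist[1], .before = 1)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(group = ifelse(is.na(.data$recist), NA_real_,
                                 recist_sign(.data$recist)),
                  .after = "recist")
}

#' The five analysis feature sets
#'
#' Returns the column-name composition of the five nested feature sets the
#' classification experiments run on:
#' \describe{
#'   \item{S1}{morphology only (7).}
#'   \item{S2}{static per-phase dynamic features (108).}
#'   \item{S3}{delta (change-rate) features (108).}
#'   \item{S4}{static + morphology (115).}
#'   \item{S5}{everything (223).}
#' }
#'
#' @param features Assembled feature tibble from [assemble_features()], used
#'   only to validate that every referenced column exists; may be omitted.
#' @return Named list of character vectors of column names.
#' @export
feature_sets <- function(features = NULL) {
  dyn <- dynamic_registry()
  morph <- feature_registry("morphology")
  static_dyn <- as.vector(vapply(static_phases(),
                                 function(p) paste0(dyn, "__", p),
                                 character(length(dyn))))
  delta <- as.vector(vapply(phase_transitions(),
                            function(tr) paste0(dyn, "__delta_", tr[1], "_",
                                                tr[2]),
                            character(length(dyn))))
  sets <- list(S1 = morph,
               S2 = static_dyn,
               S3 = delta,
               S4 = c(static_dyn, morph),
               S5 = c(static_dyn, morph, delta))
  if (!is.null(features)) {
    miss <- setdiff(unique(unlist(sets)), names(features))
    if (length(miss) > 0) {
      stop("feature table lacks column(s): ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
  }
  sets
}
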