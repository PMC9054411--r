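#' Contrast-phase identifiers, in acquisition order
#'
#' The pipeline models a four-phase dynamic contrast-enhanced CT protocol:
#' three arterial sub-phases followed by the hepatobiliary (liver and
#' gallbladder) phase. Change-rate features are defined between adjacent
#' phases in this order.
#'
#' @format Character vector of length 4.
#' @export
tace_phases <- c("arterial_early", "arterial_mid", "arterial_late",
                 "hepatobiliary")

# Arterial phases whose per-phase (static) feature blocks enter the
# multiphase static vector; the hepatobiliary block contributes through the
# late -> hepatobiliary change-rate transition only.
static_phases <- function() tace_phases[1:3]

#' Feature-name registries
#'
#' Fixed, ordered registries of the feature names emitted by each extractor.
#' The per-phase block is always `12 + 24 + 7 = 43` features: 12 first-order,
#' 24 direction-averaged texture (9 GLCM + 11 GLRLM + 4 GLZSM) and 7
#' morphological features. Output order is deterministic and follows these
#' registries.
#'
#' @param family One of `"first_order"`, `"glcm"`, `"glrlm"`, `"glzsm"`,
#'   `"morphology"`, `"texture"` (the 24 prefixed texture names) or
#'   `"block"` (all 43 per-phase names).
#' @return Character vector of feature names.
#' @export
#' @examples
#' length(feature_registry("block")) # 43
feature_registry <- function(family = c("block", "first_order", "glcm",
                                        "glrlm", "glzsm", "morphology",
                                        "texture")) {
  family <- match.arg(family)
  fo <- c("mean", "median", "minimum", "maximum", "range", "variance",
          "skewness", "kurtosis", "energy", "entropy", "uniformity",
          "mean_absolute_deviation")
  glcm <- c("energy", "contrast", "correlation", "entropy", "homogeneity",
            "dissimilarity", "sum_entropy", "cluster_shade",
            "cluster_prominence")
  glrlm <- c("short_run_emphasis", "long_run_emphasis",
             "gray_level_nonuniformity", "run_length_nonuniformity",
             "run_percentage", "low_gray_run_emphasis",
             "high_gray_run_emphasis", "short_run_low_gray_emphasis",
             "short_run_high_gray_emphasis", "long_run_low_gray_emphasis",
             "long_run_high_gray_emphasis")
  glzsm <- c("high_intensity_emphasis", "high_intensity_large_area_emphasis",
             "low_intensity_emphasis", "low_intensity_large_area_emphasis")
  morph <- c("volume", "surface_area", "density", "maximum_diameter",
             "sphericity", "compactness", "surface_to_volume_ratio")
  texture <- c(paste0("glcm_", glcm), paste0("glrlm_", glrlm),
               paste0("glzsm_", glzsm))
  switch(family,
    first_order = fo,
    glcm        = glcm,
    glrlm       = glrlm,
    glzsm       = glzsm,
    morphology  = morph,
    texture     = texture,
    block       = c(fo, texture, morph))
}

# 36 dynamic (first-order + texture) names: the per-phase features that vary
# with contrast phase and therefore take part in change rates.
dynamic_registry <- function() {
  c(feature_registry("first_order"), feature_registry("texture"))
}

# GLCM/GLRLM in-plane directions, degrees within the axial slice.
tace_directions <- c(0, 45, 90, 135)
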