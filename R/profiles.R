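# Per-group generative profiles for the synthetic-histology module.
#
# The default calibration emulates the study design this package was built
# around: four groups of rat livers (an untreated CONTROL and three
# immunosuppressive-protocol groups TMG, CMG, CEG), with lesion area
# statistics and eccentricity/circularity levels matching the pooled
# region estimators reported for those groups, and per-image lesion-presence
# probabilities matching the reported VD frequencies (50%, 90%, 75%, 66%).

# Pooled lesion-area calibration targets (px^2, at full 2572x1928 scale) and
# axis-ratio (minor/major) targets derived from the reported pooled
# eccentricity mean/SD per group via b/a = sqrt(1 - e^2).
.vq_profile_defaults <- list(
  CONTROL = list(lesion_count_range = c(5L, 60L),
                 area_mean = 88.4908, area_sd = 231.7392,
                 axis_ratio_mean = 0.605, axis_ratio_sd = 0.180,
                 boundary_roughness = 0.06, vd_presence_prob = 0.50),
  TMG     = list(lesion_count_range = c(5L, 60L),
                 area_mean = 99.1502, area_sd = 91.9057,
                 axis_ratio_mean = 0.630, axis_ratio_sd = 0.030,
                 boundary_roughness = 0.02, vd_presence_prob = 0.90),
  CMG     = list(lesion_count_range = c(5L, 60L),
                 area_mean = 77.3647, area_sd = 73.3464,
                 axis_ratio_mean = 0.630, axis_ratio_sd = 0.030,
                 boundary_roughness = 0.02, vd_presence_prob = 0.75),
  CEG     = list(lesion_count_range = c(5L, 60L),
                 area_mean = 140.1070, area_sd = 402.5104,
                 axis_ratio_mean = 0.632, axis_ratio_sd = 0.030,
                 boundary_roughness = 0.03, vd_presence_prob = 0.66)
)

#' Default generative profile for a study group
#'
#' Returns the packaged per-group parameters of the synthetic vacuole
#' sampler: lesion count range per image, lesion area mean/SD (px^2),
#' axis-ratio (minor/major) mean/SD, boundary roughness and the probability
#' that an image of that group shows vacuolar degeneration at all.
#'
#' Any field can be overridden, which is how calibration experiments and
#' separability studies configure their own conditions.
#'
#' @param group_name One of `"CONTROL"`, `"TMG"`, `"CMG"`, `"CEG"`.
#' @param overrides Named list of fields to replace in the default profile.
#' @return An object of class `vq_group_profile` (a named list).
#' @examples
#' group_profile("CONTROL")$area_mean
#' group_profile("TMG", overrides = list(area_mean = 500))$area_mean
#' @export
group_profile <- function(group_name, overrides = list()) {
  vq_check_group(group_name)
  p <- .vq_profile_defaults[[group_name]]
  p$group_name <- group_name
  if (length(overrides)) {
    bad <- setdiff(names(overrides), c(names(p)))
    if (length(bad)) {
      stop("unknown profile field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p[names(overrides)] <- overrides
  }
  validate_group_profile(p)
}

#' @keywords internal
#' @noRd
validate_group_profile <- function(p) {
  stopifnot(
    p$area_mean > 0, p$area_sd >= 0,
    p$axis_ratio_mean > 0, p$axis_ratio_mean <= 1, p$axis_ratio_sd >= 0,
    p$boundary_roughness >= 0,
    p$vd_presence_prob >= 0, p$vd_presence_prob <= 1,
    length(p$lesion_count_range) == 2L,
    p$lesion_count_range[1] >= 0,
    p$lesion_count_range[2] >= p$lesion_count_range[1]
  )
  class(p) <- "vq_group_profile"
  p
}

#' @export
print.vq_group_profile <- function(x, ...) {
  cat("<vq_group_profile> ", x$group_name, "\n",
      "  lesion area:  mean ", x$area_mean, " px^2, sd ", x$area_sd, "\n",
      "  axis ratio:   mean ", x$axis_ratio_mean, ", sd ", x$axis_ratio_sd, "\n",
      "  roughness:    ", x$boundary_roughness, "\n",
      "  VD presence:  p = ", x$vd_presence_prob, "\n",
      "  lesions/img:  ", x$lesion_count_range[1], "-",
      x$lesion_count_range[2], "\n", sep = "")
  invisible(x)
}
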