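# Lesion segmentation: exclusion masking -> contrast enhancement ->
# per-channel Otsu binarization -> logical channel fusion -> small-object
# removal. The chain marks as lesion only pixels that are bright on every
# RGB channel (white), which is what distinguishes vacuoles from the pink
# eosin background and the dark hematoxylin nuclei.

#' Segmentation parameters
#'
#' @param otsu_scale Multiplier applied to the per-channel Otsu level before
#'   thresholding; `0.5` (default) binarizes at half the Otsu level, `1`
#'   recovers plain Otsu.
#' @param fusion_mode `"AND"` (default; white = bright on all channels) or
#'   `"OR"`.
#' @param min_region_area Minimum connected-component area kept (px^2);
#'   components with fewer pixels are removed as noise.
#' @param contrast_saturation Fraction of pixels saturated at each intensity
#'   tail by the contrast stretch.
#' @param connectivity Pixel connectivity for components: `8` (default) or
#'   `4`.
#' @return A `vq_seg_params` list.
#' @export
seg_params <- function(otsu_scale = 0.5, fusion_mode = c("AND", "OR"),
                       min_region_area = 10, contrast_saturation = 0.01,
                       connectivity = 8) {
  fusion_mode <- match.arg(fusion_mode)
  stopifnot(otsu_scale > 0, otsu_scale <= 2, min_region_area >= 1,
            contrast_saturation >= 0, contrast_saturation < 0.5,
            connectivity %in% c(4, 8))
  structure(list(otsu_scale = otsu_scale, fusion_mode = fusion_mode,
                 min_region_area = min_region_area,
                 contrast_saturation = contrast_saturation,
                 connectivity = as.integer(connectivity)),
            class = "vq_seg_params")
}

#' Per-channel quantile contrast stretch
#'
#' Linearly rescales each RGB channel so that its `p` and `1-p` intensity
#' quantiles map to 0 and 255, clipping outside and rounding to the nearest
#' integer. A constant channel is returned unchanged.
#'
#' @param image H x W x 3 integer array (8-bit values).
#' @param saturation Tail fraction `p` saturated at each end.
#' @return H x W x 3 integer array.
#' @export
enhance_contrast <- function(image, saturation = 0.01) {
  out <- image
  for (ch in 1:3) {
    v <- image[, , ch]
    q <- stats::quantile(v, c(saturation, 1 - saturation), names = FALSE,
                         type = 7)
    if (q[2] <= q[1]) next  # constant (or degenerate) channel: unchanged
    out[, , ch] <- round(pmin(pmax((v - q[1]) / (q[2] - q[1]), 0), 1) * 255)
  }
  storage.mode(out) <- "integer"
  out
}

#' Otsu threshold level of an 8-bit channel
#'
#' Builds the 256-bin histogram of `values` and returns the cut level
#' maximizing the between-class variance. Candidate cuts lie halfway between
#' adjacent bins (`b + 0.5` for `b` in `0..254`, splitting `<= b` from
#' `> b`); when several cuts attain the maximum (e.g. an empty intensity
#' gap), their levels are averaged, so the returned level may be
#' half-integer or fractional.
#'
#' @param values Integer vector of intensities in `0..255` (e.g. one channel
#'   with excluded pixels already dropped).
#' @return List with `level` (numeric) and `degenerate` (`TRUE` when all
#'   values are equal, in which case `level` is that constant).
#' @export
otsu_threshold <- function(values) {
  stopifnot(length(values) > 0)
  values <- as.integer(values)
  if (min(values) == max(values)) {
    return(list(level = as.numeric(values[1]), degenerate = TRUE))
  }
  h <- as.numeric(tabulate(values + 1L, nbins = 256L))
  n <- sum(h)
  w <- cumsum(h)                      # pixels with intensity <= b
  mu <- cumsum(h * (0:255))           # intensity sum over <= b
  muT <- mu[256]
  b <- 1:255                          # cut between bins b-1 and b
  w0 <- w[b]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, 255)
  m0 <- mu[b][valid] / w0[valid]
  m1 <- (muT - mu[b][valid]) / w1[valid]
  bc[valid] <- w0[valid] * w1[valid] * (m0 - m1)^2
  best <- max(bc)
  ties <- which(bc >= best - best * 1e-12)
  level <- mean(b[ties] - 0.5)        # cut level between bins
  list(level = level, degenerate = FALSE)
}

#' Binarize all channels and fuse
#'
#' Computes the Otsu level of each RGB channel on the non-excluded pixels,
#' marks pixels with intensity `>= otsu_scale * level` as channel
#' foreground, and fuses the three channel masks with logical AND (default)
#' or OR. Excluded pixels never enter the histograms and are forced to
#' background. A degenerate (constant) channel contributes no white
#' evidence: its channel mask is all-background. If all three channels are
#' degenerate the result is an empty mask with a warning.
#'
#' @param image Contrast-enhanced H x W x 3 integer array.
#' @param exclusion_mask Logical H x W matrix (`TRUE` = excluded) or `NULL`.
#' @param params [seg_params()].
#' @return List with `mask` (logical H x W), `thresholds` (numeric length 3,
#'   `NA` for degenerate channels) and `degenerate` (logical length 3).
#' @export
binarize_fuse <- function(image, exclusion_mask = NULL,
                          params = seg_params()) {
  H <- dim(image)[1]; W <- dim(image)[2]
  use <- if (is.null(exclusion_mask)) NULL else !exclusion_mask
  thresholds <- rep(NA_real_, 3)
  degenerate <- logical(3)
  planes <- vector("list", 3)
  for (ch in 1:3) {
    v <- image[, , ch]
    vals <- if (is.null(use)) as.vector(v) else v[use]
    ot <- otsu_threshold(vals)
    degenerate[ch] <- ot$degenerate
    if (ot$degenerate) {
      planes[[ch]] <- matrix(FALSE, H, W)
    } else {
      thresholds[ch] <- params$otsu_scale * ot$level
      planes[[ch]] <- v >= thresholds[ch]
    }
  }
  if (all(degenerate)) {
    warning("all three channels are constant; returning empty mask")
    fused <- matrix(FALSE, H, W)
  } else if (params$fusion_mode == "AND") {
    keep <- !degenerate
    fused <- planes[[which(keep)[1]]]
    for (ch in which(keep)[-1]) fused <- fused & planes[[ch]]
    if (any(degenerate)) fused[] <- FALSE  # constant channel: no white
  } else {
    fused <- planes[[1]] | planes[[2]] | planes[[3]]
  }
  if (!is.null(exclusion_mask)) fused[exclusion_mask] <- FALSE
  list(mask = fused, thresholds = thresholds, degenerate = degenerate)
}

#' Remove small connected components
#'
#' Deletes every foreground component (under the configured connectivity)
#' whose pixel count is below `min_region_area`; components at exactly the
#' threshold are kept.
#'
#' @param mask Logical H x W matrix.
#' @param min_region_area Minimum retained component area (px^2).
#' @param connectivity 4 or 8.
#' @return Logical H x W matrix.
#' @export
remove_small_regions <- function(mask, min_region_area = 10,
                                 connectivity = 8) {
  lab <- vq_label(mask, connectivity)
  if (lab$n == 0L) return(mask & FALSE)
  sizes <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$n)
  keep <- which(sizes >= min_region_area)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[lab$labels %in% keep] <- TRUE
  out
}

#' Segment a micrograph into a lesion mask
#'
#' Runs the full chain on an image record: contrast enhancement, per-channel
#' Otsu binarization on non-excluded pixels, channel fusion and small-object
#' removal.
#'
#' @param record A `vq_image_record` (from the generator or
#'   [read_image_record()]).
#' @param params [seg_params()].
#' @return An object of class `vq_lesion_mask`: list with `mask` (logical
#'   H x W), `thresholds`, `degenerate`, `params`, `n_components` and
#'   `stage_pixels` (foreground counts after fusion and after small-object
#'   removal).
#' @export
segment <- function(record, params = seg_params()) {
  stopifnot(inherits(record, "vq_image_record"))
  enh <- enhance_contrast(record$image, params$contrast_saturation)
  bf <- binarize_fuse(enh, record$exclusion_mask, params)
  cleaned <- remove_small_regions(bf$mask, params$min_region_area,
                                  params$connectivity)
  lab <- vq_label(cleaned, params$connectivity)
  structure(list(mask = cleaned, thresholds = bf$thresholds,
                 degenerate = bf$degenerate, params = params,
                 n_components = lab$n,
                 stage_pixels = c(fused = sum(bf$mask),
                                  cleaned = sum(cleaned))),
            class = "vq_lesion_mask")
}

#' @export
print.vq_lesion_mask <- function(x, ...) {
  cat("<vq_lesion_mask> ", nrow(x$mask), "x", ncol(x$mask),
      ", ", x$n_components, " components, ", sum(x$mask),
      " foreground px\n", sep = "")
  cat("  thresholds (RGB): ",
      paste(signif(x$thresholds, 5), collapse = ", "), "\n", sep = "")
  invisible(x)
}
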