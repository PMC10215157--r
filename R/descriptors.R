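# Per-region shape descriptors and per-image predictor vectors.
#
# Five measures per region: area (pixel count), perimeter (chain-code length
# of the outer boundary, diagonal steps weighted sqrt(2)), major axis length
# and eccentricity of the ellipse with identical normalized second central
# moments (with the +1/12 pixel-as-unit-square variance correction), and
# circularity 4*pi*area/perimeter^2. Per image: mean and sample SD of each
# measure, giving the ten predictors used throughout the classifier search.

#' Shape descriptors of one region
#'
#' @param region A `vq_region` from [label_regions()], or an n x 2 matrix of
#'   pixel (row, col) coordinates.
#' @return A one-row data frame: `area`, `perimeter`, `mal`, `eccentricity`,
#'   `circularity`.
#' @details The moment ellipse uses per-pixel central second moments with
#'   `+1/12` added to both coordinate variances, so single-row or
#'   single-column regions keep a positive minor axis and eccentricity stays
#'   strictly below 1. `mal = 2*sqrt(2)*sqrt(m20 + m02 + D)` and
#'   `minor = 2*sqrt(2)*sqrt(m20 + m02 - D)` with
#'   `D = sqrt((m20 - m02)^2 + 4*m11^2)`;
#'   `eccentricity = sqrt(1 - (minor/mal)^2)`.
#'   Regions whose boundary cannot be traced (single pixels) raise a
#'   "degenerate region" error; such objects are normally removed upstream
#'   by the small-object filter.
#' @export
region_shape <- function(region) {
  pixels <- if (inherits(region, "vq_region")) region$pixels else region
  stopifnot(is.matrix(pixels), ncol(pixels) == 2, nrow(pixels) >= 1)
  area <- nrow(pixels)
  perimeter <- vq_chain_perimeter(pixels)
  if (perimeter == 0) {
    stop("degenerate region: boundary cannot be traced (area ", area, ")",
         call. = FALSE)
  }
  r <- pixels[, 1]; c <- pixels[, 2]
  m20 <- sum((r - mean(r))^2) / area + 1 / 12
  m02 <- sum((c - mean(c))^2) / area + 1 / 12
  m11 <- sum((r - mean(r)) * (c - mean(c))) / area
  D <- sqrt((m20 - m02)^2 + 4 * m11^2)
  mal <- 2 * sqrt(2) * sqrt(m20 + m02 + D)
  minor <- 2 * sqrt(2) * sqrt(max(m20 + m02 - D, 0))
  ecc <- sqrt(max(1 - (minor / mal)^2, 0))
  data.frame(area = area, perimeter = perimeter, mal = mal,
             eccentricity = ecc, circularity = 4 * pi * area / perimeter^2)
}

#' Shape descriptors of all regions in a mask
#'
#' @param mask A `vq_lesion_mask` or logical matrix.
#' @param image_id Optional id recorded in the output.
#' @param connectivity See [label_regions()].
#' @return Data frame with one row per region: `image_id`, `region_id` and
#'   the five measures.
#' @export
describe_regions <- function(mask, image_id = NA_character_,
                             connectivity = NULL) {
  regions <- label_regions(mask, connectivity)
  if (!length(regions)) {
    return(data.frame(image_id = character(0), region_id = integer(0),
                      area = numeric(0), perimeter = numeric(0),
                      mal = numeric(0), eccentricity = numeric(0),
                      circularity = numeric(0)))
  }
  shapes <- do.call(rbind, lapply(regions, region_shape))
  cbind(data.frame(image_id = image_id,
                   region_id = vapply(regions, `[[`, integer(1), "id")),
        shapes, row.names = NULL)
}

#' Per-image predictor vector (ten predictors)
#'
#' Aggregates region descriptors of one image into the ten predictors:
#' mean and sample SD (n-1 denominator) of area, perimeter, major axis
#' length, eccentricity and circularity, in that fixed order. An image with
#' no regions yields an all-zero vector flagged `no_lesions = TRUE`; with a
#' single region the SD components are 0 and `single_lesion = TRUE`.
#'
#' @param regions Data frame of per-region descriptors (columns `area`,
#'   `perimeter`, `mal`, `eccentricity`, `circularity`), e.g. from
#'   [describe_regions()].
#' @param image_id,group,vd_present Metadata carried into the output row.
#' @return One-row data frame: `image_id`, `group`, `vd_present`,
#'   `n_regions`, `no_lesions`, `single_lesion`, then the ten predictor
#'   columns (see `predictor_names()`).
#' @export
image_summary <- function(regions, image_id = NA_character_,
                          group = NA_character_, vd_present = NA) {
  n <- nrow(regions)
  vals <- numeric(10)
  names(vals) <- VQ_PREDICTORS
  if (n > 0) {
    for (m in VQ_MEASURES) {
      vals[paste0("mean_", m)] <- mean(regions[[m]])
      vals[paste0("sd_", m)] <- vq_sample_sd(regions[[m]])
    }
  }
  out <- data.frame(image_id = image_id, group = group,
                    vd_present = vd_present, n_regions = n,
                    no_lesions = n == 0L, single_lesion = n == 1L)
  # eccentricity measure name maps to mean_mal etc.; bind in fixed order
  cbind(out, as.data.frame(as.list(vals)))
}

#' Names of the ten predictors, in canonical order
#' @return Character vector of length 10.
#' @export
predictor_names <- function() VQ_PREDICTORS

#' Describe a whole dataset: regions and predictors tables
#'
#' Segments every image of a manifest (or in-memory record list), computes
#' per-region descriptors and per-image predictor vectors.
#'
#' @param records List of `vq_image_record`, or `NULL` to read images from
#'   `manifest` paths.
#' @param manifest Data frame as returned by [read_manifest()] or
#'   [make_dataset()]; required when `records` is `NULL`, otherwise used for
#'   metadata (matched by `image_id` / list names).
#' @param params [seg_params()].
#' @return List with `regions` (one row per region across all images) and
#'   `predictors` (one row per image, all images retained).
#' @export
describe_dataset <- function(records = NULL, manifest = NULL,
                             params = seg_params()) {
  if (is.null(records)) {
    stopifnot(!is.null(manifest))
    ids <- manifest$image_id
  } else {
    ids <- names(records)
  }
  regions_all <- list()
  preds <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    rec <- if (!is.null(records)) records[[id]] else
      read_image_record(manifest$path[i], manifest$mask_path[i],
                        group = manifest$group[i],
                        vd_present = manifest$vd_present[i])
    mask <- segment(rec, params)
    reg <- describe_regions(mask, image_id = id)
    regions_all[[id]] <- reg
    preds[[id]] <- image_summary(reg, image_id = id, group = rec$group,
                                 vd_present = rec$vd_present)
  }
  list(regions = do.call(rbind, c(regions_all, make.row.names = FALSE)),
       predictors = do.call(rbind, c(preds, make.row.names = FALSE)))
}
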