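# PNG image / mask I/O and manifest handling.

#' Write an image record to PNG
#'
#' @param record A `vq_image_record`.
#' @param image_path Output PNG path for the RGB image.
#' @param mask_path Optional output PNG path for the exclusion mask
#'   (written as 0/255 grayscale); ignored when the record has no mask.
#' @return Invisibly, `image_path`.
#' @export
write_image_record <- function(record, image_path, mask_path = NULL) {
  png::writePNG(record$image / 255, image_path)
  if (!is.null(mask_path) && !is.null(record$exclusion_mask)) {
    png::writePNG(record$exclusion_mask * 1.0, mask_path)
  }
  invisible(image_path)
}

#' Read a micrograph (and optional exclusion mask) into an image record
#'
#' Accepts 8-bit RGB PNG images; grayscale images are replicated across the
#' three channels. Masks are binarized at 0.5. The mask must match the image
#' dimensions.
#'
#' @param image_path PNG image path.
#' @param mask_path Optional PNG exclusion-mask path (`NA`/`NULL` = none).
#' @param group,vd_present Metadata to attach.
#' @return A `vq_image_record` (with `truth = NULL`).
#' @export
read_image_record <- function(image_path, mask_path = NULL,
                              group = NA_character_, vd_present = NA) {
  arr <- png::readPNG(image_path)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), c(dim(arr), 3))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  img <- round(arr * 255)
  storage.mode(img) <- "integer"
  mask <- NULL
  if (!is.null(mask_path) && !is.na(mask_path) && nzchar(mask_path)) {
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    if (!all(dim(m) == dim(img)[1:2])) {
      stop("exclusion mask dimensions do not match image", call. = FALSE)
    }
    mask <- m > 0.5
  }
  structure(list(image = img, exclusion_mask = mask, group = group,
                 vd_present = vd_present, truth = NULL, seed = NA_integer_),
            class = "vq_image_record")
}

#' Read a dataset manifest CSV
#'
#' Expected columns: `path`, `mask_path`, `group`, `vd_present`, and
#' optionally `image_id` and `seed`. Paths are resolved relative to the
#' manifest's directory.
#'
#' @param manifest_path CSV path.
#' @return Data frame with an `image_id` column and absolute paths.
#' @export
read_manifest <- function(manifest_path) {
  m <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("path", "group", "vd_present")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(m$mask_path)) m$mask_path <- NA_character_
  if (is.null(m$image_id)) {
    m$image_id <- sub("\\.[^.]*$", "", basename(m$path))
  }
  base <- dirname(normalizePath(manifest_path))
  m$path <- file.path(base, m$path)
  m$mask_path <- ifelse(is.na(m$mask_path) | m$mask_path == "",
                        NA_character_, file.path(base, m$mask_path))
  m
}
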