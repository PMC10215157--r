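# Synthetic H&E-like micrograph generator with planted vacuoles.
#
# The generator emulates the structure the segmentation chain relies on:
# a pink eosin background with Gaussian texture, darker hematoxylin nucleus
# blobs, thin near-white sinusoid specks (each below the small-object
# threshold, so they anchor the white intensity class without entering the
# lesion statistics), bright white elliptical vacuoles, and optionally a
# large white central-vein region covered by an exclusion mask.

# Palette constants (8-bit RGB). Cosmetic except for one constraint: the
# green channel of the background must sit close to the nucleus green level
# so that, after quantile contrast stretching, the Otsu cut on green falls
# between tissue and white structures rather than between nuclei and tissue.
.vq_palette <- list(
  background = c(235, 105, 185),
  background_texture_sd = 8,
  nuclei = c(120, 85, 150),
  speck = c(248, 246, 249),
  vacuole = c(250, 250, 250),
  vein = c(251, 248, 251)
)

#' Default canvas size (rows, cols)
#'
#' Half the acquisition resolution of the emulated microscope setup
#' (2572x1928 full frame), keeping default datasets fast to render while
#' preserving lesion-to-field scale.
#' @return Integer vector `c(rows, cols)`.
#' @export
default_canvas <- function() c(964L, 1286L)

# --- truncated log-normal area sampler --------------------------------------

# Moments of a log-normal truncated below at a.
.vq_tlnorm_moments <- function(mu, sigma, a) {
  mu <- unname(mu); sigma <- unname(sigma)
  la <- log(a)
  p <- stats::pnorm((mu - la) / sigma)
  m1 <- exp(mu + sigma^2 / 2) * stats::pnorm((mu + sigma^2 - la) / sigma) / p
  m2 <- exp(2 * mu + 2 * sigma^2) *
    stats::pnorm((mu + 2 * sigma^2 - la) / sigma) / p
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# Solve (mu, sigma) of the truncated log-normal so its mean/SD match the
# targets. Initialized at the untruncated moment match.
#' @keywords internal
#' @noRd
vq_tlnorm_params <- function(mean, sd, a = 10) {
  stopifnot(mean > a)
  cv2 <- (sd / mean)^2
  sigma0 <- sqrt(log(1 + cv2))
  mu0 <- log(mean) - sigma0^2 / 2
  if (sd == 0) return(c(mu = log(mean), sigma = 0))
  obj <- function(par) {
    m <- .vq_tlnorm_moments(par[1], exp(par[2]), a)
    (log(m["mean"] / mean))^2 + (log(m["sd"] / sd))^2
  }
  fit <- stats::optim(c(mu0, log(sigma0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Inverse-CDF draw from the truncated log-normal (deterministic under seed).
.vq_rtlnorm <- function(n, mu, sigma, a = 10) {
  if (sigma == 0) return(rep(exp(mu), n))
  lo <- stats::pnorm((log(a) - mu) / sigma)
  u <- stats::runif(n, lo, 1)
  exp(mu + sigma * stats::qnorm(u))
}

# --- vacuole sampling -------------------------------------------------------

#' Sample planted vacuole specifications for one image
#'
#' Draws `n_lesions` non-overlapping ellipse specifications from a group
#' profile. Areas follow a log-normal truncated below the small-object
#' threshold, calibrated so the truncated mean/SD converge to the profile's
#' `area_mean`/`area_sd`; axis ratios follow a truncated normal; orientations
#' are uniform. Placement is by rejection sampling against previously placed
#' lesions (bounding-circle test), at most `max_retries` attempts per lesion.
#'
#' @param profile A [group_profile()] object.
#' @param n_lesions Number of lesions to place (>= 0).
#' @param canvas Canvas size `c(rows, cols)`.
#' @param seed Integer RNG seed; identical inputs give identical output.
#' @param min_area Truncation floor for planted areas (px^2), matching the
#'   segmentation small-object threshold.
#' @param max_retries Placement attempts per lesion before erroring.
#' @return Data frame with one row per lesion: `center_r`, `center_c`,
#'   `major`, `minor`, `orientation`, `roughness`, `roughness_seed`,
#'   `planted_area` (= pi * major * minor / 4).
#' @export
sample_vacuoles <- function(profile, n_lesions, canvas = default_canvas(),
                            seed = 1L, min_area = 10, max_retries = 1000L) {
  stopifnot(inherits(profile, "vq_group_profile"), n_lesions >= 0)
  empty <- data.frame(center_r = numeric(0), center_c = numeric(0),
                      major = numeric(0), minor = numeric(0),
                      orientation = numeric(0), roughness = numeric(0),
                      roughness_seed = integer(0), planted_area = numeric(0))
  if (n_lesions == 0) return(empty)

  set.seed(seed)
  prm <- vq_tlnorm_params(profile$area_mean, profile$area_sd, a = min_area)
  areas <- .vq_rtlnorm(n_lesions, prm["mu"], prm["sigma"], a = min_area)

  # axis ratio q = minor/major, truncated to (0.05, 1]
  q <- stats::rnorm(n_lesions, profile$axis_ratio_mean, profile$axis_ratio_sd)
  q <- pmin(pmax(q, 0.05), 1)
  major <- 2 * sqrt(areas / (pi * q))
  minor <- q * major
  theta <- stats::runif(n_lesions, 0, pi)
  rseed <- sample.int(.Machine$integer.max, n_lesions)

  H <- canvas[1]; W <- canvas[2]
  if (any(major + 4 > min(H, W))) {
    stop("canvas too small for sampled lesion sizes", call. = FALSE)
  }
  cr <- numeric(n_lesions); cc <- numeric(n_lesions)
  for (i in seq_len(n_lesions)) {
    m <- major[i] / 2 + 2
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      r0 <- stats::runif(1, 1 + m, H - m)
      c0 <- stats::runif(1, 1 + m, W - m)
      if (i == 1L) { ok <- TRUE } else {
        j <- seq_len(i - 1L)
        ok <- all((r0 - cr[j])^2 + (c0 - cc[j])^2 >
                    ((major[i] + major[j]) / 2 + 3)^2)
      }
      if (ok) { cr[i] <- r0; cc[i] <- c0; placed <- TRUE; break }
    }
    if (!placed) {
      stop("could not place lesion ", i, " without overlap after ",
           max_retries, " retries; canvas too crowded", call. = FALSE)
    }
  }
  data.frame(center_r = cr, center_c = cc, major = major, minor = minor,
             orientation = theta, roughness = profile$boundary_roughness,
             roughness_seed = rseed,
             planted_area = pi * major * minor / 4)
}

# --- rasterization helpers --------------------------------------------------

# Logical mask of one (optionally roughened) ellipse on the canvas.
# Roughness perturbs the radius multiplicatively with two low-order angular
# harmonics; rho = 0 gives the exact ellipse.
#' @keywords internal
#' @noRd
vq_ellipse_mask <- function(canvas, center_r, center_c, major, minor,
                            orientation, roughness = 0, roughness_seed = 0L) {
  H <- canvas[1]; W <- canvas[2]
  a <- major / 2; b <- minor / 2
  pad <- ceiling(a * (1 + roughness) + 2)
  r1 <- max(1L, floor(center_r - pad)); r2 <- min(H, ceiling(center_r + pad))
  c1 <- max(1L, floor(center_c - pad)); c2 <- min(W, ceiling(center_c + pad))
  rr <- r1:r2; cc <- c1:c2
  dy <- matrix(rr - center_r, nrow = length(rr), ncol = length(cc))
  dx <- matrix(cc - center_c, nrow = length(rr), ncol = length(cc),
               byrow = TRUE)
  ct <- cos(orientation); st <- sin(orientation)
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  rho2 <- (u / a)^2 + (v / b)^2
  if (roughness > 0) {
    # draw harmonic amplitudes/phases from the lesion's own seed without
    # disturbing the caller's RNG stream
    has_rs <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
    if (has_rs) old <- get(".Random.seed", envir = .GlobalEnv)
    set.seed(roughness_seed)
    amp <- stats::runif(2, 0.5, 1); ph <- stats::runif(2, 0, 2 * pi)
    if (has_rs) assign(".Random.seed", old, envir = .GlobalEnv)
    ang <- atan2(v, u)
    f <- 1 + roughness * (amp[1] * cos(2 * ang + ph[1]) +
                            amp[2] * cos(3 * ang + ph[2])) / sqrt(2)
    inside <- rho2 <= f^2
  } else {
    inside <- rho2 <= 1
  }
  list(rows = rr, cols = cc, inside = inside)
}

# Linear (column-major, H x W) pixel indices covered by a patch.
.vq_patch_idx <- function(patch, H) {
  idx <- which(patch$inside, arr.ind = TRUE)
  if (!nrow(idx)) return(integer(0))
  (patch$cols[idx[, 2]] - 1L) * H + patch$rows[idx[, 1]]
}

# --- rendering --------------------------------------------------------------

#' Render a synthetic micrograph from vacuole specifications
#'
#' Produces an 8-bit RGB image: pink textured background, darker nucleus
#' blobs, thin near-white sinusoid specks (every speck below the
#' small-object area threshold), the planted vacuoles (near-white), and
#' optionally one large white vein region fully covered by the returned
#' exclusion mask. Nuclei and specks never overlap planted lesions (lesions
#' are painted last and the vein is placed away from them).
#'
#' @param specs Data frame from [sample_vacuoles()] (possibly 0 rows).
#' @param canvas Canvas size `c(rows, cols)`.
#' @param with_vein Plant a white central-vein region plus exclusion mask.
#' @param seed Integer RNG seed for texture, nuclei, specks and vein.
#' @param group,vd_present Metadata stored on the record.
#' @param speck_spacing Grid spacing (px) of the sinusoid specks; the
#'   default 14 yields roughly 3% of the canvas as white speck pixels,
#'   comparable to the sinusoid fraction of a liver section. Specks are
#'   placed on a jittered grid so they can never merge with each other into
#'   components at or above the small-object threshold.
#' @return An object of class `vq_image_record`: list with `image`
#'   (H x W x 3 integer array), `exclusion_mask` (logical H x W or `NULL`),
#'   `group`, `vd_present`, `truth` (the `specs` data frame), `seed`.
#' @export
render_image <- function(specs, canvas = default_canvas(), with_vein = TRUE,
                         seed = 1L, group = NA_character_,
                         vd_present = nrow(specs) > 0,
                         speck_spacing = 14) {
  H <- canvas[1]; W <- canvas[2]
  if (nrow(specs)) {
    pad <- specs$major / 2 + 2
    if (any(specs$center_r - pad < 0 | specs$center_r + pad > H + 1 |
            specs$center_c - pad < 0 | specs$center_c + pad > W + 1)) {
      stop("lesion specification outside canvas", call. = FALSE)
    }
  }
  set.seed(seed)
  pal <- .vq_palette
  # per-channel planes, painted by vectorized index assignment
  planes <- lapply(1:3, function(ch) matrix(pal$background[ch], H, W))

  # nucleus blobs: small dark disks, kept clear of planted lesions
  n_nuc <- round(H * W / 2000)
  nr <- stats::runif(n_nuc, 4, H - 3)
  nc <- stats::runif(n_nuc, 4, W - 3)
  nrad <- stats::runif(n_nuc, 2.2, 5.0)
  keep <- .vq_clear_of_lesions(nr, nc, nrad + 2, specs)
  nuc_col <- matrix(stats::rnorm(3 * n_nuc, 0, 4), ncol = 3)
  nuc_idx <- lapply(which(keep), function(i)
    .vq_patch_idx(vq_ellipse_mask(canvas, nr[i], nc[i], 2 * nrad[i],
                                  2 * nrad[i], 0), H))
  lens <- lengths(nuc_idx)
  all_idx <- unlist(nuc_idx)
  for (ch in 1:3) {
    planes[[ch]][all_idx] <- pal$nuclei[ch] +
      rep(nuc_col[which(keep), ch], lens)
  }

  # sinusoid specks: 4-9 px near-white blobs; each below the small-object
  # threshold so they are removed downstream, but together they form the
  # white intensity class that anchors both the upper contrast quantile and
  # the Otsu cut, even on lesion-free images. Jittered-grid placement keeps
  # them at least ~6 px apart so they can never merge.
  jit <- max((speck_spacing - 8) / 2, 0)
  gr <- seq(6, H - 6, by = speck_spacing)
  gc <- seq(6, W - 6, by = speck_spacing)
  sr <- rep(gr, times = length(gc)) +
    stats::runif(length(gr) * length(gc), -jit, jit)
  sc <- rep(gc, each = length(gr)) +
    stats::runif(length(gr) * length(gc), -jit, jit)
  n_spk <- length(sr)
  keep <- .vq_clear_of_lesions(sr, sc, 6, specs)
  shapes <- list(
    rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)),
    rbind(c(0, -1), c(0, 0), c(0, 1), c(1, 0), c(1, 1)),
    rbind(c(-1, 0), c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(2, 0)),
    rbind(c(0, -1), c(0, 0), c(0, 1), c(0, 2), c(1, 0), c(1, 1), c(-1, 1))
  )
  pick <- sample.int(length(shapes), n_spk, replace = TRUE)
  spk_idx <- unlist(lapply(which(keep), function(i) {
    off <- shapes[[pick[i]]]
    r <- round(sr[i]) + off[, 1]; c <- round(sc[i]) + off[, 2]
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    (c[ok] - 1L) * H + r[ok]
  }))
  for (ch in 1:3) planes[[ch]][spk_idx] <- pal$speck[ch]

  # vein: one large white ellipse, fully covered by the exclusion mask
  exclusion_mask <- NULL
  if (with_vein) {
    vrad <- min(stats::runif(1, 55, 100), (min(H, W) - 30) / 2)
    placed <- FALSE
    # shrink the vein if the canvas is too crowded for the drawn radius
    while (!placed && vrad >= 25) {
      for (try in 1:300) {
        vr <- stats::runif(1, vrad + 8, H - vrad - 8)
        vc <- stats::runif(1, vrad + 8, W - vrad - 8)
        if (!nrow(specs) ||
            all((vr - specs$center_r)^2 + (vc - specs$center_c)^2 >
                  (vrad + specs$major / 2 + 8)^2)) { placed <- TRUE; break }
      }
      if (!placed) vrad <- vrad * 0.8
    }
    if (!placed) stop("could not place vein clear of lesions", call. = FALSE)
    q <- stats::runif(1, 0.7, 0.95)
    patch <- vq_ellipse_mask(canvas, vr, vc, 2 * vrad, 2 * vrad * q,
                             stats::runif(1, 0, pi))
    vein_idx <- .vq_patch_idx(patch, H)
    for (ch in 1:3) planes[[ch]][vein_idx] <- pal$vein[ch]
    # exclusion mask: disk covering the whole vein ellipse plus a 5 px
    # safety margin, as a manual annotator would draw it
    exclusion_mask <- matrix(FALSE, H, W)
    big <- vq_ellipse_mask(canvas, vr, vc, 2 * vrad + 10, 2 * vrad + 10, 0)
    idx <- which(big$inside, arr.ind = TRUE)
    exclusion_mask[cbind(big$rows[idx[, 1]], big$cols[idx[, 2]])] <- TRUE
  }

  # vacuoles last: they overwrite anything beneath
  if (nrow(specs)) {
    les_idx <- unlist(lapply(seq_len(nrow(specs)), function(i)
      .vq_patch_idx(vq_ellipse_mask(canvas, specs$center_r[i],
                                    specs$center_c[i], specs$major[i],
                                    specs$minor[i], specs$orientation[i],
                                    specs$roughness[i],
                                    specs$roughness_seed[i]), H)))
    for (ch in 1:3) planes[[ch]][les_idx] <- pal$vacuole[ch]
  }

  # independent per-channel Gaussian texture, clipped to 8-bit
  img <- array(0L, dim = c(H, W, 3))
  for (ch in 1:3) {
    v <- planes[[ch]] + stats::rnorm(H * W, 0, pal$background_texture_sd)
    img[, , ch] <- as.integer(round(pmin(pmax(v, 0), 255)))
  }

  structure(list(image = img, exclusion_mask = exclusion_mask,
                 group = group, vd_present = vd_present,
                 truth = specs, seed = as.integer(seed)),
            class = "vq_image_record")
}

.vq_clear_of_lesions <- function(r, c, margin, specs) {
  if (!nrow(specs)) return(rep(TRUE, length(r)))
  keep <- rep(TRUE, length(r))
  for (i in seq_len(nrow(specs))) {
    d2 <- (r - specs$center_r[i])^2 + (c - specs$center_c[i])^2
    keep <- keep & d2 > (specs$major[i] / 2 + margin)^2
  }
  keep
}

#' @export
print.vq_image_record <- function(x, ...) {
  d <- dim(x$image)
  cat("<vq_image_record> ", d[1], "x", d[2],
      " group=", x$group, " vd_present=", x$vd_present,
      " lesions=", nrow(x$truth),
      if (!is.null(x$exclusion_mask)) " (+exclusion mask)" else "",
      "\n", sep = "")
  invisible(x)
}

# --- dataset generation -----------------------------------------------------

#' Default synthetic dataset configuration
#'
#' Emulates the study design: 6 CONTROL, 10 TMG, 9 CMG and 7 CEG images
#' (32 in total) at the default half-resolution canvas, each with a white
#' vein region covered by an exclusion mask.
#'
#' @param counts Named integer vector of images per group.
#' @param canvas Canvas size `c(rows, cols)`.
#' @param with_vein Plant a vein + exclusion mask in every image.
#' @param profiles Named list of [group_profile()] objects; defaults to the
#'   packaged profile of each group in `counts`.
#' @return A config list consumed by [make_dataset()].
#' @export
dataset_config <- function(counts = c(CONTROL = 6L, TMG = 10L, CMG = 9L,
                                      CEG = 7L),
                           canvas = default_canvas(), with_vein = TRUE,
                           profiles = NULL) {
  stopifnot(length(counts) >= 1, all(counts >= 0))
  for (g in names(counts)) vq_check_group(g)
  if (is.null(profiles)) {
    profiles <- lapply(names(counts), group_profile)
    names(profiles) <- names(counts)
  }
  list(counts = counts, canvas = canvas, with_vein = with_vein,
       profiles = profiles)
}

#' Generate a synthetic dataset with ground truth
#'
#' Renders all configured images, writes PNG images (and mask PNGs where an
#' exclusion mask exists), a manifest CSV
#' (`path,mask_path,group,vd_present,seed`) and a ground-truth CSV
#' (`image_id,lesion_id,center_r,center_c,major,minor,orientation,planted_area`).
#' Fully reproducible: the same `(config, master_seed)` yields byte-identical
#' files. Per-image seeds are derived by stable hashing of the master seed
#' with the group name and index, so extending a config never changes
#' existing images.
#'
#' @param config From [dataset_config()].
#' @param master_seed Integer master seed.
#' @param out_dir Output directory (created if needed); `NULL` keeps records
#'   in memory only.
#' @return Invisibly, a list with `records` (list of `vq_image_record`),
#'   `manifest` (data frame) and `truth` (data frame).
#' @export
make_dataset <- function(config = dataset_config(), master_seed = 1L,
                         out_dir = NULL) {
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "masks"), recursive = TRUE,
               showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory ",
                                   out_dir, call. = FALSE)
  }
  records <- list()
  manifest <- list()
  truth <- list()
  for (g in names(config$counts)) {
    profile <- config$profiles[[g]]
    for (i in seq_len(config$counts[[g]])) {
      id <- sprintf("%s_%02d", g, i)
      s_presence <- vq_child_seed(master_seed, "presence", g, i)
      set.seed(s_presence)
      vd <- stats::runif(1) < profile$vd_presence_prob
      n_lesions <- 0L
      if (vd) {
        n_lesions <- sample(seq(profile$lesion_count_range[1],
                                profile$lesion_count_range[2]), 1L)
      }
      s_sample <- vq_child_seed(master_seed, "sample", g, i)
      specs <- sample_vacuoles(profile, n_lesions, config$canvas,
                               seed = s_sample)
      s_render <- vq_child_seed(master_seed, "render", g, i)
      rec <- render_image(specs, config$canvas,
                          with_vein = isTRUE(config$with_vein),
                          seed = s_render, group = g, vd_present = vd)
      records[[id]] <- rec
      img_path <- if (is.null(out_dir)) NA_character_ else
        file.path("images", paste0(id, ".png"))
      mask_path <- if (is.null(out_dir) || is.null(rec$exclusion_mask))
        NA_character_ else file.path("masks", paste0(id, "_mask.png"))
      if (!is.null(out_dir)) {
        write_image_record(rec, file.path(out_dir, img_path),
                           if (is.na(mask_path)) NULL else
                             file.path(out_dir, mask_path))
      }
      manifest[[id]] <- data.frame(image_id = id, path = img_path,
                                   mask_path = mask_path, group = g,
                                   vd_present = vd, seed = rec$seed)
      if (nrow(specs)) {
        truth[[id]] <- cbind(data.frame(image_id = id,
                                        lesion_id = seq_len(nrow(specs))),
                             specs[c("center_r", "center_c", "major",
                                     "minor", "orientation", "planted_area")])
      }
    }
  }
  manifest <- do.call(rbind, c(manifest, make.row.names = FALSE))
  truth <- if (length(truth))
    do.call(rbind, c(truth, make.row.names = FALSE)) else
      data.frame(image_id = character(0), lesion_id = integer(0),
                 center_r = numeric(0), center_c = numeric(0),
                 major = numeric(0), minor = numeric(0),
                 orientation = numeric(0), planted_area = numeric(0))
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  invisible(list(records = records, manifest = manifest, truth = truth))
}
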