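# Connected-component labeling (row-run union-find, 4- or 8-connectivity)
# and Moore boundary tracing for chain-code perimeters.

#' @keywords internal
#' @noRd
vq_label <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  H <- nrow(mask); W <- ncol(mask)
  labels <- matrix(0L, H, W)
  if (!any(mask)) return(list(labels = labels, n = 0L))

  # runs per row, in raster order, merged by union-find
  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ext <- if (connectivity == 8) 1L else 0L
  prev_runs <- integer(0)
  for (r in seq_len(H)) {
    row <- mask[r, ]
    if (!any(row)) { prev_runs <- integer(0); next }
    rl <- rle(row)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    fg <- which(rl$values)
    cur <- integer(length(fg))
    for (k in seq_along(fg)) {
      id <- length(parent) + 1L
      parent[id] <- id
      run_row[id] <- r; run_s[id] <- starts[fg[k]]; run_e[id] <- ends[fg[k]]
      # union with overlapping runs of the previous row
      for (p in prev_runs) {
        if (run_s[p] <= run_e[id] + ext && run_e[p] >= run_s[id] - ext) {
          ra <- find(id); rb <- find(p)
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
      cur[k] <- id
    }
    prev_runs <- cur
  }
  # resolve roots and relabel in raster order of first run
  roots <- vapply(seq_along(parent), find, integer(1))
  first <- !duplicated(roots)
  relab <- integer(length(parent))
  relab[roots[first]] <- seq_len(sum(first))
  comp <- relab[roots]
  for (i in seq_along(parent)) {
    labels[run_row[i], run_s[i]:run_e[i]] <- comp[i]
  }
  list(labels = labels, n = max(comp))
}

#' Label connected lesion regions
#'
#' Partitions the foreground of a lesion mask into connected components
#' (8-connectivity by default) and returns one region object per component,
#' in deterministic raster-scan order (order of each component's first pixel,
#' row-major).
#'
#' @param mask A `vq_lesion_mask` from [segment()], or a logical matrix.
#' @param connectivity 4 or 8; defaults to the mask's own parameter when a
#'   `vq_lesion_mask` is given.
#' @return List of `vq_region` objects, each with `id`, `pixels` (n x 2
#'   matrix of row/col coordinates) and `area`.
#' @export
label_regions <- function(mask, connectivity = NULL) {
  if (inherits(mask, "vq_lesion_mask")) {
    if (is.null(connectivity)) connectivity <- mask$params$connectivity
    mask <- mask$mask
  }
  if (is.null(connectivity)) connectivity <- 8
  lab <- vq_label(mask, connectivity)
  if (lab$n == 0L) return(list())
  idx <- which(lab$labels > 0L)
  comp <- lab$labels[idx]
  rr <- (idx - 1L) %% nrow(mask) + 1L
  cc <- (idx - 1L) %/% nrow(mask) + 1L
  ord <- order(comp, cc, rr)
  comp <- comp[ord]; rr <- rr[ord]; cc <- cc[ord]
  bounds <- c(0L, cumsum(tabulate(comp, nbins = lab$n)))
  lapply(seq_len(lab$n), function(k) {
    sel <- (bounds[k] + 1L):bounds[k + 1L]
    structure(list(id = k, pixels = cbind(row = rr[sel], col = cc[sel]),
                   area = length(sel)),
              class = "vq_region")
  })
}

# Moore-neighbor boundary trace of one region; returns the chain-code
# perimeter (axial steps 1, diagonal steps sqrt(2)) of the outer boundary.
# A region with no traceable boundary (single pixel) returns 0.
#' @keywords internal
#' @noRd
vq_chain_perimeter <- function(pixels) {
  n <- nrow(pixels)
  if (n == 1L) return(0)
  r0 <- min(pixels[, 1]); c0 <- min(pixels[, 2])
  Hc <- max(pixels[, 1]) - r0 + 3L; Wc <- max(pixels[, 2]) - c0 + 3L
  M <- matrix(FALSE, Hc, Wc)
  M[cbind(pixels[, 1] - r0 + 2L, pixels[, 2] - c0 + 2L)] <- TRUE

  # clockwise neighbour offsets starting West (rows grow downward)
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)

  # start: first foreground pixel in raster (row-major) order
  idx <- which(t(M))[1]
  sr <- (idx - 1L) %/% Wc + 1L; sc <- (idx - 1L) %% Wc + 1L
  pr <- sr; pc <- sc
  dirb <- 1L   # backtrack direction: West of the start pixel is background
  d0 <- NA_integer_
  perim <- 0
  steps <- 0L
  max_steps <- 8L * n + 16L
  repeat {
    move <- NA_integer_
    for (k in 0:7) {
      d <- ((dirb - 1L + k) %% 8L) + 1L
      qr <- pr + dr[d]; qc <- pc + dc[d]
      if (M[qr, qc]) { move <- d; break }
    }
    if (is.na(move)) return(0)  # isolated pixel (cannot happen for n > 1)
    if (is.na(d0)) d0 <- move
    else if (pr == sr && pc == sc && move == d0) break  # loop closed
    # backtrack for the next pixel: the last background neighbour examined,
    # expressed relative to the new pixel
    bd <- ((move - 2L) %% 8L) + 1L
    br <- pr + dr[bd]; bc <- pc + dc[bd]
    pr <- pr + dr[move]; pc <- pc + dc[move]
    rel <- c(br - pr, bc - pc)
    dirb <- which(dr == rel[1] & dc == rel[2])
    perim <- perim + if (dr[move] != 0L && dc[move] != 0L) sqrt(2) else 1
    steps <- steps + 1L
    if (steps > max_steps) break  # defensive; boundary must close before this
  }
  perim
}
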