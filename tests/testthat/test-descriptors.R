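test_that("component labeling matches connectivity semantics and oracles", {
  expect_length(label_regions(matrix(FALSE, 5, 5)), 0L)

  # two separated blocks
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:3] <- TRUE
  m[7:8, 7:8] <- TRUE
  expect_length(label_regions(m), 2L)

  # diagonal pair: one region under 8-connectivity, two under 4
  d <- matrix(FALSE, 5, 5)
  d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_length(label_regions(d, connectivity = 8), 1L)
  expect_length(label_regions(d, connectivity = 4), 2L)

  # random masks against the BFS oracle (both connectivities): identical
  # partitions (same component count and same pixel->component mapping)
  set.seed(12)
  for (i in 1:15) {
    r <- matrix(runif(400) < 0.4, 20, 20)
    for (conn in c(4, 8)) {
      regions <- label_regions(r, connectivity = conn)
      ora <- oracle_label(r, conn)
      expect_equal(length(regions), max(ora))
      for (reg in regions) {
        labs <- unique(ora[reg$pixels])
        expect_length(labs, 1L)
        expect_equal(reg$area, sum(ora == labs))
      }
    }
  }
})

test_that("labeling agrees with EBImage on the 4-connectivity path", {
  skip_if_not_installed("EBImage")
  set.seed(13)
  for (i in 1:10) {
    r <- matrix(runif(625) < 0.35, 25, 25)
    ours <- label_regions(r, connectivity = 4)
    ebi <- EBImage::bwlabel(r * 1)
    expect_equal(length(ours), max(ebi))
    sizes_ours <- sort(vapply(ours, `[[`, numeric(1), "area"))
    sizes_ebi <- sort(as.numeric(tabulate(ebi[ebi > 0])))
    expect_equal(sizes_ours, sizes_ebi)
  }
})

test_that("shape descriptors are exact on analytic shapes", {
  # 10x10 filled square: area 100, chain perimeter 36, eccentricity 0
  sq <- matrix(TRUE, 10, 10)
  s <- region_shape(mask_pixels(sq))
  expect_equal(s$area, 100)
  expect_equal(s$perimeter, 36)
  expect_equal(s$eccentricity, 0)
  expect_equal(s$circularity, 4 * pi * 100 / 36^2)

  # 1x20 line: nearly degenerate ellipse
  ln <- matrix(TRUE, 1, 20)
  s <- region_shape(mask_pixels(ln))
  expect_gt(s$eccentricity, 0.99)
  expect_lt(s$eccentricity, 1)
  # hand-computed: m20 = 1/12, m02 = V + 1/12, D = V  =>  mal = 4*sqrt(V + 1/12)
  V <- sum((1:20 - 10.5)^2) / 20
  expect_equal(s$mal, 4 * sqrt(V + 1 / 12), tolerance = 1e-9)

  # rasterized disk radius 30: near-isotropic, circularity close to 1
  disk <- matrix(FALSE, 70, 70)
  for (r in 1:70) for (c in 1:70) {
    if ((r - 35.5)^2 + (c - 35.5)^2 <= 30^2) disk[r, c] <- TRUE
  }
  s <- region_shape(mask_pixels(disk))
  expect_lt(s$eccentricity, 0.15)
  expect_gt(s$circularity, 0.85)
  expect_lt(s$circularity, 1.15)
  expect_equal(s$mal, 60, tolerance = 0.05)

  # a single pixel has no traceable boundary
  expect_error(region_shape(cbind(3L, 3L)), "degenerate region")

  # two-pixel domino: boundary closes with perimeter 2
  s <- region_shape(rbind(c(2L, 2L), c(2L, 3L)))
  expect_equal(s$perimeter, 2)
})

test_that("moment ellipse equals the raw-sum oracle to 1e-9", {
  set.seed(14)
  for (i in 1:12) {
    px <- mask_pixels(random_blob(i * 3 + 1))
    s <- region_shape(px)
    o <- oracle_moment_ellipse(px)
    expect_equal(s$mal, unname(o["mal"]), tolerance = 1e-9)
    expect_equal(s$eccentricity, unname(o["eccentricity"]),
                 tolerance = 1e-9)
  }
})

test_that("descriptors scale correctly under nearest-neighbour upsampling", {
  # Area and the moment ellipse are scale-homogeneous. The chain-code
  # perimeter is bounded by its staircase factor instead: doubling turns a
  # diagonal step (sqrt(2)) into a 2 px staircase (2 + sqrt(2)), so the
  # perimeter ratio lies in [2, 2.414] depending on boundary orientation,
  # and circularity follows 4 / ratio^2.
  set.seed(15)
  for (i in 1:10) {
    m <- random_blob(i * 7 + 2, size = 20)
    up <- m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
    s1 <- region_shape(mask_pixels(m))
    s2 <- region_shape(mask_pixels(up))
    expect_equal(s2$area, 4 * s1$area)
    ratio <- s2$perimeter / s1$perimeter
    expect_gte(ratio, 1.95)
    expect_lte(ratio, 2.45)
    expect_equal(s2$mal / s1$mal, 2, tolerance = 0.05)
    expect_lt(abs(s2$eccentricity - s1$eccentricity), 0.02)
    expect_equal(s2$circularity, s1$circularity * 4 / ratio^2,
                 tolerance = 1e-9)
  }
})

test_that("eccentricity is robust to rotation and mal recovers planted axes", {
  canvas <- c(300L, 300L)
  base <- vacuoquant:::vq_ellipse_mask(canvas, 150, 150, 120, 70, 0)
  rot <- vacuoquant:::vq_ellipse_mask(canvas, 150, 150, 120, 70,
                                      37 * pi / 180)
  to_px <- function(p) {
    idx <- which(p$inside, arr.ind = TRUE)
    cbind(p$rows[idx[, 1]], p$cols[idx[, 2]])
  }
  s0 <- region_shape(to_px(base))
  s37 <- region_shape(to_px(rot))
  expect_lt(abs(s0$eccentricity - s37$eccentricity), 0.03)

  # planted ellipses >= 500 px^2: mal and area within 5% of ground truth
  set.seed(16)
  for (i in 1:8) {
    major <- runif(1, 35, 80)
    minor <- runif(1, 0.5, 0.95) * major
    if (pi * major * minor / 4 < 500) next
    p <- vacuoquant:::vq_ellipse_mask(canvas, 150, 150, major, minor,
                                      runif(1, 0, pi))
    s <- region_shape(to_px(p))
    expect_equal(s$mal, major, tolerance = 0.05)
    expect_equal(s$area, pi * major * minor / 4, tolerance = 0.05)
  }
})

test_that("image summary emits the ten predictors in canonical order", {
  regions <- data.frame(area = c(2, 4), perimeter = c(6, 8),
                        mal = c(2, 2), eccentricity = c(0.5, 0.7),
                        circularity = c(0.9, 1.1))
  s <- image_summary(regions, image_id = "a", group = "TMG",
                     vd_present = TRUE)
  expect_equal(names(s)[7:16], predictor_names())
  expect_length(predictor_names(), 10L)
  expect_equal(s$mean_area, 3)
  expect_equal(s$sd_area, sqrt(2))
  expect_equal(s$n_regions, 2L)
  expect_false(s$no_lesions)

  # identical regions: all SD components zero
  s2 <- image_summary(regions[c(1, 1), ])
  expect_equal(unlist(s2[paste0("sd_", c("area", "perimeter", "mal",
                                         "eccentricity", "circularity"))]),
               c(sd_area = 0, sd_perimeter = 0, sd_mal = 0,
                 sd_eccentricity = 0, sd_circularity = 0))

  # zero regions: flagged all-zero vector; one region: flagged zero SDs
  s0 <- image_summary(regions[0, ])
  expect_true(s0$no_lesions)
  expect_equal(sum(abs(unlist(s0[predictor_names()]))), 0)
  s1 <- image_summary(regions[1, ])
  expect_true(s1$single_lesion)
  expect_equal(s1$sd_area, 0)
  expect_equal(s1$mean_area, 2)
})
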