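# Shared fixtures, all generated in code.

tiny_canvas <- c(320L, 400L)

# A rendered record with a known number of well-sized lesions.
fixture_record <- function(n_lesions = 8, canvas = tiny_canvas,
                           group = "TMG", with_vein = FALSE, seed = 11,
                           overrides = list()) {
  prof <- group_profile(group, overrides = modifyList(
    list(area_mean = 400, area_sd = 150, boundary_roughness = 0), overrides))
  specs <- sample_vacuoles(prof, n_lesions, canvas, seed = seed)
  render_image(specs, canvas, with_vein = with_vein, seed = seed + 1,
               group = group)
}

# Random blob: union of a few overlapping discs, returned as pixel coords.
random_blob <- function(seed, size = 25) {
  set.seed(seed)
  m <- matrix(FALSE, size, size)
  for (i in 1:sample(2:4, 1)) {
    cr <- runif(1, size * 0.3, size * 0.7)
    cc <- runif(1, size * 0.3, size * 0.7)
    rad <- runif(1, size * 0.12, size * 0.28)
    for (r in 1:size) for (c in 1:size) {
      if ((r - cr)^2 + (c - cc)^2 <= rad^2) m[r, c] <- TRUE
    }
  }
  if (!any(m)) m[round(size / 2) + 0:1, round(size / 2)] <- TRUE
  m
}

mask_pixels <- function(m) which(m, arr.ind = TRUE)

# A synthetic 32-row predictor table shaped like the default study design,
# built directly (no images) for fast classifier tests.
fixture_predictor_table <- function(seed = 5, sep = 0, group_shift = 1) {
  set.seed(seed)
  groups <- rep(c("CONTROL", "TMG", "CMG", "CEG"), c(6, 10, 9, 7))
  n <- length(groups)
  base <- matrix(rnorm(n * 10), n, 10)
  colnames(base) <- predictor_names()
  # group-specific shifts; `sep` adds extra mean_mal separation to TMG
  shifts <- c(CONTROL = 0, TMG = 1, CMG = 2, CEG = 3) * group_shift
  base <- base + shifts[groups]
  base[groups == "TMG", "mean_mal"] <- base[groups == "TMG", "mean_mal"] + sep
  df <- data.frame(image_id = sprintf("img%02d", 1:n), group = groups,
                   vd_present = rep(c(TRUE, FALSE), length.out = n),
                   n_regions = 5L, no_lesions = FALSE, single_lesion = FALSE)
  cbind(df, as.data.frame(base))
}
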