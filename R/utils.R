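# Internal helpers shared across modules.

VQ_GROUPS <- c("CONTROL", "TMG", "CMG", "CEG")

# Ten per-image predictors, fixed order: mean/SD pairs of the five region
# shape measures (area, perimeter, major axis length, eccentricity,
# circularity).
VQ_PREDICTORS <- c(
  "mean_area", "sd_area",
  "mean_perimeter", "sd_perimeter",
  "mean_mal", "sd_mal",
  "mean_eccentricity", "sd_eccentricity",
  "mean_circularity", "sd_circularity"
)

VQ_MEASURES <- c("area", "perimeter", "mal", "eccentricity", "circularity")

#' @keywords internal
#' @noRd
vq_check_group <- function(group_name) {
  if (length(group_name) != 1L || !group_name %in% VQ_GROUPS) {
    stop("unknown group '", paste(group_name, collapse = ","),
         "'; valid groups: ", paste(VQ_GROUPS, collapse = ", "),
         call. = FALSE)
  }
  group_name
}

# Deterministic 31-bit string hash (polynomial rolling hash). Used to fan a
# master seed out to per-image child seeds so that adding images to a config
# never perturbs the seeds of existing ones.
#' @keywords internal
#' @noRd
vq_hash_string <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' @keywords internal
#' @noRd
vq_child_seed <- function(master_seed, ...) {
  key <- paste(..., sep = "/")
  as.integer((as.numeric(master_seed) %% 2147483647 * 48271 +
                vq_hash_string(key)) %% 2147483647)
}

# Sample standard deviation with the n-1 denominator; 0 for a single value.
#' @keywords internal
#' @noRd
vq_sample_sd <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x)
}
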