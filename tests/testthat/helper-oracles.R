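# Independent oracle implementations used to cross-check the package's own
# algorithms. These deliberately use naive, from-scratch arithmetic.

# Exhaustive Otsu: try every cut between adjacent intensity bins, compute the
# between-class variance directly from the split samples, average tied argmax
# cut levels.
oracle_otsu <- function(values) {
  values <- as.integer(values)
  best <- -Inf
  levels <- numeric(0)
  for (b in 0:254) {
    lo <- values[values <= b]
    hi <- values[values > b]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(values)
    w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best + 1e-9 * max(best, 1)) {
      best <- v
      levels <- b + 0.5
    } else if (abs(v - best) <= 1e-9 * max(abs(best), 1)) {
      levels <- c(levels, b + 0.5)
    }
  }
  mean(levels)
}

# Raw-sum second-moment ellipse: accumulates plain sums in a loop, then the
# same +1/12-corrected ellipse formulas.
oracle_moment_ellipse <- function(pixels) {
  pixels <- unname(as.matrix(pixels))
  dimnames(pixels) <- NULL
  n <- nrow(pixels)
  sr <- 0; sc <- 0
  for (i in seq_len(n)) { sr <- sr + pixels[i, 1]; sc <- sc + pixels[i, 2] }
  mr <- sr / n; mc <- sc / n
  srr <- 0; scc <- 0; src <- 0
  for (i in seq_len(n)) {
    dr <- pixels[i, 1] - mr; dc <- pixels[i, 2] - mc
    srr <- srr + dr * dr; scc <- scc + dc * dc; src <- src + dr * dc
  }
  m20 <- srr / n + 1 / 12
  m02 <- scc / n + 1 / 12
  m11 <- src / n
  D <- sqrt((m20 - m02)^2 + 4 * m11^2)
  mal <- 2 * sqrt(2) * sqrt(m20 + m02 + D)
  minor <- 2 * sqrt(2) * sqrt(max(m20 + m02 - D, 0))
  c(mal = mal, eccentricity = sqrt(max(1 - (minor / mal)^2, 0)))
}

# Breadth-first-search component labeling (4- or 8-connectivity).
oracle_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  k <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    k <- k + 1L
    queue <- start
    lab[start] <- k
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1L) %% H + 1L; c <- (cur - 1L) %/% H + 1L
      for (j in seq_len(nrow(nb))) {
        rr <- r + nb[j, 1]; cc <- c + nb[j, 2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          idx <- (cc - 1L) * H + rr
          lab[idx] <- k
          queue <- c(queue, idx)
        }
      }
    }
  }
  lab
}

# From-scratch two-class pooled-covariance LDA resubstitution predictions.
oracle_lda_predict <- function(X, y) {
  X <- as.matrix(X)
  cls <- unique(y)
  X1 <- X[y == cls[1], , drop = FALSE]
  X2 <- X[y == cls[2], , drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2)
  S <- ((n1 - 1) * stats::cov(X1) + (n2 - 1) * stats::cov(X2)) /
    (n1 + n2 - 2)
  Si <- solve(S)
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  s1 <- X %*% Si %*% m1 - drop(m1 %*% Si %*% m1) / 2 + log(n1 / (n1 + n2))
  s2 <- X %*% Si %*% m2 - drop(m2 %*% Si %*% m2) / 2 + log(n2 / (n1 + n2))
  drop(ifelse(s1 >= s2, cls[1], cls[2]))
}
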