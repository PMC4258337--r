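# Independent oracles, all deliberately naive: scalar per-pixel arithmetic,
# breadth-first flood fill, exhaustive threshold scans, and set-arithmetic
# morphology. They share nothing with the package's implementations beyond
# the definitions themselves.

# Scalar RGB -> HSI for a single pixel.
oracle_hsi_pixel <- function(r, g, b) {
  i <- (r + g + b) / 3
  s <- if (r + g + b > 0) 1 - 3 * min(r, g, b) / (r + g + b) else 0
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  if (den == 0) return(c(h = NA_real_, s = s, i = i))
  ratio <- ((r - g) + (r - b)) / 2 / den
  theta <- acos(max(-1, min(1, ratio))) * 180 / pi
  h <- if (b > g) 360 - theta else theta
  c(h = h %% 360, s = s, i = i)
}

# Flood-fill labeling via BFS; labels renumbered 1..K in raster order
# (rows top to bottom, columns left to right) of first appearance.
oracle_label <- function(mask, connectivity = 4) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  if (connectivity == 4) {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  } else {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  }
  k <- 0L
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    k <- k + 1L
    queue <- matrix(c(r0, c0), 1, 2)
    lab[r0, c0] <- k
    while (nrow(queue) > 0) {
      px <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (j in seq_along(dr)) {
        rr <- px[1] + dr[j]; cc <- px[2] + dc[j]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- k
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  lab
}

# Exhaustive Otsu scan: recompute class masses and means from scratch for
# every candidate split (bins < t vs bins >= t).
oracle_otsu <- function(counts) {
  mids <- 0:359
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 1:359) {
    lo <- 1:t; hi <- (t + 1):360
    w0 <- sum(counts[lo]); w1 <- sum(counts[hi])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[lo] * mids[lo]) / w0
    mu1 <- sum(counts[hi] * mids[hi]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v + 1e-9) { best_v <- v; best_t <- t }
  }
  best_t
}

# Set-arithmetic binary morphology over an explicit kernel matrix
# (odd-sized, origin at the center). Outside the image counts as background.
oracle_dilate <- function(mask, kern) {
  H <- nrow(mask); W <- ncol(mask)
  off <- which(kern > 0, arr.ind = TRUE) - (dim(kern)[1] + 1) / 2
  out <- matrix(FALSE, H, W)
  for (px in which(mask)) {
    r <- (px - 1) %% H + 1; c <- (px - 1) %/% H + 1
    rr <- r + off[, 1]; cc <- c + off[, 2]
    keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    out[cbind(rr[keep], cc[keep])] <- TRUE
  }
  out
}

# Erosion with replicated borders: offsets falling outside the image are
# treated as foreground (matching the package's morphology backend).
oracle_erode <- function(mask, kern) {
  H <- nrow(mask); W <- ncol(mask)
  off <- which(kern > 0, arr.ind = TRUE) - (dim(kern)[1] + 1) / 2
  out <- matrix(FALSE, H, W)
  for (px in seq_along(mask)) {
    if (!mask[px]) next
    r <- (px - 1) %% H + 1; c <- (px - 1) %/% H + 1
    rr <- r + off[, 1]; cc <- c + off[, 2]
    inside <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    out[r, c] <- all(mask[cbind(rr[inside], cc[inside])])
  }
  out
}

# A small random logical mask with roughly the given foreground density.
random_mask <- function(h, w, density = 0.45) {
  matrix(runif(h * w) < density, h, w)
}

# Single-pixel rgb_image helper.
px_image <- function(r, g, b) rgb_image(array(c(r, g, b), dim = c(1, 1, 3)))
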