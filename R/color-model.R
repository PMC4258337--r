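## HSI color model: RGB -> HSI conversion, the cyclic hue-shift transformation
## that merges the two red ends of the hue histogram, 1-degree hue histograms,
## and Otsu valley thresholding of a histogram.

#' Construct an RGB image object
#'
#' An `rgb_image` is a height x width x 3 numeric array with all channel
#' values in `[0, 1]` (8-bit inputs are divided by 255 at load time, see
#' [load_image()]).
#'
#' @param x numeric array of dimension `c(h, w, 3)` with values in `[0, 1]`.
#' @return an object of class `rgb_image`.
#' @export
rgb_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop_tongueseg("an rgb_image must be an h x w x 3 array", "tongueseg_config_error")
  if (anyNA(x) || min(x) < 0 || max(x) > 1)
    stop_tongueseg("RGB channel values must lie in [0, 1]", "tongueseg_range_error")
  structure(x, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d pixels, channels in [%.3f, %.3f]\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

#' Convert an RGB image to the HSI color model
#'
#' Computes per-pixel hue (degrees), saturation and intensity. Hue is the
#' angle
#' \deqn{\theta = \arccos\frac{\tfrac12[(R-G)+(R-B)]}{[(R-G)^2+(R-B)(G-B)]^{1/2}}}
#' taken as \eqn{H = \theta} when \eqn{B \le G} and \eqn{H = 360 - \theta}
#' when \eqn{B > G} so hue covers the full circle; saturation is
#' \eqn{S = 1 - 3\min(R,G,B)/(R+G+B)} and intensity \eqn{I = (R+G+B)/3}.
#' Achromatic pixels (`R = G = B`, where the hue denominator vanishes) get
#' `S = 0` and an undefined hue, stored as `NA`; all-black pixels
#' additionally have `I = 0` (the `S` division-by-zero guard defines
#' `S = 0` there).
#'
#' @param img an [rgb_image()] (or a plain `h x w x 3` array in `[0, 1]`).
#' @return an object of class `hsi_image`: a list with matrices `h`
#'   (degrees in `[0, 360)`, `NA` where undefined), `s` and `i` (both in
#'   `[0, 1]`).
#' @export
#' @examples
#' px <- rgb_image(array(c(1, 0, 0), dim = c(1, 1, 3)))
#' rgb_to_hsi(px)  # pure red: H = 0, S = 1, I = 1/3
rgb_to_hsi <- function(img) {
  if (!inherits(img, "rgb_image")) img <- rgb_image(img)
  d <- dim(img)
  R <- matrix(img[, , 1], d[1], d[2])
  G <- matrix(img[, , 2], d[1], d[2])
  B <- matrix(img[, , 3], d[1], d[2])
  num <- 0.5 * ((R - G) + (R - B))
  den <- sqrt((R - G)^2 + (R - B) * (G - B))
  theta <- acos(pmin(pmax(num / den, -1), 1)) * 180 / pi  # NaN where den == 0
  h <- ifelse(B > G, 360 - theta, theta) %% 360
  h[den == 0] <- NA_real_
  csum <- R + G + B
  s <- ifelse(csum > 0, 1 - 3 * pmin(R, G, B) / csum, 0)
  structure(list(h = h, s = s, i = csum / 3), class = "hsi_image")
}

#' @export
print.hsi_image <- function(x, ...) {
  cat(sprintf("<hsi_image> %d x %d pixels, %d with undefined hue\n",
              nrow(x$h), ncol(x$h), sum(is.na(x$h))))
  invisible(x)
}

#' Cyclic hue-shift transformation
#'
#' Adds 180 degrees modulo 360. In a raw hue histogram red hues sit at both
#' ends (near 0 and near 360); shifting moves the upper half of the
#' histogram to the left and the lower half to the right, so the two red
#' peaks merge into a single peak near 180 degrees. The map is a bijection
#' on hues and its own inverse; undefined hues (`NA`) stay undefined.
#'
#' @param h hue in degrees (vector or matrix), `NA` allowed.
#' @return shifted hue, same shape as `h`.
#' @export
#' @examples
#' shift_hue(c(0, 180, 350))  # 180, 0, 170
shift_hue <- function(h) (h + 180) %% 360

#' Hue histogram with 1-degree bins
#'
#' Counts pixels with defined hue into 360 one-degree bins, bin `b`
#' covering `[b, b+1)` degrees for `b = 0..359`. Pixels with undefined hue
#' are excluded from the histogram and its total. When `shifted = TRUE`
#' the hues pass through [shift_hue()] first.
#'
#' @param hsi an `hsi_image`.
#' @param mask optional logical matrix restricting the counted pixels.
#' @param shifted apply the hue-shift transformation before binning?
#' @return an object of class `hue_histogram`: list with `counts`
#'   (integer vector of length 360, named by lower bin edge), `shifted`,
#'   and `total`.
#' @export
hue_histogram <- function(hsi, mask = NULL, shifted = FALSE) {
  h <- hsi$h
  if (!is.null(mask)) {
    assert_mask(mask)
    assert_same_shape(h, mask, "mask and image")
    h <- h[mask]
  }
  h <- h[!is.na(h)]
  if (shifted) h <- shift_hue(h)
  counts <- tabulate(pmin(floor(h), 359) + 1L, nbins = 360L)
  structure(list(counts = stats::setNames(as.integer(counts), 0:359),
                 shifted = shifted, total = length(h)),
            class = "hue_histogram")
}

#' @export
print.hue_histogram <- function(x, ...) {
  cat(sprintf("<hue_histogram> %d pixels in %d nonempty 1-degree bins%s\n",
              x$total, sum(x$counts > 0), if (x$shifted) " (shifted)" else ""))
  invisible(x)
}

#' Valley threshold of a hue histogram (Otsu criterion)
#'
#' Finds the bin index `t` that best splits the histogram into a lower
#' class (bins `< t`) and an upper class (bins `>= t`) by maximizing the
#' Otsu between-class variance
#' \eqn{\sigma_B^2(t) = w_0 w_1 (\mu_0 - \mu_1)^2}. Ties are broken by the
#' smallest qualifying `t`. Applied to a shifted hue histogram of a tongue
#' scene this locates the valley separating the red tongue peak from the
#' background hue peak.
#'
#' @param hist a [hue_histogram()] with at least two nonempty bins.
#' @return the threshold bin index (a value in `1..359`): bins below it
#'   form one class, bins at or above it the other.
#' @export
valley_threshold <- function(hist) {
  counts <- as.numeric(hist$counts)
  if (hist$total < 2 || sum(counts > 0) < 2)
    stop_tongueseg("histogram has no valley (fewer than two nonempty bins)",
                   "tongueseg_no_valley")
  mids <- 0:359
  total <- sum(counts)
  w0 <- cumsum(counts)                # mass of bins 0..t-1 at index t
  m0 <- cumsum(counts * mids)
  grand <- m0[360]
  t_cand <- 1:359
  w_lo <- w0[t_cand]
  w_hi <- total - w_lo
  valid <- w_lo > 0 & w_hi > 0
  mu_lo <- m0[t_cand] / w_lo
  mu_hi <- (grand - m0[t_cand]) / w_hi
  sigma_b <- w_lo * w_hi * (mu_lo - mu_hi)^2
  sigma_b[!valid] <- -Inf
  t_cand[which.max(sigma_b)]          # which.max: first maximum = smallest t
}
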