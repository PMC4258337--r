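## Greedy color/space fusion pipeline: seeded region growing whose acceptance
## rules fuse color (hue window, saturation, intensity) with space (a
## coating-colored pixel is admitted only when already surrounded by accepted
## tongue pixels). This is what lets a thickly coated tongue be extracted as
## substance plus coating in one connected region, where pure color
## thresholding loses the coating.

#' Tongue-substance predicate
#'
#' A pixel is tongue substance iff its hue is defined, its shifted hue lies
#' within the substance window, its saturation is at least
#' `saturation_min` (hue is unreliable near zero saturation) and its
#' intensity is at least `intensity_min`. Vectorized.
#'
#' @param h raw hue in degrees (`NA` = undefined), as stored in an
#'   `hsi_image`.
#' @param s,i saturation and intensity in `[0, 1]`.
#' @param p a [fusion_params()].
#' @return logical vector.
#' @export
is_substance <- function(h, s, i, p = fusion_params()) {
  ok <- hue_circ_dist(shift_hue(h), p$hue_center) <= p$hue_half_width &
    s >= p$saturation_min & i >= p$intensity_min
  ok & !is.na(ok)
}

## Coating color rule alone (no spatial condition): white = low saturation
## and high intensity; yellow = shifted hue inside the yellow band.
matches_coating_color <- function(h, s, i, p) {
  hs <- shift_hue(h)
  white <- s < p$white_s_max & i > p$white_i_min
  yellow <- !is.na(hs) & hs >= p$yellow_band[1] & hs <= p$yellow_band[2]
  white | yellow
}

#' Greedy growth state
#'
#' The bookkeeping carried by [grow_region()]: the accepted region with
#' per-pixel justification flags, the growth frontier in insertion order,
#' and the running circular mean of accepted substance hues. Exposed so
#' the acceptance predicates can be exercised on constructed states.
#'
#' @param flags integer matrix: 0 = not accepted, 1 = substance,
#'   2 = coating, 3 = filled enclosed hole.
#' @param frontier n x 2 matrix of `(row, col)` frontier pixels in
#'   insertion order.
#' @param hue_mean running circular mean of accepted substance hues, on
#'   the shifted scale (degrees).
#' @return object of class `greedy_state`.
#' @export
greedy_state <- function(flags, frontier = matrix(integer(0), 0, 2),
                         hue_mean = NA_real_) {
  structure(list(flags = flags, frontier = frontier, hue_mean = hue_mean),
            class = "greedy_state")
}

#' Coating admissibility of a frontier pixel
#'
#' A pixel similar in color to tongue coating is admitted only when it is
#' surrounded by already-accepted tongue pixels: it must (a) match a
#' coating color rule, (b) have intensity at least `intensity_min`, and
#' (c) have at least `enclosure_min_neighbors` of its 8-neighbors already
#' accepted into the region.
#'
#' @param px pixel coordinate `c(row, col)`.
#' @param hsi an `hsi_image`.
#' @param st a [greedy_state()] (only `st$flags` is consulted).
#' @param p a [fusion_params()].
#' @return single logical.
#' @export
is_coating_admissible <- function(px, hsi, st, p = fusion_params()) {
  r <- px[1]; c <- px[2]
  if (!matches_coating_color(hsi$h[r, c], hsi$s[r, c], hsi$i[r, c], p))
    return(FALSE)
  if (hsi$i[r, c] < p$intensity_min) return(FALSE)
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[nb$dr != 0 | nb$dc != 0, ]
  rr <- r + nb$dr; cc <- c + nb$dc
  keep <- rr >= 1 & rr <= nrow(st$flags) & cc >= 1 & cc <= ncol(st$flags)
  sum(st$flags[cbind(rr[keep], cc[keep])] > 0) >= p$enclosure_min_neighbors
}

#' Most similar frontier pixel
#'
#' Returns the frontier pixel whose shifted hue is closest (circular
#' distance) to the region's running mean substance hue; pixels with
#' undefined hue rank after every defined hue; ties are broken by earliest
#' insertion into the frontier.
#'
#' @param st a [greedy_state()] with a nonempty frontier.
#' @param hsi an `hsi_image`.
#' @return pixel coordinate `c(row, col)`.
#' @export
best_candidate <- function(st, hsi) {
  if (nrow(st$frontier) == 0L)
    stop_tongueseg("frontier is empty", "tongueseg_empty_frontier")
  hs <- shift_hue(hsi$h[st$frontier])
  d <- hue_circ_dist(hs, st$hue_mean)
  d[is.na(d)] <- 361
  st$frontier[which.min(d), ]   # which.min: first = earliest insertion
}

#' Select the seed pixel for greedy growth
#'
#' With an explicit `p$seed`, validates it against the substance predicate
#' (high intensity, hue close to tongue substance) and returns it.
#' Otherwise searches the central window of the image (side fraction
#' `p$seed_search_fraction`) for the substance pixel maximizing
#' `intensity * (1 - circular hue distance to the window center / 180)`.
#' Signals `tongueseg_seed_failure` when no pixel qualifies.
#'
#' @param hsi an `hsi_image`.
#' @param p a [fusion_params()].
#' @return seed coordinate `c(row, col)`.
#' @export
select_seed <- function(hsi, p = fusion_params()) {
  if (!is.null(p$seed)) {
    r <- p$seed[1]; c <- p$seed[2]
    if (r < 1 || r > nrow(hsi$h) || c < 1 || c > ncol(hsi$h))
      stop_tongueseg("explicit seed lies outside the image", "tongueseg_seed_failure")
    if (!is_substance(hsi$h[r, c], hsi$s[r, c], hsi$i[r, c], p))
      stop_tongueseg("explicit seed is not a tongue-substance pixel",
                     "tongueseg_seed_failure")
    return(c(r, c))
  }
  H <- nrow(hsi$h); W <- ncol(hsi$h)
  half_h <- max(1L, floor(H * p$seed_search_fraction / 2))
  half_w <- max(1L, floor(W * p$seed_search_fraction / 2))
  rows <- max(1L, ceiling(H / 2) - half_h):min(H, ceiling(H / 2) + half_h)
  cols <- max(1L, ceiling(W / 2) - half_w):min(W, ceiling(W / 2) + half_w)
  h <- hsi$h[rows, cols, drop = FALSE]
  s <- hsi$s[rows, cols, drop = FALSE]
  i <- hsi$i[rows, cols, drop = FALSE]
  score <- i * (1 - hue_circ_dist(shift_hue(h), p$hue_center) / 180)
  score[!is_substance(h, s, i, p)] <- -Inf
  if (all(is.infinite(score)))
    stop_tongueseg("no qualifying seed pixel in the central search window",
                   "tongueseg_seed_failure")
  k <- which.max(score)   # column-major: smallest row, then column, on ties
  c(rows[(k - 1) %% length(rows) + 1], cols[(k - 1) %/% length(rows) + 1])
}

#' Grow the tongue region from a seed
#'
#' Implements the multiobjective greedy loop: repeatedly take the frontier
#' pixel most similar to the region (see [best_candidate()]); accept it if
#' it is tongue substance or coating-admissible, pushing its unseen
#' neighbors onto the frontier; otherwise discard it from the frontier for
#' good. The loop ends when the frontier can no longer yield an
#' acceptance. With `p$fill_enclosed_holes`, background holes fully
#' enclosed by the region are then filled (interior non-substance pixels
#' must be coating). The result is a single connected region containing
#' the seed; rejected pixels are never part of it.
#'
#' @param hsi an `hsi_image`.
#' @param seed pixel coordinate `c(row, col)` satisfying the substance
#'   predicate (see [select_seed()]).
#' @param p a [fusion_params()].
#' @return logical tongue mask with attributes `flags` (integer matrix:
#'   1 = substance, 2 = coating, 3 = filled hole), `seed`, `accepted` and
#'   `rejected` (pixel counts from the growth loop).
#' @export
grow_region <- function(hsi, seed, p = fusion_params()) {
  r <- seed[1]; c <- seed[2]
  if (!is_substance(hsi$h[r, c], hsi$s[r, c], hsi$i[r, c], p))
    stop_tongueseg("seed does not satisfy the substance predicate",
                   "tongueseg_seed_failure")
  res <- grow_region_cpp(shift_hue(hsi$h), hsi$s, hsi$i,
                         as.integer(r) - 1L, as.integer(c) - 1L,
                         p$hue_center, p$hue_half_width,
                         p$intensity_min, p$saturation_min,
                         p$white_s_max, p$white_i_min,
                         p$yellow_band[1], p$yellow_band[2],
                         p$enclosure_min_neighbors, p$connectivity)
  flags <- res$flags
  if (p$fill_enclosed_holes) {
    filled <- matrix(EBImage::fillHull((flags > 0) * 1) > 0.5,
                     nrow(flags), ncol(flags))
    flags[filled & flags == 0L] <- 3L
  }
  structure(flags > 0L, flags = flags, seed = as.integer(seed),
            accepted = res$accepted, rejected = res$rejected)
}

#' Segment a tongue image by greedy color/space fusion
#'
#' Pipeline: optionally shrink the image (longest side
#' `p$resize_longest_side`, nearest-neighbor), convert to HSI, select the
#' seed, grow the region, and upsample the mask back to the input
#' resolution. Signals `tongueseg_seed_failure` when no seed qualifies
#' (e.g. a scene without a red region).
#'
#' @param img an [rgb_image()].
#' @param p a [fusion_params()].
#' @return logical tongue mask at the input resolution, with the
#'   [grow_region()] attributes (`flags`, `seed`, `accepted`, `rejected`
#'   refer to the working resolution).
#' @export
#' @seealso [segment_morph_hsi()], [segment_sequential_hsi()]
segment_greedy_fusion <- function(img, p = fusion_params()) {
  if (!inherits(img, "rgb_image")) img <- rgb_image(img)
  d <- dim(img)
  work <- img
  scale <- 1
  if (!is.null(p$resize_longest_side) && max(d[1:2]) > p$resize_longest_side) {
    scale <- p$resize_longest_side / max(d[1:2])
    work <- rgb_image(resize_nearest(unclass(img),
                                     round(d[1] * scale), round(d[2] * scale)))
  }
  hsi <- rgb_to_hsi(work)
  seed <- select_seed(hsi, p)
  mask <- grow_region(hsi, seed, p)
  if (scale < 1) {
    up <- resize_nearest(unclass(mask), d[1], d[2])
    attributes(up) <- c(attributes(up),
                        attributes(mask)[c("flags", "seed", "accepted", "rejected")])
    mask <- up
  }
  mask
}
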