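## Morphology + HSI pipeline: hue binarization, object-region clustering
## (largest connected component), and morphological opening/closing cleanup.
## Efficient on uncoated tongues; coating pixels fall outside the red hue
## window, so thickly coated tongues lose their coating region here -- the
## documented weakness this pipeline is compared under.

#' Binarize an HSI image by hue
#'
#' A pixel is foreground iff its hue is defined and its shifted hue lies
#' within the configured window (circular distance to `hue_center` at most
#' `hue_half_width`).
#'
#' @param hsi an `hsi_image` from [rgb_to_hsi()].
#' @param p a [morph_params()] (any object with `hue_center` and
#'   `hue_half_width` works).
#' @return logical mask matrix.
#' @export
binarize_by_hue <- function(hsi, p = morph_params()) {
  hs <- shift_hue(hsi$h)
  m <- hue_circ_dist(hs, p$hue_center) <= p$hue_half_width
  m[is.na(m)] <- FALSE
  m
}

#' Keep only the largest connected foreground component
#'
#' The "object region clustering" step: connected-component analysis under
#' the configured connectivity, retaining the component with the most
#' pixels (ties broken by smallest label, i.e. raster order). An empty
#' mask is returned unchanged.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return logical mask with a single component (or empty).
#' @export
largest_cluster <- function(mask, connectivity = 4) {
  assert_mask(mask)
  if (!any(mask)) return(mask)
  lr <- sequential_label(mask, connectivity)
  best <- which.max(lr$sizes)          # first maximum = smallest label
  lr$labels == best
}

#' Morphological opening then closing with a disk element
#'
#' Opening removes foreground specks smaller than the structuring element;
#' the subsequent closing fills small holes and gulfs on the tongue body.
#'
#' @param mask logical matrix.
#' @param p a [morph_params()]; `p$se_radius` may be `NULL` for the
#'   width-proportional default.
#' @return logical mask.
#' @export
open_close <- function(mask, p = morph_params()) {
  assert_mask(mask)
  r <- effective_se_radius(p$se_radius, ncol(mask))
  k <- disk_kernel(r)
  out <- EBImage::closing(EBImage::opening(mask * 1, k), k)
  matrix(out > 0.5, nrow(mask), ncol(mask))
}

#' Segment a tongue image by morphology + HSI
#'
#' Pipeline: convert to HSI, binarize by hue, keep the largest connected
#' cluster, then clean up with opening and closing.
#'
#' @param img an [rgb_image()].
#' @param p a [morph_params()].
#' @return logical tongue mask, same size as `img`.
#' @export
#' @seealso [segment_sequential_hsi()], [segment_greedy_fusion()]
segment_morph_hsi <- function(img, p = morph_params()) {
  hsi <- rgb_to_hsi(img)
  mask <- binarize_by_hue(hsi, p)
  mask <- largest_cluster(mask, p$connectivity)
  open_close(mask, p)
}
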