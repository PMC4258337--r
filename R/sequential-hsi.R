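## Sequential-labeling + HSI pipeline: threshold the HSI image on hue AND
## intensity (F0 -> F1), label connected regions with a two-pass raster scan
## (-> A1), close small holes (-> A2), and mask the original image. The
## intensity floor is what detaches the tongue from the lip across their dark
## shared boundary.

#' Threshold an HSI image on hue and intensity
#'
#' Foreground iff the shifted hue is defined and inside the window AND the
#' intensity is at least `intensity_min`. The tongue/lip boundary has low
#' intensity, so with a suitable floor the tongue and the (equally red)
#' lip become separate components.
#'
#' @param hsi an `hsi_image`.
#' @param p a [seq_params()].
#' @return logical mask matrix (the image F1).
#' @export
threshold_hue_intensity <- function(hsi, p = seq_params()) {
  binarize_by_hue(hsi, p) & hsi$i >= p$intensity_min
}

#' Sequential connected-region labeling
#'
#' Two-pass raster-scan labeling: the first pass assigns provisional labels
#' from already-visited neighbors and records label equivalences in a
#' union-find forest; the second pass resolves roots and renumbers the
#' regions consecutively `1..K` in raster order of first appearance. The
#' partition is identical to flood fill.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return object of class `labeled_regions`: list with `labels` (integer
#'   matrix, 0 = background), `sizes` (pixel count per label) and
#'   `connectivity`.
#' @export
sequential_label <- function(mask, connectivity = 4) {
  assert_mask(mask)
  connectivity <- check_connectivity(connectivity)
  lab <- label_mask_cpp(mask, connectivity)
  k <- max(lab)
  sizes <- if (k > 0) tabulate(lab[lab > 0L], nbins = k) else integer(0)
  structure(list(labels = lab, sizes = as.integer(sizes),
                 connectivity = connectivity),
            class = "labeled_regions")
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat(sprintf("<labeled_regions> %d region(s), %d foreground pixels (connectivity %d)\n",
              length(x$sizes), sum(x$sizes), x$connectivity))
  invisible(x)
}

#' Select the tongue-candidate region from a labeling
#'
#' Returns the largest labeled region as a mask (the image A1); ties are
#' broken by the smallest label. With `p$require_center`, the region
#' containing the image center pixel is preferred when one exists -- the
#' tongue is assumed roughly centered -- falling back to the largest.
#' Note the documented failure mode: when the lip region is larger than
#' the tongue region (e.g. a coated tongue whose substance forms only a
#' ring), the lip is selected.
#'
#' @param lr a `labeled_regions` object.
#' @param p a [seq_params()] (only `require_center` is used).
#' @return logical mask of the selected region.
#' @export
select_region <- function(lr, p = seq_params()) {
  if (length(lr$sizes) == 0L)
    stop_tongueseg("no foreground region to select", "tongueseg_no_foreground")
  pick <- which.max(lr$sizes)
  if (isTRUE(p$require_center)) {
    ctr <- lr$labels[ceiling(nrow(lr$labels) / 2), ceiling(ncol(lr$labels) / 2)]
    if (ctr > 0L) pick <- ctr
  }
  lr$labels == pick
}

#' Fill small holes by morphological closing
#'
#' Binary closing with a disk structuring element; the output is a
#' superset of the input (A1 -> A2).
#'
#' @param mask logical matrix.
#' @param p a [seq_params()].
#' @return logical mask.
#' @export
close_holes <- function(mask, p = seq_params()) {
  assert_mask(mask)
  k <- disk_kernel(effective_se_radius(p$se_radius, ncol(mask)))
  out <- matrix(EBImage::closing(mask * 1, k) > 0.5, nrow(mask), ncol(mask))
  out | mask   # closing is extensive; guard against border clipping
}

#' Apply a binary mask to an RGB image
#'
#' Per-pixel product of image and mask: background pixels become black
#' `(0,0,0)`, foreground pixels are unchanged.
#'
#' @param img an [rgb_image()].
#' @param mask logical matrix of the same height and width.
#' @return an [rgb_image()].
#' @export
apply_mask <- function(img, mask) {
  if (!inherits(img, "rgb_image")) img <- rgb_image(img)
  assert_mask(mask)
  assert_same_shape(img, mask, "image and mask")
  out <- unclass(img)
  for (ch in 1:3) out[, , ch] <- out[, , ch] * mask
  rgb_image(out)
}

#' Segment a tongue image by sequential labeling + HSI
#'
#' Pipeline: convert to HSI, threshold on hue and intensity, label the
#' connected regions sequentially, select the tongue-candidate region,
#' and close small holes. Signals a `tongueseg_no_foreground` error when
#' thresholding leaves nothing to label.
#'
#' @param img an [rgb_image()].
#' @param p a [seq_params()].
#' @return logical tongue mask (the image A2).
#' @export
#' @seealso [segment_morph_hsi()], [segment_greedy_fusion()]
segment_sequential_hsi <- function(img, p = seq_params()) {
  hsi <- rgb_to_hsi(img)
  f1 <- threshold_hue_intensity(hsi, p)
  a1 <- select_region(sequential_label(f1, p$connectivity), p)
  close_holes(a1, p)
}
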