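## Parameter blocks for the three segmentation pipelines. All hue windows are
## specified on the *shifted* hue scale (see shift_hue), where red sits near
## 180 degrees; none of the source methods print their parameter values, so
## every default here is an exposed, documented choice.

check_hue_window <- function(center, half_width) {
  if (center < 0 || center >= 360)
    stop_tongueseg("hue window center must be in [0, 360)", "tongueseg_config_error")
  if (half_width <= 0 || half_width >= 180)
    stop_tongueseg("hue window half-width must be in (0, 180)", "tongueseg_config_error")
}

#' Parameters for the morphology + HSI pipeline
#'
#' @param hue_center,hue_half_width hue window on the shifted hue scale, in
#'   degrees; a pixel is red-binarized when its shifted hue lies within
#'   `hue_half_width` of `hue_center` (circular distance). Default
#'   `180 +/- 30`, the red band after the hue shift.
#' @param se_radius radius (pixels) of the disk structuring element used for
#'   opening/closing. `NULL` (default) scales a radius of 5 pixels per 400
#'   pixels of image width, with a minimum of 1.
#' @param connectivity pixel connectivity for region clustering, 4 or 8.
#' @return object of class `morph_params`.
#' @export
morph_params <- function(hue_center = 180, hue_half_width = 30,
                         se_radius = NULL, connectivity = 4) {
  check_hue_window(hue_center, hue_half_width)
  if (!is.null(se_radius) && se_radius < 1)
    stop_tongueseg("`se_radius` must be >= 1", "tongueseg_config_error")
  structure(list(hue_center = hue_center, hue_half_width = hue_half_width,
                 se_radius = se_radius,
                 connectivity = check_connectivity(connectivity)),
            class = "morph_params")
}

#' Parameters for the sequential-labeling + HSI pipeline
#'
#' @inheritParams morph_params
#' @param intensity_min minimum intensity for a pixel to be foreground, in
#'   `[0, 1]`. Must sit above the dark tongue/lip boundary so the two
#'   regions separate; default 0.15.
#' @param require_center if `TRUE`, region selection prefers the connected
#'   region containing the image center (the tongue is assumed roughly
#'   centered), falling back to the largest region.
#' @return object of class `seq_params`.
#' @export
seq_params <- function(hue_center = 180, hue_half_width = 30,
                       intensity_min = 0.15, se_radius = NULL,
                       connectivity = 4, require_center = FALSE) {
  check_hue_window(hue_center, hue_half_width)
  if (intensity_min < 0 || intensity_min > 1)
    stop_tongueseg("`intensity_min` must be in [0, 1]", "tongueseg_config_error")
  if (!is.null(se_radius) && se_radius < 1)
    stop_tongueseg("`se_radius` must be >= 1", "tongueseg_config_error")
  structure(list(hue_center = hue_center, hue_half_width = hue_half_width,
                 intensity_min = intensity_min, se_radius = se_radius,
                 connectivity = check_connectivity(connectivity),
                 require_center = isTRUE(require_center)),
            class = "seq_params")
}

#' Parameters for the greedy color/space fusion pipeline
#'
#' Tongue *substance* (the red tissue proper) is recognized by color alone:
#' shifted hue within the substance window, saturation at least
#' `saturation_min` (hue is unreliable near zero saturation), intensity at
#' least `intensity_min`. Tongue *coating* is recognized by a color rule
#' (white: low saturation and high intensity; yellow: shifted hue in the
#' yellow band) combined with a spatial rule: the pixel must already be
#' surrounded by accepted tongue pixels.
#'
#' @param hue_center,hue_half_width substance hue window on the shifted hue
#'   scale (degrees); default `180 +/- 30`.
#' @param intensity_min minimum intensity for acceptance of any pixel
#'   (substance or coating). The growth rules demand *high* intensity, a
#'   stricter bar than the thresholding pipelines' floor; default 0.30.
#' @param saturation_min minimum saturation for the substance predicate;
#'   default 0.15.
#' @param white_s_max,white_i_min white-coating rule: saturation below
#'   `white_s_max` (default 0.25) and intensity above `white_i_min`
#'   (default 0.4).
#' @param yellow_band yellow-coating rule: length-2 vector of shifted hue
#'   bounds, default `c(210, 280)` (raw hue 30-100 degrees).
#' @param enclosure_min_neighbors how many of a pixel's 8-neighbors must
#'   already be accepted before a coating-colored pixel counts as
#'   "surrounded by tongue substance"; integer in `1..8`, default 2.
#' @param seed optional explicit seed pixel `c(row, col)`; validated
#'   against the substance predicate. `NULL` selects the seed
#'   automatically.
#' @param seed_search_fraction central window fraction of the image
#'   searched for an automatic seed; default 0.3. The window must stay on
#'   the tongue: the lip shares the tongue's hue and intensity, so a wide
#'   window risks seeding there.
#' @param fill_enclosed_holes after growth, fill background holes fully
#'   enclosed by the region (interior non-substance pixels must be
#'   coating); default `TRUE`.
#' @param connectivity growth adjacency, 4 or 8; default 8.
#' @param resize_longest_side images are shrunk so their longest side is at
#'   most this many pixels before segmentation (the mask is upsampled back
#'   with nearest-neighbor); `NULL` disables. Default 400.
#' @return object of class `fusion_params`.
#' @export
fusion_params <- function(hue_center = 180, hue_half_width = 30,
                          intensity_min = 0.30, saturation_min = 0.15,
                          white_s_max = 0.25, white_i_min = 0.4,
                          yellow_band = c(210, 280),
                          enclosure_min_neighbors = 2, seed = NULL,
                          seed_search_fraction = 0.3,
                          fill_enclosed_holes = TRUE, connectivity = 8,
                          resize_longest_side = 400) {
  check_hue_window(hue_center, hue_half_width)
  for (v in c(intensity_min, saturation_min, white_s_max, white_i_min))
    if (v < 0 || v > 1)
      stop_tongueseg("thresholds must be in [0, 1]", "tongueseg_config_error")
  if (length(yellow_band) != 2L || yellow_band[1] >= yellow_band[2])
    stop_tongueseg("`yellow_band` must be increasing shifted-hue bounds",
                   "tongueseg_config_error")
  if (!enclosure_min_neighbors %in% 1:8)
    stop_tongueseg("`enclosure_min_neighbors` must be in 1..8", "tongueseg_config_error")
  if (!is.null(seed) && length(seed) != 2L)
    stop_tongueseg("`seed` must be c(row, col)", "tongueseg_config_error")
  if (seed_search_fraction <= 0 || seed_search_fraction > 1)
    stop_tongueseg("`seed_search_fraction` must be in (0, 1]", "tongueseg_config_error")
  structure(list(hue_center = hue_center, hue_half_width = hue_half_width,
                 intensity_min = intensity_min, saturation_min = saturation_min,
                 white_s_max = white_s_max, white_i_min = white_i_min,
                 yellow_band = yellow_band,
                 enclosure_min_neighbors = as.integer(enclosure_min_neighbors),
                 seed = if (!is.null(seed)) as.integer(seed),
                 seed_search_fraction = seed_search_fraction,
                 fill_enclosed_holes = isTRUE(fill_enclosed_holes),
                 connectivity = check_connectivity(connectivity),
                 resize_longest_side = resize_longest_side),
            class = "fusion_params")
}

## Effective structuring-element radius: 5 px per 400 px of image width.
effective_se_radius <- function(se_radius, width) {
  if (!is.null(se_radius)) return(as.integer(se_radius))
  max(1L, as.integer(round(5 * width / 400)))
}
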