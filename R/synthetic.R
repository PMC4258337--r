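## Synthetic tongue-scene generator with exact ground truth. The geometry is
## deliberately schematic (ellipse tongue, crescent lip, face background):
## what matters is that it reproduces the *chromatic structure* the
## segmenters rely on -- a red connected tongue, an equally red lip separated
## from it only by a low-intensity boundary band, a face whose hue lies
## outside the red window, and optional thick white/yellow coating patches
## strictly interior to the tongue.

#' Color table for the seven tongue presets
#'
#' The seven classical tongue classes: five tongue-body colors (light red,
#' light white, red, deep red, purple) plus red tongues bearing a thick
#' white or yellow coating. Body colors all fall in the shifted-hue red
#' window with saturation and intensity comfortably above the substance
#' thresholds; the white coating is near-achromatic and bright, the yellow
#' coating sits in the yellow hue band.
#'
#' @return named list: for each preset, `body` RGB and `coating` RGB (or
#'   `NULL`) and the default coating area fraction.
#' @export
tongue_presets <- function() {
  red_body <- c(0.75, 0.25, 0.30)
  list(
    light_red = list(body = c(0.85, 0.42, 0.45), coating = NULL, coating_fraction = 0),
    light_white = list(body = c(0.82, 0.45, 0.50), coating = NULL, coating_fraction = 0),
    red = list(body = red_body, coating = NULL, coating_fraction = 0),
    deep_red = list(body = c(0.60, 0.16, 0.22), coating = NULL, coating_fraction = 0),
    purple = list(body = c(0.52, 0.22, 0.32), coating = NULL, coating_fraction = 0),
    thick_white_coating = list(body = red_body, coating = c(0.84, 0.84, 0.86),
                               coating_fraction = 0.4),
    thick_yellow_coating = list(body = red_body, coating = c(0.75, 0.62, 0.28),
                                coating_fraction = 0.4)
  )
}

#' Specify a synthetic tongue scene
#'
#' @param canvas `c(height, width)` in pixels.
#' @param body_rgb tongue-body color (RGB in `[0, 1]`).
#' @param coating_rgb coating color, or `NULL` for no coating.
#' @param coating_fraction fraction of the tongue area covered by the
#'   (concentric, strictly interior) coating patch.
#' @param face_rgb face background color; its hue must stay outside the
#'   red window.
#' @param lip_rgb lip color; defaults to the tongue body color (worst case
#'   for hue-only methods).
#' @param boundary_rgb color of the low-intensity band separating tongue
#'   from lip (and shading the tongue margin); a dark desaturated
#'   green-grey, intensity 0.075.
#' @param boundary_intensity intensity of the boundary band; the band
#'   color is rescaled to this channel mean.
#' @param tongue_center_frac,tongue_axes_frac ellipse center and semi-axes
#'   as fractions of canvas height/width.
#' @param rim_scale outer scale of the dark band around the tongue
#'   (relative to the tongue ellipse).
#' @param lip_outer_scale outer scale of the lip crescent (upper half
#'   band between `rim_scale` and this value).
#' @param lip_bridge if `TRUE`, a narrow gap of the boundary band above
#'   the tongue is brightened to intensity `bridge_intensity` with the
#'   tongue's hue, bridging tongue and lip for any method whose intensity
#'   floor lies below it.
#' @param bridge_intensity intensity of the bridge pixels (default 0.20).
#' @param tongue if `FALSE`, the scene contains only face background (no
#'   tongue, rim or lip) -- a negative control.
#' @param noise_sigma standard deviation of the clipped additive Gaussian
#'   channel noise (default 0.02, mild camera noise).
#' @param rng_seed integer seed; identical seeds give bit-identical scenes.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(canvas = c(200, 200),
                       body_rgb = c(0.75, 0.25, 0.30),
                       coating_rgb = NULL, coating_fraction = 0,
                       face_rgb = c(0.78, 0.62, 0.40),
                       lip_rgb = NULL,
                       boundary_rgb = c(0.06, 0.09, 0.075),
                       boundary_intensity = 0.075,
                       tongue_center_frac = c(0.55, 0.50),
                       tongue_axes_frac = c(0.26, 0.22),
                       rim_scale = 1.07, lip_outer_scale = 1.30,
                       lip_bridge = FALSE, bridge_intensity = 0.20,
                       tongue = TRUE, noise_sigma = 0.02, rng_seed = 1L) {
  if (length(canvas) != 2L || any(canvas < 8))
    stop_tongueseg("`canvas` must be c(height, width), each >= 8", "tongueseg_config_error")
  if (coating_fraction < 0 || coating_fraction >= 1)
    stop_tongueseg("`coating_fraction` must be in [0, 1)", "tongueseg_config_error")
  if (any(tongue_center_frac + tongue_axes_frac * rim_scale > 1) ||
      any(tongue_center_frac - tongue_axes_frac * rim_scale < 0))
    stop_tongueseg("tongue ellipse (with rim) must fit inside the canvas",
                   "tongueseg_config_error")
  if (!is.null(coating_rgb) && coating_fraction <= 0)
    stop_tongueseg("a coating color needs a positive `coating_fraction`",
                   "tongueseg_config_error")
  structure(list(canvas = as.integer(canvas), body_rgb = body_rgb,
                 coating_rgb = coating_rgb, coating_fraction = coating_fraction,
                 face_rgb = face_rgb, lip_rgb = lip_rgb %||% body_rgb,
                 boundary_rgb = boundary_rgb,
                 boundary_intensity = boundary_intensity,
                 tongue_center_frac = tongue_center_frac,
                 tongue_axes_frac = tongue_axes_frac,
                 rim_scale = rim_scale, lip_outer_scale = lip_outer_scale,
                 lip_bridge = isTRUE(lip_bridge),
                 bridge_intensity = bridge_intensity,
                 tongue = isTRUE(tongue),
                 noise_sigma = noise_sigma, rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

#' Render a synthetic tongue scene
#'
#' Paints the face background, tongue ellipse, dark margin band, lip
#' crescent and optional coating patch, then adds clipped Gaussian channel
#' noise. Ground truth is exact: the tongue mask is the tongue ellipse
#' (coating included, lip and margin excluded) and the coating submask the
#' interior patch.
#'
#' @param spec a [scene_spec()].
#' @return list of class `tongue_scene`: `image` ([rgb_image()]), `truth`
#'   (tongue mask), `coating` (coating submask), and `spec`.
#' @export
make_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("`spec` must be a scene_spec")
  H <- spec$canvas[1]; W <- spec$canvas[2]
  r <- matrix(seq_len(H), H, W)
  c_ <- matrix(seq_len(W), H, W, byrow = TRUE)
  cr <- spec$tongue_center_frac[1] * H
  cc <- spec$tongue_center_frac[2] * W
  ar <- spec$tongue_axes_frac[1] * H
  ac <- spec$tongue_axes_frac[2] * W
  ## Elliptical coordinate: e <= 1 inside the tongue; the area inside
  ## e <= t is a fraction t of the tongue area, so the coating patch is
  ## simply e <= coating_fraction.
  e <- ((r - cr) / ar)^2 + ((c_ - cc) / ac)^2

  img <- array(rep(spec$face_rgb, each = H * W), dim = c(H, W, 3))
  paint <- function(img, where, rgb) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[where] <- rgb[ch]
      img[, , ch] <- plane
    }
    img
  }
  truth <- matrix(FALSE, H, W)
  coating <- matrix(FALSE, H, W)

  if (spec$tongue) {
    band_rgb <- spec$boundary_rgb * spec$boundary_intensity /
      mean(spec$boundary_rgb)
    lip_zone <- e > spec$rim_scale^2 & e <= spec$lip_outer_scale^2 & r < cr
    img <- paint(img, lip_zone, spec$lip_rgb)
    rim <- e > 1 & e <= spec$rim_scale^2
    img <- paint(img, rim, band_rgb)
    img <- paint(img, e <= 1, spec$body_rgb)
    truth <- e <= 1
    if (!is.null(spec$coating_rgb)) {
      coating <- e <= spec$coating_fraction
      img <- paint(img, coating, spec$coating_rgb)
    }
    if (spec$lip_bridge) {
      bridge <- rim & r < cr & abs(c_ - cc) <= 2
      img <- paint(img, bridge,
                   spec$body_rgb * spec$bridge_intensity / mean(spec$body_rgb))
    }
  }

  if (spec$noise_sigma > 0) {
    img <- with_seed(spec$rng_seed, {
      img + array(rnorm(length(img), 0, spec$noise_sigma), dim = dim(img))
    })
    img <- pmin(pmax(img, 0), 1)
  }
  structure(list(image = rgb_image(img), truth = truth, coating = coating,
                 spec = spec),
            class = "tongue_scene")
}

#' @export
print.tongue_scene <- function(x, ...) {
  cat(sprintf("<tongue_scene> %d x %d, tongue %d px, coating %d px\n",
              nrow(x$truth), ncol(x$truth), sum(x$truth), sum(x$coating)))
  invisible(x)
}

#' Render one of the seven preset tongue scenes
#'
#' @param name preset name, one of `names(tongue_presets())`.
#' @param canvas `c(height, width)`; default 200 x 200.
#' @param rng_seed integer noise seed.
#' @param ... further arguments passed to [scene_spec()] (e.g.
#'   `noise_sigma`, `lip_bridge`).
#' @return a `tongue_scene` (see [make_scene()]).
#' @export
#' @examples
#' sc <- preset_scene("thick_white_coating", rng_seed = 7)
#' sum(sc$coating) / sum(sc$truth)  # about 0.4
preset_scene <- function(name, canvas = c(200, 200), rng_seed = 1L, ...) {
  presets <- tongue_presets()
  if (!name %in% names(presets))
    stop_tongueseg(sprintf("unknown preset '%s'", name), "tongueseg_config_error")
  pr <- presets[[name]]
  make_scene(scene_spec(canvas = canvas, body_rgb = pr$body,
                        coating_rgb = pr$coating,
                        coating_fraction = pr$coating_fraction,
                        rng_seed = rng_seed, ...))
}
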