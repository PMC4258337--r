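## Pixel-level segmentation accuracy: confusion counts against a reference
## mask and the recognition/error rates, plus a batch comparison table
## across methods and scenes.

#' Confusion counts between a predicted and a reference mask
#'
#' Per-pixel 2x2 tally with `ref` as ground truth: `tp` = true tongue
#' pixels recovered, `fn` = tongue pixels missed, `fp` = background pixels
#' claimed as tongue, `tn` = background pixels left alone. The four counts
#' always sum to the pixel count.
#'
#' @param pred,ref logical masks of identical shape.
#' @return object of class `confusion_counts`.
#' @export
confusion <- function(pred, ref) {
  assert_mask(pred, "pred"); assert_mask(ref, "ref")
  assert_same_shape(pred, ref, "pred and ref")
  structure(list(tp = sum(pred & ref), fn = sum(!pred & ref),
                 fp = sum(pred & !ref), tn = sum(!pred & !ref)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FN=%d FP=%d TN=%d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Recognition and error rates
#'
#' Recognition rate \eqn{\eta = TP/(TP+FN)}, the fraction of true tongue
#' pixels recovered; error rate \eqn{\varepsilon = FP/(FP+TP)}, the
#' fraction of predicted tongue pixels that are actually background. A
#' rate whose denominator is zero (empty reference, empty prediction) is
#' reported as `NA`, never as 0.
#'
#' @param cc a [confusion()] result.
#' @return object of class `tongue_metrics`: list with `recognition` and
#'   `error`, each in `[0, 1]` or `NA`.
#' @export
seg_metrics <- function(cc) {
  eta <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_
  eps <- if (cc$tp + cc$fp > 0) cc$fp / (cc$fp + cc$tp) else NA_real_
  structure(list(recognition = eta, error = eps), class = "tongue_metrics")
}

#' @export
print.tongue_metrics <- function(x, ...) {
  cat(sprintf("<tongue_metrics> recognition = %s, error = %s\n",
              ifelse(is.na(x$recognition), "NA", sprintf("%.2f%%", 100 * x$recognition)),
              ifelse(is.na(x$error), "NA", sprintf("%.2f%%", 100 * x$error))))
  invisible(x)
}

segmenter_for <- function(method) {
  switch(method,
         morph = function(img, p) segment_morph_hsi(img, p %||% morph_params()),
         sequential = function(img, p) segment_sequential_hsi(img, p %||% seq_params()),
         greedy = function(img, p) segment_greedy_fusion(img, p %||% fusion_params()),
         stop_tongueseg(sprintf("unknown method '%s'", method), "tongueseg_config_error"))
}

#' Compare segmentation methods across scenes
#'
#' Runs each segmenter on each scene and tabulates recognition and error
#' rates (as percentages, 2 decimals) plus wall-clock seconds per run
#' (informational only). A failing cell (e.g. seed failure on a scene
#' without a tongue) is recorded as `NA` with the error message in
#' `status`; the batch always completes.
#'
#' @param scenes list of scenes; each a list with elements `image` (an
#'   [rgb_image()]), `truth` (reference mask), and optionally `id`,
#'   `preset`, `seed`.
#' @param methods character vector from `"morph"`, `"sequential"`,
#'   `"greedy"`.
#' @param configs named list of parameter objects per method (defaults
#'   used where absent).
#' @return data.frame with columns `scene_id`, `preset`, `seed`, `method`,
#'   `eta_pct`, `eps_pct`, `seconds`, `status`.
#' @export
compare_methods <- function(scenes, methods = c("morph", "sequential", "greedy"),
                            configs = list()) {
  if (length(scenes) < 1L || length(methods) < 1L)
    stop_tongueseg("need at least one scene and one method", "tongueseg_config_error")
  rows <- list()
  for (si in seq_along(scenes)) {
    sc <- scenes[[si]]
    for (m in methods) {
      t0 <- proc.time()[["elapsed"]]
      ans <- tryCatch({
        mask <- segmenter_for(m)(sc$image, configs[[m]])
        mt <- seg_metrics(confusion(mask, sc$truth))
        list(eta = 100 * mt$recognition, eps = 100 * mt$error, status = "ok")
      }, error = function(e) list(eta = NA_real_, eps = NA_real_,
                                  status = conditionMessage(e)))
      rows[[length(rows) + 1L]] <- data.frame(
        scene_id = sc$id %||% si, preset = sc$preset %||% NA_character_,
        seed = sc$seed %||% NA_integer_, method = m,
        eta_pct = round(ans$eta, 2), eps_pct = round(ans$eps, 2),
        seconds = round(proc.time()[["elapsed"]] - t0, 3),
        status = ans$status, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
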