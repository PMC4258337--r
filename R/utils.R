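## Shared helpers: circular hue arithmetic, mask plumbing, condition classes.
## Coordinate convention (used everywhere): row-major matrices, origin at the
## top-left corner, pixel coordinates are (row, col), 1-based in R.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Circular distance between hue angles
#'
#' Shortest angular distance between two hues on the 360-degree circle.
#' `NA` hues (undefined hue, i.e. achromatic pixels) yield `NA`.
#'
#' @param a,b hue angles in degrees; vectors are recycled.
#' @return numeric vector of distances in `[0, 180]`.
#' @export
#' @examples
#' hue_circ_dist(350, 10)  # 20, across the wrap
hue_circ_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

stop_tongueseg <- function(msg, class) {
  stop(structure(
    class = c(class, "tongueseg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("`%s` must be a logical matrix", arg))
  invisible(mask)
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop_tongueseg(sprintf("shape mismatch between %s", what), "tongueseg_shape_error")
  invisible(NULL)
}

check_connectivity <- function(connectivity) {
  if (!connectivity %in% c(4L, 8L))
    stop_tongueseg("`connectivity` must be 4 or 8", "tongueseg_config_error")
  as.integer(connectivity)
}

## Disk structuring element of the given pixel radius (odd-sized brush).
disk_kernel <- function(radius) {
  radius <- as.integer(radius)
  if (radius < 1L) stop_tongueseg("`se_radius` must be >= 1", "tongueseg_config_error")
  EBImage::makeBrush(2L * radius + 1L, shape = "disc")
}

## Nearest-neighbour resize of a matrix or H x W x C array; deterministic,
## used both to shrink images before segmentation and to upsample masks back.
resize_nearest <- function(x, new_h, new_w) {
  d <- dim(x)
  rows <- pmin(d[1], floor((seq_len(new_h) - 0.5) * d[1] / new_h) + 1L)
  cols <- pmin(d[2], floor((seq_len(new_w) - 0.5) * d[2] / new_w) + 1L)
  if (length(d) == 2L) x[rows, cols, drop = FALSE] else x[rows, cols, , drop = FALSE]
}

## Evaluate an expression under a fixed RNG seed, restoring the caller's
## RNG state afterwards (keeps the generator reproducible without side effects).
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
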