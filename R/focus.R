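#' Normalized gradient-energy focus metric
#'
#' Sharpness score of an image region: mean squared gradient magnitude
#' (central differences) divided by the squared mean intensity. The
#' normalization makes the score invariant to global intensity rescaling,
#' so plane selection is robust to illumination drift between stacks.
#'
#' @param region Intensity matrix, at least 16 x 16 px.
#' @return A non-negative scalar; 0 for a constant region.
#' @export
focus_metric <- function(region) {
  stopifnot(is.matrix(region))
  if (nrow(region) < 16 || ncol(region) < 16) {
    stop("Region must be at least 16 x 16 px.", call. = FALSE)
  }
  m <- mean(region)
  if (m == 0 || stats::sd(region) == 0) return(0)
  core <- region[2:(nrow(region) - 1), 2:(ncol(region) - 1)]
  gy <- (region[3:nrow(region), 2:(ncol(region) - 1)] -
           region[1:(nrow(region) - 2), 2:(ncol(region) - 1)]) / 2
  gx <- (region[2:(nrow(region) - 1), 3:ncol(region)] -
           region[2:(nrow(region) - 1), 1:(ncol(region) - 2)]) / 2
  mean(gx^2 + gy^2) / m^2
}

#' Select the in-focus plane of a z-stack for a region of interest
#'
#' Scores every page of the stack with [focus_metric()] inside the ROI and
#' returns the sharpest one; ties break toward the lowest z. This is the
#' software counterpart of per-object focal selection on a multi-position
#' stack, where objects sit at different depths and each is measured on its
#' own best plane.
#'
#' @param stack List of intensity matrices (pages of one z-stack).
#' @param roi ROI as `c(xmin, xmax, ymin, ymax)` in 1-based pixel indices,
#'   or `NULL` for the full frame.
#' @param z Optional z positions of the pages, um (defaults to page index).
#' @return A list: `index` of the chosen page, `z` of that page, and
#'   `scores`, a tibble of per-plane `z` and `score`.
#' @export
best_plane <- function(stack, roi = NULL, z = NULL) {
  stopifnot(is.list(stack), length(stack) >= 2)
  if (is.null(z)) z <- seq_along(stack)
  stopifnot(length(z) == length(stack))
  crop <- function(m) {
    if (is.null(roi)) return(m)
    xi <- max(1, floor(roi[1])):min(ncol(m), ceiling(roi[2]))
    yi <- max(1, floor(roi[3])):min(nrow(m), ceiling(roi[4]))
    if (length(xi) < 16 || length(yi) < 16) {
      stop("ROI is empty or smaller than 16 x 16 px.", call. = FALSE)
    }
    m[yi, xi, drop = FALSE]
  }
  scores <- vapply(stack, function(p) focus_metric(crop(p)), numeric(1))
  best <- which.max(scores) # first max -> lowest z on ties
  list(index = best, z = z[best],
       scores = tibble::tibble(z = z, score = scores))
}
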