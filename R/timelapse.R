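#' Render a time-lapse of z-stacks from a scene
#'
#' Renders one z-stack (one page per plane of `stack_plan`) at every
#' acquisition time from 0 to `duration_h` in steps of `cadence_h`, together
#' with the ground-truth table from [scene_truth()]. With `dir = NULL` the
#' frames are kept in memory; otherwise each timepoint is written as a
#' multi-page 16-bit grayscale TIFF `t0000.tif`, `t0001.tif`, ... with the
#' ground truth as `groundtruth.csv` and the calibration (pixel size, z
#' planes, timestamps, seed) as a `calibration.yaml` sidecar. Output is
#' byte-identical across runs for a fixed scene seed.
#'
#' @param scene A scene from [spherical_scene()], [tubular_scene()] or
#'   [yeast_scene()].
#' @param duration_h Total duration, hours.
#' @param cadence_h Acquisition interval, hours (e.g. 1.5 for the 90-minute
#'   cadence used for cysts, 0.25 for the 15-minute yeast cadence).
#' @param stack_plan Z positions of the stack pages, um (see [plan_stack()]).
#'   Default `0` (single plane).
#' @param dir Output directory, or `NULL` (default) for an in-memory result.
#' @return A list with `timelapse` (a `timelapse` object) and `truth`
#'   (tibble).
#' @export
make_timelapse <- function(scene, duration_h, cadence_h, stack_plan = 0,
                           dir = NULL) {
  stopifnot(cadence_h > 0, duration_h >= 0)
  times <- seq(0, duration_h, by = cadence_h)
  truth <- scene_truth(scene, times)
  render_stack <- function(tm) {
    lapply(stack_plan, function(z) render_frame(scene, z = z, time = tm))
  }
  if (is.null(dir)) {
    frames <- lapply(times, render_stack)
    tl <- new_timelapse(times = times, z_planes = stack_plan,
                        pixel_equiv = scene$pixel_equiv, frames = frames)
  } else {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, sprintf("t%04d.tif", seq_along(times) - 1))
    for (i in seq_along(times)) {
      pages <- lapply(render_stack(times[i]), function(m) m / 65535)
      tiff::writeTIFF(pages, paths[i], bits.per.sample = 16,
                      compression = "none")
    }
    cal <- list(
      pixel_equiv = scene$pixel_equiv,
      z_planes = as.numeric(stack_plan),
      times_h = as.numeric(times),
      kind = scene$kind,
      i0 = scene$i0,
      seed = scene$seed
    )
    yaml::write_yaml(cal, file.path(dir, "calibration.yaml"))
    utils::write.csv(truth, file.path(dir, "groundtruth.csv"),
                     row.names = FALSE)
    tl <- new_timelapse(times = times, z_planes = stack_plan,
                        pixel_equiv = scene$pixel_equiv, paths = paths)
  }
  list(timelapse = tl, truth = truth)
}

new_timelapse <- function(times, z_planes, pixel_equiv, frames = NULL,
                          paths = NULL) {
  structure(
    list(times = times, z_planes = z_planes, pixel_equiv = pixel_equiv,
         frames = frames, paths = paths),
    class = "timelapse"
  )
}

#' @export
print.timelapse <- function(x, ...) {
  cat(sprintf(
    "<timelapse> %d timepoints (%g..%g h), %d z-plane(s), %g um/px, %s\n",
    length(x$times), min(x$times), max(x$times), length(x$z_planes),
    x$pixel_equiv, if (is.null(x$paths)) "in memory" else "on disk"))
  invisible(x)
}

#' Number of timepoints in a timelapse
#' @param tl A `timelapse`.
#' @return Integer count.
#' @export
n_timepoints <- function(tl) length(tl$times)

#' Fetch the z-stack of one timepoint
#'
#' @param tl A `timelapse` from [make_timelapse()] or [read_timelapse()].
#' @param i Timepoint index (1-based).
#' @return A list of intensity matrices (counts), one per z plane.
#' @export
get_stack <- function(tl, i) {
  stopifnot(inherits(tl, "timelapse"), i >= 1, i <= length(tl$times))
  if (!is.null(tl$frames)) return(tl$frames[[i]])
  pages <- tiff::readTIFF(tl$paths[i], all = TRUE)
  n_pages <- length(pages)
  if (n_pages != length(tl$z_planes)) {
    stop("File ", tl$paths[i], " has ", n_pages, " pages; calibration says ",
         length(tl$z_planes), ".", call. = FALSE)
  }
  lapply(pages, function(p) p * 65535)
}

#' Read a time-lapse directory
#'
#' Loads a directory written by [make_timelapse()] (or any acquisition laid
#' out the same way): files `t<index>.tif` with one page per z plane and a
#' `calibration.yaml` sidecar carrying pixel size, z planes and timestamps.
#' Frames are loaded lazily, sorted by time index regardless of listing
#' order; inconsistent page counts across files are reported as an error
#' naming the offending files.
#'
#' @param dir Directory path.
#' @return A `timelapse` object.
#' @export
read_timelapse <- function(dir) {
  cal_path <- file.path(dir, "calibration.yaml")
  if (!file.exists(cal_path)) {
    stop("Missing calibration sidecar ", cal_path, call. = FALSE)
  }
  cal <- yaml::read_yaml(cal_path)
  for (f in c("pixel_equiv", "z_planes", "times_h")) {
    if (is.null(cal[[f]])) {
      stop("Calibration sidecar lacks field '", f, "'.", call. = FALSE)
    }
  }
  files <- list.files(dir, pattern = "^t\\d+\\.tif$", full.names = TRUE)
  if (length(files) == 0) stop("No t<index>.tif files in ", dir,
                               call. = FALSE)
  idx <- as.integer(sub("^t(\\d+)\\.tif$", "\\1", basename(files)))
  files <- files[order(idx)]
  if (length(files) != length(cal$times_h)) {
    stop("Found ", length(files), " frames but calibration lists ",
         length(cal$times_h), " timepoints.", call. = FALSE)
  }
  counts <- vapply(files, function(f) {
    NROW(tiff::readTIFF(f, all = TRUE, payload = FALSE))
  }, numeric(1))
  expected <- length(cal$z_planes)
  bad <- counts != expected
  if (any(bad)) {
    stop("Inconsistent page counts (expected ", expected, "): ",
         paste0(basename(files[bad]), " (", counts[bad], ")",
                collapse = ", "), call. = FALSE)
  }
  new_timelapse(times = as.numeric(cal$times_h),
                z_planes = as.numeric(cal$z_planes),
                pixel_equiv = cal$pixel_equiv, paths = files)
}

#' Write measurement records and a reproducibility report
#'
#' Writes each named tibble of `records` to `<name>.csv` (units belong in
#' the column names; stable column order; deterministic bytes for identical
#' input) and a `report.json` carrying the run configuration, its hash and
#' the seeds, so a run can be reproduced exactly.
#'
#' @param records Named list of data frames.
#' @param dir Output directory (created if needed).
#' @param config Optional named list recorded in the report (seeds, scene
#'   and fit parameters, ...).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(records, dir, config = list()) {
  stopifnot(is.list(records))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(names(records)) && length(records) > 0) {
    stop("`records` must be a named list of data frames.", call. = FALSE)
  }
  paths <- character(0)
  for (nm in names(records)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(records[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  report <- list(
    config = config,
    config_hash = digest::digest(config),
    files = basename(paths),
    package_version = as.character(utils::packageVersion("capsmorph"))
  )
  rp <- file.path(dir, "report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, rp))
}
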