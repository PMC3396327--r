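# Image and result I/O: 8-bit grayscale PNG for scenes, CSV for per-scene
# tables, JSON (with a full config snapshot) for summaries.

#' Read and write scenes as 8-bit grayscale PNG
#'
#' Scene pixels are quantized to the 8-bit grid at generation time, so a
#' write/read round trip reproduces the scene bit-exactly.
#'
#' @param scene A `scene_image` or plain scene matrix in `[0, 1]`.
#' @param path PNG file path.
#' @return `write_scene_png()` returns `path` invisibly; `read_scene_png()`
#'   returns a `scene_image` (with `id` taken from the file name).
#' @export
write_scene_png <- function(scene, path) {
  px <- if (inherits(scene, "scene_image")) scene$pixels else scene
  if (!is.matrix(px) || min(px) < 0 || max(px) > 1)
    stop_chord("chord_domain_error", "scene pixels must be a matrix in [0, 1]")
  png::writePNG(px, path)
  invisible(path)
}

#' @rdname write_scene_png
#' @export
read_scene_png <- function(path) {
  if (!file.exists(path))
    stop_chord("chord_parse_error", "PNG file not found: %s", path)
  px <- tryCatch(png::readPNG(path), error = function(e)
    stop_chord("chord_parse_error", "malformed PNG %s: %s", path,
               conditionMessage(e)))
  if (length(dim(px)) == 3) px <- px[, , 1]   # grayscale written as channels
  structure(list(pixels = px, centers = NULL, spec = NULL,
                 id = sub("\\.png$", "", basename(path))),
            class = "scene_image")
}

#' Write an experiment result to a directory
#'
#' Produces `<kind>_scenes.csv` (the per-scene table), `<kind>_summary.json`
#' (condition summaries, regression block if any, and the full config and
#' seed snapshot, so the artifact is self-describing) and `<kind>.png`
#' (the default plot).
#'
#' @param result A `chord_experiment`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "chord_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, result$kind)
  csv <- paste0(base, "_scenes.csv")
  utils::write.csv(result$data, csv, row.names = FALSE)
  js <- paste0(base, "_summary.json")
  payload <- list(kind = result$kind, seed = result$seed,
                  summary = result$summary, regression = result$regression,
                  config = unclass(result$config))
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  fig <- paste0(base, ".png")
  grDevices::png(fig, width = 640, height = 480)
  plot(result)
  grDevices::dev.off()
  invisible(c(csv = csv, json = js, png = fig))
}
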