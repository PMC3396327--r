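#' Configuration for the scene-representation pipeline
#'
#' Collects every tunable of the encoder, generator, memory and experiment
#' runners in one validated list.  Unknown keys are rejected so that stale
#' configuration files fail loudly.
#'
#' @param scene_size Side of the square scene raster in pixels.
#' @param roi_size Side of the square object patch / region of interest.
#' @param ct_scale Leading constant of the chorus transform: `"inv_sqrt_n"`
#'   (default, `1/sqrt(n)`), `"inv_n"` (`1/n`) or `"one"`.
#' @param minkowski_p Minkowski exponent of the measurement-space metric
#'   (`2` = Euclidean; must be `>= 1`).
#' @param gabor_scales Gabor filter scales (carrier wavelengths) in pixels.
#' @param gabor_orientations Gabor carrier orientations in degrees; `0` is a
#'   horizontal carrier, i.e. the filter responds to vertical structure.
#' @param gabor_sigma_ratio Gaussian-envelope sigma as a fraction of the
#'   carrier wavelength.
#' @param gabor_pool_grid Pooling grid resolution: mean filter-energy is taken
#'   over a `gabor_pool_grid x gabor_pool_grid` grid of equal cells.
#' @param detect_sigma Sigma (pixels) of the Gaussian used for region-of-interest
#'   detection by convolution-argmax.
#' @param n_shape_prototypes Number of shape prototypes for the chorus code.
#' @param layout_sigma Sigma (pixels) of the Gaussian patches in rendered
#'   layout images.
#' @param layout_render_scale Factor mapping an observed inter-object
#'   displacement to a rendered offset from the canvas-centre key patch.  The
#'   default `0.5` keeps every geometrically feasible displacement (components
#'   up to 100 px) on the canvas.
#' @param layout_grid_rows,layout_grid_cols Row/column displacement offsets
#'   (scene units, relative to the fixated object) whose crossing defines the
#'   10 layout prototypes for top fixation; the bottom-fixation grid is the
#'   mirror image (all offsets negated).
#' @param lsh_tables,lsh_bits Hash-index geometry: number of tables and number
#'   of sign bits per table address.
#' @param object_categories Parametric object families known to the generator.
#' @param n_familiar_categories How many of `object_categories` (taken from the
#'   front) count as familiar; the remainder are held out as novel categories.
#' @param n_object_pool Number of distinct familiar exemplars in a training
#'   catalog's object pool.
#' @param n_train_scenes Default training-catalog size.
#' @param train_displacement_rows,train_displacement_cols Row/column components
#'   whose crossing defines the catalog's inventory of familiar layouts.
#' @param novel_layout_margin Minimum Chebyshev distance (pixels) of a "novel
#'   layout" displacement from every training displacement.
#' @param displacement_step,displacement_levels Step size (pixels) and number
#'   of levels of the graded-displacement experiment.
#' @param nn_k Number of nearest neighbours retrieved per query.
#'
#' @return An object of class `chord_config` (a named list).
#' @examples
#' cfg <- chord_config()
#' cfg$detect_sigma
#' @export
chord_config <- function(scene_size = 150,
                         roi_size = 50,
                         ct_scale = c("inv_sqrt_n", "inv_n", "one"),
                         minkowski_p = 2,
                         gabor_scales = c(5, 10),
                         gabor_orientations = c(0, 90),
                         gabor_sigma_ratio = 0.56,
                         gabor_pool_grid = 5,
                         detect_sigma = 17.5,
                         n_shape_prototypes = 10,
                         layout_sigma = 10,
                         layout_render_scale = 0.5,
                         layout_grid_rows = c(52, 64, 76, 88, 100),
                         layout_grid_cols = c(-25, 25),
                         lsh_tables = 10,
                         lsh_bits = 64,
                         object_categories = c("ellipse", "rectangle",
                                               "annulus", "triangle", "blob",
                                               "ring_texture", "cross",
                                               "grating"),
                         n_familiar_categories = 6,
                         n_object_pool = 60,
                         n_train_scenes = 2000,
                         train_displacement_rows = c(52, 64, 76, 88, 100),
                         train_displacement_cols = c(-35, -12, 12, 35),
                         novel_layout_margin = 8,
                         displacement_step = 10,
                         displacement_levels = 5,
                         nn_k = 5) {
  ct_scale <- match.arg(ct_scale)
  cfg <- list(
    scene_size = scene_size, roi_size = roi_size, ct_scale = ct_scale,
    minkowski_p = minkowski_p, gabor_scales = gabor_scales,
    gabor_orientations = gabor_orientations,
    gabor_sigma_ratio = gabor_sigma_ratio, gabor_pool_grid = gabor_pool_grid,
    detect_sigma = detect_sigma, n_shape_prototypes = n_shape_prototypes,
    layout_sigma = layout_sigma, layout_render_scale = layout_render_scale,
    layout_grid_rows = layout_grid_rows, layout_grid_cols = layout_grid_cols,
    lsh_tables = lsh_tables, lsh_bits = lsh_bits,
    object_categories = object_categories,
    n_familiar_categories = n_familiar_categories,
    n_object_pool = n_object_pool, n_train_scenes = n_train_scenes,
    train_displacement_rows = train_displacement_rows,
    train_displacement_cols = train_displacement_cols,
    novel_layout_margin = novel_layout_margin,
    displacement_step = displacement_step,
    displacement_levels = displacement_levels,
    nn_k = nn_k
  )
  validate_config(cfg)
  structure(cfg, class = "chord_config")
}

validate_config <- function(cfg) {
  if (!is_count(cfg$scene_size, 10) || !is_count(cfg$roi_size, 2) ||
      cfg$roi_size >= cfg$scene_size)
    stop_chord("chord_config_error", "invalid scene/roi geometry")
  if (!is.numeric(cfg$minkowski_p) || cfg$minkowski_p < 1)
    stop_chord("chord_config_error", "minkowski_p must be >= 1")
  if (!all(cfg$gabor_orientations %in% c(0, 90)))
    stop_chord("chord_config_error",
               "only axis-aligned Gabor orientations (0, 90) are supported")
  if (!is_count(cfg$gabor_pool_grid) || cfg$roi_size %% cfg$gabor_pool_grid != 0)
    stop_chord("chord_config_error", "gabor_pool_grid must divide roi_size")
  if (!is.numeric(cfg$detect_sigma) || cfg$detect_sigma <= 0)
    stop_chord("chord_config_error", "detect_sigma must be positive")
  if (!is_count(cfg$n_shape_prototypes))
    stop_chord("chord_config_error", "n_shape_prototypes must be a count")
  if (length(cfg$layout_grid_rows) * length(cfg$layout_grid_cols) < 1)
    stop_chord("chord_config_error", "empty layout grid")
  if (!is_count(cfg$lsh_tables) || !is_count(cfg$lsh_bits))
    stop_chord("chord_config_error", "invalid hash-table geometry")
  if (!is_count(cfg$n_familiar_categories) ||
      cfg$n_familiar_categories > length(cfg$object_categories))
    stop_chord("chord_config_error",
               "n_familiar_categories exceeds the number of object families")
  invisible(cfg)
}

#' Read a configuration from a YAML file
#'
#' Keys absent from the file keep their defaults; keys unknown to
#' [chord_config()] raise a configuration error.
#'
#' @param path Path to a YAML file of configuration overrides.
#' @return A validated `chord_config` object.
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop_chord("chord_parse_error", "config file not found: %s", path)
  vals <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop_chord("chord_parse_error", "malformed YAML in %s: %s",
               path, conditionMessage(e)))
  if (is.null(vals)) vals <- list()
  known <- names(formals(chord_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_chord("chord_config_error", "unknown config key(s) in %s: %s",
               path, paste(bad, collapse = ", "))
  do.call(chord_config, vals)
}

#' Write a configuration to a YAML file
#' @param cfg A `chord_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "chord_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.chord_config <- function(x, ...) {
  cat("<chord_config>\n")
  cat(sprintf("  scene %dx%d, ROI %dx%d, %d shape prototypes, CT scale %s\n",
              x$scene_size, x$scene_size, x$roi_size, x$roi_size,
              x$n_shape_prototypes, x$ct_scale))
  cat(sprintf("  Gabor scales {%s} px, orientations {%s} deg, %dx%d pooling\n",
              paste(x$gabor_scales, collapse = ", "),
              paste(x$gabor_orientations, collapse = ", "),
              x$gabor_pool_grid, x$gabor_pool_grid))
  cat(sprintf("  LSH: %d tables x %d bits; detection sigma %.1f px\n",
              x$lsh_tables, x$lsh_bits, x$detect_sigma))
  invisible(x)
}
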