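# Scene front end: Gaussian-convolution ROI detection, Gabor feature
# encoding, shape-prototype chorus codes, fixation-dependent layout codes,
# and assembly of the three-part scene representation.
#
# All filtering is axis-aligned and separable, so convolutions are carried
# out as banded-matrix products with exact zero padding (black background).

# Gabor bank: for each scale, row/column tap vectors of the quadrature pair.
# Orientation 0 puts the carrier along columns (responds to vertical
# structure); orientation 90 along rows.
.build_gabor_bank <- function(config) {
  lapply(config$gabor_scales, function(lambda) {
    sigma <- config$gabor_sigma_ratio * lambda
    radius <- max(3L, ceiling(2.5 * sigma))
    t <- seq(-radius, radius)
    env <- exp(-t^2 / (2 * sigma^2))
    even <- env * cos(2 * pi * t / lambda)
    even <- even - env * sum(even) / sum(env)     # zero-mean, stays separable
    odd <- env * sin(2 * pi * t / lambda)
    n <- config$roi_size
    list(env = corr_band_matrix(n, env / sum(env)),
         even = corr_band_matrix(n, even),
         odd = corr_band_matrix(n, odd))
  })
}

# mean-pooling matrix: roi_size -> pool_grid
.build_pool <- function(config) {
  n <- config$roi_size; g <- config$gabor_pool_grid
  cell <- n / g
  G <- matrix(0, n, g)
  for (j in seq_len(g)) G[((j - 1) * cell + 1):(j * cell), j] <- 1 / cell
  G
}

#' Construct a scene encoder
#'
#' Bundles everything needed to turn a raw scene into its representation:
#' the detection filter, the Gabor bank, the shape prototypes (Gabor codes of
#' randomly drawn familiar-family objects) and the two fixation-dependent
#' layout prototype sets.  Encoders are deterministic given `(config, seed)`.
#'
#' @param config A [chord_config()].
#' @param seed Seed governing the random choice of shape prototypes.
#' @return An object of class `chord_encoder`.
#' @examples
#' enc <- chord_encoder(chord_config(), seed = 1)
#' enc
#' @export
chord_encoder <- function(config = chord_config(), seed = 1L) {
  validate_config(config)
  n <- config$scene_size
  det_taps <- gaussian_taps(config$detect_sigma,
                            radius = min(ceiling(2.5 * config$detect_sigma),
                                         n - 1))
  enc <- list(
    config = config,
    seed = as.integer(seed),
    detect = corr_band_matrix(n, det_taps),
    gabor = .build_gabor_bank(config),
    pool = .build_pool(config)
  )
  # shape prototypes: random exemplars of the familiar families, Gabor-coded
  fam <- config$object_categories[seq_len(config$n_familiar_categories)]
  protos <- with_seed(sub_seed(seed, 11), {
    lapply(seq_len(config$n_shape_prototypes), function(i)
      object_spec(fam[(i - 1) %% length(fam) + 1], sample.int(1e8, 1) + 6e8))
  })
  enc$shape_categories <- vapply(protos, `[[`, "", "category")
  feats <- t(vapply(protos, function(sp)
    .gabor_features(make_object(sp, config$roi_size), enc),
    numeric(4 * config$gabor_pool_grid^2)))
  enc$shape_prototypes <- prototype_set(feats, p = config$minkowski_p)
  # layout prototypes: mirror grids for top and bottom fixation
  grid <- as.matrix(expand.grid(row = config$layout_grid_rows,
                                col = config$layout_grid_cols))
  enc$layout_offsets <- list(top = grid, bottom = -grid)
  enc$layouts <- lapply(enc$layout_offsets, function(g) {
    imgs <- lapply(seq_len(nrow(g)), function(j)
      .render_layout(g[j, ], config))
    flat <- t(vapply(imgs, as.vector, numeric(n * n)))
    list(images = imgs, flat = flat, norms2 = rowSums(flat^2))
  })
  class(enc) <- "chord_encoder"
  enc
}

#' @export
print.chord_encoder <- function(x, ...) {
  cat(sprintf(
    "<chord_encoder> %d shape prototypes (%s), %d layout prototypes/fixation, seed %d\n",
    length(x$shape_categories),
    paste(unique(x$shape_categories), collapse = ", "),
    nrow(x$layout_offsets$top), x$seed))
  invisible(x)
}

# fixation-centred layout raster: key Gaussian patch at the canvas centre,
# other patch offset by displacement * layout_render_scale
.render_layout <- function(displacement, config) {
  n <- config$scene_size; s <- config$layout_sigma
  ctr <- (n + 1) / 2
  off <- displacement * config$layout_render_scale
  if (any(abs(off) > (n - 1) / 2))
    stop_chord("chord_layout_error",
               "displacement (%s) outside the renderable range",
               paste(displacement, collapse = ", "))
  g1 <- exp(-(seq_len(n) - ctr)^2 / (2 * s^2))
  r2 <- exp(-(seq_len(n) - ctr - off[1])^2 / (2 * s^2))
  c2 <- exp(-(seq_len(n) - ctr - off[2])^2 / (2 * s^2))
  pmax(outer(g1, g1), outer(r2, c2))
}

#' Build the layout prototype set for one fixation
#'
#' Ten two-Gaussian-patch rasters: the key patch is identical across the set
#' (canvas centre); the other patch sits at each grid offset.  The grids for
#' top and bottom fixation are mirror images of each other.
#'
#' @param fixation `"top"` or `"bottom"`.
#' @param encoder A [chord_encoder()].
#' @return List with `fixation`, `offsets` (10 x 2 matrix of scene-unit
#'   displacements) and `images` (list of rasters).
#' @export
build_layout_prototypes <- function(fixation = c("top", "bottom"),
                                    encoder) {
  fixation <- match.arg(fixation)
  stopifnot(inherits(encoder, "chord_encoder"))
  list(fixation = fixation,
       offsets = encoder$layout_offsets[[fixation]],
       images = encoder$layouts[[fixation]]$images)
}

#' Detect regions of interest by Gaussian convolution
#'
#' The scene is filtered with an isotropic Gaussian and the first ROI is the
#' location of the filtered maximum (restricted to centres whose patch lies
#' fully inside the scene).  Each further ROI is found after zeroing a patch-
#' sized window around the previous maximum.
#'
#' @param scene A `scene_image` or a plain scene matrix.
#' @param encoder A [chord_encoder()].
#' @param n_rois Number of regions to detect.
#' @return List of detections, each with `center` (row, col), `patch`
#'   (`roi_size` square crop) and `score`; ordered by detection score.
#' @export
detect_rois <- function(scene, encoder, n_rois = 2) {
  stopifnot(inherits(encoder, "chord_encoder"))
  px <- if (inherits(scene, "scene_image")) scene$pixels else scene
  cfg <- encoder$config
  if (!is.matrix(px) || any(dim(px) != cfg$scene_size))
    stop_chord("chord_dimension_error", "scene must be %d x %d",
               cfg$scene_size, cfg$scene_size)
  if (max(px) <= 0)
    stop_chord("chord_detection_error", "scene is empty (all-zero)")
  half <- cfg$roi_size / 2
  lo <- half; hi <- cfg$scene_size - half
  valid <- matrix(FALSE, cfg$scene_size, cfg$scene_size)
  valid[lo:hi, lo:hi] <- TRUE
  work <- px               # suppression zeroes the detected patch itself
  margin <- 3              # covers detection jitter, removes the whole object
  out <- vector("list", n_rois)
  for (k in seq_len(n_rois)) {
    score <- sep_filter(work, encoder$detect, encoder$detect)
    masked <- ifelse(valid, score, -Inf)
    peak <- max(masked)
    if (!is.finite(peak) || peak <= 1e-12)
      stop_chord("chord_detection_error",
                 "found only %d salient region(s), %d requested", k - 1, n_rois)
    w <- which(masked == peak)[1]
    r <- (w - 1) %% cfg$scene_size + 1
    cl <- (w - 1) %/% cfg$scene_size + 1
    rows <- (r - half + 1):(r + half)
    cols <- (cl - half + 1):(cl + half)
    out[[k]] <- list(center = c(r, cl), patch = px[rows, cols], score = peak)
    sup_r <- max(1, r - half + 1 - margin):min(cfg$scene_size, r + half + margin)
    sup_c <- max(1, cl - half + 1 - margin):min(cfg$scene_size, cl + half + margin)
    work[sup_r, sup_c] <- 0
  }
  out
}

# pooled Gabor energies of one patch (plain numeric, length 4 * grid^2)
.gabor_features <- function(patch, enc) {
  G <- enc$pool
  feats <- lapply(enc$gabor, function(f) {
    # orientation 0: carrier along columns
    e0 <- f$env %*% patch %*% t(f$even)
    o0 <- f$env %*% patch %*% t(f$odd)
    en0 <- sqrt(e0^2 + o0^2)
    # orientation 90: carrier along rows
    e9 <- f$even %*% patch %*% t(f$env)
    o9 <- f$odd %*% patch %*% t(f$env)
    en9 <- sqrt(e9^2 + o9^2)
    c(t(G) %*% en0 %*% G, t(G) %*% en9 %*% G)
  })
  unlist(feats, use.names = FALSE)
}

#' Gabor-energy features of an object patch
#'
#' Quadrature-pair (phase-invariant) Gabor energy at each configured scale
#' and orientation, mean-pooled over a regular grid of cells.  The feature
#' length is `n_filters * pool_grid^2` and is constant across patches; an
#' all-zero patch maps to the all-zero vector.
#'
#' @param patch `roi_size x roi_size` numeric matrix.
#' @param encoder A [chord_encoder()].
#' @return Numeric feature vector.
#' @export
gabor_encode <- function(patch, encoder) {
  stopifnot(inherits(encoder, "chord_encoder"))
  n <- encoder$config$roi_size
  if (!is.matrix(patch) || any(dim(patch) != n))
    stop_chord("chord_dimension_error", "patch must be %d x %d", n, n)
  .gabor_features(patch, encoder)
}

#' Encode an object patch against the shape prototypes
#'
#' @param patch `roi_size` square numeric matrix.
#' @param encoder A [chord_encoder()].
#' @param mode `"ct"` for the chorus code over the shape prototypes (length
#'   `n_shape_prototypes`), `"raw"` for the unreduced Gabor feature vector.
#' @return Numeric code vector.
#' @export
encode_roi <- function(patch, encoder, mode = c("ct", "raw")) {
  mode <- match.arg(mode)
  g <- gabor_encode(patch, encoder)
  if (mode == "raw") return(g)
  as.numeric(chorus_transform(g, encoder$shape_prototypes,
                              scale = encoder$config$ct_scale))
}

# chorus code of an observed displacement against one fixation's layout set
.layout_code <- function(displacement, fixation, enc) {
  cfg <- enc$config
  v <- as.vector(.render_layout(displacement, cfg))
  L <- enc$layouts[[fixation]]
  d2 <- pmax(L$norms2 - 2 * drop(L$flat %*% v) + sum(v * v), 0)
  tiny <- which(d2 < 1e-8 * sum(v * v))   # exact zero at a matching prototype
  for (j in tiny) d2[j] <- sum((L$flat[j, ] - v)^2)
  .ct_scale_value(cfg$ct_scale, nrow(L$flat)) * sqrt(d2)
}

#' Encode the spatial layout of a detected ROI pair
#'
#' Renders the observed arrangement as a fixation-centred two-patch raster
#' (key patch at the canonical location, other patch at its observed
#' displacement) and takes the chorus code of pixel-space distances to the
#' fixation's 10 layout prototypes.
#'
#' @param key_center,other_center `(row, col)` centres of the fixated and the
#'   remaining ROI.
#' @param fixation `"top"` or `"bottom"`.
#' @param encoder A [chord_encoder()].
#' @return Numeric layout code (length = number of layout prototypes).
#' @export
encode_layout <- function(key_center, other_center,
                          fixation = c("top", "bottom"), encoder) {
  fixation <- match.arg(fixation)
  stopifnot(inherits(encoder, "chord_encoder"))
  .layout_code(as.numeric(other_center) - as.numeric(key_center),
               fixation, encoder)
}

# full encoding of a scene: both fixations, both encoding modes, one
# detection + one Gabor pass per ROI
encode_scene_full <- function(scene, encoder) {
  rois <- detect_rois(scene, encoder, n_rois = 2)
  ctrs <- do.call(rbind, lapply(rois, `[[`, "center"))
  ord <- order(ctrs[, 1], ctrs[, 2])     # lexicographic: top first
  top <- rois[[ord[1]]]; bottom <- rois[[ord[2]]]
  g_top <- .gabor_features(top$patch, encoder)
  g_bot <- .gabor_features(bottom$patch, encoder)
  P <- encoder$shape_prototypes
  s <- .ct_scale_value(encoder$config$ct_scale, nrow(P$prototypes))
  ct_top <- s * .proto_dist(g_top, P$prototypes, P$p)
  ct_bot <- s * .proto_dist(g_bot, P$prototypes, P$p)
  id <- if (inherits(scene, "scene_image")) scene$id else NULL
  mk <- function(fix) {
    key <- if (fix == "top") top else bottom
    oth <- if (fix == "top") bottom else top
    structure(list(
      fix_code = if (fix == "top") ct_top else ct_bot,
      other_code = if (fix == "top") ct_bot else ct_top,
      fix_raw = if (fix == "top") g_top else g_bot,
      other_raw = if (fix == "top") g_bot else g_top,
      layout_code = .layout_code(oth$center - key$center, fix, encoder),
      fixation = fix, mode = "ct", scene_id = id,
      centers = rbind(key = key$center, other = oth$center)),
      class = "scene_rep")
  }
  list(top = mk("top"), bottom = mk("bottom"))
}

#' Encode a scene for a given fixation
#'
#' Detects the two ROIs, labels them top/bottom lexicographically by (row,
#' col) of the detected centres, and concatenates the fixated-ROI code, the
#' other-ROI code and the layout code.  In `"ct"` mode all three parts are
#' chorus codes of length `n_shape_prototypes` (30 dimensions in total by
#' default); in `"raw"` mode the two ROI parts carry the unreduced Gabor
#' vectors while the layout stays chorus-coded.
#'
#' @param scene A `scene_image` or scene matrix.
#' @param fixation `"top"` or `"bottom"`.
#' @param encoder A [chord_encoder()].
#' @param mode `"ct"` or `"raw"`.
#' @return An object of class `scene_rep` with fields `fix_code`,
#'   `other_code`, `layout_code`, `fixation`, `mode`, `centers`.
#' @export
encode_scene <- function(scene, fixation = c("top", "bottom"), encoder,
                         mode = c("ct", "raw")) {
  fixation <- match.arg(fixation)
  mode <- match.arg(mode)
  rep <- encode_scene_full(scene, encoder)[[fixation]]
  as_mode(rep, mode)
}

# view a full representation in one encoding mode
as_mode <- function(rep, mode) {
  if (mode == "raw") {
    rep$fix_code <- rep$fix_raw
    rep$other_code <- rep$other_raw
  }
  rep$mode <- mode
  rep$fix_raw <- rep$other_raw <- NULL
  rep
}

#' @export
print.scene_rep <- function(x, ...) {
  cat(sprintf(
    "<scene_rep> fixation %s, mode %s: fix %d + other %d + layout %d dims\n",
    x$fixation, x$mode, length(x$fix_code), length(x$other_code),
    length(x$layout_code)))
  invisible(x)
}

#' Flatten a scene representation to one numeric row
#'
#' @param rep A `scene_rep`.
#' @return Named numeric vector (fix, other, layout components concatenated).
#' @export
rep_as_row <- function(rep) {
  stopifnot(inherits(rep, "scene_rep"))
  v <- c(rep$fix_code, rep$other_code, rep$layout_code)
  names(v) <- c(paste0("fix", seq_along(rep$fix_code)),
                paste0("other", seq_along(rep$other_code)),
                paste0("layout", seq_along(rep$layout_code)))
  v
}
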