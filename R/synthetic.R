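# Synthetic object and scene generator.
#
# Parametric grayscale object families stand in for a natural-image object
# database: each family has a recognizable shared structure and substantial
# within-family variability (size, elongation, rotation, texture frequency,
# contrast), so that exemplars of one family are closer to each other than to
# other families in feature space, without being identical.

#' Specify a synthetic object
#'
#' @param category Object family name; see `chord_config()$object_categories`.
#' @param seed Integer seed; a spec renders to the identical patch every time.
#' @return An object of class `object_spec`.
#' @export
object_spec <- function(category, seed) {
  categories <- c("ellipse", "rectangle", "cross", "annulus", "triangle",
                  "grating", "blob", "ring_texture")
  if (!is.character(category) || length(category) != 1 ||
      !(category %in% categories))
    stop_chord("chord_config_error", "unknown object category '%s'",
               paste(category, collapse = ","))
  structure(list(category = category, seed = as.integer(seed)),
            class = "object_spec")
}

#' Render a synthetic object patch
#'
#' Draws the family parameters from the spec's seed, renders the shape
#' analytically on a `size x size` grid, recentres it on its intensity
#' centroid (so convolution-based detection recovers the placement centre),
#' and quantizes to the 8-bit grayscale grid.
#'
#' @param spec An [object_spec()].
#' @param size Patch side in pixels.
#' @return `size x size` numeric matrix in `[0, 1]` with a positive maximum.
#' @examples
#' p <- make_object(object_spec("ellipse", 1))
#' range(p)
#' @export
make_object <- function(spec, size = 50) {
  stopifnot(inherits(spec, "object_spec"))
  img <- with_seed(sub_seed(spec$seed, match(spec$category, c(
    "ellipse", "rectangle", "cross", "annulus", "triangle",
    "grating", "blob", "ring_texture"))), {
    .apply_texture(.render_object(spec$category, size))
  })
  img <- .centroid_center(img)
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255   # 8-bit grid, PNG-exact
  if (max(img) <= 0)
    stop_chord("chord_domain_error", "rendered object is empty")
  img
}

.render_object <- function(category, size) {
  ctr <- (size + 1) / 2
  rr <- matrix(seq_len(size) - ctr, size, size)        # row offsets
  cc <- t(rr)                                          # col offsets
  amp <- stats::runif(1, 0.55, 1)
  # categories have a canonical orientation with modest jitter, as in
  # photographed object databases; isotropic families ignore the rotation
  rot <- stats::rnorm(1, 0, 0.15)
  u <-  cos(rot) * cc + sin(rot) * rr                  # rotated coords
  v <- -sin(rot) * cc + cos(rot) * rr
  switch(category,
    ellipse = {
      a <- stats::runif(1, 10, 20); b <- stats::runif(1, 7, 15)
      amp * ((u / a)^2 + (v / b)^2 <= 1)
    },
    rectangle = {
      a <- stats::runif(1, 8, 18); b <- stats::runif(1, 8, 18)
      amp * (abs(u) <= a & abs(v) <= b)
    },
    cross = {
      arm <- stats::runif(1, 12, 20); th <- stats::runif(1, 3, 7)
      amp * ((abs(u) <= arm & abs(v) <= th) | (abs(v) <= arm & abs(u) <= th))
    },
    annulus = {
      ro <- stats::runif(1, 12, 20); ri <- ro * stats::runif(1, 0.4, 0.7)
      r <- sqrt(u^2 + v^2)
      amp * (r <= ro & r >= ri)
    },
    triangle = {
      s <- stats::runif(1, 13, 21)
      ang <- pi / 2 + rot + c(0, 2 * pi / 3, 4 * pi / 3) +
        stats::rnorm(3, sd = 0.15)
      px <- s * cos(ang); py <- s * sin(ang)
      inside <- rep(TRUE, length(u))
      for (i in 1:3) {                                  # half-plane test
        j <- i %% 3 + 1
        ex <- px[j] - px[i]; ey <- py[j] - py[i]
        side <- ex * (as.vector(v) - py[i]) - ey * (as.vector(u) - px[i])
        ref  <- ex * (mean(py) - py[i]) - ey * (mean(px) - px[i])
        inside <- inside & (side * ref >= 0)
      }
      amp * matrix(inside, size, size)
    },
    grating = {
      period <- stats::runif(1, 6, 14); rad <- stats::runif(1, 14, 20)
      win <- sqrt(u^2 + v^2) <= rad
      amp * win * (0.5 + 0.5 * sin(2 * pi * u / period))
    },
    blob = {
      k <- sample(3:5, 1)
      img <- matrix(0, size, size)
      for (i in seq_len(k)) {
        s <- stats::runif(1, 3, 6)
        dr <- stats::runif(1, -10, 10); dc <- stats::runif(1, -10, 10)
        img <- img + exp(-((rr - dr)^2 + (cc - dc)^2) / (2 * s^2))
      }
      amp * img / max(img)
    },
    ring_texture = {
      period <- stats::runif(1, 4, 9); rad <- stats::runif(1, 15, 21)
      r <- sqrt(u^2 + v^2)
      amp * (r <= rad) * (0.5 + 0.5 * cos(2 * pi * r / period))
    },
    stop_chord("chord_config_error", "unknown object category '%s'", category))
}

# Exemplar-specific surface texture: multiplicative smoothed speckle over the
# shape's support.  Photographic exemplars of one category share coarse
# structure but differ idiosyncratically in local appearance; this gives the
# families the same statistics (large, high-dimensional within-family
# variation in raw feature space, while family identity stays decodable from
# coarse structure).
.apply_texture <- function(img, sd = 0.55, smooth_sigma = 4) {
  n <- nrow(img)
  z <- matrix(stats::rnorm(n * n), n, n)
  taps <- gaussian_taps(smooth_sigma)
  M <- corr_band_matrix(n, taps)
  z <- M %*% z %*% t(M)
  z <- z / stats::sd(z)
  pmin(pmax(img * (1 + sd * z), 0), 1)
}

# sample one element of a vector (safe for length-1 vectors)
sample1 <- function(v) v[sample.int(length(v), 1)]

# integer shift putting the intensity centroid at the patch centre
.centroid_center <- function(img) {
  tot <- sum(img)
  if (tot <= 0) return(img)
  n <- nrow(img); ctr <- (n + 1) / 2
  cr <- sum(row(img) * img) / tot
  cl <- sum(col(img) * img) / tot
  dr <- round(ctr - cr); dc <- round(ctr - cl)
  if (dr == 0 && dc == 0) return(img)
  out <- matrix(0, n, n)
  src_r <- seq_len(n) - dr; src_c <- seq_len(n) - dc
  okr <- src_r >= 1 & src_r <= n; okc <- src_c >= 1 & src_c <= n
  out[which(okr), which(okc)] <- img[src_r[okr], src_c[okc]]
  out
}

#' Specify a two-object scene
#'
#' @param objects List of two [object_spec()]s.
#' @param centers List or 2-row matrix of the two placement centres
#'   `(row, col)`, 1-indexed.
#' @param id Optional scene identifier.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(objects, centers, id = NULL) {
  if (length(objects) != 2 || !all(vapply(objects, inherits, TRUE, "object_spec")))
    stop_chord("chord_config_error", "need exactly two object specs")
  if (is.list(centers)) centers <- do.call(rbind, centers)
  centers <- matrix(as.numeric(centers), nrow = 2)
  structure(list(objects = objects, centers = centers, id = id),
            class = "scene_spec")
}

#' Render a scene from its specification
#'
#' Places the two object patches on a black background (composition by
#' pixelwise maximum).  Placements that push a patch out of bounds, overlap
#' the two patch boxes, or put the centres closer than half a patch apart are
#' rejected.
#'
#' @param spec A [scene_spec()].
#' @param config A [chord_config()].
#' @return A `scene_image`: list with `pixels` (scene matrix in `[0, 1]`),
#'   `centers`, `spec`, `id`.
#' @export
make_scene <- function(spec, config = chord_config()) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- config$scene_size; half <- config$roi_size / 2
  ctr <- spec$centers
  lo <- half; hi <- n - half
  if (any(ctr < lo) || any(ctr > hi))
    stop_chord("chord_config_error",
               "placement centre outside the feasible band [%g, %g]", lo, hi)
  if (sqrt(sum((ctr[1, ] - ctr[2, ])^2)) < half)
    stop_chord("chord_config_error", "placement centres closer than %g px", half)
  d <- abs(ctr[1, ] - ctr[2, ])
  if (d[1] < config$roi_size && d[2] < config$roi_size)
    stop_chord("chord_config_error", "object boxes overlap")
  px <- matrix(0, n, n)
  for (i in 1:2) {
    patch <- make_object(spec$objects[[i]], config$roi_size)
    rows <- (ctr[i, 1] - half + 1):(ctr[i, 1] + half)
    cols <- (ctr[i, 2] - half + 1):(ctr[i, 2] + half)
    px[rows, cols] <- pmax(px[rows, cols], patch)
  }
  structure(list(pixels = px, centers = ctr, spec = spec, id = spec$id),
            class = "scene_image")
}

#' @export
print.scene_image <- function(x, ...) {
  cat(sprintf("<scene_image> %dx%d px, objects [%s] at (%s), (%s)%s\n",
              nrow(x$pixels), ncol(x$pixels),
              paste(vapply(x$spec$objects, `[[`, "", "category"), collapse = ", "),
              paste(x$centers[1, ], collapse = ","),
              paste(x$centers[2, ], collapse = ","),
              if (is.null(x$id)) "" else paste0(", id ", x$id)))
  invisible(x)
}

#' Displacement series for the graded-change experiment
#'
#' Starting from a base scene, one object (the lexicographically later one,
#' so the top/bottom fixation labelling stays constant across the series) is
#' displaced in `step`-pixel increments along the given axis, moving towards
#' larger coordinates.  Horizontal displacement uses a vertically arranged
#' base scene and vice versa, so that every displaced placement stays in
#' bounds and the boxes never overlap.
#'
#' @param base A [scene_spec()] prepared by [displacement_base_spec()] or any
#'   spec with room for the full series.
#' @param axis `"horizontal"` or `"vertical"`: the direction along which the
#'   second object moves.
#' @param step Displacement increment in pixels.
#' @param levels Number of displaced variants.
#' @param config A [chord_config()].
#' @return List with `reference` (the rendered base scene) and `scenes`
#'   (list of `levels` rendered variants, level `j` displaced by `j * step`).
#' @export
make_displacement_series <- function(base, axis = c("horizontal", "vertical"),
                                     step = 10, levels = 5,
                                     config = chord_config()) {
  axis <- match.arg(axis)
  stopifnot(inherits(base, "scene_spec"))
  mover <- 2L                     # convention: second centre is displaced
  dim_i <- if (axis == "horizontal") 2L else 1L
  scenes <- vector("list", levels)
  for (j in seq_len(levels)) {
    ctr <- base$centers
    ctr[mover, dim_i] <- ctr[mover, dim_i] + j * step
    sp <- scene_spec(base$objects, ctr,
                     id = paste0(base$id, "-d", j * step))
    scenes[[j]] <- make_scene(sp, config)   # bounds/overlap checked there
  }
  list(reference = make_scene(base, config), scenes = scenes,
       displacement = seq_len(levels) * step, axis = axis)
}

# Base spec with room for a full displacement series along `axis`.  Scenes
# keep the top/bottom two-object structure in both cases; the bottom object
# is the one displaced, so the fixation labelling is stable across a series.
displacement_base_spec <- function(objects, axis, config, id = NULL) {
  half <- config$roi_size / 2
  lo <- half; hi <- config$scene_size - half
  span <- config$displacement_step * config$displacement_levels
  if (axis == "horizontal") {
    # bottom object moves right, traversing the layout grid's column span:
    # its base column offset sits at the left edge of that span
    d_row <- sample1((config$roi_size + 2):(hi - lo))
    r1 <- sample1(lo:(hi - d_row))
    d_col <- -span %/% 2
    c1 <- sample1(max(lo, lo - d_col):min(hi, hi - span - d_col))
    centers <- rbind(c(r1, c1), c(r1 + d_row, c1 + d_col))
  } else {
    # bottom object moves further down from the minimum feasible separation
    d_row <- config$roi_size                 # touching boxes, no overlap
    r1 <- lo
    if (r1 + d_row + span > hi)
      stop_chord("chord_config_error", "no room for the vertical series")
    d_col <- sample1(-35:35)
    c1 <- sample1(max(lo, lo - d_col):min(hi, hi - d_col))
    centers <- rbind(c(r1, c1), c(r1 + d_row, c1 + d_col))
  }
  scene_spec(objects, centers, id = id)
}

#' Structural transformations of a scene
#'
#' @param base A [scene_spec()].
#' @param kind `"T"` (joint translation of both objects), `"R"` (reversal:
#'   the two objects swap placement centres) or `"TR"` (both).
#' @param translation Integer `(row, col)` vector for `"T"`/`"TR"`.
#' @param config A [chord_config()].
#' @return The transformed scene as a `scene_image`.
#' @export
make_transformed_scene <- function(base, kind = c("T", "R", "TR"),
                                   translation = c(0, 0),
                                   config = chord_config()) {
  kind <- match.arg(kind)
  stopifnot(inherits(base, "scene_spec"))
  ctr <- base$centers
  objects <- base$objects
  if (kind %in% c("R", "TR")) ctr <- ctr[2:1, , drop = FALSE]
  if (kind %in% c("T", "TR"))
    ctr <- sweep(ctr, 2, -as.numeric(translation))
  sp <- scene_spec(objects, ctr, id = paste0(base$id, "-", kind))
  make_scene(sp, config)
}

# ---- training catalog and experiment condition sets -------------------------

#' Build a training catalog of familiar scenes
#'
#' The catalog fixes an object pool (`n_object_pool` exemplars spread over the
#' familiar families), a discrete inventory of layout displacements, and
#' `n_scenes` scene specifications pairing pooled objects under inventory
#' layouts with jittered absolute placement.
#'
#' @param config A [chord_config()].
#' @param seed Master seed.
#' @param n_scenes Number of training scenes (default from the config).
#' @return An object of class `chord_catalog`.
#' @export
training_catalog <- function(config = chord_config(), seed = 1L,
                             n_scenes = config$n_train_scenes) {
  fam <- config$object_categories[seq_len(config$n_familiar_categories)]
  pool <- with_seed(sub_seed(seed, 101), {
    lapply(seq_len(config$n_object_pool), function(i)
      object_spec(fam[(i - 1) %% length(fam) + 1],
                  seed = sample.int(1e8, 1)))
  })
  inventory <- as.matrix(expand.grid(row = config$train_displacement_rows,
                                     col = config$train_displacement_cols))
  scenes <- with_seed(sub_seed(seed, 102), {
    lapply(seq_len(n_scenes), function(i) {
      oi <- sample.int(length(pool), 2)
      disp <- inventory[sample.int(nrow(inventory), 1), ]
      .place_with_displacement(pool[oi], disp, config,
                               id = sprintf("train-%04d", i))
    })
  })
  structure(list(pool = pool, inventory = inventory, scenes = scenes,
                 familiar = fam,
                 novel_categories = setdiff(config$object_categories, fam),
                 config = config, seed = seed),
            class = "chord_catalog")
}

#' @export
print.chord_catalog <- function(x, ...) {
  cat(sprintf(
    "<chord_catalog> %d scenes, %d pooled exemplars over {%s}, %d layouts\n",
    length(x$scenes), length(x$pool), paste(x$familiar, collapse = ", "),
    nrow(x$inventory)))
  invisible(x)
}

# random absolute placement realizing a given relative displacement
.place_with_displacement <- function(objects, disp, config, id = NULL) {
  half <- config$roi_size / 2
  lo <- half; hi <- config$scene_size - half
  r1 <- sample1(max(lo, lo - disp[1]):min(hi, hi - disp[1]))
  c1 <- sample1(max(lo, lo - disp[2]):min(hi, hi - disp[2]))
  scene_spec(objects, rbind(c(r1, c1), c(r1 + disp[1], c1 + disp[2])), id = id)
}

# displacement not in (and not near) the training inventory
.novel_displacement <- function(catalog, config) {
  repeat {
    d <- c(sample1(config$roi_size + 2:50), sample1(-40:40))
    gaps <- apply(catalog$inventory, 1,
                  function(v) max(abs(v - d)))
    if (min(gaps) >= config$novel_layout_margin) return(d)
  }
}

#' Generate a set of test scenes for one productivity condition
#'
#' Conditions: `"familiar"` re-uses catalog training scenes verbatim; `"N"`
#' pairs one novel object with a new exemplar of a familiar family under an
#' inventory layout; `"NN"` uses two novel objects under an inventory layout;
#' `"L"` pairs two familiar-family exemplars under a displacement at least
#' `novel_layout_margin` pixels (Chebyshev) from every inventory layout.
#' "Novel object" defaults to an exemplar of a held-out family
#' (`novelty = "category"`); `novelty = "exemplar"` instead draws an unseen
#' exemplar of a familiar family, the second novelty axis.
#'
#' @param condition One of `"familiar"`, `"N"`, `"NN"`, `"L"`.
#' @param n Number of scenes.
#' @param catalog A [training_catalog()].
#' @param seed Seed for the condition set.
#' @param novelty `"category"` or `"exemplar"`.
#' @return List of `scene_image`s; each carries attributes `condition` and
#'   `novel` (logical per object).
#' @export
make_condition_set <- function(condition = c("familiar", "N", "NN", "L"),
                               n, catalog, seed = 1L,
                               novelty = c("category", "exemplar")) {
  condition <- match.arg(condition)
  novelty <- match.arg(novelty)
  stopifnot(inherits(catalog, "chord_catalog"))
  config <- catalog$config
  if (novelty == "category" && length(catalog$novel_categories) == 0)
    stop_chord("chord_config_error", "no held-out categories available")
  novel_spec <- function() {
    if (novelty == "category")
      object_spec(sample(catalog$novel_categories, 1), sample.int(1e8, 1))
    else
      object_spec(sample(catalog$familiar, 1), sample.int(1e8, 1) + 2e8)
  }
  familiar_exemplar <- function()  # unseen exemplar of a familiar family
    object_spec(sample(catalog$familiar, 1), sample.int(1e8, 1) + 4e8)
  with_seed(sub_seed(seed, 7), {
    lapply(seq_len(n), function(i) {
      if (condition == "familiar") {
        sp <- catalog$scenes[[sample.int(length(catalog$scenes), 1)]]
        novel <- c(FALSE, FALSE)
      } else {
        if (condition == "N") {
          objs <- list(novel_spec(), familiar_exemplar())
          novel <- c(TRUE, FALSE)
          if (stats::runif(1) < 0.5) { objs <- rev(objs); novel <- rev(novel) }
        } else if (condition == "NN") {
          objs <- list(novel_spec(), novel_spec()); novel <- c(TRUE, TRUE)
        } else {
          objs <- list(familiar_exemplar(), familiar_exemplar())
          novel <- c(FALSE, FALSE)
        }
        disp <- if (condition == "L") .novel_displacement(catalog, config)
                else catalog$inventory[sample.int(nrow(catalog$inventory), 1), ]
        sp <- .place_with_displacement(objs, disp, config,
                                       id = sprintf("%s-%04d", condition, i))
      }
      sc <- make_scene(sp, config)
      attr(sc, "condition") <- condition
      attr(sc, "novel") <- novel
      sc
    })
  })
}
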