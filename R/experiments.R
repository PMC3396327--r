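# Reproducible runners for the three simulation experiments and the
# ct-vs-raw encoding control.  Every runner is deterministic given
# (config, seed) and returns a `chord_experiment` with the per-scene table,
# per-condition summaries and a config/seed snapshot.

#' Mean and normal-approximation 95% confidence interval
#'
#' @param values Numeric vector with at least two elements.
#' @return List with `mean`, `half_width` (`1.96 * sd / sqrt(n)`), `sd`, `n`.
#' @examples
#' summarize_ci(1:5)  # mean 3, half-width 1.96 * sqrt(2.5) / sqrt(5)
#' @export
summarize_ci <- function(values) {
  values <- check_numeric_vector(values, "values")
  if (length(values) < 2)
    stop_chord("chord_stats_error", "need at least 2 values to summarize")
  n <- length(values)
  list(mean = mean(values),
       half_width = 1.96 * stats::sd(values) / sqrt(n),
       sd = stats::sd(values), n = n)
}

.experiment_result <- function(kind, data, summary, config, seed,
                               regression = NULL, extra = list()) {
  structure(c(list(kind = kind, data = data, summary = summary,
                   regression = regression, config = config, seed = seed),
              extra),
            class = "chord_experiment")
}

#' @export
print.chord_experiment <- function(x, ...) {
  cat(sprintf("<chord_experiment> %s (seed %d, n = %d observations)\n",
              x$kind, x$seed, nrow(x$data)))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$regression))
    cat(sprintf(
      "  OLS: delta = %.4f + %.4f * displacement; R^2 = %.3f, F(1, %d) = %.4g, p = %.3g\n",
      x$regression$intercept, x$regression$slope, x$regression$r_squared,
      x$regression$df_residual, x$regression$f_statistic, x$regression$p_value))
  invisible(x)
}

#' @export
plot.chord_experiment <- function(x, ...) {
  s <- x$summary
  if (x$kind == "displacement") {
    graphics::plot(s$displacement, s$mean, type = "b", pch = 16,
                   xlab = "displacement (px)", ylab = "dissimilarity",
                   ylim = range(c(s$mean - s$ci, s$mean + s$ci)),
                   main = "Graded displacement", ...)
    ok <- s$ci > 0
    graphics::arrows(s$displacement[ok], (s$mean - s$ci)[ok],
                     s$displacement[ok], (s$mean + s$ci)[ok],
                     angle = 90, code = 3, length = 0.04)
  } else {
    bp <- graphics::barplot(s$mean, names.arg = s$condition,
                            ylab = "dissimilarity",
                            ylim = c(0, max(s$mean + s$ci) * 1.15),
                            main = paste("Experiment:", x$kind), ...)
    ok <- s$ci > 0
    graphics::arrows(bp[ok], (s$mean - s$ci)[ok], bp[ok], (s$mean + s$ci)[ok],
                     angle = 90, code = 3, length = 0.04)
  }
  invisible(x)
}

#' Productivity experiment: novelty of scene constituents
#'
#' Populates a memory with a training catalog, then queries test scenes from
#' the familiar / one-novel-object (N) / two-novel-objects (NN) / novel-
#' layout (L) conditions and records each query's composite best-match
#' dissimilarity.  In `"raw"` mode the ROI components are raw Gabor vectors
#' (layout stays chorus-coded) and retrieval is brute force.
#'
#' @param config A [chord_config()].
#' @param seed Master seed.
#' @param n_per_condition Test scenes per condition.
#' @param n_train Training-catalog size.
#' @param mode `"ct"`, `"raw"`, or both (each mode queried on the same
#'   stimuli and memory).
#' @param conditions Condition subset to run.
#' @param novelty Passed to [make_condition_set()].
#' @param memory Optionally, a pre-populated memory (its encoder's catalog
#'   must match `catalog`); used to share work across calls.
#' @param catalog Optionally, a pre-built [training_catalog()].
#' @return A `chord_experiment`; its `data` has one row per (condition, mode,
#'   scene) with the composite dissimilarity and fallback flag.
#' @export
run_productivity <- function(config = chord_config(), seed = 1L,
                             n_per_condition = 2000,
                             n_train = config$n_train_scenes,
                             mode = c("ct", "raw"),
                             conditions = c("familiar", "N", "NN", "L"),
                             novelty = "category",
                             memory = NULL, catalog = NULL) {
  mode <- match.arg(mode, several.ok = TRUE)
  if (is.null(catalog))
    catalog <- training_catalog(config, seed, n_scenes = n_train)
  if (is.null(memory)) {
    enc <- chord_encoder(config, seed)
    memory <- chord_memory(enc)
    for (sp in catalog$scenes) store_scene(memory, make_scene(sp, config))
  }
  rows <- list()
  for (cond in conditions) {
    scenes <- make_condition_set(cond, n_per_condition, catalog,
                                 seed = sub_seed(seed, match(cond, conditions)),
                                 novelty = novelty)
    for (i in seq_along(scenes)) {
      for (md in mode) {
        q <- query_scene(memory, scenes[[i]], k = config$nn_k, mode = md)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, mode = md, scene = i, delta = q$composite,
          fallback = any(q$fallback))
      }
    }
  }
  data <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(data, list(data$mode, data$condition),
                                         drop = TRUE), function(d) {
    s <- summarize_ci(d$delta)
    data.frame(condition = d$condition[1], mode = d$mode[1], mean = s$mean,
               ci = s$half_width, n = s$n)
  }))
  rownames(summary) <- NULL
  .experiment_result("productivity", data, summary, config, seed,
                     extra = list(memory = memory, catalog = catalog))
}

#' Graded-displacement experiment
#'
#' For each generated scene, one object is displaced in `step`-pixel
#' increments along a random axis (horizontal or vertical) and the direct
#' composite dissimilarity between the reference scene and each displaced
#' variant is computed.  An ordinary least-squares regression of
#' dissimilarity on displacement is fitted over all `n_scenes * levels`
#' points.
#'
#' @param config A [chord_config()].
#' @param seed Master seed.
#' @param n_scenes Number of scene series.
#' @param levels Displacement levels per scene.
#' @param step Displacement increment in pixels.
#' @param encoder Optionally a pre-built encoder.
#' @return A `chord_experiment` with a `regression` block (slope, intercept,
#'   `r_squared`, `f_statistic`, `df_residual`, `p_value`).
#' @export
run_displacement <- function(config = chord_config(), seed = 1L,
                             n_scenes = 2000,
                             levels = config$displacement_levels,
                             step = config$displacement_step,
                             encoder = NULL) {
  if (is.null(encoder)) encoder <- chord_encoder(config, seed)
  fam <- config$object_categories[seq_len(config$n_familiar_categories)]
  rows <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    series <- with_seed(sub_seed(seed, 2000 + i), {
      objs <- list(object_spec(sample(fam, 1), sample.int(1e8, 1)),
                   object_spec(sample(fam, 1), sample.int(1e8, 1)))
      axis <- sample(c("horizontal", "vertical"), 1)
      base <- displacement_base_spec(objs, axis, config,
                                     id = sprintf("disp-%04d", i))
      c(make_displacement_series(base, axis, step, levels, config),
        list(axis_used = axis))
    })
    delta <- vapply(series$scenes, function(sc)
      compare_scenes(series$reference, sc, encoder)$composite, numeric(1))
    rows[[i]] <- data.frame(scene = i, axis = series$axis_used,
                            level = seq_len(levels),
                            displacement = series$displacement, delta = delta)
  }
  data <- do.call(rbind, rows)
  fit <- stats::lm(delta ~ displacement, data = data)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  regression <- list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    f_statistic = unname(fstat[1]),
    df_residual = unname(fstat[3]),
    p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                               lower.tail = FALSE)))
  summary_tab <- do.call(rbind, lapply(split(data, data$level), function(d) {
    s <- summarize_ci(d$delta)
    data.frame(level = d$level[1], displacement = d$displacement[1],
               mean = s$mean, ci = s$half_width, n = s$n)
  }))
  rownames(summary_tab) <- NULL
  .experiment_result("displacement", data, summary_tab, config, seed,
                     regression = regression)
}

#' Structural-change experiment: translation vs reversal
#'
#' For each generated base scene, builds a jointly translated variant (T), a
#' variant with the two objects' locations reversed (R), and one with both
#' transformations (TR), and records the direct composite dissimilarity
#' between base and variant.  The translation vector is drawn uniformly from
#' the in-bounds joint shifts of magnitude at least 10 px.
#'
#' @param config A [chord_config()].
#' @param seed Master seed.
#' @param n_per_condition Scenes per condition.
#' @param encoder Optionally a pre-built encoder.
#' @return A `chord_experiment`.
#' @export
run_qualitative <- function(config = chord_config(), seed = 1L,
                            n_per_condition = 2000, encoder = NULL) {
  if (is.null(encoder)) encoder <- chord_encoder(config, seed)
  fam <- config$object_categories[seq_len(config$n_familiar_categories)]
  half <- config$roi_size / 2
  lo <- half; hi <- config$scene_size - half
  rows <- list()
  for (cond in c("T", "R", "TR")) {
    for (i in seq_len(n_per_condition)) {
      pair <- with_seed(sub_seed(seed, 5000 + i +
                                   match(cond, c("T", "R", "TR")) * 100000), {
        objs <- list(object_spec(sample(fam, 1), sample.int(1e8, 1)),
                     object_spec(sample(fam, 1), sample.int(1e8, 1)))
        repeat {   # base with room for a non-trivial joint shift
          disp <- c(sample1((config$roi_size + 2):90), sample1(-35:35))
          base <- .place_with_displacement(objs, disp, config,
                                           id = sprintf("%s-%04d", cond, i))
          ctr <- base$centers
          dr <- c(lo - min(ctr[, 1]), hi - max(ctr[, 1]))
          dc <- c(lo - min(ctr[, 2]), hi - max(ctr[, 2]))
          if ((dr[2] - dr[1]) + (dc[2] - dc[1]) < 24) next
          tv <- c(0, 0); tries <- 0
          while (sqrt(sum(tv^2)) < 10 && tries < 200) {
            tv <- c(sample1(dr[1]:dr[2]), sample1(dc[1]:dc[2]))
            tries <- tries + 1
          }
          if (sqrt(sum(tv^2)) >= 10) break
        }
        list(base = make_scene(base, config),
             variant = make_transformed_scene(
               base, cond, translation = if (cond == "R") c(0, 0) else tv,
               config = config))
      })
      d <- compare_scenes(pair$base, pair$variant, encoder)$composite
      rows[[length(rows) + 1L]] <- data.frame(condition = cond, scene = i,
                                              delta = d)
    }
  }
  data <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(data, data$condition), function(d) {
    s <- summarize_ci(d$delta)
    data.frame(condition = d$condition[1], mean = s$mean, ci = s$half_width,
               n = s$n)
  }))
  rownames(summary) <- NULL
  summary <- summary[match(c("T", "R", "TR"), summary$condition), ]
  .experiment_result("qualitative", data, summary, config, seed)
}
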