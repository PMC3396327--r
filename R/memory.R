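# Associative scene memory: one record per (scene, fixation), keyed by the
# fixated-ROI chorus code in a multi-table LSH index.  Raw-mode payloads are
# kept on the same records and queried by brute force (raw Gabor keys have a
# different dimensionality, and the raw control is a representational
# comparison, not a hashing benchmark).

#' Create an empty scene memory
#'
#' The memory is an environment (records are appended in place).  Its hash
#' index is built lazily at the first query, calibrating the hash offsets on
#' the keys stored so far; later insertions are hashed incrementally.
#'
#' @param encoder A [chord_encoder()]; all stored and queried scenes are
#'   encoded with it.
#' @param params An [lsh_params()] for the index geometry.
#' @return An object of class `chord_memory`.
#' @examples
#' enc <- chord_encoder(chord_config(), seed = 1)
#' mem <- chord_memory(enc)
#' @export
chord_memory <- function(encoder,
                         params = lsh_params(
                           n_tables = encoder$config$lsh_tables,
                           bits_per_table = encoder$config$lsh_bits,
                           seed = sub_seed(encoder$seed, 77))) {
  stopifnot(inherits(encoder, "chord_encoder"))
  m <- new.env(parent = emptyenv())
  m$encoder <- encoder
  m$params <- params
  m$records <- list()
  m$ids <- new.env(hash = TRUE, parent = emptyenv())
  m$index <- NULL          # built lazily at first query
  m$n_indexed <- 0L
  class(m) <- "chord_memory"
  m
}

#' @export
print.chord_memory <- function(x, ...) {
  cat(sprintf("<chord_memory> %d records (%d scenes), index %s\n",
              length(x$records), length(x$records) / 2,
              if (is.null(x$index)) "not yet built" else "built"))
  invisible(x)
}

#' Number of records in a memory
#' @param x A `chord_memory`.
#' @return Integer record count (two per stored two-object scene).
#' @export
memory_size <- function(x) {
  stopifnot(inherits(x, "chord_memory"))
  length(x$records)
}

#' Store a scene in the memory
#'
#' The scene is encoded under each fixation and one record per fixation is
#' appended: the fixated-ROI code is the key; the payload carries the
#' other-ROI code, the layout code, the raw Gabor vectors and provenance.
#'
#' @param memory A [chord_memory()].
#' @param scene A `scene_image` (or scene matrix).
#' @param id Scene identifier; defaults to the scene's own id.  Storing the
#'   same (id, fixation) twice is an error.
#' @return Number of records added (invisibly): 2 for a two-object scene.
#' @export
store_scene <- function(memory, scene, id = NULL) {
  stopifnot(inherits(memory, "chord_memory"))
  if (is.null(id))
    id <- if (inherits(scene, "scene_image") && !is.null(scene$id)) scene$id
          else sprintf("scene-%05d", length(memory$records) / 2 + 1)
  reps <- encode_scene_full(scene, memory$encoder)
  for (fix in c("top", "bottom")) {
    tag <- paste(id, fix, sep = "#")
    if (!is.null(memory$ids[[tag]]))
      stop_chord("chord_duplicate_error",
                 "scene '%s' fixation '%s' is already stored", id, fix)
  }
  for (fix in c("top", "bottom")) {
    r <- reps[[fix]]
    rec <- list(key = r$fix_code, other = r$other_code,
                layout = r$layout_code, fix_raw = r$fix_raw,
                other_raw = r$other_raw, scene_id = id, fixation = fix)
    memory$records[[length(memory$records) + 1L]] <- rec
    memory$ids[[paste(id, fix, sep = "#")]] <- length(memory$records)
    if (!is.null(memory$index)) {
      lsh_insert(memory$index, rec$key, length(memory$records))
      memory$n_indexed <- memory$n_indexed + 1L
    }
  }
  invisible(2L)
}

# build the hash index over all records stored so far, plus flat matrices
# for vectorized dissimilarity evaluation
.build_memory_index <- function(memory) {
  n <- length(memory$records)
  if (n == 0) stop_chord("chord_empty_memory_error", "memory is empty")
  keys <- t(vapply(memory$records, `[[`, numeric(
    length(memory$records[[1]]$key)), "key"))
  idx <- lsh_index(ncol(keys), memory$params, calibration = keys)
  for (i in seq_len(n)) lsh_insert(idx, keys[i, ], i)
  memory$index <- idx
  memory$n_indexed <- n
  invisible(memory)
}

# flat matrices over all records, cached against the current record count
.memory_mats <- function(memory) {
  n <- length(memory$records)
  if (!is.null(memory$mats) && memory$mats$n == n) return(memory$mats)
  g <- function(field) t(vapply(memory$records, `[[`,
                                numeric(length(memory$records[[1]][[field]])),
                                field))
  memory$mats <- list(n = n, key = g("key"), other = g("other"),
                      layout = g("layout"), fix_raw = g("fix_raw"),
                      other_raw = g("other_raw"))
  memory$mats
}

.row_dist <- function(M, v) sqrt(pmax(rowSums(M * M) - 2 * drop(M %*% v) +
                                        sum(v * v), 0))

#' Dissimilarity between two scene representations
#'
#' The sum of the Euclidean distances between the three corresponding
#' components (fixated ROI, layout, other ROI), with equal weights.  This is
#' a pseudometric on representations: non-negative, symmetric, and obeying
#' the triangle inequality; it is zero iff all three components coincide.
#'
#' @param r1,r2 `scene_rep` objects of the same mode and component lengths.
#' @return An object of class `chord_dissimilarity`: list with `value` and
#'   the three `components` (named `fix`, `layout`, `other`).
#' @examples
#' # identical representations have dissimilarity 0
#' @export
scene_dissimilarity <- function(r1, r2) {
  stopifnot(inherits(r1, "scene_rep"), inherits(r2, "scene_rep"))
  if (!identical(r1$mode, r2$mode))
    stop_chord("chord_dimension_error", "representations differ in mode")
  if (length(r1$fix_code) != length(r2$fix_code) ||
      length(r1$other_code) != length(r2$other_code) ||
      length(r1$layout_code) != length(r2$layout_code))
    stop_chord("chord_dimension_error",
               "representations differ in component lengths")
  comp <- c(fix = sqrt(sum((r1$fix_code - r2$fix_code)^2)),
            layout = sqrt(sum((r1$layout_code - r2$layout_code)^2)),
            other = sqrt(sum((r1$other_code - r2$other_code)^2)))
  structure(list(value = sum(comp), components = comp),
            class = "chord_dissimilarity")
}

#' @export
print.chord_dissimilarity <- function(x, ...) {
  cat(sprintf("<chord_dissimilarity> %.4f (fix %.4f + layout %.4f + other %.4f)\n",
              x$value, x$components["fix"], x$components["layout"],
              x$components["other"]))
  invisible(x)
}

#' Query the memory with a scene
#'
#' The scene is encoded under both fixations.  For each fixation, candidate
#' records are gathered from the hash index (in `"ct"` mode; `"raw"` mode
#' scans all records), ranked by the three-component dissimilarity between
#' the query representation and each record, and the `k` best are kept.  If
#' the candidate set is empty the query falls back to a brute-force scan over
#' all records and the result is flagged.  The composite dissimilarity is
#' the mean over the two fixations of the best (minimum) match.
#'
#' @param memory A populated [chord_memory()].
#' @param scene A `scene_image` (or scene matrix).
#' @param k Matches reported per fixation.
#' @param mode `"ct"` or `"raw"`.
#' @return An object of class `chord_query`: list with `matches` (data frame:
#'   fixation, rank, scene_id, stored fixation, delta and its components),
#'   `best` (named per-fixation minima), `composite`, `fallback` (named
#'   logical) and `mode`.
#' @export
query_scene <- function(memory, scene, k = 5, mode = c("ct", "raw")) {
  mode <- match.arg(mode)
  stopifnot(inherits(memory, "chord_memory"))
  if (length(memory$records) == 0)
    stop_chord("chord_empty_memory_error", "memory is empty")
  if (is.null(memory$index)) .build_memory_index(memory)
  reps <- encode_scene_full(scene, memory$encoder)
  mats <- .memory_mats(memory)
  rows <- list(); best <- c(top = NA_real_, bottom = NA_real_)
  fallback <- c(top = FALSE, bottom = FALSE)
  for (fix in c("top", "bottom")) {
    r <- reps[[fix]]
    if (mode == "ct") {
      cand <- unlist(lsh_query(memory$index, r$fix_code))
      if (length(cand) == 0) {
        cand <- seq_len(length(memory$records))
        fallback[fix] <- TRUE
      }
      d_fix <- .row_dist(mats$key[cand, , drop = FALSE], r$fix_code)
      d_other <- .row_dist(mats$other[cand, , drop = FALSE], r$other_code)
    } else {
      cand <- seq_len(length(memory$records))
      d_fix <- .row_dist(mats$fix_raw[cand, , drop = FALSE], r$fix_raw)
      d_other <- .row_dist(mats$other_raw[cand, , drop = FALSE], r$other_raw)
    }
    d_lay <- .row_dist(mats$layout[cand, , drop = FALSE], r$layout_code)
    delta <- d_fix + d_lay + d_other
    ord <- order(delta)[seq_len(min(k, length(delta)))]
    rows[[fix]] <- data.frame(
      fixation = fix, rank = seq_along(ord),
      scene_id = vapply(memory$records[cand[ord]], `[[`, "", "scene_id"),
      stored_fixation = vapply(memory$records[cand[ord]], `[[`, "", "fixation"),
      delta = delta[ord], d_fix = d_fix[ord], d_layout = d_lay[ord],
      d_other = d_other[ord], row.names = NULL)
    best[fix] <- delta[ord[1]]
  }
  structure(list(matches = rbind(rows$top, rows$bottom), best = best,
                 composite = mean(best), fallback = fallback, mode = mode),
            class = "chord_query")
}

#' @export
print.chord_query <- function(x, ...) {
  cat(sprintf("<chord_query> mode %s, composite dissimilarity %.4f%s\n",
              x$mode, x$composite,
              if (any(x$fallback)) " (brute-force fallback used)" else ""))
  print(utils::head(x$matches, 4))
  invisible(x)
}

#' Direct (retrieval-free) composite dissimilarity of two scenes
#'
#' Encodes both scenes under both fixations and averages the per-fixation
#' dissimilarities — the comparison used by the displacement and structural-
#' change experiments, where the two scenes are given rather than retrieved.
#'
#' @param scene1,scene2 `scene_image`s (or scene matrices).
#' @param encoder A [chord_encoder()].
#' @param mode `"ct"` or `"raw"`.
#' @return List with `composite`, per-fixation `delta`, and `components`
#'   (2 x 3 matrix).
#' @export
compare_scenes <- function(scene1, scene2, encoder, mode = c("ct", "raw")) {
  mode <- match.arg(mode)
  a <- encode_scene_full(scene1, encoder)
  b <- encode_scene_full(scene2, encoder)
  ds <- lapply(c(top = "top", bottom = "bottom"), function(f)
    scene_dissimilarity(as_mode(a[[f]], mode), as_mode(b[[f]], mode)))
  delta <- vapply(ds, `[[`, numeric(1), "value")
  list(composite = mean(delta), delta = delta,
       components = t(vapply(ds, `[[`, numeric(3), "components")))
}

# ---- persistence ------------------------------------------------------------

#' Dump or load a memory as JSON lines
#'
#' One JSON object per record.  Loading reconstructs the record list; the
#' hash index is rebuilt lazily on the first query.
#'
#' @param memory A `chord_memory`.
#' @param path File path.
#' @param encoder Encoder to attach to the loaded memory (must be the one the
#'   records were encoded with for queries to be meaningful).
#' @return `dump_memory()` returns `path` invisibly; `load_memory()` a
#'   `chord_memory`.
#' @export
dump_memory <- function(memory, path) {
  stopifnot(inherits(memory, "chord_memory"))
  con <- file(path, "w"); on.exit(close(con))
  for (rec in memory$records)
    writeLines(jsonlite::toJSON(rec, digits = NA, auto_unbox = TRUE), con)
  invisible(path)
}

#' @rdname dump_memory
#' @export
load_memory <- function(path, encoder) {
  if (!file.exists(path))
    stop_chord("chord_parse_error", "memory dump not found: %s", path)
  lines <- readLines(path)
  m <- chord_memory(encoder)
  for (ln in lines) {
    rec <- jsonlite::fromJSON(ln)
    rec$key <- as.numeric(rec$key); rec$other <- as.numeric(rec$other)
    rec$layout <- as.numeric(rec$layout)
    rec$fix_raw <- as.numeric(rec$fix_raw)
    rec$other_raw <- as.numeric(rec$other_raw)
    m$records[[length(m$records) + 1L]] <- rec
    m$ids[[paste(rec$scene_id, rec$fixation, sep = "#")]] <- length(m$records)
  }
  m
}
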