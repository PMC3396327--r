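#' Parameters of the locality-sensitive hash index
#'
#' @param n_tables Number of hash tables (default 10).
#' @param bits_per_table Sign bits concatenated into one table address
#'   (default 64).
#' @param radius Neighbourhood radius `R` used when describing the locality
#'   property (collisions should be likely within `R`).
#' @param exclusion Exclusion factor `c > 1` (collisions should be unlikely
#'   beyond `c * R`).
#' @param seed Seed for drawing the hash family.
#' @return An object of class `lsh_params`.
#' @export
lsh_params <- function(n_tables = 10, bits_per_table = 64,
                       radius = 0.1, exclusion = 2, seed = 1L) {
  if (!is_count(n_tables) || !is_count(bits_per_table))
    stop_chord("chord_config_error", "n_tables and bits_per_table must be counts")
  if (!is.numeric(exclusion) || exclusion <= 1)
    stop_chord("chord_config_error", "exclusion factor c must be > 1")
  structure(list(n_tables = as.integer(n_tables),
                 bits_per_table = as.integer(bits_per_table),
                 radius = radius, exclusion = exclusion,
                 seed = as.integer(seed)),
            class = "lsh_params")
}

#' A single kernelized hash function
#'
#' The bit is the sign of a linear functional of the vector of kernel values
#' (here: distances) between the input and a set of landmark points:
#' `h(x) = sign(a' k_x - b)`, with `sign(0) = +1` for determinism.
#'
#' @param weights Numeric weight vector `a`, one weight per landmark.
#' @param offset Scalar offset `b`.
#' @param landmarks A [prototype_set()] of landmark points.
#' @return An object of class `kernel_hash`.
#' @examples
#' h <- kernel_hash_function(c(1, -1), 0, prototype_set(rbind(c(0, 0), c(1, 0))))
#' kernel_hash(c(0.2, 0), h)  # -1
#' @export
kernel_hash_function <- function(weights, offset, landmarks) {
  if (!inherits(landmarks, "chorus_prototypes"))
    stop_chord("chord_config_error", "landmarks must be a prototype_set")
  weights <- check_numeric_vector(weights, "weights")
  if (length(weights) != nrow(landmarks$prototypes))
    stop_chord("chord_dimension_error",
               "need one weight per landmark (%d != %d)",
               length(weights), nrow(landmarks$prototypes))
  structure(list(weights = weights, offset = as.numeric(offset),
                 landmarks = landmarks),
            class = "kernel_hash")
}

#' Evaluate a kernelized hash bit
#'
#' @param x Input vector in measurement space.
#' @param h A [kernel_hash_function()].
#' @return `+1` or `-1`.
#' @export
kernel_hash <- function(x, h) {
  stopifnot(inherits(h, "kernel_hash"))
  x <- check_numeric_vector(x, "x")
  if (length(x) != ncol(h$landmarks$prototypes))
    stop_chord("chord_dimension_error",
               "input has length %d but landmarks have length %d",
               length(x), ncol(h$landmarks$prototypes))
  kx <- .proto_dist(x, h$landmarks$prototypes, h$landmarks$p)
  v <- sum(h$weights * kx) - h$offset
  if (v >= 0) 1L else -1L
}

#' Winner-take-all hash of a chorus code
#'
#' Each bias vector perturbs the code and the index of the minimum perturbed
#' entry is recorded (minimum, because chorus-code entries are distances:
#' smaller means more similar).  With a zero bias this is plain
#' nearest-prototype assignment, i.e. the head of the rank-order code.  Ties
#' go to the lower index.
#'
#' @param code Numeric chorus code.
#' @param biases List of numeric bias vectors, each the length of `code`, or a
#'   matrix with one bias per row.
#' @return Integer vector of winner indices, one per bias vector.
#' @examples
#' wta_hash(c(0.5, 0.2, 0.9), list(c(0, 0.4, -0.9)))  # 3
#' @export
wta_hash <- function(code, biases) {
  code <- check_numeric_vector(code, "code")
  if (is.matrix(biases)) biases <- asplit(biases, 1)
  if (!is.list(biases) || length(biases) == 0)
    stop_chord("chord_config_error", "need a non-empty list of bias vectors")
  vapply(biases, function(b) {
    b <- check_numeric_vector(b, "bias")
    if (length(b) != length(code))
      stop_chord("chord_dimension_error", "bias length != code length")
    which.min(code + b)   # which.min ties to the lower index
  }, integer(1))
}

#' Draw a reproducible set of winner-take-all bias vectors
#'
#' @param n_biases Number of bias vectors.
#' @param dim Code length.
#' @param sd Standard deviation of the normal biases.
#' @param seed RNG seed.
#' @return List of `n_biases` numeric vectors.
#' @export
wta_biases <- function(n_biases, dim, sd = 1, seed = 1L) {
  if (!is_count(n_biases) || !is_count(dim))
    stop_chord("chord_config_error", "n_biases and dim must be counts")
  with_seed(seed, lapply(seq_len(n_biases),
                         function(i) stats::rnorm(dim, sd = sd)))
}

#' Pairwise-order agreement between two vectors
#'
#' Counts the index pairs on which the two vectors agree in order:
#' `PO(x, y) = sum_{i} sum_{j < i} T((x_i - x_j) (y_i - y_j))` with
#' `T(t) = 1` for `t > 0` and `0` otherwise.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Non-negative integer, at most `n (n - 1) / 2`.
#' @examples
#' pairwise_order(c(1, 2, 3), c(1, 3, 2))  # 2
#' @export
pairwise_order <- function(x, y) {
  x <- check_numeric_vector(x, "x"); y <- check_numeric_vector(y, "y")
  if (length(x) != length(y))
    stop_chord("chord_dimension_error", "vectors have different lengths")
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  sum((dx * dy)[lower.tri(dx)] > 0)
}

#' Min-k signature of a chorus code
#'
#' The set of indices of the `k` smallest code entries (the `k` nearest
#' prototypes); ties go to the lower index.  Collision probability of such
#' signatures tracks the Jaccard similarity of the underlying sets.
#'
#' @param code Numeric chorus code of length `n`.
#' @param k Signature size, `1 <= k <= n`.
#' @return Integer vector of `k` prototype indices, nearest first.
#' @examples
#' min_k_signature(c(0.5, 0.2, 0.9, 0.1), 2)  # 4, 2
#' @export
min_k_signature <- function(code, k) {
  code <- check_numeric_vector(code, "code")
  if (!is_count(k) || k > length(code))
    stop_chord("chord_config_error", "k must satisfy 1 <= k <= length(code)")
  order(code, seq_along(code))[seq_len(k)]
}

#' Jaccard similarity of two index sets
#'
#' @param a,b Vectors interpreted as sets; at least one must be non-empty.
#' @return `|a n b| / |a u b|` in `[0, 1]`.
#' @examples
#' jaccard(1:3, 2:4)  # 0.5
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0)
    stop_chord("chord_domain_error", "both sets are empty")
  length(intersect(a, b)) / length(u)
}

# ---- multi-table hash index over chorus codes -------------------------------

#' Create a locality-sensitive hash index over chorus codes
#'
#' Each table address concatenates `bits_per_table` sign bits
#' `sign(a' code - b)`; the weight vectors `a` are standard normal over the
#' code space (the code itself already being the vector of kernel values to
#' the landmarks) and each offset `b` is drawn uniformly between the 5th and
#' 95th percentile of `a' code` over a calibration sample, so that the bits
#' split the data cloud.  Without a calibration sample the offsets are zero.
#'
#' The index is an environment and is modified in place by [lsh_insert()].
#'
#' @param dim Code length the index is built for.
#' @param params An [lsh_params()] object.
#' @param calibration Optional numeric matrix of sample codes (one per row)
#'   used to place the offsets.
#' @return An object of class `lsh_index`.
#' @examples
#' idx <- lsh_index(3, lsh_params(seed = 7))
#' lsh_insert(idx, c(0.1, 0.5, 0.9), "rec-1")
#' lsh_query(idx, c(0.1, 0.5, 0.9))
#' @export
lsh_index <- function(dim, params = lsh_params(), calibration = NULL) {
  if (!is_count(dim)) stop_chord("chord_config_error", "dim must be a count")
  stopifnot(inherits(params, "lsh_params"))
  nb <- params$n_tables * params$bits_per_table
  A <- with_seed(params$seed, matrix(stats::rnorm(dim * nb), nrow = dim))
  b <- numeric(nb)
  if (!is.null(calibration)) {
    calibration <- as.matrix(calibration)
    if (ncol(calibration) != dim)
      stop_chord("chord_dimension_error",
                 "calibration codes have length %d, index expects %d",
                 ncol(calibration), dim)
    proj <- calibration %*% A
    qs <- apply(proj, 2, stats::quantile, probs = c(0.05, 0.95), names = FALSE)
    b <- with_seed(sub_seed(params$seed, 1), stats::runif(nb, qs[1, ], qs[2, ]))
  }
  idx <- new.env(parent = emptyenv())
  idx$dim <- as.integer(dim)
  idx$params <- params
  idx$A <- A
  idx$b <- b
  idx$tables <- lapply(seq_len(params$n_tables),
                       function(i) new.env(hash = TRUE, parent = emptyenv()))
  idx$n_stored <- 0L
  class(idx) <- "lsh_index"
  idx
}

# table addresses for one or more codes; codes as rows of a matrix
.lsh_addresses <- function(idx, codes) {
  codes <- if (is.matrix(codes)) codes else matrix(codes, nrow = 1)
  if (ncol(codes) != idx$dim)
    stop_chord("chord_dimension_error",
               "code length %d does not match index dimension %d",
               ncol(codes), idx$dim)
  bits <- sweep(codes %*% idx$A, 2, idx$b) >= 0    # sign(0) = +1
  nb <- idx$params$bits_per_table
  vapply(seq_len(idx$params$n_tables), function(t) {
    block <- bits[, ((t - 1) * nb + 1):(t * nb), drop = FALSE]
    apply(block, 1, function(z) paste(as.integer(z), collapse = ""))
  }, character(nrow(codes)))
}

#' Insert a record into a hash index
#'
#' The payload is appended to exactly one bucket per table, addressed by that
#' table's bit string for the key.
#'
#' @param idx An [lsh_index()].
#' @param key Numeric chorus code used as the key.
#' @param payload Arbitrary payload reference (typically a record id).
#' @return The index, invisibly (modified in place).
#' @export
lsh_insert <- function(idx, key, payload) {
  stopifnot(inherits(idx, "lsh_index"))
  addr <- .lsh_addresses(idx, as.numeric(key))
  for (t in seq_len(idx$params$n_tables)) {
    a <- addr[t]
    tab <- idx$tables[[t]]
    tab[[a]] <- c(tab[[a]], list(payload))
  }
  idx$n_stored <- idx$n_stored + 1L
  invisible(idx)
}

#' Query a hash index
#'
#' Returns the union, over tables, of the bucket contents at the key's
#' addresses, deduplicated.  An exact re-query of a stored key always
#' retrieves its payload.  Candidate ranking is left to the caller.
#'
#' @param idx An [lsh_index()].
#' @param key Numeric chorus code.
#' @return List of candidate payloads (possibly empty).
#' @export
lsh_query <- function(idx, key) {
  stopifnot(inherits(idx, "lsh_index"))
  addr <- .lsh_addresses(idx, as.numeric(key))
  out <- list()
  for (t in seq_len(idx$params$n_tables)) {
    hit <- idx$tables[[t]][[addr[t]]]
    if (!is.null(hit)) out <- c(out, hit)
  }
  out[!duplicated(out)]
}

#' @export
print.lsh_index <- function(x, ...) {
  cat(sprintf("<lsh_index> dim %d, %d tables x %d bits, %d records\n",
              x$dim, x$params$n_tables, x$params$bits_per_table, x$n_stored))
  invisible(x)
}
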