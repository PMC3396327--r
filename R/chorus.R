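#' Prototype sets for the chorus transform
#'
#' A prototype set is an ordered collection of reference points in measurement
#' space, together with the Minkowski exponent of the metric used to compare
#' inputs against them.  Duplicated prototypes are permitted but flagged with a
#' warning and recorded in the `"duplicated"` attribute.
#'
#' @param x Numeric matrix with one prototype per row, or a numeric vector
#'   (a single prototype).
#' @param p Minkowski exponent of the metric (`p >= 1`; `2` = Euclidean).
#' @return An object of class `chorus_prototypes`.
#' @examples
#' P <- prototype_set(rbind(c(0, 0), c(3, 4)))
#' chorus_transform(c(3, 0), P)
#' @export
prototype_set <- function(x, p = 2) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) < 1 || !all(is.finite(x)))
    stop_chord("chord_config_error",
               "prototypes must be a finite numeric matrix with >= 1 row")
  if (!is.numeric(p) || length(p) != 1 || p < 1)
    stop_chord("chord_config_error", "metric order p must be >= 1")
  dup <- duplicated(as.data.frame(x))
  if (any(dup))
    warning("prototype set contains duplicated prototypes (rows ",
            paste(which(dup), collapse = ", "), ")")
  structure(list(prototypes = unname(x), p = p, duplicated = dup),
            class = "chorus_prototypes")
}

#' @export
print.chorus_prototypes <- function(x, ...) {
  cat(sprintf("<chorus_prototypes> n = %d prototypes in R^%d, l_%g metric\n",
              nrow(x$prototypes), ncol(x$prototypes), x$p))
  invisible(x)
}

#' @export
length.chorus_prototypes <- function(x) nrow(x$prototypes)

# Fast internal path: Minkowski distances from vector x to the rows of P.
# The Euclidean branch uses the expanded quadratic form; entries driven to
# ~0 by cancellation are recomputed exactly so that self-distances are 0.
.proto_dist <- function(x, P, p) {
  if (p == 2) {
    d2 <- rowSums(P * P) - 2 * drop(P %*% x) + sum(x * x)
    d2 <- pmax(d2, 0)
    tiny <- which(d2 < 1e-8 * (sum(x * x) + 1))
    for (j in tiny) d2[j] <- sum((P[j, ] - x)^2)
    sqrt(d2)
  } else {
    rowSums(abs(sweep(P, 2, x))^p)^(1 / p)
  }
}

.ct_scale_value <- function(scale, n) {
  switch(scale,
         inv_sqrt_n = 1 / sqrt(n),
         inv_n      = 1 / n,
         one        = 1,
         stop_chord("chord_config_error", "unknown CT scale '%s'", scale))
}

#' The chorus transform
#'
#' Encodes an input vector as the vector of its scaled distances to an ordered
#' set of prototypes.  When the number of prototypes is smaller than the
#' measurement-space dimensionality this is a dimensionality reduction that
#' approximately preserves inter-point distance relations.
#'
#' @param x Numeric input vector.
#' @param P A [prototype_set()] whose prototypes have the same length as `x`.
#' @param scale Leading constant: `"inv_sqrt_n"` (default), `"inv_n"`, or
#'   `"one"`.
#' @return A `chorus_code`: numeric vector of length `length(P)` with
#'   attributes `scale` (the numeric constant used) and `scale_rule`.
#' @examples
#' P <- prototype_set(rbind(c(0, 0), c(3, 4)))
#' chorus_transform(c(3, 0), P)          # (3, 4) / sqrt(2)
#' chorus_transform(c(0, 0), P)[1] == 0  # self-zero
#' @export
chorus_transform <- function(x, P, scale = c("inv_sqrt_n", "inv_n", "one")) {
  scale <- match.arg(scale)
  if (!inherits(P, "chorus_prototypes"))
    stop_chord("chord_config_error", "P must be a prototype_set")
  x <- check_numeric_vector(x, "x")
  if (length(x) != ncol(P$prototypes))
    stop_chord("chord_dimension_error",
               "input has length %d but prototypes have length %d",
               length(x), ncol(P$prototypes))
  n <- nrow(P$prototypes)
  s <- .ct_scale_value(scale, n)
  structure(s * .proto_dist(x, P$prototypes, P$p),
            scale = s, scale_rule = scale, class = "chorus_code")
}

#' @export
print.chorus_code <- function(x, ...) {
  cat(sprintf("<chorus_code> n = %d, scale = %.4g\n", length(x),
              attr(x, "scale")))
  print(as.numeric(x), ...)
  invisible(x)
}

#' Rank-order-of-distances code
#'
#' Discretizes an input into the permutation of prototype indices ordered by
#' increasing distance to the input.  Ties are broken towards the lower
#' prototype index, so the code is deterministic.
#'
#' @inheritParams chorus_transform
#' @return Integer vector: a permutation of `1:n`, closest prototype first,
#'   of class `rod_code`.
#' @examples
#' P <- prototype_set(rbind(c(0, 0), c(3, 4), c(10, 0)))
#' rod_encode(c(3, 0), P)  # distances (3, 4, 7) -> order 1, 2, 3
#' @export
rod_encode <- function(x, P) {
  if (!inherits(P, "chorus_prototypes"))
    stop_chord("chord_config_error", "P must be a prototype_set")
  x <- check_numeric_vector(x, "x")
  if (length(x) != ncol(P$prototypes))
    stop_chord("chord_dimension_error",
               "input has length %d but prototypes have length %d",
               length(x), ncol(P$prototypes))
  d <- .proto_dist(x, P$prototypes, P$p)
  structure(order(d, seq_along(d)), class = "rod_code")
}

#' Compare two rank-order codes by Spearman correlation
#'
#' Each code is read as the ranking it assigns to the prototypes (the rank of
#' prototype `j` is its position in the list); the Spearman coefficient of the
#' two rankings is returned.  Since the codes are permutations there are no
#' ties and the closed form `1 - 6 * sum(d^2) / (n (n^2 - 1))` applies.
#'
#' @param a,b Rank-order codes ([rod_encode()] output or integer permutations)
#'   of equal length `n >= 2`.
#' @return Spearman correlation in `[-1, 1]`; exactly 1 iff `a == b`.
#' @examples
#' rod_compare(1:4, c(2, 1, 3, 4))  # 0.8
#' @export
rod_compare <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b))
    stop_chord("chord_dimension_error", "codes have different lengths")
  n <- length(a)
  if (n < 2)
    stop_chord("chord_config_error",
               "rank correlation needs at least 2 prototypes")
  if (!identical(sort(a), seq_len(n)) || !identical(sort(b), seq_len(n)))
    stop_chord("chord_domain_error", "codes must be permutations of 1..n")
  ra <- integer(n); ra[a] <- seq_len(n)   # rank assigned to each prototype
  rb <- integer(n); rb[b] <- seq_len(n)
  1 - 6 * sum((ra - rb)^2) / (n * (n^2 - 1))
}

#' Number of distinct rank-order codes
#'
#' @param n Prototype count (`n >= 0`).
#' @return `n!`, the number of permutations of the `n` prototype indices.
#' @examples
#' rod_code_count(10)  # 3628800
#' @export
rod_code_count <- function(n) {
  if (!is_count(n, min = 0))
    stop_chord("chord_domain_error", "n must be a non-negative integer")
  factorial(n)
}

#' Read and write prototype sets as CSV
#'
#' One prototype per row, plain numeric columns.  The metric order is not
#' stored in the file; supply it on reading.
#'
#' @param P A `chorus_prototypes` object.
#' @param path CSV file path.
#' @param p Minkowski exponent to attach on reading.
#' @return `write_prototypes()` returns `path` invisibly;
#'   `read_prototypes()` returns a `chorus_prototypes` object.
#' @export
write_prototypes <- function(P, path) {
  stopifnot(inherits(P, "chorus_prototypes"))
  utils::write.table(P$prototypes, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_prototypes
#' @export
read_prototypes <- function(path, p = 2) {
  if (!file.exists(path))
    stop_chord("chord_parse_error", "prototype file not found: %s", path)
  m <- tryCatch(as.matrix(utils::read.table(path, sep = ",", header = FALSE)),
                error = function(e)
                  stop_chord("chord_parse_error", "malformed prototype CSV %s: %s",
                             path, conditionMessage(e)))
  storage.mode(m) <- "double"
  prototype_set(m, p = p)
}
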