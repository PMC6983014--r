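#' Euclidean distance between two points
#'
#' @param x,y numeric vectors of equal length.
#' @return `sqrt(sum((x - y)^2))`.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y))
    stop(sprintf("dimension mismatch: %d vs %d", length(x), length(y)))
  sqrt(sum((x - y)^2))
}

.as_point_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1L)
  as.matrix(points)
}

#' Median sample of a point set
#'
#' The class median is the sample whose cumulated Euclidean distance to all
#' other samples of the set is minimal; ties break to the lowest row index.
#'
#' @param points numeric matrix, one point per row (a vector is treated as
#'   1-dimensional points).
#' @return the 1-based row index of the median sample.
#' @export
class_median <- function(points) {
  points <- .as_point_matrix(points)
  if (nrow(points) == 0L) stop("empty point set has no median")
  if (nrow(points) == 1L) return(1L)
  D <- as.matrix(stats::dist(points))
  unname(which.min(rowSums(D)))  # which.min: first (lowest-index) minimum
}

#' Within-class compactness of a point set
#'
#' Euclidean distance from the class median sample to the farthest sample of
#' the same class. The farthest sample is deliberately included: dropping an
#' outermost member would shrink the class boundary and misclassify future
#' samples near it.
#'
#' @param points numeric matrix, one point per row.
#' @return nonnegative scalar; 0 for a single point.
#' @export
within_class_compactness <- function(points) {
  points <- .as_point_matrix(points)
  if (nrow(points) == 0L) stop("empty point set")
  if (nrow(points) == 1L) return(0)
  D <- as.matrix(stats::dist(points))
  max(D[class_median(points), ])
}

#' Between-class distance of two point sets
#'
#' The minimum Euclidean distance over all cross pairs, i.e. the gap between
#' the closest boundary samples of the two classes.
#'
#' @param a,b numeric matrices, one point per row, equal column counts.
#' @return nonnegative scalar (0 when the classes touch or overlap).
#' @export
between_class_distance <- function(a, b) {
  a <- .as_point_matrix(a)
  b <- .as_point_matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty point set")
  if (ncol(a) != ncol(b)) stop("dimension mismatch between classes")
  # |p - q|^2 = |p|^2 + |q|^2 - 2 p.q, computed blockwise
  cross <- tcrossprod(a, b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * cross
  sqrt(max(min(d2), 0))
}

.zscore_columns <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2L, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  scale(x, center = mu, scale = s)
}

# Core computation on an already column-prepared matrix.
.objective_core <- function(xs, labels, aggregate, sentinel) {
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("objective requires at least 2 classes")
  idx <- lapply(classes, function(cl) which(labels == cl))
  D <- as.matrix(stats::dist(xs))
  med <- integer(length(classes))
  comp <- numeric(length(classes))
  for (i in seq_along(classes)) {
    ii <- idx[[i]]
    Di <- D[ii, ii, drop = FALSE]
    m <- which.min(rowSums(Di))
    med[i] <- ii[m]
    comp[i] <- max(Di[m, ])
  }
  pairs <- utils::combn(seq_along(classes), 2L)
  btw <- apply(pairs, 2L, function(p)
    min(D[idx[[p[1L]]], idx[[p[2L]]], drop = FALSE]))
  num <- if (aggregate == "worst") min(btw) else mean(btw)
  den <- if (aggregate == "worst") max(comp) else mean(comp)
  value <- if (den > 0) num / den else if (num > 0) sentinel else 0
  list(classes = classes, median_index = med, compactness = comp,
       pairs = pairs, between = btw, value = value)
}

.prep_objective_input <- function(x, labels, subset, zscore) {
  x <- as.matrix(x)
  if (length(labels) != nrow(x))
    stop("labels length must equal the number of rows")
  if (!is.null(subset)) {
    subset <- as.integer(subset)
    if (!length(subset)) stop("subset must select at least one column")
    if (any(subset < 1L | subset > ncol(x))) stop("subset index out of range")
    x <- x[, subset, drop = FALSE]
  }
  if (zscore) x <- .zscore_columns(x)
  x
}

#' Discriminant feature-distribution objective
#'
#' Ratio of between-class distance to within-class compactness, computed on
#' (by default z-scored) feature columns. With the default worst-case
#' aggregation the numerator is the minimum between-class distance over all
#' class pairs and the denominator the maximum within-class compactness over
#' classes, so maximizing the objective improves the worst-separated pair.
#' Perfectly compact, separated classes (zero denominator, positive
#' numerator) return the large finite `sentinel` so search comparisons stay
#' total; fully coincident classes return 0.
#'
#' @param x numeric matrix, one sample per row.
#' @param labels class ids, one per row; at least 2 classes, each with at
#'   least 2 samples, for the value to be meaningful.
#' @param subset optional integer column subset to restrict to.
#' @param aggregate `"worst"` (default) or `"mean"` (per-class/pair average).
#' @param zscore z-score each column (using the data handed in) before
#'   computing distances; default TRUE because the feature bank mixes units.
#' @param sentinel value returned when compactness is exactly 0 with
#'   positive separation; default 1e12.
#' @return a single numeric value.
#' @seealso [objective_report()] for the per-class breakdown.
#' @export
objective_value <- function(x, labels, subset = NULL,
                            aggregate = c("worst", "mean"),
                            zscore = TRUE, sentinel = 1e12) {
  aggregate <- match.arg(aggregate)
  xs <- .prep_objective_input(x, labels, subset, zscore)
  .objective_core(xs, labels, aggregate, sentinel)$value
}

#' Per-class breakdown of the discriminant objective
#'
#' @inheritParams objective_value
#' @return An object of class `objective_report`: per-class median row
#'   index and compactness, per-pair between-class distance, and the
#'   aggregate `value`.
#' @export
objective_report <- function(x, labels, subset = NULL,
                             aggregate = c("worst", "mean"),
                             zscore = TRUE, sentinel = 1e12) {
  aggregate <- match.arg(aggregate)
  xs <- .prep_objective_input(x, labels, subset, zscore)
  core <- .objective_core(xs, labels, aggregate, sentinel)
  structure(
    list(per_class = data.frame(class = core$classes,
                                median_index = core$median_index,
                                compactness = core$compactness),
         between = data.frame(class_a = core$classes[core$pairs[1L, ]],
                              class_b = core$classes[core$pairs[2L, ]],
                              distance = core$between),
         aggregate = aggregate,
         value = core$value),
    class = "objective_report")
}

#' @export
print.objective_report <- function(x, ...) {
  cat(sprintf("objective_report (%s aggregation): value = %g\n",
              x$aggregate, x$value))
  cat("per-class compactness:\n")
  print(x$per_class, row.names = FALSE)
  cat("between-class distances:\n")
  print(x$between, row.names = FALSE)
  invisible(x)
}

#' Serialize an objective report to JSON
#' @param report an `objective_report`.
#' @param path optional file; if `NULL` the JSON string is returned.
#' @export
objective_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "objective_report"))
  j <- jsonlite::toJSON(unclass(report), dataframe = "columns",
                        auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(path)
}

# Fast criterion factory for SFFS over a fixed pool: the pool columns are
# z-scored once, then J(S) evaluates the objective on the selected columns.
#' Build a filter-stage criterion from labeled feature columns
#'
#' Returns `J(indices)`, the discriminant objective restricted to the given
#' columns, for use with [sffs_search()]. Columns are z-scored once against
#' the pool handed in.
#'
#' @param x numeric matrix (samples x pool features).
#' @param labels class ids per row.
#' @param aggregate,sentinel passed to the objective.
#' @return function taking an integer index vector and returning the
#'   objective value.
#' @export
objective_criterion <- function(x, labels, aggregate = c("worst", "mean"),
                                sentinel = 1e12) {
  aggregate <- match.arg(aggregate)
  xs <- .zscore_columns(as.matrix(x))
  labels <- labels
  function(idx) {
    .objective_core(xs[, idx, drop = FALSE], labels, aggregate,
                    sentinel)$value
  }
}
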