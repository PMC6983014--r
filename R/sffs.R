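.check_J <- function(val, idx) {
  if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
    stop("criterion returned a non-finite value on subset {",
         paste(idx, collapse = ", "), "}")
  val
}

.new_trace <- function() {
  list(best_per_size = list(),
       steps = data.frame(action = character(), feature = integer(),
                          size = integer(), J = numeric()))
}

.record_best <- function(trace, subset, J) {
  k <- as.character(length(subset))
  cur <- trace$best_per_size[[k]]
  if (is.null(cur) || J > cur$J)
    trace$best_per_size[[k]] <- list(subset = subset, J = J)
  trace
}

.record_step <- function(trace, action, feature, subset, J) {
  trace$steps <- rbind(trace$steps, data.frame(
    action = action, feature = feature, size = length(subset), J = J))
  trace
}

.best_overall <- function(trace) {
  sizes <- as.integer(names(trace$best_per_size))
  Js <- vapply(trace$best_per_size, `[[`, numeric(1L), "J")
  # highest J; ties to the smaller subset
  ord <- order(-Js, sizes)
  trace$best_per_size[[ord[1L]]]
}

# argmax with deterministic lowest-candidate tie-break
.scan_best <- function(cands, eval_fn) {
  best_J <- -Inf
  best_c <- NA_integer_
  for (cand in cands) {
    J <- eval_fn(cand)
    if (J > best_J) {
      best_J <- J
      best_c <- cand
    }
  }
  list(feature = best_c, J = best_J)
}

#' Sequential floating forward search
#'
#' Greedy forward selection with conditional backward exclusion: after each
#' inclusion of the criterion-maximizing feature, features are removed (one
#' at a time, best removal first) for as long as removal strictly improves
#' the recorded best criterion at the smaller size. The strict-improvement
#' rule makes the recorded bests a monotone bounded sequence, so the search
#' always terminates. Ties in any argmax break to the lowest feature index,
#' making the search fully deterministic.
#'
#' @param n_features size of the feature pool (candidates are `1:n_features`).
#' @param J criterion function: takes an integer index vector, returns a
#'   single finite numeric to maximize.
#' @param d_max maximum subset size to visit; default 8.
#' @param min_improvement an inclusion must improve the criterion by at
#'   least this much to be accepted; default 1e-9, a float-noise guard.
#' @return list with `subset` (the best-criterion subset over all sizes
#'   visited, sorted), `J` (its criterion value), and `trace` (class
#'   `sffs_trace`: best subset per size and the full add/remove step log).
#' @export
sffs_search <- function(n_features, J, d_max = 8L, min_improvement = 1e-9) {
  n_features <- as.integer(n_features)
  if (n_features < 2L) stop("pool must contain at least 2 features")
  d_max <- as.integer(d_max)
  if (d_max < 1L || d_max > n_features)
    stop("d_max must satisfy 1 <= d_max <= n_features")
  evalJ <- function(idx) .check_J(J(idx), idx)

  trace <- .new_trace()
  Y <- integer(0)
  J_cur <- -Inf
  repeat {
    # inclusion step
    cands <- setdiff(seq_len(n_features), Y)
    if (!length(cands)) break
    inc <- .scan_best(cands, function(f) evalJ(sort(c(Y, f))))
    if (length(Y) > 0L && inc$J - J_cur < min_improvement) break
    Y <- sort(c(Y, inc$feature))
    J_cur <- inc$J
    trace <- .record_best(trace, Y, J_cur)
    trace <- .record_step(trace, "add", inc$feature, Y, J_cur)

    # conditional exclusion steps
    while (length(Y) >= 3L) {
      exc <- .scan_best(Y, function(f) evalJ(setdiff(Y, f)))
      smaller <- trace$best_per_size[[as.character(length(Y) - 1L)]]
      if (!is.null(smaller) && exc$J <= smaller$J) break
      Y <- setdiff(Y, exc$feature)
      J_cur <- exc$J
      trace <- .record_best(trace, Y, J_cur)
      trace <- .record_step(trace, "remove", exc$feature, Y, J_cur)
    }
    if (length(Y) >= d_max) break
  }
  best <- .best_overall(trace)
  class(trace) <- "sffs_trace"
  list(subset = sort(best$subset), J = best$J, trace = trace)
}

#' Plain sequential forward selection (greedy baseline)
#'
#' Adds the criterion-maximizing feature at every step, with no exclusion,
#' until `d_max` features are selected or no inclusion improves the
#' criterion. Serves as the baseline the floating search must dominate.
#'
#' @inheritParams sffs_search
#' @return list with `subset`, `J`, `trace` as in [sffs_search()].
#' @export
sfs_search <- function(n_features, J, d_max = 8L, min_improvement = 1e-9) {
  n_features <- as.integer(n_features)
  if (n_features < 1L) stop("pool must contain at least 1 feature")
  d_max <- as.integer(d_max)
  if (d_max < 1L || d_max > n_features)
    stop("d_max must satisfy 1 <= d_max <= n_features")
  evalJ <- function(idx) .check_J(J(idx), idx)
  trace <- .new_trace()
  Y <- integer(0)
  J_cur <- -Inf
  while (length(Y) < d_max) {
    cands <- setdiff(seq_len(n_features), Y)
    if (!length(cands)) break
    inc <- .scan_best(cands, function(f) evalJ(sort(c(Y, f))))
    if (length(Y) > 0L && inc$J - J_cur < min_improvement) break
    Y <- sort(c(Y, inc$feature))
    J_cur <- inc$J
    trace <- .record_best(trace, Y, J_cur)
    trace <- .record_step(trace, "add", inc$feature, Y, J_cur)
  }
  best <- .best_overall(trace)
  class(trace) <- "sffs_trace"
  list(subset = sort(best$subset), J = best$J, trace = trace)
}

#' @export
print.sffs_trace <- function(x, ...) {
  cat(sprintf("sffs_trace: %d steps, sizes visited: %s\n",
              nrow(x$steps),
              paste(sort(as.integer(names(x$best_per_size))),
                    collapse = ", ")))
  invisible(x)
}

#' Write a search trace as JSON lines
#'
#' One JSON object per step (`action`, `feature`, `size`, `J`), suitable as
#' an audit log.
#'
#' @param trace an `sffs_trace`.
#' @param path output file.
#' @export
sffs_trace_jsonl <- function(trace, path) {
  stopifnot(inherits(trace, "sffs_trace"))
  lines <- vapply(seq_len(nrow(trace$steps)), function(i)
    as.character(jsonlite::toJSON(as.list(trace$steps[i, ]),
                                  auto_unbox = TRUE, digits = NA)),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}
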