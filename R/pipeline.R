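.axis_names <- c("A_x", "A_y", "A_z", "G_x", "G_y", "G_z")

#' Column indices of one sensor axis in the 138-column feature matrix
#' @param axis axis number 1..6 (order: A_x, A_y, A_z, G_x, G_y, G_z) or an
#'   axis name from that set.
#' @return integer vector of 23 column indices.
#' @export
axis_columns <- function(axis) {
  if (is.character(axis)) axis <- match(axis, .axis_names)
  axis <- as.integer(axis)
  if (is.na(axis) || axis < 1L || axis > 6L) stop("axis must be 1..6")
  (axis - 1L) * 23L + 1:23
}

#' Pipeline configuration
#'
#' Collects every tunable of the hybrid selection pipeline with the
#' defaults used throughout: 128-sample windows with 50% overlap, five
#' filter iterations (hence 10 candidate subsets per axis), SFFS capped at
#' 8 features, a linear-kernel OAA SVM with C = 1, and wrapper-driven
#' refinement of the combined set switched on.
#'
#' @param seed master RNG seed for splits.
#' @param window_len,step windowing parameters in samples.
#' @param n_iterations filter iterations; each contributes 2 candidate
#'   subsets per axis.
#' @param d_max SFFS subset-size cap.
#' @param min_improvement SFFS inclusion threshold.
#' @param C,kernel SVM cost and kernel (`"linear"` or `"radial"`).
#' @param refine run a wrapper-accuracy-driven SFFS over the union of the
#'   per-axis winners (reduces the union to a compact final set).
#' @param aggregate objective aggregation, `"worst"` or `"mean"`.
#' @param val_fraction fraction of windows held out for validation.
#' @param filter_fraction fraction of the non-validation part given to the
#'   filter stage each iteration (the rest is the wrapper test half).
#' @param stratified stratify random splits by activity label.
#' @param group `NULL`, or `"experiment"` to assign whole recording
#'   sessions to the validation half (each user's alternate sessions).
#' @return an object of class `har_config`.
#' @export
har_config <- function(seed = 1L, window_len = 128L, step = 64L,
                       n_iterations = 5L, d_max = 8L,
                       min_improvement = 1e-9, C = 1,
                       kernel = c("linear", "radial"), refine = TRUE,
                       aggregate = c("worst", "mean"),
                       val_fraction = 0.5, filter_fraction = 0.5,
                       stratified = TRUE, group = NULL) {
  kernel <- match.arg(kernel)
  aggregate <- match.arg(aggregate)
  if (val_fraction <= 0 || val_fraction >= 1 ||
      filter_fraction <= 0 || filter_fraction >= 1)
    stop("fractions must lie in (0, 1)")
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  structure(list(seed = as.integer(seed), window_len = as.integer(window_len),
                 step = as.integer(step),
                 n_iterations = as.integer(n_iterations),
                 d_max = as.integer(d_max),
                 min_improvement = min_improvement, C = C, kernel = kernel,
                 refine = isTRUE(refine), aggregate = aggregate,
                 val_fraction = val_fraction,
                 filter_fraction = filter_fraction,
                 stratified = isTRUE(stratified), group = group),
            class = "har_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [har_config()] arguments.
#' @return a `har_config`.
#' @export
har_config_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configurations")
  vals <- yaml::read_yaml(path)
  do.call(har_config, vals[names(vals) %in% names(formals(har_config))])
}

# stratified draw of round(frac * n) indices per class (plain random draw
# when stratified = FALSE); idx is the index pool, labels parallel to idx
.draw_fraction <- function(idx, labels, frac, stratified) {
  if (!stratified)
    return(sort(sample(idx, floor(length(idx) * frac + 0.5))))
  taken <- integer(0)
  for (cl in sort(unique(labels))) {
    pool <- idx[labels == cl]
    k <- floor(length(pool) * frac + 0.5)
    taken <- c(taken, sample(pool, k))
  }
  sort(taken)
}

#' Split windows into validation, filter, and wrapper-test parts
#'
#' Half the windows (grouped by recording session when `group =
#' "experiment"`, otherwise a stratified random half) are set aside for
#' final validation and never touch selection. The remainder is re-split
#' independently in each filter iteration: a filter half, itself divided
#' into two equal parts that each feed one SFFS run, and a wrapper test
#' half used only to score candidate subsets. All draws derive from the
#' configuration seed, so the split plan is reproducible.
#'
#' @param fm a `har_features` object (labels and provenance included).
#' @param config a [har_config()].
#' @return list with `validation` (row indices) and `iterations`, a list of
#'   `n_iterations` lists with `filter_a`, `filter_b`, `wrapper_test`.
#' @export
split_dataset <- function(fm, config = har_config()) {
  stopifnot(inherits(fm, "har_features"))
  labels <- fm$label
  counts <- table(labels)
  small <- names(counts)[counts < 4L]
  if (length(small))
    stop("classes with fewer than 4 windows: ", paste(small, collapse = ", "))
  n <- length(labels)
  .with_seed(config$seed, {
    if (identical(config$group, "experiment") &&
        length(unique(fm$meta$experiment_id)) > 1L) {
      # hold out each user's alternate sessions (2nd, 4th, ...) wholesale
      val <- integer(0)
      for (u in unique(fm$meta$user_id)) {
        exps <- sort(unique(fm$meta$experiment_id[fm$meta$user_id == u]))
        hold <- exps[seq_along(exps) %% 2L == 0L]
        val <- c(val, which(fm$meta$user_id == u &
                              fm$meta$experiment_id %in% hold))
      }
      val <- sort(val)
    } else {
      val <- .draw_fraction(seq_len(n), labels, config$val_fraction,
                            config$stratified)
    }
    rest <- setdiff(seq_len(n), val)
    iterations <- lapply(seq_len(config$n_iterations), function(i) {
      filt <- .draw_fraction(rest, labels[rest],
                             config$filter_fraction, config$stratified)
      wrap <- setdiff(rest, filt)
      fa <- .draw_fraction(filt, labels[filt], 0.5, config$stratified)
      fb <- setdiff(filt, fa)
      list(filter_a = fa, filter_b = fb, wrapper_test = wrap)
    })
    list(validation = val, iterations = iterations)
  })
}

#' Filter stage: per-axis SFFS candidate subsets
#'
#' For each of the six sensor axes and each iteration, two independent SFFS
#' runs (one per filter half, each restricted to that axis's 23 feature
#' columns) maximize the discriminant feature-distribution objective,
#' yielding `2 * n_iterations` candidate subsets per axis (10 at the
#' defaults, 60 overall).
#'
#' @param fm a `har_features` object.
#' @param splits output of [split_dataset()].
#' @param config a [har_config()].
#' @return object of class `axis_candidates`: named list (one entry per
#'   axis) of candidate lists, each candidate carrying `subset` (base
#'   feature indices 1..23), `columns` (global column ids), `filter_J`,
#'   `iteration`, `half`.
#' @export
run_filter <- function(fm, splits, config = har_config()) {
  stopifnot(inherits(fm, "har_features"))
  out <- vector("list", 6L)
  names(out) <- .axis_names
  for (axis in 1:6) {
    cols <- axis_columns(axis)
    cands <- list()
    for (it in seq_along(splits$iterations)) {
      halves <- splits$iterations[[it]][c("filter_a", "filter_b")]
      for (h in c("filter_a", "filter_b")) {
        rows <- halves[[h]]
        J <- objective_criterion(fm$x[rows, cols, drop = FALSE],
                                 fm$label[rows],
                                 aggregate = config$aggregate)
        res <- sffs_search(23L, J, d_max = config$d_max,
                           min_improvement = config$min_improvement)
        cands[[length(cands) + 1L]] <- list(
          subset = res$subset, columns = cols[res$subset],
          filter_J = res$J, iteration = it,
          half = if (h == "filter_a") "a" else "b")
      }
    }
    out[[axis]] <- cands
  }
  class(out) <- "axis_candidates"
  out
}

#' @export
print.axis_candidates <- function(x, ...) {
  for (ax in names(x))
    cat(sprintf("%s: %d candidate subsets (sizes %s)\n", ax, length(x[[ax]]),
                paste(vapply(x[[ax]], function(c) length(c$subset),
                             integer(1L)), collapse = ", ")))
  invisible(x)
}

.wrapper_accuracy <- function(fm, cols, train_rows, test_rows, config) {
  model <- train_oaa_linear(fm$x[train_rows, cols, drop = FALSE],
                            fm$label[train_rows],
                            C = config$C, kernel = config$kernel)
  evaluate_oaa(model, fm$x[test_rows, cols, drop = FALSE],
               fm$label[test_rows])$accuracy
}

#' Wrapper stage: pick the best candidate subset per axis by SVM accuracy
#'
#' Every candidate subset is scored by training a one-against-all SVM on
#' the two filter halves of its own iteration (combined) and measuring
#' accuracy on that iteration's wrapper test half. Per axis the candidate
#' with the highest accuracy wins; ties break to the smaller subset, then
#' to the lexicographically smallest feature indices.
#'
#' @param candidates output of [run_filter()].
#' @param fm a `har_features` object.
#' @param splits output of [split_dataset()].
#' @param config a [har_config()].
#' @return named list (per axis) with `subset`, `columns`, `accuracy`, and
#'   `all_accuracies` (one value per candidate, in candidate order).
#' @export
run_wrapper <- function(candidates, fm, splits, config = har_config()) {
  stopifnot(inherits(candidates, "axis_candidates"))
  out <- vector("list", 6L)
  names(out) <- .axis_names
  for (ax in names(candidates)) {
    cands <- candidates[[ax]]
    if (!length(cands)) stop("no candidate subsets for axis ", ax)
    accs <- vapply(cands, function(cand) {
      it <- splits$iterations[[cand$iteration]]
      .wrapper_accuracy(fm, cand$columns,
                        c(it$filter_a, it$filter_b), it$wrapper_test,
                        config)
    }, numeric(1L))
    best <- 1L
    for (i in seq_along(cands)[-1L]) {
      a <- cands[[i]]; b <- cands[[best]]
      better <- accs[i] > accs[best] ||
        (accs[i] == accs[best] &&
           (length(a$subset) < length(b$subset) ||
              (length(a$subset) == length(b$subset) &&
                 .lex_less(a$subset, b$subset))))
      if (better) best <- i
    }
    out[[ax]] <- list(subset = cands[[best]]$subset,
                      columns = cands[[best]]$columns,
                      accuracy = accs[best],
                      candidate = best,
                      all_accuracies = accs)
  }
  out
}

.lex_less <- function(a, b) {
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Combine per-axis winners, optionally refine, and validate
#'
#' The union of the six per-axis best subsets forms the combined feature
#' set. With `refine = TRUE` (default) a second, wrapper-accuracy-driven
#' SFFS over that union compresses it to a compact final set (the
#' mechanism that takes a ~40-feature union down to a handful). The final
#' model is trained on all non-validation windows and evaluated on the
#' validation half, both with the selected set and with all 138 features
#' as the no-selection baseline.
#'
#' @param best_per_axis output of [run_wrapper()].
#' @param fm a `har_features` object.
#' @param splits output of [split_dataset()].
#' @param config a [har_config()].
#' @return list with `final_columns`, `final_names`, `union_columns`,
#'   `confusion_selected`, `confusion_baseline`, and `refine_trace` (or
#'   `NULL` when refinement is off).
#' @export
combine_and_validate <- function(best_per_axis, fm, splits,
                                 config = har_config()) {
  union_cols <- sort(unique(unlist(lapply(best_per_axis, `[[`, "columns"))))
  if (!length(union_cols)) stop("empty union of per-axis subsets")
  refine_trace <- NULL
  if (config$refine && length(union_cols) > 1L) {
    # averaging the wrapper accuracy over every iteration's split keeps the
    # refinement from overfitting (or saturating on) a single test half
    J <- function(idx) {
      cols <- union_cols[idx]
      mean(vapply(splits$iterations, function(it)
        .wrapper_accuracy(fm, cols, c(it$filter_a, it$filter_b),
                          it$wrapper_test, config), numeric(1L)))
    }
    res <- sffs_search(length(union_cols), J,
                       d_max = min(config$d_max, length(union_cols)),
                       min_improvement = config$min_improvement)
    final_cols <- union_cols[res$subset]
    refine_trace <- res$trace
  } else {
    final_cols <- union_cols
  }
  trainval <- sort(unlist(c(splits$iterations[[1L]][c("filter_a", "filter_b",
                                                      "wrapper_test")])))
  val <- splits$validation
  model_sel <- train_oaa_linear(fm$x[trainval, final_cols, drop = FALSE],
                                fm$label[trainval],
                                C = config$C, kernel = config$kernel)
  cm_sel <- evaluate_oaa(model_sel, fm$x[val, final_cols, drop = FALSE],
                         fm$label[val])
  model_all <- train_oaa_linear(fm$x[trainval, , drop = FALSE],
                                fm$label[trainval],
                                C = config$C, kernel = config$kernel)
  cm_all <- evaluate_oaa(model_all, fm$x[val, , drop = FALSE],
                         fm$label[val])
  list(final_columns = final_cols,
       final_names = har_feature_names()[final_cols],
       union_columns = union_cols,
       confusion_selected = cm_sel,
       confusion_baseline = cm_all,
       refine_trace = refine_trace)
}

#' Run the full hybrid feature-selection pipeline
#'
#' Splits the windows, runs the per-axis SFFS filter (10 candidate subsets
#' per axis at the defaults), scores candidates with the SVM wrapper,
#' combines and optionally refines the per-axis winners, and validates the
#' final set against the all-features baseline on the held-out half.
#'
#' @param fm a `har_features` object from [extract_features()].
#' @param config a [har_config()].
#' @return An object of class `har_pipeline_result`.
#' @export
run_pipeline <- function(fm, config = har_config()) {
  stopifnot(inherits(fm, "har_features"))
  splits <- split_dataset(fm, config)
  candidates <- run_filter(fm, splits, config)
  best <- run_wrapper(candidates, fm, splits, config)
  final <- combine_and_validate(best, fm, splits, config)
  structure(list(config = config,
                 n_windows = nrow(fm$x),
                 candidates = candidates,
                 best_per_axis = best,
                 final_columns = final$final_columns,
                 final_names = final$final_names,
                 union_columns = final$union_columns,
                 confusion_selected = final$confusion_selected,
                 confusion_baseline = final$confusion_baseline,
                 splits = splits),
            class = "har_pipeline_result")
}

#' @export
print.har_pipeline_result <- function(x, ...) {
  cat("hybrid feature-selection pipeline result\n")
  cat(sprintf("  windows: %d; candidates: %d per axis (%d total)\n",
              x$n_windows, length(x$candidates[[1L]]),
              sum(vapply(x$candidates, length, integer(1L)))))
  for (ax in names(x$best_per_axis)) {
    b <- x$best_per_axis[[ax]]
    cat(sprintf("  %s best subset {%s}, wrapper accuracy %.4f\n", ax,
                paste0("f_", b$subset, collapse = ", "), b$accuracy))
  }
  cat(sprintf("  final set (%d): %s\n", length(x$final_names),
              paste(x$final_names, collapse = ", ")))
  cat(sprintf("  validation accuracy: %.4f with selection, %.4f without\n",
              x$confusion_selected$accuracy, x$confusion_baseline$accuracy))
  invisible(x)
}

#' Serialize a pipeline result to canonical JSON
#'
#' The serialization is a pure function of the result (no timestamps or
#' environment echoes), so identical data, configuration and seed produce
#' byte-identical JSON.
#'
#' @param res a `har_pipeline_result`.
#' @param path optional output file; if `NULL`, the JSON string is returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
pipeline_result_json <- function(res, path = NULL) {
  stopifnot(inherits(res, "har_pipeline_result"))
  payload <- list(
    config = unclass(res$config),
    n_windows = res$n_windows,
    candidates = lapply(res$candidates, function(ax) lapply(ax, function(c)
      list(subset = c$subset, filter_J = c$filter_J,
           iteration = c$iteration, half = c$half))),
    best_per_axis = lapply(res$best_per_axis, function(b)
      list(subset = b$subset, accuracy = b$accuracy,
           all_accuracies = b$all_accuracies)),
    final_features = res$final_names,
    final_columns = res$final_columns,
    union_columns = res$union_columns,
    validation = list(
      accuracy_selected = res$confusion_selected$accuracy,
      accuracy_baseline = res$confusion_baseline$accuracy,
      recall_selected = unname(res$confusion_selected$recall),
      precision_selected = unname(res$confusion_selected$precision),
      counts_selected = unname(res$confusion_selected$counts)))
  j <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                        null = "null")
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(j)
}
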