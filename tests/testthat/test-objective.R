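test_that("euclidean distance matches hand values and a loop oracle", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(1:5, 1:5), 0)
  expect_error(euclidean_distance(1:3, 1:4), "mismatch")
  harsel:::.with_seed(3L, {
    for (i in 1:20) {
      a <- rnorm(10)
      b <- rnorm(10)
      expect_equal(euclidean_distance(a, b),
                   sqrt(sum(vapply(1:10, function(j) (a[j] - b[j])^2,
                                   numeric(1L)))),
                   tolerance = 1e-12)
    }
  })
})

test_that("class median minimizes the cumulated distance with ties to the
           lowest index", {
  # 1-D points {0, 1, 10}: cumulated distances 11, 10, 19 -> median is 1
  expect_identical(class_median(matrix(c(0, 1, 10), ncol = 1)), 2L)
  expect_identical(class_median(matrix(c(2, 2), ncol = 1)), 1L)
  expect_identical(class_median(matrix(5, ncol = 1)), 1L)
  expect_error(class_median(matrix(numeric(0), ncol = 1)), "empty")
})

test_that("compactness is the median-to-farthest distance and grows with
           outliers", {
  pts <- matrix(c(0, 0, 0, 1), ncol = 2, byrow = TRUE)
  expect_equal(within_class_compactness(pts), 1)
  expect_equal(within_class_compactness(matrix(3, 4, 2)), 0)
  expect_equal(within_class_compactness(matrix(c(1, 1), ncol = 2)), 0)
  base <- toy_points(centers = list(c(0, 0)))$x
  with_outlier <- rbind(base, c(50, 50))
  expect_gt(within_class_compactness(with_outlier),
            within_class_compactness(base))
})

test_that("between-class distance is the minimum cross-pair gap, symmetric", {
  a <- matrix(c(0, 0, 0, 1), ncol = 2, byrow = TRUE)
  b <- matrix(c(10, 0, 10, 1), ncol = 2, byrow = TRUE)
  expect_equal(between_class_distance(a, b), 10)
  expect_equal(between_class_distance(b, a), 10)
  expect_equal(between_class_distance(a, rbind(b, c(0, 1))), 0)
})

test_that("objective agrees with brute force on random labeled point sets", {
  # dimensions >= 2: in 1-D with even class sizes the cumulated-distance
  # profile is flat between the two middle points, so median ties are
  # generic there and tie-breaking under float rounding is not comparable
  # across independent implementations
  harsel:::.with_seed(23L, {
    for (i in 1:60) {
      k <- sample(2:4, 1L)
      n_per <- sample(3:10, 1L)
      d <- sample(2:8, 1L)
      x <- matrix(rnorm(k * n_per * d, sd = 2), ncol = d)
      labels <- rep(seq_len(k), each = n_per)
      x <- x + labels  # shift classes apart a little
      expect_equal(objective_value(x, labels),
                   oracle_objective(x, labels), tolerance = 1e-9)
    }
  })
})

test_that("objective handles separations, degeneracies and invariances", {
  # two tight classes far apart, unscaled: ratio is 10 by construction
  x <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  labels <- c(1, 1, 2, 2)
  expect_equal(objective_value(x, labels, zscore = FALSE), 10)

  # coincident classes give 0; compact separated classes hit the sentinel
  xc <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1))
  expect_equal(objective_value(xc, labels, zscore = FALSE), 0)
  xs <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  expect_equal(objective_value(xs, labels, zscore = FALSE), 1e12)

  expect_error(objective_value(x, rep(1, 4)), "2 classes")

  # rigid motions leave the unscaled objective unchanged
  tp <- toy_points()
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- tp$x %*% R + matrix(c(3, -2), nrow(tp$x), 2, byrow = TRUE)
  expect_equal(objective_value(rot, tp$labels, zscore = FALSE),
               objective_value(tp$x, tp$labels, zscore = FALSE),
               tolerance = 1e-9)

  # duplicating every point changes nothing (unscaled: the sample-sd
  # z-scoring itself depends weakly on n)
  expect_equal(objective_value(rbind(tp$x, tp$x), rep(tp$labels, 2),
                               zscore = FALSE),
               objective_value(tp$x, tp$labels, zscore = FALSE),
               tolerance = 1e-9)

  # pushing one class away never decreases the unscaled objective
  base <- objective_value(tp$x, tp$labels, zscore = FALSE)
  moved <- tp$x
  moved[tp$labels == 2, ] <- moved[tp$labels == 2, ] + 100
  expect_gte(objective_value(moved, tp$labels, zscore = FALSE), base)
})

test_that("objective report carries consistent per-class pieces", {
  tp <- toy_points()
  rep_ <- objective_report(tp$x, tp$labels)
  expect_s3_class(rep_, "objective_report")
  expect_identical(rep_$per_class$class, sort(unique(tp$labels)))
  expect_true(all(rep_$per_class$compactness >= 0))
  expect_identical(nrow(rep_$between), 3L)
  expect_equal(rep_$value, objective_value(tp$x, tp$labels))
  j <- objective_report_json(rep_)
  expect_true(jsonlite::validate(j))
})

test_that("objective_criterion matches objective_value on column subsets", {
  tp <- toy_points()
  x <- cbind(tp$x, matrix(rnorm(nrow(tp$x) * 3), ncol = 3))
  J <- objective_criterion(x, tp$labels)
  for (s in list(1L, c(1L, 2L), c(2L, 4L), 1:5))
    expect_equal(J(s), objective_value(x, tp$labels, subset = s),
                 tolerance = 1e-12)
})
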