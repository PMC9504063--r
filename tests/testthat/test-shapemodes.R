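make_class_contours <- function(n_per_class, classes, seed0 = 1000L) {
  labels <- rep(seq_along(classes), each = n_per_class)
  contours <- lapply(seq_along(labels), function(i)
    extract_contour(render_cell(classes[[labels[i]]], rng_seed = seed0 + i)))
  list(contours = contours, labels = labels)
}

test_that("train/test split is stratified, exhaustive and seeded", {
  s <- split_train_test(1:100, train_fraction = 0.8, seed = 3)
  expect_identical(length(s$train), 80L)
  expect_identical(length(s$test), 20L)
  expect_setequal(c(s$train, s$test), 1:100)
  # per-group 8/2 on two groups of 10
  g <- rep(c("a", "b"), each = 10)
  s2 <- split_train_test(1:20, groups = g, seed = 3)
  expect_identical(sum(s2$train <= 10), 8L)
  expect_identical(sum(s2$train > 10), 8L)
  # determinism
  expect_identical(split_train_test(1:100, seed = 3), s)
  expect_false(identical(split_train_test(1:100, seed = 4)$train, s$train))
  # a 1-cell group goes wholly to test
  g3 <- c(rep("a", 9), "b")
  expect_message(s3 <- split_train_test(1:10, groups = g3, seed = 1), "test")
  expect_true(10 %in% s3$test)
})

test_that("the fitted model is deterministic with orthonormal components", {
  cc <- make_class_contours(30, list(amoeboid_class(1), ramified_class()))
  m1 <- shape_modes(cc$contours, k = 2, seed = 11)
  m2 <- shape_modes(cc$contours, k = 2, seed = 11)
  expect_equal(m1$centers, m2$centers)
  expect_identical(m1$cluster, m2$cluster)
  # orthonormal basis
  G <- unname(crossprod(m1$basis))
  expect_equal(G, diag(ncol(m1$basis)), tolerance = 1e-8)
  # explained variance non-increasing and a model summary that adds up
  expect_true(all(diff(m1$explained_variance) <= 1e-12))
  expect_gte(sum(m1$explained_variance[seq_len(m1$n_components_used)]), 0.95 - 1e-9)
  # k distinct centroids
  expect_gt(min(stats::dist(m1$centers)), 0)
  expect_error(shape_modes(cc$contours[1:3], k = 5), class = "mgmorph_param_error")
})

test_that("duplicating every training contour leaves the model unchanged", {
  cc <- make_class_contours(20, list(amoeboid_class(1), ramified_class()))
  m1 <- shape_modes(cc$contours, k = 2, seed = 7)
  m2 <- shape_modes(c(cc$contours, cc$contours), k = 2, seed = 7)
  expect_equal(m1$centers, m2$centers, tolerance = 1e-6)
  expect_equal(m1$mean_shape, m2$mean_shape, tolerance = 1e-9)
})

test_that("centroid shapes map to their own modes; assignments are invariant", {
  cc <- make_class_contours(30, list(amoeboid_class(1), ramified_class()))
  m <- shape_modes(cc$contours, k = 2, seed = 11)
  # fixed point: the back-projected centroid contours classify as themselves
  cents <- coef(m)
  pr <- predict(m, cents)
  expect_identical(pr$sm, seq_len(m$k))
  # translation/rotation of inputs does not change assignments
  pr0 <- predict(m, cc$contours)
  move <- function(v, th, dr, dc) cbind(
    v[, 1] * cos(th) + v[, 2] * sin(th) + dr,
    -v[, 1] * sin(th) + v[, 2] * cos(th) + dc)
  pr1 <- predict(m, lapply(cc$contours, move, th = 1.1, dr = 40, dc = -12))
  expect_identical(pr0$sm, pr1$sm)
})

test_that("two planted classes are recovered almost perfectly (k = 2)", {
  cc <- make_class_contours(60, list(amoeboid_class(1), ramified_class()))
  split <- split_train_test(seq_along(cc$contours), groups = cc$labels, seed = 5)
  m <- shape_modes(cc$contours[split$train], k = 2, seed = 5)
  pr <- predict(m, cc$contours[split$test])
  ari <- adjusted_rand_index(pr$sm, cc$labels[split$test])
  expect_gte(ari, 0.9)
  # our ARI agrees with the mclust reference implementation
  expect_equal(ari, mclust::adjustedRandIndex(pr$sm, cc$labels[split$test]))
})

test_that("five planted classes are recovered with k = 5", {
  classes <- list(
    amoeboid = amoeboid_class(1),
    rod      = shape_class_spec(20, elongation = 3),
    bipolar  = shape_class_spec(14, n_branches = 2, branch_length_um = 35,
                                branch_width_um = 6, tortuosity = 0.2),
    ramified = ramified_class(),
    bushy    = shape_class_spec(18, n_branches = 6, branch_length_um = 15,
                                branch_width_um = 8, tortuosity = 0.4))
  cc <- make_class_contours(40, classes, seed0 = 5000L)
  split <- split_train_test(seq_along(cc$contours), groups = cc$labels, seed = 2)
  m <- shape_modes(cc$contours[split$train], k = 5, seed = 2)
  pr <- predict(m, cc$contours)
  expect_gte(adjusted_rand_index(pr$sm, cc$labels), 0.7)
  # SM labels ordered by increasing mean aspect ratio
  expect_true(all(diff(m$mean_aspect_ratio) >= 0))
  expect_s3_class(m$linkage, "hclust")
})

test_that("frequency rows sum to 100 with the spreadsheet variance convention", {
  # one group concentrated in a single mode of five
  f1 <- sm_frequency(rep(3L, 12), rep("g", 12), k = 5)
  expect_equal(unname(rowSums(f1$freq)), 100)
  expect_equal(unname(f1$freq["g", ]), c(0, 0, 100, 0, 0))
  expect_equal(unname(f1$variance["g"]), stats::var(c(100, 0, 0, 0, 0)))
  expect_equal(unname(f1$variance["g"]), 2000)
  # uniform assignment: zero variance
  f2 <- sm_frequency(rep(1:5, 4), rep("g", 20), k = 5)
  expect_equal(unname(f2$freq["g", ]), rep(20, 5))
  expect_equal(unname(f2$variance["g"]), 0)
  # multiple groups: each row sums to 100 within 1e-6
  set.seed(2)
  sm <- sample(1:5, 300, replace = TRUE)
  gr <- sample(c("a", "b", "c"), 300, replace = TRUE)
  f3 <- sm_frequency(sm, gr, k = 5)
  expect_true(all(abs(rowSums(f3$freq) - 100) < 1e-6))
  expect_true(all(f3$variance >= 0))
})

test_that("sm_feature_table joins assignments to records and flags gaps", {
  rec <- data.frame(cell_id = c("a", "b", "c"), area_um2 = c(1, 2, 3),
                    degenerate = FALSE)
  asg <- data.frame(cell_id = c("b", "c"), sm = c(2L, 1L))
  tab <- sm_feature_table(asg, rec)
  expect_identical(tab$sm, c(2L, 1L))
  expect_identical(tab$area_um2, c(2, 3))
  bad <- data.frame(cell_id = "zz", sm = 1L)
  expect_error(sm_feature_table(bad, rec), "zz", class = "mgmorph_param_error")
  empty <- data.frame(cell_id = character(), sm = integer())
  expect_identical(nrow(sm_feature_table(empty, rec)), 0L)
})

test_that("a model survives the JSON round trip with identical assignments", {
  cc <- make_class_contours(25, list(amoeboid_class(1), ramified_class()))
  m <- shape_modes(cc$contours, k = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_shape_mode_model(m, path)
  m2 <- read_shape_mode_model(path)
  expect_identical(predict(m2, cc$contours)$sm, predict(m, cc$contours)$sm)
})
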