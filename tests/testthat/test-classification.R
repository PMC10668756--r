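test_that("feature extraction is plain arithmetic on the masks", {
  px <- matrix(0L, 40, 100)
  head <- make_disc(40, 100, 20, 15, 6)
  tail <- make_rect(40, 100, 14, 26, 22, 90)
  px[head] <- 200L
  px[tail] <- 50L
  f <- extract_features(intensity_image(px), head, tail)
  expect_equal(f$mean_head_intensity, 200)
  expect_equal(f$mean_tail_intensity, 50)
  expect_equal(f$head_tail_area_ratio, sum(head) / sum(tail))
  # head sits at the far left of the combined bounding box
  expect_lt(f$head_relative_position, -0.8)

  empty <- matrix(FALSE, 40, 100)
  f2 <- extract_features(intensity_image(px), head, empty)
  expect_equal(f2$mean_tail_intensity, 0)
  expect_equal(f2$head_tail_area_ratio, 100)  # the configured cap
  expect_error(extract_features(intensity_image(px), empty, tail), "empty head")
})

make_separable_set <- function(n = 40) {
  set.seed(123)
  ratio <- c(runif(n / 2, 0.05, 0.5), runif(n / 2, 30, 100))
  data.frame(head_tail_area_ratio = ratio,
             head_relative_position = runif(n, -1, 1),
             mean_head_intensity = runif(n, 150, 250),
             mean_tail_intensity = runif(n, 0, 60))
}

test_that("a perfectly separable single feature yields a depth-1 pure tree", {
  df <- make_separable_set(40)
  labels <- rep(c("tailed_comet", "head_only"), each = 20)
  tree <- train_tree(df, labels, depth_limit = 3)
  expect_true(tree$root$left$leaf && tree$root$right$leaf)
  expect_equal(tree$root$feature, 1L)
  expect_equal(tree$root$left$purity, 1)
  expect_equal(tree$root$right$purity, 1)
  expect_equal(unname(predict(tree, df)), labels)
})

test_that("label inversion swaps leaf classes but keeps the structure", {
  df <- make_separable_set(40)
  labels <- rep(c("tailed_comet", "head_only"), each = 20)
  flipped <- ifelse(labels == "tailed_comet", "head_only", "tailed_comet")
  t1 <- train_tree(df, labels)
  t2 <- train_tree(df, flipped)
  expect_equal(t2$root$feature, t1$root$feature)
  expect_equal(t2$root$threshold, t1$root$threshold)
  expect_equal(t2$root$left$class,
               setdiff(c("head_only", "tailed_comet"), t1$root$left$class))
})

test_that("training is deterministic and rejects degenerate inputs", {
  df <- make_separable_set(40)
  labels <- rep(c("tailed_comet", "head_only"), each = 20)
  j1 <- jsonlite::toJSON(unclass(train_tree(df, labels)), auto_unbox = TRUE, digits = NA)
  j2 <- jsonlite::toJSON(unclass(train_tree(df, labels)), auto_unbox = TRUE, digits = NA)
  expect_identical(j1, j2)
  expect_error(train_tree(df, rep("head_only", 40)),
               class = "cometseg_singleclass_error")
  expect_error(train_tree(df[1:4, ], labels[1:4]), "at least 10")
})

test_that("every split reduces weighted Gini impurity", {
  set <- generate_labeled_feature_set(120, synth_config(seed = 7))
  tree <- train_tree(set$features, set$labels, depth_limit = 3)
  gini_of <- function(lab) { p <- table(lab) / length(lab); 1 - sum(p^2) }
  check <- function(node, X, lab) {
    if (node$leaf) return(invisible(NULL))
    left <- X[, node$feature] <= node$threshold
    parent <- gini_of(lab)
    child <- (sum(left) * gini_of(lab[left]) +
                sum(!left) * gini_of(lab[!left])) / length(lab)
    expect_lte(child, parent + 1e-12)
    check(node$left, X[left, , drop = FALSE], lab[left])
    check(node$right, X[!left, , drop = FALSE], lab[!left])
  }
  check(tree$root, as.matrix(set$features), set$labels)
})

test_that("synthetic-data classifier generalizes to held-out examples", {
  train_set <- generate_labeled_feature_set(500, synth_config(seed = 7))
  tree <- train_tree(train_set$features, train_set$labels, depth_limit = 3, seed = 7)
  test_set <- generate_labeled_feature_set(200, synth_config(seed = 8))
  acc <- mean(predict(tree, test_set$features) == test_set$labels)
  expect_gte(acc, 0.95)

  # independent CART implementation reaches the same accuracy regime and
  # agrees with ours on held-out cases
  skip_if_not_installed("rpart")
  rp <- rpart::rpart(label ~ ., method = "class",
                     data = cbind(train_set$features, label = factor(train_set$labels)),
                     control = rpart::rpart.control(maxdepth = 3, cp = 0.001, minsplit = 2))
  rp_pred <- as.character(predict(rp, test_set$features, type = "class"))
  expect_gte(mean(rp_pred == test_set$labels), 0.95)
  expect_gte(mean(rp_pred == predict(tree, test_set$features)), 0.95)
})

test_that("prediction is constant over each leaf's decision region", {
  set <- generate_labeled_feature_set(120, synth_config(seed = 14))
  tree <- train_tree(set$features, set$labels)
  # independent traversal used as the region-membership oracle
  oracle <- function(node, x) {
    while (!node$leaf) node <- if (x[node$feature] <= node$threshold) node$left else node$right
    node$class
  }
  set.seed(200)
  probes <- data.frame(head_tail_area_ratio = runif(150, 0, 120),
                       head_relative_position = runif(150, -1, 1),
                       mean_head_intensity = runif(150, 0, 255),
                       mean_tail_intensity = runif(150, 0, 255))
  got <- predict(tree, probes)
  want <- apply(as.matrix(probes), 1, function(x) oracle(tree$root, x))
  expect_equal(unname(got), unname(want))
})

test_that("model JSON round-trip preserves all predictions", {
  set <- generate_labeled_feature_set(120, synth_config(seed = 14))
  tree <- train_tree(set$features, set$labels)
  path <- withr::local_tempfile(fileext = ".json")
  save_tree_model(tree, path)
  back <- load_tree_model(path)
  set.seed(300)
  probes <- data.frame(head_tail_area_ratio = runif(100, 0, 120),
                       head_relative_position = runif(100, -1, 1),
                       mean_head_intensity = runif(100, 0, 255),
                       mean_tail_intensity = runif(100, 0, 255))
  expect_identical(predict(back, probes), predict(tree, probes))
})

test_that("a tail-less feature vector is classified head_only by the default model", {
  f <- list(head_tail_area_ratio = 100, head_relative_position = 0,
            mean_head_intensity = 200, mean_tail_intensity = 0)
  expect_equal(predict(default_tree_model(), f), "head_only")
})
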