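test_that("background estimation is the masked-out median", {
  px <- matrix(10L, 60, 60)
  disc <- make_disc(60, 60, 30, 30, 8)
  px[disc] <- 200L
  img <- intensity_image(px)
  expect_equal(estimate_background(img, list(disc)), 10)
  expect_equal(estimate_background(img, list()), 10)  # comets barely move the median

  set.seed(77)
  noisy <- intensity_image(pmax(matrix(round(rnorm(3600, 10, 2)), 60, 60), 0L))
  expect_gte(estimate_background(noisy, list(disc)), 9)
  expect_lte(estimate_background(noisy, list(disc)), 11)

  big <- matrix(TRUE, 60, 60)
  expect_error(estimate_background(img, list(big)),
               class = "cometseg_background_error")
})

test_that("comet measurement follows the printed tail-moment definition", {
  px <- matrix(0L, 50, 120)
  head <- make_rect(50, 120, 20, 26, 10, 19)   # 70 px
  tail <- make_rect(50, 120, 21, 25, 20, 59)   # 200 px, rightmost col 59
  px[head] <- 10L   # head DNA 700
  px[tail] <- 1L    # tail DNA wrong on purpose; fix a few pixels below
  px[21, 20:29] <- 11L  # +100 over the 1s -> tail DNA 190 + 110 = 300
  img <- intensity_image(px)
  seg <- cometseg:::new_comet_segmentation(1, head, tail, TRUE)
  m <- measure_comet(img, seg, background = 0)
  expect_equal(m$head_dna, 700)
  expect_equal(m$tail_dna, 300)
  expect_equal(m$tail_dna_fraction, 0.3)
  expect_equal(m$tail_length, 40)      # rightmost tail col 59 - head col 19
  expect_equal(m$tail_moment, 12)

  headonly <- cometseg:::new_comet_segmentation(1, head, head & !head, FALSE)
  m0 <- measure_comet(img, headonly, background = 0)
  expect_equal(m0$tail_dna_fraction, 0)
  expect_equal(m0$tail_moment, 0)

  dark <- intensity_image(matrix(5L, 50, 120))
  expect_error(measure_comet(dark, seg, background = 5),
               class = "cometseg_measurement_error")
})

test_that("tail moment grows strictly with the tail DNA fraction at fixed geometry", {
  head <- make_rect(40, 120, 15, 25, 10, 20)
  tail <- make_rect(40, 120, 15, 25, 21, 80)
  moments <- vapply(c(100L, 200L, 300L), function(v) {
    px <- matrix(0L, 40, 120)
    px[head] <- 50L
    px[tail] <- v %/% 100L
    img <- intensity_image(px)
    seg <- cometseg:::new_comet_segmentation(1, head, tail, TRUE)
    measure_comet(img, seg, 0)$tail_moment
  }, 0)
  expect_true(all(diff(moments) > 0))
})

test_that("a measured synthetic comet reproduces its drawn tail moment", {
  # drawn fraction 0.68 over a 100 px tail: moment near 68
  cfg <- synth_config(seed = 3, n_comets = 1, tail_prob = 1,
                      tail_fraction_range = c(0.68, 0.68),
                      tail_length_range = c(100, 100),
                      head_radius_range = c(10, 10),
                      width = 280L, height = 160L)
  sc <- generate_assay_image(cfg)
  segs <- segment_image(sc$image, seg_config(), default_tree_model())
  acc <- Filter(function(s) s$accepted && s$has_tail, segs)
  expect_length(acc, 1L)
  bg <- estimate_background(sc$image, lapply(segs, function(s) s$head | s$tail))
  m <- measure_comet(sc$image, acc[[1]], bg)
  expect_equal(m$tail_moment, 68, tolerance = 0.1)
})

test_that("IoU identities, symmetry and monotone shrinkage", {
  a <- make_disc(40, 40, 20, 20, 8)
  b <- make_rect(40, 40, 10, 30, 10, 30)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, !a & FALSE), 0)
  expect_equal(iou(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), 1)
  expect_equal(iou(a, b), iou(b, a))
  # two 10x10 squares overlapping in a 5x10 strip: 50 / 150
  s1 <- make_rect(30, 30, 1, 10, 1, 10)
  s2 <- make_rect(30, 30, 6, 15, 1, 10)
  expect_equal(iou(s1, s2), 1 / 3)
  # removing pixels of b outside a never decreases the IoU
  b2 <- b & (a | make_rect(40, 40, 10, 20, 10, 30))
  expect_gte(iou(a, b2), iou(a, b))
  expect_error(iou(a, matrix(FALSE, 10, 10)), class = "cometseg_dim_error")
})

test_that("matching truth against itself is perfect, empty predictions score zero", {
  sc <- generate_assay_image(synth_config(seed = 19, n_comets = 5))
  preds <- truth_as_predictions(sc$truth)
  res <- match_and_evaluate(preds, sc$truth)
  expect_equal(res$detection_rate, 100)
  expect_equal(res$mean_iou_head, 1)
  expect_equal(res$mean_iou_tail, 1)
  empty <- match_and_evaluate(list(), sc$truth)
  expect_equal(empty$detection_rate, 0)
})

test_that("greedy matching equals brute-force optimal assignment on full scenes", {
  model <- default_tree_model()
  for (seed in c(42, 43)) {
    sc <- generate_assay_image(synth_config(seed = seed))
    segs <- segment_image(sc$image, seg_config(), model)
    res <- match_and_evaluate(segs, sc$truth, min_overlap = 0.2)
    M <- matrix(0, length(sc$truth), length(segs))
    for (i in seq_along(sc$truth)) {
      tw <- sc$truth[[i]]$head | sc$truth[[i]]$tail
      for (j in seq_along(segs)) M[i, j] <- iou(tw, segs[[j]]$head | segs[[j]]$tail)
    }
    oracle <- brute_force_match(M, 0.2)
    expect_equal(nrow(res$matches), oracle$count)
    expect_equal(sum(res$matches$iou_whole), oracle$total, tolerance = 1e-9)
  }
})

test_that("measured tail moments regress on truth with slope near one", {
  model <- default_tree_model()
  true_m <- c(); meas_m <- c()
  for (seed in 101:105) {
    sc <- generate_assay_image(synth_config(seed = seed))
    segs <- segment_image(sc$image, seg_config(), model)
    res <- match_and_evaluate(segs, sc$truth)
    bg <- estimate_background(sc$image, lapply(segs, function(s) s$head | s$tail))
    for (k in seq_len(nrow(res$matches))) {
      j <- res$matches$predicted[k]
      if (!segs[[j]]$accepted) next
      true_m <- c(true_m, sc$truth[[res$matches$truth[k]]]$tail_moment)
      meas_m <- c(meas_m, measure_comet(sc$image, segs[[j]], bg)$tail_moment)
    }
  }
  expect_gte(length(true_m), 50L)
  slope <- unname(coef(lm(meas_m ~ true_m))[2])
  expect_gte(slope, 0.9)
  expect_lte(slope, 1.1)
})
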