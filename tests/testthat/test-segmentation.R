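test_that("preprocessing leaves a constant image unchanged", {
  img <- intensity_image(matrix(37L, 40, 40))
  out <- preprocess(img, seg_config())
  expect_identical(out$pixels, img$pixels)
  expect_error(preprocess(intensity_image(matrix(1L, 2, 2)),
                          seg_config(noise_element_size = 9L)),
               class = "cometseg_config_error")
})

test_that("preprocessing removes isolated bright pixels and caps the maximum", {
  sc <- generate_assay_image(synth_config(seed = 6, n_comets = 2))
  px <- sc$image$pixels
  # sprinkle 50 isolated single-pixel spikes on a fixed grid away from comets
  spots <- expand.grid(y = seq(10, 470, by = 95), x = seq(10, 630, by = 63))[1:50, ]
  covered <- Reduce(`|`, lapply(sc$truth, function(g) g$head | g$tail))
  for (k in seq_len(nrow(spots))) {
    y <- spots$y[k]; x <- spots$x[k]
    if (!any(covered[(y - 1):(y + 1), (x - 1):(x + 1)])) px[y, x] <- 250L
  }
  img <- intensity_image(px)
  out <- preprocess(img, seg_config())
  # an isolated maximum is a pixel strictly brighter than all 8 neighbours by a margin
  count_spikes <- function(p) {
    n <- 0L
    for (k in seq_len(nrow(spots))) {
      y <- spots$y[k]; x <- spots$x[k]
      nb <- p[(y - 1):(y + 1), (x - 1):(x + 1)]
      if (p[y, x] >= 200 && sum(nb >= 200) == 1L) n <- n + 1L
    }
    n
  }
  expect_gt(count_spikes(img$pixels), 40L)
  expect_equal(count_spikes(out$pixels), 0L)
  expect_lte(max(out$pixels), max(img$pixels))
})

test_that("preprocessing is nearly idempotent", {
  sc <- generate_assay_image(synth_config(seed = 13))
  once <- preprocess(sc$image, seg_config())
  twice <- preprocess(once, seg_config())
  expect_lt(mean(twice$pixels != once$pixels), 0.01)
})

test_that("candidate location finds each well-separated comet and nothing in blank scenes", {
  blank <- generate_assay_image(synth_config(seed = 2, n_comets = 0))
  expect_length(locate_candidates(preprocess(blank$image), seg_config()), 0)

  sc <- generate_assay_image(synth_config(seed = 17, n_comets = 8))
  regions <- locate_candidates(preprocess(sc$image), seg_config())
  expect_length(regions, 8L)
  # regions come back sorted by centroid, row-major
  ys <- vapply(regions, function(r) r$centroid[["y"]], 0)
  expect_true(all(diff(ys) >= 0 |
                    vapply(seq_len(length(regions) - 1), function(i) {
                      regions[[i + 1]]$centroid[["x"]] >= regions[[i]]$centroid[["x"]]
                    }, TRUE)))
})

test_that("sub-minimum specks are dropped from the candidate list", {
  sc <- generate_assay_image(synth_config(seed = 23, n_comets = 3))
  px <- sc$image$pixels
  px[100:101, 300] <- 230L   # 2-3 px speck, below min_candidate_area
  regions <- locate_candidates(preprocess(intensity_image(px)), seg_config())
  expect_length(regions, 3L)
  for (r in regions) {
    expect_gte(r$area, seg_config()$min_candidate_area)
  }
})

test_that("head segmentation recovers the true head of a synthetic comet", {
  sc <- single_comet_scene(seed = 31, damaged = TRUE)
  pp <- preprocess(sc$image)
  regions <- locate_candidates(pp, seg_config())
  expect_length(regions, 1L)
  head <- segment_head(pp, regions[[1]], seg_config())
  expect_false(is.null(head))
  expect_gte(iou(head, sc$truth[[1]]$head), 0.9)
})

test_that("a filled disc passes the shape constraints, a thin bar fails them", {
  px <- matrix(10L, 80, 80)
  px[make_disc(80, 80, 40, 40, 12)] <- 200L
  img <- intensity_image(px)
  regions <- locate_candidates(img, seg_config())
  stats <- cometseg:::shape_stats(make_disc(80, 80, 40, 40, 12))
  expect_gte(stats$circularity, 0.85)
  expect_gte(stats$convexity, 0.95)
  head <- segment_head(img, regions[[1]], seg_config())
  expect_false(is.null(head))

  bar <- matrix(10L, 60, 80)
  bar[30:31, 10:69] <- 200L
  bimg <- intensity_image(bar)
  bregions <- locate_candidates(bimg, seg_config())
  expect_length(bregions, 1L)
  expect_null(segment_head(bimg, bregions[[1]], seg_config()))
  # a 3-px-wide bar survives the morphological opening but still has no
  # acceptably circular head, so the pipeline discards its region
  bar3 <- matrix(10L, 60, 80)
  bar3[29:31, 10:69] <- 200L
  segs <- segment_image(intensity_image(bar3), seg_config(), default_tree_model())
  expect_length(segs, 1L)
  expect_equal(segs[[1]]$discard_reason, "no_head")
  expect_false(segs[[1]]$accepted)
})

test_that("tail segmentation is tight for undamaged cells and accurate for tails", {
  und <- single_comet_scene(seed = 37, damaged = FALSE)
  pp <- preprocess(und$image)
  regions <- locate_candidates(pp, seg_config())
  head <- segment_head(pp, regions[[1]], seg_config())
  tail <- segment_tail(pp, regions[[1]], head, seg_config())
  expect_lte(sum(tail), 0.05 * sum(head))  # hull slack only
  expect_false(any(head & tail))

  dmg <- single_comet_scene(seed = 41, damaged = TRUE)
  pp2 <- preprocess(dmg$image)
  regions2 <- locate_candidates(pp2, seg_config())
  head2 <- segment_head(pp2, regions2[[1]], seg_config())
  tail2 <- segment_tail(pp2, regions2[[1]], head2, seg_config())
  expect_gte(iou(tail2, dmg$truth[[1]]$tail), 0.7)
  expect_false(any(head2 & tail2))
})

test_that("geometric filters discard rotated and imbalanced comets but spare head-only cells", {
  head <- make_disc(200, 200, 100, 60, 10)
  # tail rotated ~40 degrees above the axis
  rot <- matrix(FALSE, 200, 200)
  for (t in 0:80) {
    y <- round(100 - t * sin(40 * pi / 180)); x <- round(60 + t * cos(40 * pi / 180))
    rot[(y - 5):(y + 5), x] <- TRUE
  }
  rot <- rot & !head
  seg <- cometseg:::new_comet_segmentation(1, head, rot, TRUE)
  out <- apply_geometric_filters(seg, seg_config(parallel_tol_deg = 15))
  expect_false(out$accepted)
  expect_equal(out$discard_reason, "orientation")

  straight <- make_rect(200, 200, 90, 110, 60, 140) & !head
  seg2 <- cometseg:::new_comet_segmentation(1, head, straight, TRUE)
  out2 <- apply_geometric_filters(seg2, seg_config())
  expect_true(out2$accepted)

  tiny_tail <- make_rect(200, 200, 99, 101, 71, 73) & !head
  seg3 <- cometseg:::new_comet_segmentation(1, head, tiny_tail, TRUE)
  out3 <- apply_geometric_filters(seg3, seg_config())
  expect_equal(out3$discard_reason, "ratio")   # head/tail area ratio too high

  headonly <- cometseg:::new_comet_segmentation(1, head,
                                                matrix(FALSE, 200, 200), FALSE)
  expect_true(apply_geometric_filters(headonly, seg_config())$accepted)
})

test_that("full pipeline is deterministic and recovers a 10-comet scene", {
  sc <- generate_assay_image(synth_config(seed = 42))
  model <- default_tree_model()
  segs <- segment_image(sc$image, seg_config(), model)
  res <- match_and_evaluate(segs, sc$truth)
  expect_gte(res$detection_rate, 90)
  again <- segment_image(sc$image, seg_config(), model)
  expect_identical(lapply(segs, `[[`, "head"), lapply(again, `[[`, "head"))
  expect_identical(lapply(segs, `[[`, "tail"), lapply(again, `[[`, "tail"))
  # blank image -> empty result
  blank <- generate_assay_image(synth_config(seed = 3, n_comets = 0))
  expect_length(segment_image(blank$image, seg_config(), model), 0)
  # head and tail are disjoint and confined near their candidate region
  for (s in segs) {
    expect_false(any(s$head & s$tail))
  }
})

test_that("segmentation of a noiseless render matches the noisy-limit segmentation", {
  cfg <- synth_config(seed = 51, n_comets = 4)
  sc <- generate_assay_image(cfg)
  cfg0 <- cfg; cfg0$noise_sd <- 0
  sc0 <- generate_assay_image(cfg0)
  model <- default_tree_model()
  segs0 <- segment_image(sc0$image, seg_config(), model)
  segs_direct <- segment_image(sc0$noiseless, seg_config(), model)
  expect_identical(lapply(segs0, `[[`, "head"), lapply(segs_direct, `[[`, "head"))
  expect_identical(lapply(segs0, `[[`, "tail"), lapply(segs_direct, `[[`, "tail"))
})
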