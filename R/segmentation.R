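# The four-stage comet segmenter: morphological preprocessing, global
# threshold candidate location, per-region head segmentation under shape
# constraints, and convex-hull tail delimitation, followed by the
# geometric discard rules (head/tail area ratio, parallelism to the
# electrophoresis axis). Everything is deterministic.

#' Segmentation configuration
#'
#' @param noise_element_size side of the square structuring element used by
#'   the grayscale opening/closing in [preprocess()] (odd, px).
#' @param threshold_scale histogram scale for the global Otsu threshold;
#'   `"log"` (default) suits background-dominated fluorescence scenes.
#' @param threshold_offset additive offset applied to the automatic global
#'   threshold (intensity counts; negative rescues dim images).
#' @param min_candidate_area,max_candidate_area candidate region area
#'   bounds (px).
#' @param head_min_area,head_max_area accepted head area bounds (px).
#' @param head_min_circularity minimum circularity 4*pi*A/P^2 of the head.
#' @param head_min_convexity minimum convexity A / convex-hull-area.
#' @param head_separability_min Otsu separability (eta) below which the
#'   within-region histogram is treated as unimodal and the whole region
#'   becomes the head (undamaged cells: nothing to split).
#' @param ratio_interval accepted head/tail area ratio interval.
#' @param parallel_tol_deg maximum |angle| between the head-centroid to
#'   farthest-tail-pixel vector and the +x axis (degrees).
#' @param tail_smooth_size diameter of the disc element closing the region
#'   before the convex hull (px).
#' @return list of class `seg_config`.
#' @export
seg_config <- function(noise_element_size = 3L,
                       threshold_scale = "log",
                       threshold_offset = 0,
                       min_candidate_area = 30L,
                       max_candidate_area = 20000L,
                       head_min_area = 30L,
                       head_max_area = 5000L,
                       head_min_circularity = 0.7,
                       head_min_convexity = 0.9,
                       head_separability_min = 0.85,
                       ratio_interval = c(0.05, 20),
                       parallel_tol_deg = 15,
                       tail_smooth_size = 5L) {
  stopifnot(noise_element_size >= 1, min_candidate_area > 0,
            max_candidate_area >= min_candidate_area,
            head_min_area > 0, head_max_area >= head_min_area,
            head_min_circularity > 0, head_min_circularity <= 1,
            head_min_convexity > 0, head_min_convexity <= 1,
            length(ratio_interval) == 2, ratio_interval[1] < ratio_interval[2])
  structure(as.list(environment()), class = "seg_config")
}

#' Morphological noise reduction
#'
#' Grayscale opening followed by closing with a square element. Dimensions
#' and bit depth are unchanged; the opening guarantees the output maximum
#' never exceeds the input maximum.
#'
#' @param image an [intensity_image].
#' @param config a [seg_config()].
#' @return The filtered [intensity_image].
#' @export
preprocess <- function(image, config = seg_config()) {
  stopifnot(inherits(image, "intensity_image"))
  k <- config$noise_element_size
  if (k > min(image$height, image$width)) {
    stop(errorCondition("structuring element larger than the image",
                        class = c("cometseg_config_error", "cometseg_error")))
  }
  if (k <= 1) return(image)
  kern <- EBImage::makeBrush(odd_size(k), "box")
  mx <- max_intensity(image)
  # EBImage grayscale morphology operates on [0, 1]
  sc <- image$pixels / mx
  out <- EBImage::closing(EBImage::opening(sc, kern), kern) * mx
  intensity_image(pmin(pmax(round(out), 0), mx), image$bit_depth)
}

odd_size <- function(k) if (k %% 2 == 0) k + 1L else as.integer(k)

#' Locate candidate comet regions
#'
#' Global automatic threshold (Otsu between-class-variance criterion on the
#' configured histogram scale, plus the configured offset), binarization,
#' 8-connected component labelling, and an area filter. Regions are
#' returned sorted by centroid in row-major order (top to bottom, then
#' left to right).
#'
#' @param image a preprocessed [intensity_image].
#' @param config a [seg_config()].
#' @return list of regions; each has `pixels` (linear indices into the
#'   image matrix), `area`, `bbox` (`c(x0, y0, x1, y1)`, 0-based,
#'   inclusive), and `centroid` (`c(x, y)`, 0-based).
#' @export
locate_candidates <- function(image, config = seg_config()) {
  stopifnot(inherits(image, "intensity_image"))
  auto <- otsu_threshold(image$pixels, max_intensity(image),
                         scale = config$threshold_scale)$threshold
  # no-signal guard: on background-only scenes the automatic split lands
  # inside the noise, at or below the global median; nothing to segment
  if (auto <= stats::median(image$pixels)) return(list())
  thr <- auto + config$threshold_offset
  bw <- image$pixels > thr
  lab <- label_components(bw)
  n <- max(lab)
  regions <- list()
  for (i in seq_len(n)) {
    idx <- which(lab == i)
    a <- length(idx)
    if (a < config$min_candidate_area || a > config$max_candidate_area) next
    rr <- ((idx - 1L) %% image$height) + 1L
    cc <- ((idx - 1L) %/% image$height) + 1L
    regions[[length(regions) + 1L]] <-
      list(pixels = idx, area = a,
           bbox = c(x0 = min(cc) - 1L, y0 = min(rr) - 1L,
                    x1 = max(cc) - 1L, y1 = max(rr) - 1L),
           centroid = c(x = mean(cc) - 1, y = mean(rr) - 1))
  }
  if (length(regions) > 1L) {
    ord <- order(vapply(regions, function(r) r$centroid["y"], 0),
                 vapply(regions, function(r) r$centroid["x"], 0))
    regions <- regions[ord]
  }
  regions
}

region_mask <- function(region, image) {
  m <- matrix(FALSE, image$height, image$width)
  m[region$pixels] <- TRUE
  m
}

#' Segment the head of a candidate region
#'
#' The head is the brightest spot of the region: the within-region
#' histogram is thresholded automatically (same Otsu criterion, restricted
#' to region pixels) and the connected blob with the highest mean intensity
#' is kept, subject to shape constraints: area within
#' `[head_min_area, head_max_area]`, circularity `4*pi*A/P^2` (perimeter
#' from the boundary pixel chain) at least `head_min_circularity`, and
#' convexity `A / convex-hull-area` at least `head_min_convexity`.
#' If the within-region histogram is not separable (Otsu eta below
#' `head_separability_min`) the region is an undamaged head-only cell and
#' the entire region is taken as the head.
#'
#' @param image preprocessed [intensity_image].
#' @param region one region from [locate_candidates()].
#' @param config a [seg_config()].
#' @return A logical head mask, or `NULL` if no blob satisfies the
#'   constraints (a no-head outcome: the region will be discarded).
#' @export
segment_head <- function(image, region, config = seg_config()) {
  rmask <- region_mask(region, image)
  ot <- otsu_threshold(image$pixels[region$pixels], max_intensity(image),
                       scale = config$threshold_scale)
  if (ot$eta < config$head_separability_min) {
    cand <- rmask
  } else {
    bw <- rmask & image$pixels > ot$threshold
    lab <- label_components(bw)
    if (max(lab) == 0L) return(NULL)
    means <- vapply(seq_len(max(lab)), function(k) mean(image$pixels[lab == k]), 0)
    areas <- vapply(seq_len(max(lab)), function(k) sum(lab == k), 0L)
    means[areas < 5L] <- -Inf          # ignore speck blobs
    if (all(!is.finite(means))) return(NULL)
    cand <- lab == which.max(means)
  }
  a <- sum(cand)
  if (a < config$head_min_area || a > config$head_max_area) return(NULL)
  sh <- shape_stats(cand)
  if (sh$circularity < config$head_min_circularity) return(NULL)
  if (sh$convexity < config$head_min_convexity) return(NULL)
  cand
}

# circularity 4*pi*A/P^2 with the perimeter from EBImage's boundary pixel
# chain; convexity A over filled-convex-hull area
shape_stats <- function(mask) {
  a <- sum(mask)
  per <- EBImage::computeFeatures.shape(t(mask) * 1L)[1, "s.perimeter"]
  hull_area <- sum(fill_convex_hull(mask))
  list(area = a,
       circularity = if (per > 0) min(4 * pi * a / per^2, 1) else 1,
       convexity = a / hull_area)
}

#' Segment the tail of a candidate region
#'
#' Smooths the region by a binary closing, takes the filled convex hull of
#' the smoothed region (how the tail is delimited), and removes the head.
#'
#' @param image preprocessed [intensity_image] (dimensions only).
#' @param region candidate region.
#' @param head logical head mask from [segment_head()].
#' @param config a [seg_config()].
#' @return Logical tail mask (possibly empty), disjoint from the head.
#' @export
segment_tail <- function(image, region, head, config = seg_config()) {
  rmask <- region_mask(region, image)
  k <- odd_size(config$tail_smooth_size)
  sm <- EBImage::closing(rmask, EBImage::makeBrush(k, "disc")) > 0
  fill_convex_hull(sm) & !head
}

#' Apply the geometric discard rules
#'
#' Comets with an inappropriate head-to-tail area ratio, or whose
#' head-centroid to farthest-tail-pixel direction deviates from the +x
#' electrophoresis axis by more than the tolerance, are discarded.
#' Head-only cells are exempt from both tests.
#'
#' @param seg a `comet_segmentation` (see [segment_image()]).
#' @param config a [seg_config()].
#' @return The segmentation with `accepted` / `discard_reason` updated.
#' @export
apply_geometric_filters <- function(seg, config = seg_config()) {
  if (!isTRUE(seg$has_tail) || !any(seg$tail)) return(seg)
  ratio <- sum(seg$head) / sum(seg$tail)
  if (ratio < config$ratio_interval[1] || ratio > config$ratio_interval[2]) {
    seg$accepted <- FALSE
    seg$discard_reason <- "ratio"
    return(seg)
  }
  hp <- which(seg$head, arr.ind = TRUE)
  centroid <- colMeans(hp)                      # (row, col)
  tp <- which(seg$tail, arr.ind = TRUE)
  d2 <- (tp[, 1] - centroid[1])^2 + (tp[, 2] - centroid[2])^2
  far <- tp[which.max(d2), ]
  ang <- atan2(far[1] - centroid[1], far[2] - centroid[2]) * 180 / pi
  if (abs(ang) > config$parallel_tol_deg) {
    seg$accepted <- FALSE
    seg$discard_reason <- "orientation"
  }
  seg
}

new_comet_segmentation <- function(region_id, head, tail, has_tail,
                                   accepted = TRUE, discard_reason = "none") {
  structure(list(region_id = region_id, head = head, tail = tail,
                 has_tail = has_tail, accepted = accepted,
                 discard_reason = discard_reason),
            class = "comet_segmentation")
}

#' Segment every comet in an image
#'
#' Runs the full pipeline: [preprocess()], [locate_candidates()],
#' [segment_head()], [segment_tail()], the decision-tree comet/no-tail
#' classification (a predicted head-only cell has its tail mask emptied),
#' and [apply_geometric_filters()]. A per-region failure discards that
#' region without aborting the others.
#'
#' @param image an [intensity_image] (raw; preprocessing is applied here).
#' @param config a [seg_config()].
#' @param model a trained [train_tree()] model; `default_tree_model()` when
#'   omitted.
#' @return list of `comet_segmentation` objects, each with logical masks
#'   `head` and `tail`, `has_tail`, `accepted`, and `discard_reason`
#'   (`"none"`, `"ratio"`, `"orientation"` or `"no_head"`).
#' @export
segment_image <- function(image, config = seg_config(),
                          model = default_tree_model()) {
  pp <- preprocess(image, config)
  regions <- locate_candidates(pp, config)
  out <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    region <- regions[[i]]
    head <- segment_head(pp, region, config)
    if (is.null(head)) {
      empty <- matrix(FALSE, image$height, image$width)
      out[[i]] <- new_comet_segmentation(i, empty, empty, FALSE,
                                         accepted = FALSE,
                                         discard_reason = "no_head")
      next
    }
    tail <- segment_tail(pp, region, head, config)
    feats <- extract_features(pp, head, tail)
    cls <- predict(model, feats)
    if (identical(cls, "head_only")) {
      tail <- matrix(FALSE, image$height, image$width)
    }
    seg <- new_comet_segmentation(i, head, tail,
                                  has_tail = identical(cls, "tailed_comet") && any(tail))
    out[[i]] <- apply_geometric_filters(seg, config)
  }
  out
}
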