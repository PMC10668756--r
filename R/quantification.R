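# Per-comet DNA-damage metrics and the detection/IoU evaluation harness.
# The damage statistic is the tail moment: tail length times the fraction
# of total (background-subtracted) DNA found in the tail. Lengths are in
# pixels and fractions in [0, 1], so typical damaged comets score tens of
# px-fraction units.

#' Estimate the background intensity level
#'
#' Median intensity of the pixels outside every comet mask.
#'
#' @param image an [intensity_image].
#' @param masks list of logical matrices (or a single matrix) covering the
#'   comets; may be empty.
#' @return Background level (numeric scalar).
#' @export
estimate_background <- function(image, masks = list()) {
  stopifnot(inherits(image, "intensity_image"))
  if (is.matrix(masks)) masks <- list(masks)
  covered <- matrix(FALSE, image$height, image$width)
  for (m in masks) covered <- covered | m
  if (mean(covered) >= 0.9) {
    stop(errorCondition("comet masks cover 90% or more of the image; background is not estimable",
                        class = c("cometseg_background_error", "cometseg_error")))
  }
  stats::median(image$pixels[!covered])
}

#' Measure a segmented comet
#'
#' DNA sums are clamped background-subtracted integrated intensities,
#' `sum(max(pixel - background, 0))`, over the head and tail masks. The
#' tail length is the horizontal distance in pixels between the rightmost
#' head column and the rightmost tail column (comets are near-parallel to
#' the x axis by construction; 0 without a tail). The tail moment is
#' `tail_length * tail_dna_fraction`.
#'
#' @param image the [intensity_image] the comet was segmented from.
#' @param seg an accepted `comet_segmentation`.
#' @param background background level from [estimate_background()].
#' @return list with `head_area`, `tail_area` (px), `head_dna`, `tail_dna`
#'   (background-subtracted counts), `tail_dna_fraction` in \[0, 1\],
#'   `tail_length` (px) and `tail_moment`.
#' @export
measure_comet <- function(image, seg, background) {
  px <- image$pixels
  head_dna <- sum(pmax(px[seg$head] - background, 0))
  tail_dna <- if (any(seg$tail)) sum(pmax(px[seg$tail] - background, 0)) else 0
  total <- head_dna + tail_dna
  if (total <= 0) {
    stop(errorCondition("comet has zero background-subtracted DNA",
                        class = c("cometseg_measurement_error", "cometseg_error")))
  }
  frac <- tail_dna / total
  tail_len <- 0
  if (any(seg$tail)) {
    head_right <- max(which(colSums(seg$head) > 0))
    tail_right <- max(which(colSums(seg$tail) > 0))
    tail_len <- max(tail_right - head_right, 0)
  } else {
    frac <- 0
  }
  list(head_area = sum(seg$head), tail_area = sum(seg$tail),
       head_dna = head_dna, tail_dna = tail_dna,
       tail_dna_fraction = frac, tail_length = tail_len,
       tail_moment = tail_len * frac)
}

#' Intersection over union of two masks
#'
#' `|a & b| / |a | b|`; defined as 1 when both masks are empty.
#'
#' @param a,b logical matrices of identical dimensions.
#' @return IoU in \[0, 1\].
#' @export
iou <- function(a, b) {
  if (!all(dim(a) == dim(b))) {
    stop(errorCondition("mask dimensions differ", class = c("cometseg_dim_error", "cometseg_error")))
  }
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Match predictions against ground truth and score them
#'
#' One-to-one greedy matching by descending whole-comet IoU (head and tail
#' united); pairs under `min_overlap` stay unmatched. Reports the
#' detection rate (percent of ground-truth comets matched) and the mean
#' head and tail IoU over matched pairs. Tail IoU averages over pairs
#' where either tail is non-empty, so undamaged cells do not dilute it.
#'
#' @param predicted list of `comet_segmentation` objects.
#' @param truth list of ground-truth comets (with `head` / `tail` masks),
#'   e.g. from [generate_assay_image()].
#' @param min_overlap minimum whole-comet IoU for a valid match.
#' @return list of class `match_result`: `detection_rate` (percent),
#'   `mean_iou_head`, `mean_iou_tail`, `n_truth`, `n_predicted`,
#'   `matches` (data.frame: truth index, prediction index, IoUs).
#' @export
match_and_evaluate <- function(predicted, truth, min_overlap = 0.2) {
  np <- length(predicted); nt <- length(truth)
  if (np && nt) {
    M <- matrix(0, nt, np)
    for (i in seq_len(nt)) {
      tw <- truth[[i]]$head | truth[[i]]$tail
      for (j in seq_len(np)) {
        M[i, j] <- iou(tw, predicted[[j]]$head | predicted[[j]]$tail)
      }
    }
  } else {
    M <- matrix(0, nt, np)
  }
  pairs <- greedy_match(M, min_overlap)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    ih <- iou(truth[[i]]$head, predicted[[j]]$head)
    either_tail <- any(truth[[i]]$tail) || any(predicted[[j]]$tail)
    it <- if (either_tail) iou(truth[[i]]$tail, predicted[[j]]$tail) else NA_real_
    data.frame(truth = i, predicted = j, iou_whole = M[i, j],
               iou_head = ih, iou_tail = it)
  })
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(truth = integer(0), predicted = integer(0),
               iou_whole = numeric(0), iou_head = numeric(0), iou_tail = numeric(0))
  tail_ious <- matches$iou_tail[!is.na(matches$iou_tail)]
  structure(list(
    detection_rate = if (nt) 100 * nrow(matches) / nt else NA_real_,
    mean_iou_head = if (nrow(matches)) mean(matches$iou_head) else NA_real_,
    mean_iou_tail = if (length(tail_ious)) mean(tail_ious) else NA_real_,
    n_truth = nt, n_predicted = np, matches = matches
  ), class = "match_result")
}

# repeatedly take the best remaining (truth, prediction) pair
greedy_match <- function(M, min_overlap) {
  pairs <- matrix(integer(0), 0, 2)
  if (!length(M)) return(pairs)
  M2 <- M
  repeat {
    best <- which.max(M2)
    if (!length(best) || M2[best] < min_overlap) break
    i <- ((best - 1L) %% nrow(M2)) + 1L
    j <- ((best - 1L) %/% nrow(M2)) + 1L
    pairs <- rbind(pairs, c(i, j))
    M2[i, ] <- -1; M2[, j] <- -1
  }
  pairs
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> detection %.1f%% (%d/%d truth, %d predicted)\n",
              x$detection_rate, nrow(x$matches), x$n_truth, x$n_predicted))
  cat(sprintf("  mean IoU head %.3f | tail %.3f\n",
              x$mean_iou_head, x$mean_iou_tail))
  invisible(x)
}
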