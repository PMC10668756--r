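# Synthetic comet-assay scenes with exact ground truth.
#
# A comet is rendered as a flat-topped Gaussian head disc (intensity
# sigma = 2 * radius, truncated at the radius, so the rim still carries
# ~88% of the peak) plus, when damaged, a horizontal band of exponentially
# decaying intensity starting inside the head boundary and extending
# tailward. The band half-width equals the head radius, so head + tail
# form the classic comet silhouette whose convex hull is tight. The tail
# amplitude is solved analytically so the integrated tail intensity is
# exactly the drawn DNA fraction of the comet total (up to integer
# quantization of the rendered pixels).

#' Synthetic scene configuration
#'
#' Defaults emulate 8-bit SYBR-stained comet micrographs with clearly
#' visible migration: dark noisy background, bright near-circular heads,
#' and tails whose surface brightness stays above the detection floor.
#' Ranges are sampled uniformly per comet.
#'
#' @param width,height scene size in pixels.
#' @param bit_depth 8 or 16.
#' @param background_level,noise_sd background intensity and additive
#'   Gaussian noise sigma, in intensity counts.
#' @param n_comets number of comets to place.
#' @param head_radius_range head radius bounds (px).
#' @param head_peak_range peak head intensity bounds (counts above background).
#' @param tail_prob probability that a comet is damaged (has a tail).
#' @param tail_length_range tail length bounds (px beyond the head boundary).
#' @param tail_fraction_range bounds for the fraction of total comet DNA in
#'   the tail, within \[0, 1\].
#' @param tail_decay_mult exponential decay length constant of the tail
#'   intensity profile, as a multiple of the tail length (4 = gentle fade;
#'   the tail tip retains exp(-1/4) ~ 78% of the root intensity).
#' @param orientation_jitter_deg maximum absolute tail angle about the +x
#'   (electrophoresis) direction, degrees.
#' @param min_spacing minimum gap between comet bounding boxes (px).
#' @param seed integer random seed (Mersenne-Twister, documented draw order).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(width = 640L, height = 480L, bit_depth = 8L,
                         background_level = 20, noise_sd = 3,
                         n_comets = 10L,
                         head_radius_range = c(8, 11),
                         head_peak_range = c(160, 230),
                         tail_prob = 0.5,
                         tail_length_range = c(55, 85),
                         tail_fraction_range = c(0.4, 0.6),
                         tail_decay_mult = 4,
                         orientation_jitter_deg = 6,
                         min_spacing = 4,
                         seed = 1L) {
  stopifnot(width >= 1, height >= 1, bit_depth %in% c(8L, 16L),
            n_comets >= 0, tail_prob >= 0, tail_prob <= 1,
            diff(head_radius_range) >= 0, diff(tail_length_range) >= 0,
            diff(tail_fraction_range) >= 0, tail_decay_mult > 0)
  if (tail_fraction_range[1] < 0 || tail_fraction_range[2] > 1) {
    stop("tail_fraction_range must lie within [0, 1]")
  }
  structure(as.list(environment()), class = "synth_config")
}

# All stochastic code in the package runs under an explicitly named RNG so
# fixtures reproduce across platforms; the caller's RNG state is restored.
with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Generate a synthetic comet-assay image with ground truth
#'
#' Deterministic for a given seed. Per-comet parameters are drawn in a
#' documented order: first the damaged/undamaged Bernoulli sequence for all
#' comets (`runif(n_comets) < tail_prob`), then per comet its radius, peak,
#' tail length, DNA fraction, orientation, and placement rejections.
#'
#' @param config a [synth_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{image}{noisy [intensity_image].}
#'     \item{noiseless}{noiseless [intensity_image] (background + comets).}
#'     \item{truth}{list of ground-truth comets, each with logical matrices
#'       `head` and `tail`, `has_tail`, `tail_length` (px),
#'       `tail_fraction`, `tail_moment` (= length x fraction), `centre`
#'       (0-based x, y) and `peak`.}
#'     \item{config}{the configuration, seed included.}
#'   }
#' @export
generate_assay_image <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_rng_seed(config$seed, generate_assay_image_impl(config))
}

generate_assay_image_impl <- function(config) {
  W <- config$width; H <- config$height
  n <- config$n_comets
  canvas <- matrix(0, H, W)
  truth <- vector("list", n)
  has_tail <- if (n > 0) stats::runif(n) < config$tail_prob else logical(0)
  boxes <- list()
  for (i in seq_len(n)) {
    r <- stats::runif(1, config$head_radius_range[1], config$head_radius_range[2])
    pk <- stats::runif(1, config$head_peak_range[1], config$head_peak_range[2])
    L <- if (has_tail[i]) stats::runif(1, config$tail_length_range[1], config$tail_length_range[2]) else 0
    f <- if (has_tail[i]) stats::runif(1, config$tail_fraction_range[1], config$tail_fraction_range[2]) else 0
    th <- if (has_tail[i]) stats::runif(1, -1, 1) * config$orientation_jitter_deg * pi / 180 else 0
    ext_x <- r + L * cos(abs(th)) + 2
    ext_y <- r + L * sin(abs(th)) + 2
    placedBox <- NULL
    for (attempt in seq_len(2000L)) {
      cx <- stats::runif(1, r + 3, W - ext_x - 1)
      cy <- stats::runif(1, ext_y + 1, H - ext_y - 1)
      box <- c(cx - r - 2, cx + ext_x, cy - ext_y, cy + ext_y) +
        c(-1, 1, -1, 1) * config$min_spacing / 2
      clash <- FALSE
      for (b in boxes) {
        if (!(box[2] < b[1] || b[2] < box[1] || box[4] < b[3] || b[4] < box[3])) {
          clash <- TRUE; break
        }
      }
      if (!clash) { placedBox <- box; break }
    }
    if (is.null(placedBox)) {
      stop(errorCondition(
        sprintf("could not place comet %d of %d under the minimum-spacing constraint (%g px) in a %d x %d scene",
                i, n, config$min_spacing, W, H),
        class = c("cometseg_placement_error", "cometseg_error")))
    }
    boxes[[length(boxes) + 1L]] <- placedBox
    cm <- render_comet(cx, cy, r, pk, L, f, th, H, W, config$tail_decay_mult)
    canvas <- canvas + cm$intensity
    truth[[i]] <- list(head = cm$head, tail = cm$tail, has_tail = has_tail[i],
                       tail_length = L, tail_fraction = f,
                       tail_moment = L * f,
                       centre = c(x = cx - 1, y = cy - 1), peak = pk)
  }
  maxv <- 2^config$bit_depth - 1
  noiseless <- pmin(round(canvas + config$background_level), maxv)
  noisy <- canvas + config$background_level +
    stats::rnorm(H * W, 0, config$noise_sd)
  noisy <- pmin(pmax(round(noisy), 0), maxv)
  list(image = intensity_image(noisy, config$bit_depth),
       noiseless = intensity_image(noiseless, config$bit_depth),
       truth = truth, config = config)
}

# Render one comet on the full canvas; cx, cy are 1-based pixel-centre
# coordinates. Returns the intensity layer and exact head/tail masks.
render_comet <- function(cx, cy, r, peak, L, f, theta, H, W, decay_mult) {
  pad <- 2
  x0 <- max(1L, floor(cx - r - pad)); x1 <- min(W, ceiling(cx + r + L + pad))
  y0 <- max(1L, floor(cy - r - L - pad)); y1 <- min(H, ceiling(cy + r + L + pad))
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE) - cx
  gy <- matrix(ys, length(ys), length(xs)) - cy
  rho2 <- gx^2 + gy^2
  headI <- exp(-rho2 / (2 * (2 * r)^2))
  headI[rho2 > r^2] <- 0
  hmask <- rho2 <= r^2
  tmask <- matrix(FALSE, length(ys), length(xs))
  tailI <- matrix(0, length(ys), length(xs))
  if (L > 0 && f > 0) {
    u <- gx * cos(theta) + gy * sin(theta)
    v <- -gx * sin(theta) + gy * cos(theta)
    band <- u > 0 & u <= r + L & abs(v) <= r
    tau <- decay_mult * L
    tdist <- pmax(u - r, 0)
    tailI[band] <- exp(-tdist[band] / tau)
    tailI[hmask] <- 0
    tmask <- band & !hmask
    SH <- sum(headI); ST <- sum(tailI)
    amp <- f * SH / ((1 - f) * ST)   # solves tail/(head+tail) = f
    tailI <- amp * tailI
  }
  layer <- peak * (headI + tailI)
  intensity <- matrix(0, H, W)
  intensity[ys, xs] <- layer
  head <- matrix(FALSE, H, W); head[ys, xs] <- hmask
  tail <- matrix(FALSE, H, W); tail[ys, xs] <- tmask
  list(intensity = intensity, head = head, tail = tail)
}

#' Generate a labelled feature set for classifier training
#'
#' Renders `n` single-comet patches under `config` and computes the four
#' classification features with [extract_features()] the same way the
#' pipeline builds them at prediction time: the patch is preprocessed and
#' thresholded, the candidate region containing the comet is smoothed and
#' hulled, and the tail candidate is that hull minus the head. The head
#' mask and the labels come from the ground truth, so the examples are
#' labelled exactly. If thresholding fails to produce a region (it should
#' not at the default signal-to-noise), the ground-truth hull is the
#' fallback candidate.
#'
#' @param n number of examples (>= 2).
#' @param config a [synth_config()]; its seed derives the per-patch seeds.
#' @param require_both_classes error (class
#'   `cometseg_singleclass_error`) if the draw contains one class only;
#'   off by default since extreme `tail_prob` legitimately yields
#'   single-class sets.
#' @return list with `features` (data.frame, one row per comet, columns in
#'   the canonical order) and `labels` (character, `"tailed_comet"` /
#'   `"head_only"`).
#' @export
generate_labeled_feature_set <- function(n, config = synth_config(),
                                         require_both_classes = FALSE) {
  stopifnot(n >= 2)
  patch_cfg <- config
  patch_cfg$width <- 220L; patch_cfg$height <- 100L
  patch_cfg$n_comets <- 1L
  seg_cfg <- seg_config()
  rows <- vector("list", n)
  labels <- character(n)
  for (i in seq_len(n)) {
    patch_cfg$seed <- (config$seed * 1000L + i) %% .Machine$integer.max
    sc <- generate_assay_image(patch_cfg)
    gt <- sc$truth[[1]]
    pp <- preprocess(sc$image, seg_cfg)
    regions <- locate_candidates(pp, seg_cfg)
    overlap <- vapply(regions, function(r) sum(gt$head[r$pixels]), 0L)
    if (length(regions) && max(overlap) > 0L) {
      cand <- segment_tail(pp, regions[[which.max(overlap)]], gt$head, seg_cfg)
    } else {
      cand <- fill_convex_hull(gt$head | gt$tail) & !gt$head
    }
    rows[[i]] <- extract_features(pp, gt$head, cand)
    labels[i] <- if (gt$has_tail) "tailed_comet" else "head_only"
  }
  feats <- do.call(rbind, lapply(rows, as.data.frame))
  if (require_both_classes && length(unique(labels)) < 2L) {
    stop(errorCondition(
      "drawn sample contains a single class; increase n or adjust tail_prob",
      class = c("cometseg_singleclass_error", "cometseg_error")))
  }
  list(features = feats, labels = labels)
}

#' Generate a noisy one-breakpoint piecewise-linear dataset
#'
#' `y = intercept + slope1 * x` up to the breakpoint, continuous there, and
#' with slope `slope2` beyond; additive Gaussian noise.
#'
#' @param intercept,slope1,slope2 line parameters.
#' @param breakpoint changepoint, strictly inside the range of `x`.
#' @param noise_sigma Gaussian noise standard deviation (0 for exact data).
#' @param x numeric design points.
#' @param seed integer seed.
#' @return list with numeric vectors `x` and `y`.
#' @export
generate_piecewise_dataset <- function(intercept, slope1, slope2, breakpoint,
                                       noise_sigma, x, seed = 1L) {
  if (breakpoint <= min(x) || breakpoint >= max(x)) {
    stop(errorCondition("breakpoint must lie strictly inside the range of x",
                        class = c("cometseg_parameter_error", "cometseg_error")))
  }
  y0 <- intercept + slope1 * pmin(x, breakpoint) +
    slope2 * pmax(x - breakpoint, 0)
  y <- with_rng_seed(seed, y0 + stats::rnorm(length(x), 0, noise_sigma))
  list(x = x, y = y)
}
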