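# Shared fixture builders. Everything is generated in code at test time.

# filled disc mask centred at (cy, cx), 1-based matrix coordinates
make_disc <- function(nrow, ncol, cy, cx, r) {
  gy <- matrix(seq_len(nrow), nrow, ncol)
  gx <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  (gy - cy)^2 + (gx - cx)^2 <= r^2
}

# rectangular mask by 1-based inclusive bounds
make_rect <- function(nrow, ncol, y0, y1, x0, x1) {
  m <- matrix(FALSE, nrow, ncol)
  m[y0:y1, x0:x1] <- TRUE
  m
}

# a small single-comet scene; damaged controls tail presence
single_comet_scene <- function(seed = 1, damaged = TRUE, ...) {
  generate_assay_image(synth_config(
    seed = seed, n_comets = 1, tail_prob = if (damaged) 1 else 0,
    width = 240L, height = 140L, ...))
}

# wrap ground-truth masks as prediction-like segmentation objects
truth_as_predictions <- function(truth) {
  lapply(seq_along(truth), function(i) {
    g <- truth[[i]]
    cometseg:::new_comet_segmentation(i, g$head, g$tail, g$has_tail)
  })
}

# brute-force 8-connected labelling by repeated pixel-pair union
brute_force_label <- function(mask) {
  idx <- which(mask)
  parent <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(mask)
  coords <- cbind(((idx - 1) %% nr) + 1, ((idx - 1) %/% nr) + 1)
  for (a in seq_along(idx)) {
    for (b in seq_len(a - 1L)) {
      if (max(abs(coords[a, ] - coords[b, ])) <= 1) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_along(idx), find, 0L)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[idx] <- match(roots, unique(roots))
  lab
}

# exhaustive best one-to-one matching oracle: maximize matched count, then
# total IoU, over all assignments with IoU >= min_overlap
brute_force_match <- function(M, min_overlap) {
  edges <- which(M >= min_overlap, arr.ind = TRUE)
  best <- list(count = 0L, total = 0)
  recurse <- function(k, used_t, used_p, count, total) {
    if (count + (nrow(edges) - k + 1L) < best$count) return()
    if (k > nrow(edges)) {
      if (count > best$count ||
          (count == best$count && total > best$total + 1e-12)) {
        best <<- list(count = count, total = total)
      }
      return()
    }
    i <- edges[k, 1]; j <- edges[k, 2]
    if (!(i %in% used_t) && !(j %in% used_p)) {
      recurse(k + 1L, c(used_t, i), c(used_p, j), count + 1L, total + M[i, j])
    }
    recurse(k + 1L, used_t, used_p, count, total)
  }
  recurse(1L, integer(0), integer(0), 0L, 0)
  best
}
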