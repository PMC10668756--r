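# Mask utilities shared by the project store, the segmenter and the
# evaluation harness. Masks are logical matrices in image layout
# (rows = y, columns = x).

# Run-length encode a logical matrix over its linear (column-major) indices.
mask_to_rle <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) {
    return(list(nrow = nrow(mask), ncol = ncol(mask),
                starts = integer(0), lengths = integer(0)))
  }
  brk <- c(TRUE, diff(idx) != 1L)
  start_pos <- which(brk)
  starts <- idx[start_pos]
  ends <- idx[c(start_pos[-1L] - 1L, length(idx))]
  list(nrow = nrow(mask), ncol = ncol(mask),
       starts = as.integer(starts), lengths = as.integer(ends - starts + 1L))
}

rle_to_mask <- function(rle) {
  m <- matrix(FALSE, rle$nrow, rle$ncol)
  if (length(rle$starts)) {
    idx <- unlist(mapply(function(s, l) s:(s + l - 1L), rle$starts, rle$lengths,
                         SIMPLIFY = FALSE), use.names = FALSE)
    m[idx] <- TRUE
  }
  m
}

# Oriented boundary contour of the largest object in a mask, as an n x 2
# matrix of 0-based (x, y) pixel coordinates. EBImage works in (x, y) layout,
# hence the transpose.
mask_to_contour <- function(mask) {
  if (!any(mask)) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  oc <- EBImage::ocontour(t(mask) * 1L)
  pts <- oc[[which.max(vapply(oc, nrow, 0L))]]
  colnames(pts) <- c("x", "y")
  pts
}

# Rasterize a simple closed polygon of 0-based (x, y) vertices onto an
# nrow x ncol grid: even-odd interior test on pixel centres, plus the
# boundary pixels themselves.
polygon_to_mask <- function(poly, nrow, ncol) {
  m <- matrix(FALSE, nrow, ncol)
  if (is.null(poly) || nrow(poly) == 0) return(m)
  px <- poly[, 1]; py <- poly[, 2]
  xs <- max(0, floor(min(px))):min(ncol - 1, ceiling(max(px)))
  ys <- max(0, floor(min(py))):min(nrow - 1, ceiling(max(py)))
  if (!length(xs) || !length(ys)) return(m)
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  n <- length(px)
  inside <- logical(length(gx))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > gy) != (py[j] > gy))
    if (any(crosses)) {
      xint <- (px[j] - px[i]) * (gy[crosses] - py[i]) / (py[j] - py[i]) + px[i]
      flip <- gx[crosses] < xint
      inside[crosses][flip] <- !inside[crosses][flip]
    }
    j <- i
  }
  m[cbind(gy + 1L, gx + 1L)[inside, , drop = FALSE]] <- TRUE
  # draw the boundary edges so thin or axis-aligned polygon borders close
  j <- n
  for (i in seq_len(n)) {
    steps <- max(abs(px[i] - px[j]), abs(py[i] - py[j]), 1) * 2
    t <- seq(0, 1, length.out = ceiling(steps) + 1)
    bx <- round(px[j] + t * (px[i] - px[j]))
    by <- round(py[j] + t * (py[i] - py[j]))
    ok <- bx >= 0 & bx < ncol & by >= 0 & by < nrow
    m[cbind(by + 1L, bx + 1L)[ok, , drop = FALSE]] <- TRUE
    j <- i
  }
  m
}

# Filled convex hull of the TRUE pixels of a mask (half-plane test on the
# hull polygon, so the fill is exact for the convex case).
fill_convex_hull <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)         # (row, col)
  if (nrow(pts) < 3) return(mask)
  h <- grDevices::chull(pts[, 2], pts[, 1])  # clockwise in (x, y)
  hp <- pts[h, , drop = FALSE]
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  ys <- min(pts[, 1]):max(pts[, 1])
  xs <- min(pts[, 2]):max(pts[, 2])
  gy <- matrix(ys, length(ys), length(xs))
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  inside <- matrix(TRUE, length(ys), length(xs))
  nh <- nrow(hp)
  for (k in seq_len(nh)) {
    p1 <- hp[k, ]
    p2 <- hp[if (k == nh) 1L else k + 1L, ]
    cr <- (p2[2] - p1[2]) * (gy - p1[1]) - (p2[1] - p1[1]) * (gx - p1[2])
    inside <- inside & (cr <= 1e-9)
  }
  out[cbind(as.vector(gy)[inside], as.vector(gx)[inside])] <- TRUE
  out
}

# 8-connected component labelling. Foreground pixels become graph vertices,
# edges join 8-neighbours, components come from igraph. Returns an integer
# matrix of labels (0 = background), numbered in first-pixel order.
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nr <- nrow(mask); nc <- ncol(mask)
  pos <- matrix(0L, nr, nc)
  pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + d[1L]; c2 <- cc + d[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    if (any(ok)) {
      edges <- c(edges, rbind(pos[idx[ok]], pos[cbind(r2[ok], c2[ok])]))
    }
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber so labels increase with the first linear index of each component
  first <- tapply(idx, memb, min)
  remap <- integer(length(first))
  remap[order(first)] <- seq_along(first)
  lab[idx] <- remap[memb]
  lab
}
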