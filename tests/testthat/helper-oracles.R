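# Brute-force oracles, independent of the package's implementation paths.

# 8-connected labeling by literal BFS flood fill
oracle_flood_fill <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!m[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
            m[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          queue[[length(queue) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# canonical renumbering so two labelings can be compared as partitions
canonical_labels <- function(lab) {
  idx <- which(lab > 0)
  first <- tapply(idx, lab[idx], min)
  ord <- rank(first)
  out <- lab
  out[idx] <- as.integer(ord[as.character(lab[idx])])
  out
}

# exhaustive-search Otsu on the package's 256-bin convention: for every
# candidate threshold, compute the two class means directly from the pixels
oracle_otsu_threshold <- function(x, max_intensity) {
  bins <- pmin(pmax(ceiling(x / max_intensity * 256), 1L), 256L)
  level <- (bins - 0.5) * max_intensity / 256
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 1:255) {
    g0 <- level[bins <= t]; g1 <- level[bins > t]
    if (length(g0) == 0 || length(g1) == 0) next
    v <- length(g0) * length(g1) * (mean(g0) - mean(g1))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t * max_intensity / 256
}

# per-pixel neighbour counting with the reduced-adjacency convention:
# a diagonal neighbour is not counted when one of the two shared orthogonal
# corner pixels is foreground
oracle_skeleton_degrees <- function(m, reduced = TRUE) {
  h <- nrow(m); w <- ncol(m)
  deg <- matrix(0L, h, w)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!m[i, j]) next
    d <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- i + dr; c2 <- j + dc
      if (r2 < 1 || r2 > h || c2 < 1 || c2 > w || !m[r2, c2]) next
      if (reduced && dr != 0 && dc != 0 && (m[r2, j] || m[i, c2])) next
      d <- d + 1L
    }
    deg[i, j] <- d
  }
  deg
}

# brute-force rasterization: stamp a disc of radius r on every centerline px
oracle_dilate_centerline <- function(px, r, h, w) {
  out <- matrix(FALSE, h, w)
  for (k in seq_len(nrow(px))) {
    for (dr in -r:r) for (dc in -r:r) {
      if (dr^2 + dc^2 > r^2) next
      r2 <- px[k, 1] + dr; c2 <- px[k, 2] + dc
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) out[r2, c2] <- TRUE
    }
  }
  out
}

# grayscale opening with a disc, literal min/max over in-bounds offsets
oracle_opening_disc <- function(x, r) {
  h <- nrow(x); w <- ncol(x)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= r^2, ]
  er <- matrix(0, h, w)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    r2 <- i + off$dr; c2 <- j + off$dc
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
    er[i, j] <- min(x[cbind(r2[ok], c2[ok])])
  }
  op <- matrix(0, h, w)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    r2 <- i + off$dr; c2 <- j + off$dc
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
    op[i, j] <- max(er[cbind(r2[ok], c2[ok])])
  }
  op
}

# exhaustive per-pixel sorted-neighbourhood median with reflected edges
oracle_median <- function(x, r) {
  h <- nrow(x); w <- ncol(x)
  ridx <- c(rev(seq_len(r)), seq_len(h), h - seq_len(r) + 1)
  cidx <- c(rev(seq_len(r)), seq_len(w), w - seq_len(r) + 1)
  pad <- x[ridx, cidx]
  out <- matrix(0, h, w)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    nb <- pad[i:(i + 2 * r), j:(j + 2 * r)]
    out[i, j] <- sort(nb)[ceiling(length(nb) / 2) + (length(nb) %% 2 == 0) * 0]
  }
  out
}
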