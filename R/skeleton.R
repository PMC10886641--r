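#' Topological skeletonization of a binary mask
#'
#' Thins the mask to a 1-pixel-wide, 8-connected skeleton by Zhang-Suen
#' parallel thinning, followed by three guarantees the downstream graph
#' analysis relies on:
#' \itemize{
#'   \item every connected component of the mask keeps at least one skeleton
#'     pixel (parallel thinning can erase tiny blobs entirely; the pixel
#'     closest to the component centroid is restored),
#'   \item no 2x2 solid block survives (residual thick spots are removed by
#'     sequentially deleting simple pixels), and
#'   \item staircase corners are canonicalized: a degree-2 pixel whose two
#'     neighbours are themselves adjacent is redundant and is removed, so
#'     paths take the taut 8-connected route and path lengths track the
#'     geometric centerline length.
#' }
#' The skeleton is always a subset of the input mask and has the same number
#' of 8-connected components.
#'
#' @param mask a [binary_mask].
#' @return A [binary_mask] containing the skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- unclass(mask)
  sk <- zhang_suen(m)
  sk <- restore_lost_components(m, sk)
  sk <- remove_thick_blocks(sk)
  sk <- remove_corner_pixels(sk)
  binary_mask(sk, ppm_of(mask))
}

# shift a logical matrix by (dr, dc), padding with FALSE
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# the 8 neighbours in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
zs_neighbours <- function(m) {
  list(
    shift_mat(m, 1, 0),   # P2: value of the pixel's north neighbour
    shift_mat(m, 1, -1),  # P3
    shift_mat(m, 0, -1),  # P4
    shift_mat(m, -1, -1), # P5
    shift_mat(m, -1, 0),  # P6
    shift_mat(m, -1, 1),  # P7
    shift_mat(m, 0, 1),   # P8
    shift_mat(m, 1, 1)    # P9
  )
}

zhang_suen <- function(m) {
  m <- m > 0
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      P <- zs_neighbours(m)
      B <- Reduce(`+`, P)
      A <- Reduce(`+`, lapply(1:8, function(i) (!P[[i]]) & P[[c(2:8, 1)[i]]]))
      if (phase == 1) {
        cond <- (!P[[1]] | !P[[3]] | !P[[5]]) & (!P[[3]] | !P[[5]] | !P[[7]])
      } else {
        cond <- (!P[[1]] | !P[[3]] | !P[[7]]) & (!P[[1]] | !P[[5]] | !P[[7]])
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

restore_lost_components <- function(orig, skel) {
  lab <- label_8connected(orig)
  n <- max(lab)
  if (n == 0) return(skel)
  kept <- unique(lab[skel])
  lost <- setdiff(seq_len(n), kept)
  for (k in lost) {
    idx <- which(lab == k)
    rr <- (idx - 1) %% nrow(orig) + 1
    cc <- (idx - 1) %/% nrow(orig) + 1
    d2 <- (rr - mean(rr))^2 + (cc - mean(cc))^2
    skel[idx[which.min(d2)]] <- TRUE
  }
  skel
}

# crossing number A(p): 1 <=> p is a simple point (8-connected foreground)
crossing_number <- function(m, r, c) {
  h <- nrow(m); w <- ncol(m)
  at <- function(dr, dc) {
    r2 <- r + dr; c2 <- c + dc
    r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w && m[r2, c2]
  }
  seq8 <- c(at(-1, 0), at(-1, 1), at(0, 1), at(1, 1),
            at(1, 0), at(1, -1), at(0, -1), at(-1, -1))
  sum(!seq8 & seq8[c(2:8, 1)])
}

neighbour_count_in <- function(m, r, c) {
  h <- nrow(m); w <- ncol(m)
  s <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w && m[r2, c2]) s <- s + 1L
  }
  s
}

# delete simple pixels until no 2x2 solid block remains; when a block has
# no locally simple pixel (the crossing-number test is conservative), fall
# back to a tentative deletion checked against the global component count
remove_thick_blocks <- function(m) {
  repeat {
    blk <- m & shift_mat(m, -1, 0) & shift_mat(m, 0, -1) & shift_mat(m, -1, -1)
    idx <- which(blk)  # top-left corners of solid 2x2 blocks
    if (length(idx) == 0) return(m)
    deleted <- FALSE
    for (i in idx) {
      r <- (i - 1) %% nrow(m) + 1
      c <- (i - 1) %/% nrow(m) + 1
      for (off in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (!m[r2, c2]) next
        if (crossing_number(m, r2, c2) == 1 &&
            neighbour_count_in(m, r2, c2) >= 2) {
          m[r2, c2] <- FALSE
          deleted <- TRUE
          break
        }
      }
      if (deleted) break
    }
    if (!deleted) {
      ncomp <- max(label_8connected(m))
      for (i in idx) {
        r <- (i - 1) %% nrow(m) + 1
        c <- (i - 1) %/% nrow(m) + 1
        for (off in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
          r2 <- r + off[1]; c2 <- c + off[2]
          if (!m[r2, c2]) next
          m2 <- m; m2[r2, c2] <- FALSE
          if (max(label_8connected(m2)) == ncomp) {
            m <- m2
            deleted <- TRUE
            break
          }
        }
        if (deleted) break
      }
    }
    if (!deleted) return(m)  # irreducible crossing; leave it in place
  }
}

# remove degree-2 pixels whose two neighbours are mutually adjacent:
# the pixel only bends the path around a corner its neighbours already span
remove_corner_pixels <- function(m) {
  h <- nrow(m); w <- ncol(m)
  repeat {
    deg <- skeleton_neighbour_counts(m)
    cand <- which(m & deg == 2)
    deleted <- FALSE
    for (i in cand) {
      r <- (i - 1) %% h + 1
      c <- (i - 1) %/% h + 1
      if (!m[r, c] || neighbour_count_in(m, r, c) != 2) next
      nb <- list()
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w && m[r2, c2])
          nb[[length(nb) + 1]] <- c(r2, c2)
      }
      if (max(abs(nb[[1]] - nb[[2]])) == 1) {  # neighbours adjacent
        m[r, c] <- FALSE
        deleted <- TRUE
      }
    }
    if (!deleted) return(m)
  }
}

#' Raw 8-neighbour counts of a skeleton
#'
#' For every pixel, the number of foreground pixels among its 8 neighbours.
#'
#' @param skel logical matrix.
#' @return Integer matrix of neighbour counts.
#' @keywords internal
skeleton_neighbour_counts <- function(skel) {
  P <- zs_neighbours(skel > 0)
  Reduce(`+`, P)
}

# number of redundant diagonal links per pixel: a diagonal adjacency p~q is
# redundant when one of the two shared orthogonal corner pixels is also
# foreground (the connection is already carried by two orthogonal steps).
redundant_diagonal_counts <- function(m) {
  red <- matrix(0L, nrow(m), ncol(m))
  for (d in list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    q <- shift_mat(m, -d[1], -d[2])           # q fg at p + d
    corner1 <- shift_mat(m, -d[1], 0)          # (r + dr, c)
    corner2 <- shift_mat(m, 0, -d[2])          # (r, c + dc)
    red <- red + (m & q & (corner1 | corner2))
  }
  red
}

#' Junction and endpoint degrees of skeleton pixels
#'
#' Degrees in the skeleton adjacency graph. With `reduced = TRUE` (the
#' convention used by [analyze_skeleton()]), diagonal adjacencies that
#' merely shortcut two orthogonal steps are not counted, so staircase
#' corners along a path do not masquerade as junctions; with
#' `reduced = FALSE` the raw 8-neighbour count is returned.
#'
#' @param skel a [binary_mask] or logical matrix.
#' @param reduced drop redundant diagonal links (default TRUE).
#' @return Integer matrix of per-pixel degrees (0 outside the skeleton).
#' @export
skeleton_degrees <- function(skel, reduced = TRUE) {
  m <- unclass(skel) > 0
  deg <- skeleton_neighbour_counts(m)
  if (reduced) deg <- deg - redundant_diagonal_counts(m)
  deg * m
}

#' Skeleton-graph analysis
#'
#' Decomposes a 1-px skeleton into a graph per connected component:
#' junction nodes (pixels with more than 2 adjacent skeleton pixels, with
#' 8-adjacent junction pixels merged into a single node), endpoint nodes
#' (exactly 1 neighbour), and branches (maximal paths between nodes).
#' Adjacency is the reduced 8-connectivity of [skeleton_degrees()]:
#' diagonal links shortcutting two orthogonal steps are ignored, so only
#' genuine side-branches create junctions. Branch length is the geometric
#' path length: 1 per orthogonal step, sqrt(2) per diagonal step, also
#' reported in microns via the calibration.
#'
#' Special components: an isolated single pixel is reported as one
#' degenerate branch of length 1 px with one endpoint and no junction
#' (`degenerate = TRUE`); a pure closed ring (every pixel with 2 neighbours)
#' is one cyclic branch with zero endpoints and zero junctions
#' (`has_cycle = TRUE`).
#'
#' @param skel a [binary_mask] holding a skeleton (no 2x2 solid block).
#' @param mask optional: the [binary_mask] the skeleton was thinned from.
#'   When given, branch lengths are end-cap compensated: thinning erodes a
#'   tube's rounded cap back past the centerline end, so at every endpoint
#'   node the branch is extended along its local tangent by the overshoot of
#'   the cap boundary beyond the tube half-width (half-width estimated per
#'   component from the distance transform of the mask).
#' @return An object of class `skeleton_graph`: list with `components`
#'   (one record per connected component: `branch_count`, `junction_count`,
#'   `endpoint_count`, `branch_lengths_px`, `branch_lengths_um`, `nodes`
#'   data.frame, `edges` data.frame, `pixel_idx`, `degenerate`, `has_cycle`)
#'   and `pixels_per_micron`.
#' @export
analyze_skeleton <- function(skel, mask = NULL) {
  stopifnot(inherits(skel, "binary_mask"))
  ppm <- ppm_of(skel)
  m <- unclass(skel)
  blk <- m & shift_mat(m, -1, 0) & shift_mat(m, 0, -1) & shift_mat(m, -1, -1)
  if (any(blk))
    stop("input is not a 1-px skeleton: solid 2x2 foreground block found")
  h <- nrow(m)
  lab <- label_8connected(m)
  ncomp <- max(lab)
  deg <- skeleton_degrees(m, reduced = TRUE)
  jmask <- m & deg > 2
  jlab <- label_8connected(jmask)
  dm <- NULL
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "binary_mask"), all(dim(mask) == dim(skel)))
    if (!all(unclass(skel)[unclass(mask) == FALSE] == FALSE))
      stop("skeleton is not a subset of `mask`")
    dm <- as.matrix(EBImage::distmap(unclass(mask) * 1.0))
  }
  comps <- vector("list", ncomp)
  for (ci in seq_len(ncomp)) {
    idx <- which(lab == ci)
    ce <- analyze_one_component(m, idx, deg, jlab, h, ppm, ci)
    if (!is.null(dm)) ce <- compensate_end_caps(ce, unclass(mask), dm, h, ppm)
    comps[[ci]] <- ce
  }
  structure(list(components = comps, pixels_per_micron = ppm, labels = lab),
            class = "skeleton_graph")
}

# march from pixel (er, ec) along unit direction ua until leaving the mask;
# returns the last foreground parameter value (0.5 px steps)
march_to_boundary <- function(mask, er, ec, ua, t_max, h, W) {
  t_hit <- 0
  for (t in seq(0.5, t_max, by = 0.5)) {
    pr <- as.integer(round(er + t * ua[1]))
    pc <- as.integer(round(ec + t * ua[2]))
    if (pr < 1 || pr > h || pc < 1 || pc > W || !mask[pr, pc]) break
    t_hit <- t
  }
  t_hit
}

# extend branches terminating at endpoint nodes by the cap overshoot:
# distance from the endpoint to the mask boundary along the branch tangent,
# minus the tube radius. The radius is measured by the same marching
# procedure, perpendicular to the branch at mid-path pixels, so the
# orientation-dependent rasterization bias cancels. Negative overshoots
# never shorten a branch.
compensate_end_caps <- function(ce, mask, dm, h, ppm) {
  if (ce$degenerate || ce$has_cycle || nrow(ce$edges) == 0) return(ce)
  half_width <- stats::median(dm[ce$pixel_idx])
  W <- ncol(mask)
  kinds <- ce$nodes$kind
  for (ei in seq_len(nrow(ce$edges))) {
    path <- ce$edges$path_idx[[ei]]
    np <- length(path)
    # tube radius: perpendicular marches at up to 5 mid-path pixels
    r_samp <- numeric(0)
    if (np >= 4) {
      mids <- unique(round(seq(0.25, 0.75, length.out = 5) * (np - 1)) + 1)
      for (k in mids) {
        lo <- max(1, k - 2); hi <- min(np, k + 2)
        pr1 <- (path[lo] - 1) %% h + 1; pc1 <- (path[lo] - 1) %/% h + 1
        pr2 <- (path[hi] - 1) %% h + 1; pc2 <- (path[hi] - 1) %/% h + 1
        tg <- c(pr2 - pr1, pc2 - pc1)
        nt <- sqrt(sum(tg^2))
        if (nt == 0) next
        perp <- c(-tg[2], tg[1]) / nt
        kr <- (path[k] - 1) %% h + 1; kc <- (path[k] - 1) %/% h + 1
        r_samp <- c(r_samp,
                    march_to_boundary(mask, kr, kc, perp, 4 * half_width,
                                      h, W),
                    march_to_boundary(mask, kr, kc, -perp, 4 * half_width,
                                      h, W))
      }
    }
    r_tube <- if (length(r_samp) >= 4) stats::median(r_samp)
              else half_width - 0.5
    for (side in 1:2) {
      v <- if (side == 1) ce$edges$node_a[ei] else ce$edges$node_b[ei]
      if (is.na(v) || kinds[v] != "endpoint") next
      epix <- if (side == 1) path[1] else path[np]
      ref <- if (side == 1) path[min(4, np)] else path[max(1, np - 3)]
      er <- (epix - 1) %% h + 1; ec <- (epix - 1) %/% h + 1
      rr <- (ref - 1) %% h + 1; rc <- (ref - 1) %/% h + 1
      u <- c(er - rr, ec - rc)
      nu <- sqrt(sum(u^2))
      if (nu == 0) next
      u <- u / nu
      # march a small fan around the tangent: the eroded tail may curve
      t_cap <- r_tube + 2           # erosion cannot exceed the cap radius
      t_ahead <- 0
      for (a in c(0, -pi / 6, pi / 6)) {
        ua <- c(cos(a) * u[1] - sin(a) * u[2],
                sin(a) * u[1] + cos(a) * u[2])
        t_ahead <- max(t_ahead,
                       march_to_boundary(mask, er, ec, ua,
                                         r_tube + t_cap + 1, h, W))
      }
      # + 0.25: the 0.5-px march samples the boundary half a step late on
      # average, and the same quantization affects the radius marches
      ext <- min(max(0, t_ahead - r_tube + 0.25), t_cap)
      ce$edges$length_px[ei] <- ce$edges$length_px[ei] + ext
    }
  }
  ce$edges$length_um <- ce$edges$length_px / ppm
  ce$branch_lengths_px <- ce$edges$length_px
  ce$branch_lengths_um <- ce$edges$length_um
  ce
}

#' @export
print.skeleton_graph <- function(x, ...) {
  nb <- vapply(x$components, function(ce) ce$branch_count, numeric(1))
  nj <- vapply(x$components, function(ce) ce$junction_count, numeric(1))
  cat(sprintf("<skeleton_graph> %d components, %d branches, %d junctions\n",
              length(x$components), sum(nb), sum(nj)))
  invisible(x)
}

step_len <- function(i1, i2, h) {
  r1 <- (i1 - 1) %% h; c1 <- (i1 - 1) %/% h
  r2 <- (i2 - 1) %% h; c2 <- (i2 - 1) %/% h
  if (r1 != r2 && c1 != c2) sqrt(2) else 1
}

analyze_one_component <- function(m, idx, deg, jlab, h, ppm, ci) {
  w <- ncol(m)
  rr <- (idx - 1) %% h + 1
  cc <- (idx - 1) %/% h + 1
  n <- length(idx)
  # isolated pixel: degenerate single "drop"
  if (n == 1) {
    nodes <- data.frame(id = 1L, kind = "endpoint", row = rr, col = cc)
    edges <- data.frame(id = 1L, node_a = 1L, node_b = 1L,
                        length_px = 1, length_um = 1 / ppm)
    edges$path_idx <- list(idx)
    return(list(component_id = ci, branch_count = 1L, junction_count = 0L,
                endpoint_count = 1L, branch_lengths_px = 1,
                branch_lengths_um = 1 / ppm, nodes = nodes, edges = edges,
                pixel_idx = idx, degenerate = TRUE, has_cycle = FALSE))
  }
  # reduced adjacency lists within the component
  pos <- new.env(hash = TRUE, size = n)
  for (k in seq_len(n)) assign(as.character(idx[k]), k, envir = pos)
  nbrs <- vector("list", n)
  for (k in seq_len(n)) {
    r <- rr[k]; c <- cc[k]
    nb <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > h || c2 < 1 || c2 > w || !m[r2, c2]) next
      if (dr != 0 && dc != 0 && (m[r2, c] || m[r, c2])) next  # redundant
      nb <- c(nb, get(as.character((c2 - 1) * h + r2), envir = pos))
    }
    nbrs[[k]] <- nb
  }
  dg <- lengths(nbrs)
  is_junc <- deg[idx] > 2
  is_end <- dg == 1
  # node ids: junction clusters first (by jlab id), then endpoints
  jl <- jlab[idx]                 # 0 for non-junction pixels
  jids <- sort(unique(jl[jl > 0]))
  node_of <- integer(n)           # node id per pixel (0 = branch pixel)
  for (k in seq_len(n)) if (jl[k] > 0) node_of[k] <- match(jl[k], jids)
  njn <- length(jids)
  ends <- which(is_end & !is_junc)
  for (i in seq_along(ends)) node_of[ends[i]] <- njn + i
  n_nodes <- njn + length(ends)
  # pure cycle: no nodes at all
  if (n_nodes == 0) {
    len <- trace_cycle(nbrs, idx, h)
    edges <- data.frame(id = 1L, node_a = NA_integer_, node_b = NA_integer_,
                        length_px = len, length_um = len / ppm)
    edges$path_idx <- list(idx)
    return(list(component_id = ci, branch_count = 1L, junction_count = 0L,
                endpoint_count = 0L, branch_lengths_px = len,
                branch_lengths_um = len / ppm,
                nodes = data.frame(id = integer(0), kind = character(0),
                                   row = integer(0), col = integer(0)),
                edges = edges, pixel_idx = idx,
                degenerate = FALSE, has_cycle = TRUE))
  }
  kind <- c(rep("junction", njn), rep("endpoint", length(ends)))
  node_row <- node_col <- numeric(n_nodes)
  for (v in seq_len(n_nodes)) {
    px <- which(node_of == v)
    node_row[v] <- mean(rr[px]); node_col[v] <- mean(cc[px])
  }
  nodes <- data.frame(id = seq_len(n_nodes), kind = kind,
                      row = node_row, col = node_col)
  # trace branches
  visited <- rep(FALSE, n)        # visited branch (non-node) pixels
  lens <- numeric(0)
  e_a <- e_b <- integer(0)
  paths <- list()
  has_cycle <- FALSE
  node_px <- which(node_of > 0)
  for (p in node_px) {
    for (q in nbrs[[p]]) {
      if (node_of[q] > 0) {
        # node-node adjacency: intra-cluster links are not branches
        if (node_of[q] == node_of[p]) next
        if (idx[p] < idx[q]) {   # record each such branch once
          lens <- c(lens, step_len(idx[p], idx[q], h))
          e_a <- c(e_a, node_of[p]); e_b <- c(e_b, node_of[q])
          paths[[length(paths) + 1]] <- c(idx[p], idx[q])
        }
        next
      }
      if (visited[q]) next
      len <- step_len(idx[p], idx[q], h)
      path <- c(idx[p], idx[q])
      prev <- p; cur <- q
      repeat {
        visited[cur] <- TRUE
        nxt <- setdiff(nbrs[[cur]], prev)
        if (length(nxt) > 1) {
          nd <- nxt[node_of[nxt] > 0]
          nxt <- if (length(nd) > 0) nd[1] else nxt[!visited[nxt]][1]
        }
        if (length(nxt) == 0 || is.na(nxt)) break
        len <- len + step_len(idx[cur], idx[nxt], h)
        path <- c(path, idx[nxt])
        if (node_of[nxt] > 0) {
          lens <- c(lens, len)
          e_a <- c(e_a, node_of[p]); e_b <- c(e_b, node_of[nxt])
          paths[[length(paths) + 1]] <- path
          if (node_of[nxt] == node_of[p]) has_cycle <- TRUE
          break
        }
        prev <- cur; cur <- nxt
      }
    }
  }
  # refine each junction point as the least-squares intersection of the
  # directions of its incident arms (thinning displaces the raw junction
  # cluster off the true branch point by up to the tube radius), then
  # extend each arm from the pixel where its trace stopped to that point
  if (length(lens) > 0) {
    for (v in seq_len(njn)) {
      inc <- which(e_a == v | e_b == v)
      if (length(inc) == 0) next
      ctr <- c(node_row[v], node_col[v])
      jref <- refine_junction_point(ctr, inc, e_a, paths, h)
      if (sqrt(sum((jref - ctr)^2)) <= 3) {
        node_row[v] <- jref[1]; node_col[v] <- jref[2]
      }
    }
    nodes$row <- node_row; nodes$col <- node_col
    # measure junction-terminated arms up to a pixel clear of the junction
    # zone (thinning wiggles the skeleton there), then straight to the
    # junction point
    for (ei in seq_along(lens)) {
      path <- paths[[ei]]
      np <- length(path)
      for (side in 1:2) {
        v <- if (side == 1) e_a[ei] else e_b[ei]
        if (kind[v] != "junction" || np < 2) next
        # anchor pixel: up to 4 steps out of the junction zone, but never
        # past the middle (both ends may be junctions)
        kk <- max(2L, min(5L, as.integer(floor((np + 1) / 2))))
        if (side == 1) {
          for (j in seq_len(kk - 1))
            lens[ei] <- lens[ei] - step_len(path[j], path[j + 1], h)
          pix <- path[kk]
        } else {
          for (j in seq_len(kk - 1))
            lens[ei] <- lens[ei] - step_len(path[np - j], path[np - j + 1], h)
          pix <- path[np - kk + 1]
        }
        pr <- (pix - 1) %% h + 1; pc <- (pix - 1) %/% h + 1
        lens[ei] <- lens[ei] +
          sqrt((pr - node_row[v])^2 + (pc - node_col[v])^2)
      }
    }
  }
  edges <- data.frame(id = seq_along(lens), node_a = e_a, node_b = e_b,
                      length_px = lens, length_um = lens / ppm)
  edges$path_idx <- paths
  list(component_id = ci,
       branch_count = length(lens),
       junction_count = njn,
       endpoint_count = length(ends),
       branch_lengths_px = lens,
       branch_lengths_um = lens / ppm,
       nodes = nodes, edges = edges, pixel_idx = idx,
       degenerate = FALSE, has_cycle = has_cycle)
}

# least-squares intersection point of the arm axes incident to a junction:
# each arm contributes the line through its near-junction pixels; solve
# sum_i (I - d_i d_i^T) (x - p_i) = 0. Falls back to `ctr` when degenerate.
refine_junction_point <- function(ctr, inc, e_a, paths, h) {
  A <- matrix(0, 2, 2); b <- c(0, 0); used <- 0L
  for (ei in inc) {
    path <- paths[[ei]]
    # orient so the path leaves this junction
    fwd <- path
    # take the pixels nearest this junction end
    d_first <- sum((c((path[1] - 1) %% h + 1, (path[1] - 1) %/% h + 1) -
                      ctr)^2)
    d_last <- sum((c((path[length(path)] - 1) %% h + 1,
                     (path[length(path)] - 1) %/% h + 1) - ctr)^2)
    if (d_last < d_first) fwd <- rev(path)
    take <- fwd[seq_len(min(6, length(fwd)))]
    if (length(take) < 3) next
    pr <- (take - 1) %% h + 1; pc <- (take - 1) %/% h + 1
    mu <- c(mean(pr), mean(pc))
    X <- cbind(pr - mu[1], pc - mu[2])
    sv <- svd(X)
    d <- sv$v[, 1]
    P <- diag(2) - d %*% t(d)
    A <- A + P; b <- b + P %*% mu
    used <- used + 1L
  }
  if (used < 2 || abs(det(A)) < 1e-8) return(ctr)
  as.numeric(solve(A, b))
}

trace_cycle <- function(nbrs, idx, h) {
  # every pixel has exactly 2 neighbours; walk once around
  start <- 1L
  prev <- start
  cur <- nbrs[[start]][1]
  len <- step_len(idx[start], idx[cur], h)
  while (cur != start) {
    nxt <- setdiff(nbrs[[cur]], prev)[1]
    len <- len + step_len(idx[cur], idx[nxt], h)
    prev <- cur; cur <- nxt
  }
  len
}

#' Prune short terminal spurs from a skeleton
#'
#' Iteratively removes terminal branches (endpoint to junction) shorter
#' than `min_px`: these arise when thinning a tube whose boundary bulges
#' (noise, caps) and would otherwise inflate junction and branch counts.
#' Branches between two endpoints — whole small objects — are never pruned.
#' The junction-cluster pixels themselves are kept, so components are never
#' disconnected or lost.
#'
#' @param skel a skeleton [binary_mask].
#' @param min_px prune branches strictly shorter than this many pixels
#'   (default 6, about the tube diameter and below the shortest plausible
#'   mitochondrion at the default calibration).
#' @return The pruned skeleton [binary_mask].
#' @export
prune_skeleton <- function(skel, min_px = 6) {
  stopifnot(inherits(skel, "binary_mask"))
  if (min_px <= 0) return(skel)
  m <- unclass(skel)
  ppm <- ppm_of(skel)
  for (iter in 1:10) {
    g <- analyze_skeleton(binary_mask(m, ppm))
    deg <- skeleton_degrees(m, reduced = TRUE)
    jpx <- which(deg > 2)            # junction-cluster pixels stay in place
    drop_idx <- integer(0)
    for (ce in g$components) {
      if (ce$junction_count == 0 || nrow(ce$edges) == 0) next
      kinds <- ce$nodes$kind
      for (ei in seq_len(nrow(ce$edges))) {
        a <- ce$edges$node_a[ei]; b <- ce$edges$node_b[ei]
        if (is.na(a) || is.na(b)) next
        if (xor(kinds[a] == "endpoint", kinds[b] == "endpoint") &&
            ce$edges$length_px[ei] < min_px) {
          drop_idx <- c(drop_idx, setdiff(ce$edges$path_idx[[ei]], jpx))
        }
      }
    }
    if (length(drop_idx) == 0) break
    m[unique(drop_idx)] <- FALSE
    m <- remove_corner_pixels(m)
  }
  binary_mask(m, ppm)
}
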