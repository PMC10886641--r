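#' Specification of a synthetic mitochondrial scene
#'
#' Describes a single-cell fluorescence micrograph to simulate: a mix of
#' branched tubular networks (grown as self-avoiding lattice random walks
#' with per-step branching), short individual mitochondria (rods, optionally
#' spheres/"drops"), and optionally fully looped "donuts". Objects are placed
#' without overlap and with a clearance that keeps distinct tubes from fusing
#' after PSF blur, so the recorded ground truth (class, branch lengths,
#' junction/endpoint counts, centerline, area) stays exact.
#'
#' Defaults emulate the acquisition they stand in for: 23.4 px/um
#' calibration, a 16-bit camera, super-resolution-grade PSF (sigma 1.2 px,
#' about 50 nm), network branches of 0.8-2.5 um against individual
#' mitochondria of 0.3-1.0 um (matching the reported order of per-cell
#' medians: individuals around 0.4-1 um, network branches 1.2-2.3 um), and
#' a mixed Poisson + Gaussian camera noise model.
#'
#' @param image_size integer vector (H, W) in pixels.
#' @param pixels_per_micron calibration (default 23.4 px/um).
#' @param n_networks number of branched networks.
#' @param n_individuals number of individual mitochondria.
#' @param branch_length_range network branch length range in um (min, max).
#' @param individual_length_range individual mitochondrion length range in um.
#' @param branching_prob per-growth-step probability that a branch splits.
#' @param tube_radius tube half-width in px.
#' @param psf_sigma isotropic Gaussian PSF sigma in px (0 = no blur).
#' @param background_level constant background intensity.
#' @param background_gradient additional left-to-right linear background
#'   ramp amplitude (0 = flat background).
#' @param object_intensity peak added intensity of an object above background.
#' @param noise_model list with `poisson_scale` (intensity units per photon;
#'   0 disables shot noise) and `gaussian_sd` (additive read noise sd).
#' @param include_loops if TRUE, add `n_loops` closed rings (class `loop`).
#' @param n_loops number of loops when `include_loops`.
#' @param sphere_fraction fraction of individuals rendered as discs
#'   (single-pixel centerline, aspect ratio near 1).
#' @param network_shape `"random"` (stochastic branching), `"Y"` (trunk
#'   splitting into two at its end) or `"T"` (perpendicular branch from the
#'   trunk midpoint); the deterministic shapes always have 3 branches and
#'   1 junction.
#' @param seed integer seed; identical specs give bit-identical scenes.
#' @return A validated object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(512L, 512L),
                       pixels_per_micron = 23.4,
                       n_networks = 3,
                       n_individuals = 8,
                       branch_length_range = c(0.8, 2.5),
                       individual_length_range = c(0.3, 1.0),
                       branching_prob = 0.06,
                       tube_radius = 2,
                       psf_sigma = 1.2,
                       background_level = 100,
                       background_gradient = 0,
                       object_intensity = 900,
                       noise_model = list(poisson_scale = 4, gaussian_sd = 20),
                       include_loops = FALSE,
                       n_loops = 2,
                       sphere_fraction = 0,
                       network_shape = c("random", "Y", "T"),
                       seed = NULL) {
  network_shape <- match.arg(network_shape)
  if (length(image_size) == 1) image_size <- rep(image_size, 2)
  image_size <- as.integer(image_size)
  stopifnot(all(image_size > 0), pixels_per_micron > 0,
            n_networks >= 0, n_individuals >= 0,
            length(branch_length_range) == 2,
            branch_length_range[1] <= branch_length_range[2],
            branch_length_range[1] > 0,
            length(individual_length_range) == 2,
            individual_length_range[1] <= individual_length_range[2],
            individual_length_range[1] > 0,
            branching_prob >= 0, branching_prob <= 1,
            sphere_fraction >= 0, sphere_fraction <= 1,
            tube_radius >= 1, psf_sigma >= 0,
            background_level >= 0, background_gradient >= 0,
            object_intensity > 0)
  if (!is.list(noise_model) ||
      is.null(noise_model$poisson_scale) || is.null(noise_model$gaussian_sd) ||
      noise_model$poisson_scale < 0 || noise_model$gaussian_sd < 0)
    stop("`noise_model` must be list(poisson_scale >= 0, gaussian_sd >= 0)")
  structure(list(image_size = image_size,
                 pixels_per_micron = pixels_per_micron,
                 n_networks = n_networks, n_individuals = n_individuals,
                 branch_length_range = branch_length_range,
                 individual_length_range = individual_length_range,
                 branching_prob = branching_prob,
                 tube_radius = tube_radius, psf_sigma = psf_sigma,
                 background_level = background_level,
                 background_gradient = background_gradient,
                 object_intensity = object_intensity,
                 noise_model = noise_model,
                 include_loops = include_loops, n_loops = n_loops,
                 sphere_fraction = sphere_fraction,
                 network_shape = network_shape, seed = seed),
            class = "scene_spec")
}

# run expr under a local RNG state seeded with `seed` (NULL = use current)
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# the 8 lattice directions, ordered by angle
DIRS <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
              dc = c(0, 1, 1, 1, 0, -1, -1, -1))

rotate_dir <- function(d, k) ((d - 1 + k) %% 8) + 1

#' Generate a synthetic micrograph with ground truth
#'
#' Grows and rasterizes the objects described by a [scene_spec()], renders
#' the fluorescence image (centerlines dilated to the tube radius, Gaussian
#' PSF, background, Poisson and Gaussian noise), and records exact per-object
#' ground truth before rasterization.
#'
#' @param spec a [scene_spec()].
#' @return An object of class `mito_scene`: list with
#'   \describe{
#'     \item{image}{the noisy rendered [micrograph]}
#'     \item{truth_mask}{[binary_mask] of the noiseless dilated centerlines}
#'     \item{ground_truth}{list of per-object records (`object_id`, `class`,
#'       `true_branch_lengths_um`, `true_junction_count`,
#'       `true_endpoint_count`, `centerline_pixels`, `true_area_px`)}
#'     \item{spec}{the spec}
#'   }
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_local_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  ppm <- spec$pixels_per_micron
  clearance <- 2 * spec$tube_radius + 8
  margin <- spec$tube_radius + ceiling(2 * spec$psf_sigma) + 2
  committed <- matrix(numeric(0), ncol = 2)  # all committed centerline px
  objects <- list()
  oid <- 0L

  add_object <- function(class, edges, junctions, endpoints) {
    oid <<- oid + 1L
    pix <- do.call(rbind, lapply(edges, `[[`, "pixels"))
    pix <- unique(pix)
    committed <<- rbind(committed, pix)
    lens <- vapply(edges, function(e) chain_length(e$pixels), numeric(1))
    objects[[oid]] <<- list(
      object_id = oid, class = class,
      true_branch_lengths_um = lens / ppm,
      true_junction_count = junctions,
      true_endpoint_count = endpoints,
      centerline_pixels = pix,
      true_area_px = NA_integer_)
  }

  for (i in seq_len(spec$n_networks)) {
    tree <- grow_network(spec, committed, clearance, margin)
    if (is.null(tree))
      stop(sprintf(paste0("object placement failed: scene too crowded ",
                          "(image %dx%d, %d networks, %d individuals, ",
                          "clearance %d px)"),
                   H, W, spec$n_networks, spec$n_individuals, clearance))
    add_object("network", tree$edges, tree$n_junctions, tree$n_endpoints)
  }
  n_spheres <- round(spec$sphere_fraction * spec$n_individuals)
  for (i in seq_len(spec$n_individuals)) {
    sphere <- i <= n_spheres
    seg <- grow_individual(spec, committed, clearance, margin, sphere)
    if (is.null(seg))
      stop(sprintf(paste0("object placement failed: scene too crowded ",
                          "(image %dx%d, %d networks, %d individuals, ",
                          "clearance %d px)"),
                   H, W, spec$n_networks, spec$n_individuals, clearance))
    add_object("individual", list(seg), 0L, if (sphere) 1L else 2L)
  }
  if (isTRUE(spec$include_loops)) {
    for (i in seq_len(spec$n_loops)) {
      ring <- place_loop(spec, committed, clearance, margin)
      if (is.null(ring))
        stop("object placement failed: no room for loops at clearance ",
             clearance, " px")
      add_object("loop", list(ring), 0L, 0L)
    }
  }

  # rasterize: per-object disc dilation of the centerline
  truth <- matrix(FALSE, H, W)
  r <- spec$tube_radius
  off <- disc_offsets(r)
  for (ob in objects) {
    stamp <- stamp_disc(ob$centerline_pixels, off, H, W)
    objects[[ob$object_id]]$true_area_px <- nrow(stamp)
    truth[stamp] <- TRUE
  }

  img <- matrix(spec$background_level, H, W)
  if (spec$background_gradient > 0)
    img <- img + matrix(spec$background_gradient *
                          (col(img) - 1) / max(W - 1, 1), H, W)
  sig <- truth * 1.0
  if (spec$psf_sigma > 0)
    sig <- as.matrix(EBImage::gblur(sig, sigma = spec$psf_sigma))
  img <- img + spec$object_intensity * sig
  if (spec$noise_model$poisson_scale > 0) {
    p <- spec$noise_model$poisson_scale
    img <- matrix(stats::rpois(length(img), pmax(img, 0) / p) * p, H, W)
  }
  if (spec$noise_model$gaussian_sd > 0)
    img <- img + matrix(stats::rnorm(length(img),
                                     sd = spec$noise_model$gaussian_sd), H, W)
  img <- pmin(pmax(img, 0), 65535)

  structure(list(image = micrograph(img, ppm, 16L),
                 truth_mask = binary_mask(truth, ppm),
                 ground_truth = objects,
                 spec = spec),
            class = "mito_scene")
}

#' @export
print.mito_scene <- function(x, ...) {
  cls <- vapply(x$ground_truth, `[[`, character(1), "class")
  cat(sprintf("<mito_scene> %d x %d px, %d objects (%s)\n",
              nrow(x$image), ncol(x$image), length(cls),
              paste(sprintf("%d %s", table(cls), names(table(cls))),
                    collapse = ", ")))
  invisible(x)
}

#' Tabular summary of scene ground truth
#'
#' @param object a `mito_scene`.
#' @param ... unused.
#' @return data.frame with one row per simulated object.
#' @export
summary.mito_scene <- function(object, ...) {
  do.call(rbind, lapply(object$ground_truth, function(ob) {
    data.frame(object_id = ob$object_id, class = ob$class,
               n_branches = length(ob$true_branch_lengths_um),
               total_branch_len_um = sum(ob$true_branch_lengths_um),
               median_branch_len_um = stats::median(ob$true_branch_lengths_um),
               true_junction_count = ob$true_junction_count,
               true_endpoint_count = ob$true_endpoint_count,
               true_area_px = ob$true_area_px)
  }))
}

# geometric length of a pixel chain (1 per orthogonal, sqrt(2) per diagonal)
chain_length <- function(px) {
  if (nrow(px) < 2) return(0)
  d <- abs(diff(px))
  sum(ifelse(rowSums(d) == 2, sqrt(2), 1))
}

disc_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  as.matrix(g[g$dr^2 + g$dc^2 <= r^2, ])
}

# all pixels covered by discs centred on the centerline; returns (row,col)
stamp_disc <- function(px, off, H, W) {
  rr <- rep(px[, 1], each = nrow(off)) + off[, 1]
  cc <- rep(px[, 2], each = nrow(off)) + off[, 2]
  ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  unique(cbind(rr[ok], cc[ok]))
}

min_dist2 <- function(p, pts) {
  if (nrow(pts) == 0) return(Inf)
  min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)
}

# walk a straight-ish chain from `start` along direction index `d`
# for `len_px` geometric length; clearance-checked against `blocked`
# (minus an exemption zone of radius excl around `exempt_at`, if given).
walk_chain <- function(start, d, len_px, turn_prob, blocked, clearance,
                       H, W, margin, exempt_at = NULL) {
  excl2 <- (clearance + 2)^2
  cl2 <- clearance^2
  px <- matrix(start, ncol = 2)
  pos <- start
  len <- 0
  tail_keep <- clearance + 2
  while (len < len_px) {
    if (stats::runif(1) < turn_prob)
      d <- rotate_dir(d, sample(c(-1L, 1L), 1))
    nxt <- pos + DIRS[d, ]
    if (nxt[1] <= margin || nxt[1] > H - margin ||
        nxt[2] <= margin || nxt[2] > W - margin)
      return(NULL)
    # clearance against other objects/branches
    chk <- blocked
    if (!is.null(exempt_at) && nrow(chk) > 0) {
      keep <- (chk[, 1] - exempt_at[1])^2 + (chk[, 2] - exempt_at[2])^2 > excl2
      chk <- chk[keep, , drop = FALSE]
    }
    if (min_dist2(nxt, chk) < cl2) return(NULL)
    # self-clearance against own chain except the recent tail
    if (nrow(px) > tail_keep) {
      own <- px[seq_len(nrow(px) - tail_keep), , drop = FALSE]
      if (min_dist2(nxt, own) < cl2) return(NULL)
    }
    len <- len + if (all(DIRS[d, ] != 0)) sqrt(2) else 1
    px <- rbind(px, nxt)
    pos <- nxt
  }
  list(pixels = px, end = pos, dir = d, length_px = len)
}

draw_len_px <- function(range_um, ppm) stats::runif(1, range_um[1], range_um[2]) * ppm

# grow one branched network; returns list(edges, n_junctions, n_endpoints)
grow_network <- function(spec, committed, clearance, margin) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  ppm <- spec$pixels_per_micron
  rng_um <- spec$branch_length_range
  min_seg <- max(4, floor(rng_um[1] * ppm))
  for (attempt in 1:60) {
    root <- c(sample(seq(margin + 1, H - margin), 1),
              sample(seq(margin + 1, W - margin), 1))
    if (min_dist2(root, committed) < clearance^2) next
    d0 <- sample(8L, 1)
    if (spec$network_shape == "Y") {
      tree <- grow_shape_y(spec, root, d0, committed, clearance, margin)
    } else if (spec$network_shape == "T") {
      tree <- grow_shape_t(spec, root, d0, committed, clearance, margin)
    } else {
      force_branch <- attempt > 30
      tree <- grow_random_tree(spec, root, d0, committed, clearance, margin,
                               min_seg, force_branch)
    }
    if (!is.null(tree)) return(tree)
  }
  NULL
}

grow_shape_y <- function(spec, root, d0, committed, clearance, margin) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  ppm <- spec$pixels_per_micron
  trunk <- walk_chain(root, d0, draw_len_px(spec$branch_length_range, ppm),
                      0.1, committed, clearance, H, W, margin)
  if (is.null(trunk)) return(NULL)
  blocked <- rbind(committed, trunk$pixels)
  arms <- list()
  for (k in c(-1L, 1L)) {   # +-45 degrees off the trunk direction
    arm <- walk_chain(trunk$end, rotate_dir(trunk$dir, k),
                      draw_len_px(spec$branch_length_range, ppm),
                      0.1, blocked, clearance, H, W, margin,
                      exempt_at = trunk$end)
    if (is.null(arm)) return(NULL)
    blocked <- rbind(blocked, arm$pixels)
    arms[[length(arms) + 1]] <- arm
  }
  list(edges = c(list(trunk), arms), n_junctions = 1L, n_endpoints = 3L)
}

grow_shape_t <- function(spec, root, d0, committed, clearance, margin) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  ppm <- spec$pixels_per_micron
  # the junction splits the trunk into two branches; draw each half from
  # the branch-length range so no branch falls below it
  l1 <- draw_len_px(spec$branch_length_range, ppm)
  l2 <- draw_len_px(spec$branch_length_range, ppm)
  trunk <- walk_chain(root, d0, l1 + l2,
                      0.05, committed, clearance, H, W, margin)
  if (is.null(trunk)) return(NULL)
  n <- nrow(trunk$pixels)
  d <- abs(diff(trunk$pixels))
  steps <- cumsum(ifelse(rowSums(d) == 2, sqrt(2), 1))
  mid <- min(which(steps >= l1) + 1L, n - 2L)
  jpos <- trunk$pixels[mid, ]
  # perpendicular to the trunk CHORD: the final walk direction can differ
  # from the overall orientation, and a stem that is not clearly
  # perpendicular can run parallel inside the junction exemption zone
  v <- trunk$pixels[n, ] - trunk$pixels[1, ]
  dir_ang <- atan2(DIRS[, 1], DIRS[, 2])
  chord_ang <- atan2(v[1], v[2])
  d_chord <- which.min(abs(atan2(sin(chord_ang - dir_ang),
                                 cos(chord_ang - dir_ang))))
  stem <- walk_chain(jpos, rotate_dir(d_chord, sample(c(-2L, 2L), 1)),
                     draw_len_px(spec$branch_length_range, ppm),
                     0.05, rbind(committed, trunk$pixels), clearance,
                     H, W, margin, exempt_at = jpos)
  if (is.null(stem)) return(NULL)
  e1 <- list(pixels = trunk$pixels[1:mid, , drop = FALSE])
  e2 <- list(pixels = trunk$pixels[mid:n, , drop = FALSE])
  list(edges = list(e1, e2, stem), n_junctions = 1L, n_endpoints = 3L)
}

grow_random_tree <- function(spec, root, d0, committed, clearance, margin,
                             min_seg, force_branch) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  ppm <- spec$pixels_per_micron
  max_edges <- 9L
  edges <- list()
  junctions <- list()
  blocked <- committed
  # tips: list of (pos, dir, origin of the edge)
  tips <- list(list(pos = root, dir = d0, origin = NULL))
  forced_done <- FALSE
  while (length(tips) > 0) {
    tip <- tips[[1]]; tips <- tips[-1]
    target <- draw_len_px(spec$branch_length_range, ppm)
    px <- matrix(tip$pos, ncol = 2)
    pos <- tip$pos; d <- tip$dir; len <- 0
    split <- FALSE
    excl2 <- (clearance + 2)^2
    while (len < target) {
      if (stats::runif(1) < 0.08) d <- rotate_dir(d, sample(c(-1L, 1L), 1))
      nxt <- pos + DIRS[d, ]
      if (nxt[1] <= margin || nxt[1] > H - margin ||
          nxt[2] <= margin || nxt[2] > W - margin) return(NULL)
      chk <- blocked
      if (!is.null(tip$origin) && nrow(chk) > 0) {
        keep <- (chk[, 1] - tip$origin[1])^2 +
          (chk[, 2] - tip$origin[2])^2 > excl2
        chk <- chk[keep, , drop = FALSE]
      }
      if (min_dist2(nxt, chk) < clearance^2) return(NULL)
      if (nrow(px) > clearance + 2) {
        own <- px[seq_len(nrow(px) - clearance - 2), , drop = FALSE]
        if (min_dist2(nxt, own) < clearance^2) return(NULL)
      }
      len <- len + if (all(DIRS[d, ] != 0)) sqrt(2) else 1
      px <- rbind(px, nxt)
      pos <- nxt
      can_split <- len >= min_seg &&
        length(edges) + length(tips) + 2 <= max_edges
      want_split <- stats::runif(1) < spec$branching_prob ||
        (force_branch && !forced_done && length(junctions) == 0)
      if (can_split && want_split) {
        split <- TRUE
        forced_done <- TRUE
        break
      }
    }
    edges[[length(edges) + 1]] <- list(pixels = px, end = pos, dir = d)
    blocked <- rbind(blocked, px)
    if (split) {
      junctions[[length(junctions) + 1]] <- pos
      side <- sample(c(-2L, 2L), 1)
      tips <- c(tips, list(list(pos = pos, dir = d, origin = pos),
                           list(pos = pos, dir = rotate_dir(d, side),
                                origin = pos)))
    }
  }
  if (length(junctions) == 0) return(NULL)  # networks need >= 1 junction
  # endpoints: edge extremities that are not junction pixels
  jmat <- do.call(rbind, junctions)
  extremes <- do.call(rbind, lapply(edges, function(e)
    rbind(e$pixels[1, ], e$pixels[nrow(e$pixels), ])))
  extremes <- unique(extremes)
  is_j <- apply(extremes, 1, function(p)
    any(jmat[, 1] == p[1] & jmat[, 2] == p[2]))
  list(edges = edges, n_junctions = length(junctions),
       n_endpoints = sum(!is_j))
}

grow_individual <- function(spec, committed, clearance, margin, sphere) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  ppm <- spec$pixels_per_micron
  for (attempt in 1:80) {
    start <- c(sample(seq(margin + 1, H - margin), 1),
               sample(seq(margin + 1, W - margin), 1))
    if (min_dist2(start, committed) < clearance^2) next
    if (sphere)
      return(list(pixels = matrix(start, ncol = 2), end = start, dir = 1L,
                  length_px = 0))
    seg <- walk_chain(start, sample(8L, 1),
                      draw_len_px(spec$individual_length_range, ppm),
                      0.08, committed, clearance, H, W, margin)
    if (!is.null(seg)) return(seg)
  }
  NULL
}

place_loop <- function(spec, committed, clearance, margin) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  ppm <- spec$pixels_per_micron
  for (attempt in 1:80) {
    rad <- stats::runif(1, 0.4, 0.8) * ppm
    ctr <- c(sample(seq(margin + ceiling(rad) + 1, H - margin - ceiling(rad)), 1),
             sample(seq(margin + ceiling(rad) + 1, W - margin - ceiling(rad)), 1))
    th <- seq(0, 2 * pi, length.out = max(32, ceiling(2 * pi * rad)))
    px <- unique(cbind(round(ctr[1] + rad * sin(th)),
                       round(ctr[2] + rad * cos(th))))
    ok <- all(apply(px, 1, function(p)
      min_dist2(p, committed) >= clearance^2))
    if (!ok) next
    return(list(pixels = px, end = px[1, ], dir = 1L,
                length_px = 2 * pi * rad))
  }
  NULL
}

#' Empirical signal-to-noise ratio of a rendered scene
#'
#' (mean object intensity - mean background intensity) / sd of the
#' background, measured against the ground-truth mask.
#'
#' @param scene a `mito_scene`.
#' @return A single number.
#' @export
scene_snr <- function(scene) {
  stopifnot(inherits(scene, "mito_scene"))
  img <- unclass(scene$image)
  fg <- unclass(scene$truth_mask)
  (mean(img[fg]) - mean(img[!fg])) / stats::sd(img[!fg])
}

#' Write a scene to disk
#'
#' Writes the micrograph (and optionally the ground-truth mask) as
#' single-plane grayscale TIFFs, the per-object ground truth as JSON, and a
#' CSV summary table.
#'
#' @param scene a `mito_scene`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @param write_mask also write the truth mask TIFF.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scene <- function(scene, dir, prefix = "scene", write_mask = TRUE) {
  stopifnot(inherits(scene, "mito_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(image = file.path(dir, paste0(prefix, ".tif")),
             truth_json = file.path(dir, paste0(prefix, "_truth.json")),
             truth_csv = file.path(dir, paste0(prefix, "_truth.csv")))
  write_micrograph(scene$image, paths[["image"]])
  if (write_mask) {
    paths <- c(paths, mask = file.path(dir, paste0(prefix, "_mask.tif")))
    tiff::writeTIFF(unclass(scene$truth_mask) * 1.0, paths[["mask"]],
                    bits.per.sample = 8)
  }
  gt <- lapply(scene$ground_truth, function(ob) {
    ob$centerline_pixels <- apply(ob$centerline_pixels, 1,
                                  function(p) list(row = p[1], col = p[2]))
    ob
  })
  jsonlite::write_json(gt, paths[["truth_json"]], auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(summary(scene), paths[["truth_csv"]], row.names = FALSE)
  invisible(paths)
}
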