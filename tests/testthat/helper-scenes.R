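# Shared fixtures: small scenes and truth-matching utilities.

noise_off <- list(poisson_scale = 0, gaussian_sd = 0)

small_scene_spec <- function(seed, ...) {
  args <- utils::modifyList(
    list(image_size = c(256L, 256L), n_networks = 1, n_individuals = 3,
         seed = seed),
    list(...))
  do.call(scene_spec, args)
}

# run the morphology chain on a scene and join recovered objects to truth
# (each ground-truth object located via its first centerline pixel)
recover_scene <- function(scene, from = c("otsu", "truth"), prune_px = 6) {
  from <- match.arg(from)
  mask <- if (from == "otsu") binarize_otsu(scene$image) else scene$truth_mask
  comps <- label_components(mask)
  skel <- prune_skeleton(skeletonize(mask), min_px = prune_px)
  graphs <- analyze_skeleton(skel, mask = mask)
  objects <- classify_objects(graphs, comps)
  matched <- lapply(scene$ground_truth, function(ob) {
    px <- ob$centerline_pixels[1, ]
    cid <- comps$labels[px[1], px[2]]
    row <- objects[objects$component_id == cid, ]
    list(truth = ob, recovered = if (cid > 0 && nrow(row) == 1) row else NULL)
  })
  list(mask = mask, components = comps, skeleton = skel, graphs = graphs,
       objects = objects, matched = matched)
}

# per-cell morphometrics computed straight from ground truth (independent
# of the image-analysis path)
truth_morphometrics <- function(scene) {
  gt <- scene$ground_truth
  cls <- vapply(gt, `[[`, character(1), "class")
  nets <- gt[cls == "network"]; inds <- gt[cls == "individual"]
  net_branches <- unlist(lapply(nets, `[[`, "true_branch_lengths_um"))
  list(
    n_networks = length(nets),
    n_individuals = length(inds),
    ratio = if (length(nets)) length(inds) / length(nets) else NA_real_,
    median_network_branch_len_um =
      if (length(nets)) median(net_branches) else NA_real_,
    median_individual_len_um =
      if (length(inds))
        median(vapply(inds, function(o) o$true_branch_lengths_um[1],
                      numeric(1)))
      else NA_real_,
    mean_junctions_per_network =
      if (length(nets))
        mean(vapply(nets, `[[`, numeric(1), "true_junction_count"))
      else NA_real_,
    footprint_um2 = sum(vapply(gt, `[[`, numeric(1), "true_area_px")) /
      scene$spec$pixels_per_micron^2
  )
}

# draw a binary matrix mask from seeded uniform noise
random_mask <- function(seed, h = 32, w = 32, p = 0.3) {
  set.seed(seed)
  matrix(runif(h * w) < p, h, w)
}

make_mask <- function(m, ppm = 23.4) binary_mask(m, pixels_per_micron = ppm)
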