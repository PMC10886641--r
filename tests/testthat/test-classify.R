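# build a mito_objects table directly (bypassing image analysis) for the
# aggregation tests
fake_objects <- function(classes, junctions = NULL, branch_lists = NULL,
                         aspects = NULL, areas = NULL) {
  n <- length(classes)
  if (n == 0) {
    out <- data.frame(component_id = integer(0), mito_class = character(0),
                      reason = character(0), branch_count = integer(0),
                      junction_count = integer(0), endpoint_count = integer(0),
                      area_um2 = numeric(0), aspect_ratio = numeric(0),
                      median_branch_len_um = numeric(0),
                      total_branch_len_um = numeric(0), degenerate = logical(0))
    class(out) <- c("mito_objects", "data.frame")
    return(out)
  }
  if (is.null(junctions)) junctions <- ifelse(classes == "network", 1L, 0L)
  if (is.null(branch_lists))
    branch_lists <- lapply(classes, function(cl)
      if (cl == "network") c(1.5, 1.2) else 0.5)
  if (is.null(aspects)) aspects <- rep(2, n)
  if (is.null(areas)) areas <- rep(1, n)
  out <- data.frame(component_id = seq_len(n), mito_class = classes,
                    reason = NA_character_,
                    branch_count = lengths(branch_lists),
                    junction_count = junctions,
                    endpoint_count = ifelse(classes == "loop", 0L, 2L),
                    area_um2 = areas, aspect_ratio = aspects,
                    median_branch_len_um =
                      vapply(branch_lists, median, numeric(1)),
                    total_branch_len_um =
                      vapply(branch_lists, sum, numeric(1)),
                    degenerate = FALSE, stringsAsFactors = FALSE)
  out$branch_lengths_um <- branch_lists
  class(out) <- c("mito_objects", "data.frame")
  out
}

test_that("the two-class filter follows the branch/junction rules", {
  # individual: one branch, zero junctions (a bar)
  m <- matrix(FALSE, 12, 20); m[6, 4:16] <- TRUE
  mask <- make_mask(m)
  obj <- classify_objects(analyze_skeleton(skeletonize(mask)),
                          label_components(mask))
  expect_identical(obj$mito_class, "individual")
  # network: three branches, one junction (a T)
  m2 <- matrix(FALSE, 22, 30)
  m2[8, 3:26] <- TRUE; m2[9:18, 14] <- TRUE
  mask2 <- make_mask(m2)
  obj2 <- classify_objects(analyze_skeleton(skeletonize(mask2)),
                           label_components(mask2))
  expect_identical(obj2$mito_class, "network")
  expect_identical(obj2$branch_count, 3L)
  expect_identical(obj2$junction_count, 1L)
})

test_that("closed rings are unclassified loops, not individuals", {
  m <- matrix(FALSE, 24, 24)
  th <- seq(0, 2 * pi, length.out = 300)
  m[unique(cbind(round(12 + 7 * sin(th)), round(12 + 7 * cos(th))))] <- TRUE
  mask <- make_mask(m)
  obj <- classify_objects(analyze_skeleton(skeletonize(mask)),
                          label_components(mask))
  expect_identical(obj$mito_class, "unclassified")
  expect_identical(obj$reason, "loop")
})

test_that("generated loops survive the pipeline as unclassified objects", {
  sc <- generate_scene(small_scene_spec(55, n_networks = 0, n_individuals = 0,
                                        include_loops = TRUE, n_loops = 2,
                                        noise_model = noise_off))
  rec <- recover_scene(sc)
  for (mt in rec$matched) {
    expect_identical(mt$truth$class, "loop")
    expect_identical(mt$recovered$mito_class, "unclassified")
  }
})

test_that("classification partitions every component, exhaustively", {
  for (seed in 61:65) {
    sc <- generate_scene(small_scene_spec(seed, n_networks = 1,
                                          n_individuals = 4,
                                          include_loops = seed %% 2 == 0))
    rec <- recover_scene(sc)
    tab <- table(factor(rec$objects$mito_class,
                        c("network", "individual", "unclassified")))
    expect_identical(sum(tab), nrow(rec$components$stats))
    expect_identical(nrow(rec$objects), nrow(rec$components$stats))
  }
})

test_that("cell aggregation computes the five parameters and the ratio", {
  obj <- fake_objects(c(rep("individual", 6), rep("network", 2)),
                      junctions = c(rep(0L, 6), 20L, 16L))
  cell <- cell_morphometrics(obj, footprint_um2 = 100, cell_id = "c1")
  expect_equal(cell$individual_to_network_ratio, 3.0)
  expect_equal(cell$mean_junctions_per_network, 18.0)
  expect_equal(cell$n_networks, 2L)
  expect_equal(cell$n_individuals, 6L)
  expect_equal(cell$footprint_um2, 100)
  expect_equal(cell$median_network_branch_len_um, median(c(1.5, 1.2)))
  expect_equal(cell$median_individual_len_um, 0.5)
})

test_that("empty object sets propagate as NA, never silent zeros", {
  obj <- fake_objects(rep("individual", 3))
  cell <- cell_morphometrics(obj, footprint_um2 = 1)
  expect_true(is.na(cell$individual_to_network_ratio))
  expect_true(is.na(cell$median_network_branch_len_um))
  expect_true(is.na(cell$mean_junctions_per_network))
  none <- cell_morphometrics(fake_objects(character(0)), footprint_um2 = 0)
  expect_true(is.na(none$median_individual_len_um))
  expect_identical(none$n_individuals, 0L)
})

test_that("per-cell fields match values computed from ground truth", {
  for (seed in 71:75) {
    sc <- generate_scene(small_scene_spec(seed, image_size = c(320L, 320L),
                                          n_networks = 2, n_individuals = 5,
                                          noise_model = noise_off))
    rec <- recover_scene(sc)
    cell <- cell_morphometrics(rec$objects,
                               mitochondrial_footprint(rec$components))
    tru <- truth_morphometrics(sc)
    expect_identical(cell$n_networks, tru$n_networks)
    expect_identical(cell$n_individuals, tru$n_individuals)
    expect_equal(cell$individual_to_network_ratio, tru$ratio)
    expect_equal(cell$mean_junctions_per_network,
                 tru$mean_junctions_per_network)
    expect_lt(abs(cell$footprint_um2 - tru$footprint_um2) /
                tru$footprint_um2, 0.15)
    px_tol <- 2 / 23.4
    expect_lt(abs(cell$median_network_branch_len_um -
                    tru$median_network_branch_len_um), px_tol)
    expect_lt(abs(cell$median_individual_len_um -
                    tru$median_individual_len_um), px_tol)
  }
})

test_that("individuals are shorter than network branches on such scenes", {
  for (seed in 81:83) {
    sc <- generate_scene(small_scene_spec(seed, image_size = c(320L, 320L),
                                          n_networks = 2, n_individuals = 5))
    rec <- recover_scene(sc)
    cell <- cell_morphometrics(rec$objects,
                               mitochondrial_footprint(rec$components))
    expect_lt(cell$median_individual_len_um,
              cell$median_network_branch_len_um)
  }
})

test_that("aspect ratios separate generated spheres from rods", {
  sph <- generate_scene(small_scene_spec(91, n_networks = 0,
                                         n_individuals = 6,
                                         sphere_fraction = 1))
  rod <- generate_scene(small_scene_spec(92, n_networks = 0,
                                         n_individuals = 6,
                                         individual_length_range = c(0.8, 1),
                                         sphere_fraction = 0))
  ar_sph <- recover_scene(sph)$objects$aspect_ratio
  ar_rod <- recover_scene(rod)$objects$aspect_ratio
  expect_lt(median(ar_sph), 1.3)
  expect_gt(median(ar_rod), 1.5)
  expect_lt(max(ar_sph), min(ar_rod))
})

test_that("analyze_cell ties the chain together on a default scene", {
  sc <- generate_scene(small_scene_spec(99, n_networks = 1,
                                        n_individuals = 3))
  res <- analyze_cell(sc$image, cell_id = "demo")
  expect_s3_class(res$cell, "mito_cell")
  expect_identical(res$cell$cell_id, "demo")
  expect_identical(res$cell$n_networks + res$cell$n_individuals +
                     res$cell$n_unclassified, nrow(res$objects))
  expect_output(print(res$cell), "footprint")
})
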