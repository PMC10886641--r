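test_that("identical specs give bit-identical scenes and traces", {
  sp <- small_scene_spec(11)
  s1 <- generate_scene(sp); s2 <- generate_scene(sp)
  expect_identical(unclass(s1$image), unclass(s2$image))
  expect_identical(unclass(s1$truth_mask), unclass(s2$truth_mask))
  expect_identical(summary(s1), summary(s2))
  tspec <- trace_spec(n_frames = 40, slope = 2, noise_sd = 5, seed = 3)
  expect_identical(generate_trace(tspec)$intensities,
                   generate_trace(tspec)$intensities)
})

test_that("a single noiseless segment yields one individual of the drawn length", {
  sp <- small_scene_spec(5, n_networks = 0, n_individuals = 1,
                         individual_length_range = c(2, 2),
                         noise_model = noise_off)
  sc <- generate_scene(sp)
  expect_length(sc$ground_truth, 1)
  ob <- sc$ground_truth[[1]]
  expect_identical(ob$class, "individual")
  expect_length(ob$true_branch_lengths_um, 1)
  expect_identical(ob$true_junction_count, 0L)
  # discrete steps overshoot the 2 um target by at most one diagonal step
  expect_gte(ob$true_branch_lengths_um, 2)
  expect_lte(ob$true_branch_lengths_um, 2 + sqrt(2) / 23.4)
})

test_that("Y-shaped networks have 3 branches, 1 junction, 3 endpoints", {
  for (seed in 1:4) {
    sp <- small_scene_spec(seed, n_networks = 1, n_individuals = 0,
                           network_shape = "Y", noise_model = noise_off)
    ob <- generate_scene(sp)$ground_truth[[1]]
    expect_identical(ob$class, "network")
    expect_length(ob$true_branch_lengths_um, 3)
    expect_identical(ob$true_junction_count, 1L)
    expect_identical(ob$true_endpoint_count, 3L)
  }
})

test_that("recorded object areas equal a brute-force dilation oracle", {
  sp <- small_scene_spec(9, n_networks = 1, n_individuals = 2,
                         tube_radius = 2, noise_model = noise_off)
  sc <- generate_scene(sp)
  for (ob in sc$ground_truth) {
    stamp <- oracle_dilate_centerline(ob$centerline_pixels, 2, 256, 256)
    expect_identical(ob$true_area_px, sum(stamp))
  }
})

test_that("every generated object satisfies its class definition", {
  for (seed in 21:25) {
    sp <- small_scene_spec(seed, n_networks = 2, n_individuals = 4,
                           include_loops = TRUE, n_loops = 1)
    for (ob in generate_scene(sp)$ground_truth) {
      nb <- length(ob$true_branch_lengths_um)
      if (ob$class == "network") {
        expect_gt(nb, 1)
        expect_gte(ob$true_junction_count, 1)
      } else if (ob$class == "individual") {
        expect_identical(nb, 1L)
        expect_identical(ob$true_junction_count, 0L)
      } else {
        expect_identical(ob$class, "loop")
        expect_identical(ob$true_endpoint_count, 0L)
      }
      expect_gt(ob$true_area_px, 0)
    }
  }
})

test_that("increasing gaussian noise strictly decreases scene SNR", {
  snr <- vapply(c(10, 30, 60), function(sd) {
    sp <- small_scene_spec(13, noise_model = list(poisson_scale = 0,
                                                  gaussian_sd = sd))
    scene_snr(generate_scene(sp))
  }, numeric(1))
  expect_true(all(diff(snr) < 0))
})

test_that("scene placement failure raises an error naming the crowding", {
  sp <- small_scene_spec(1, image_size = c(64, 64), n_networks = 0,
                         n_individuals = 60)
  expect_error(generate_scene(sp), "placement failed")
})

test_that("noiseless traces follow the configured line and step exactly", {
  tr <- generate_trace(trace_spec(n_frames = 10, baseline = 100, slope = 2))
  expect_equal(tr$intensities, seq(100, 118, by = 2))
  expect_equal(tr$times, seq(0, 45, by = 5))
  tr2 <- generate_trace(trace_spec(n_frames = 60, baseline = 1000, slope = 0,
                                   fccp_frame = 50, fccp_drop = 800))
  expect_equal(max(tr2$intensities) - tr2$intensities[60], 800)
})

test_that("OLS recovers the trace slope across seeds (Monte-Carlo)", {
  slopes <- vapply(1:500, function(s) {
    tr <- generate_trace(trace_spec(n_frames = 100, baseline = 50, slope = 3,
                                    noise_sd = 5, seed = 1000 + s))
    # per-frame slope: fit returns per-minute (dt = 5 s -> 12 frames/min)
    fit_rate(tr)$slope / 12
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 3), 3 * se)
})

test_that("trace CSV round-trips through write_traces/read_traces", {
  traces <- list(
    generate_trace(trace_spec(n_frames = 20, slope = 1, noise_sd = 2,
                              seed = 1), "t1", "DCF", "Control"),
    generate_trace(trace_spec(n_frames = 20, slope = 2, noise_sd = 2,
                              seed = 2), "t2", "MitoSOX", "PINK1"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces(traces, path)
  back <- read_traces(path)
  expect_setequal(names(back), c("t1", "t2"))
  expect_equal(back$t1$intensities, traces[[1]]$intensities)
  expect_identical(back$t2$group, "PINK1")
})

test_that("scene files are written as TIFF + JSON + CSV and read back", {
  sc <- generate_scene(small_scene_spec(3))
  dir <- withr::local_tempdir()
  paths <- write_scene(sc, dir, prefix = "demo")
  expect_true(all(file.exists(paths)))
  img <- read_micrograph(paths[["image"]])
  expect_identical(dim(img), dim(sc$image))
  gt <- jsonlite::read_json(paths[["truth_json"]])
  expect_length(gt, length(sc$ground_truth))
})
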