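test_that("grow_network obeys its growth rule in degenerate settings", {
  # no seeds, no nuisance objects: empty annotation set
  p0 <- scene_params(n_seeds = 0, n_debris = 0, n_out_of_plane = 0)
  expect_length(grow_network(p0)$polylines, 0)

  # straight growth: tortuosity 0, no branching, 20 steps of 5 px
  p1 <- scene_params(field_px = c(512, 512), n_seeds = 1, n_steps = 20,
                     branch_prob = 0, step_px = 5, tortuosity_sd = 0,
                     n_debris = 0, n_out_of_plane = 0, seed = 2)
  net <- grow_network(p1)
  expect_length(net$polylines, 1)
  expect_equal(polyline_length(net$polylines[[1]]), 100, tolerance = 1e-9)

  # determinism
  expect_identical(grow_network(p1), grow_network(p1))
})

test_that("branch counts follow the per-step branching probability", {
  # one seed on a huge field (growth never clips); the number of direct
  # (first-order) branches of the seeded fragment is Binomial(n_steps,
  # branch_prob); compare the mean over RNG seeds within 3 sd of the mean
  base <- scene_params(field_px = c(2000, 2000), n_seeds = 1, n_steps = 100,
                       branch_prob = 0.1, step_px = 2, tortuosity_sd = 0.05,
                       n_debris = 0, n_out_of_plane = 0)
  n_rng <- 200
  branches <- vapply(seq_len(n_rng), function(s) {
    p <- base; p$seed <- s
    net <- grow_network(p)
    depths <- vapply(net$polylines, function(q) attr(q, "depth"), integer(1))
    sum(depths == 1L)
  }, integer(1))
  expected <- 100 * 0.1
  se <- sqrt(100 * 0.1 * 0.9 / n_rng)
  expect_lt(abs(mean(branches) - expected), 3 * se)
})

test_that("rendering is deterministic and places ridges on the truth", {
  # empty truth without noise: constant background
  p <- scene_params(field_px = c(64, 64), n_seeds = 0, n_debris = 0,
                    n_out_of_plane = 0, noise_sd = 0, seed = 5)
  img <- render_scene(annotation_set("e", list(), 1.3), p)
  expect_equal(length(unique(as.vector(img$pixels))), 1)

  # single straight vessel: the brightest pixels hug the polyline
  p2 <- scene_params(field_px = c(128, 64), n_seeds = 0, n_debris = 0,
                     n_out_of_plane = 0, noise_sd = 0, seed = 5)
  pl <- polyline(rbind(c(20, 32), c(108, 32)))
  truth <- annotation_set("v", list(pl), 1.3)
  img2 <- render_scene(truth, p2)
  bright <- which(img2$pixels >= max(img2$pixels) - 1e-9, arr.ind = TRUE)
  expect_true(all(abs(bright[, 1] - 33) <= p2$vessel_width_px))
  expect_true(all(bright[, 2] - 1 >= 20 - p2$vessel_width_px &
                    bright[, 2] - 1 <= 108 + p2$vessel_width_px))

  # bit-identical rerun
  p3 <- small_scene_params(seed = 12)
  t3 <- grow_network(p3, "d")
  expect_identical(render_scene(t3, p3)$pixels, render_scene(t3, p3)$pixels)

  # phase mode inverts contrast: vessels darker than background
  p4 <- scene_params(field_px = c(128, 64), n_seeds = 0, n_debris = 0,
                     n_out_of_plane = 0, noise_sd = 0, modality = "phase",
                     seed = 5)
  img4 <- render_scene(truth, p4)
  on_vessel <- img4$pixels[33, 40:90]
  background <- img4$pixels[10, 40:90]
  expect_true(mean(on_vessel) < mean(background))
})

test_that("ground-truth length is independent of rendering", {
  p <- small_scene_params(seed = 9)
  truth <- grow_network(p, "s")
  L1 <- total_vessel_length(truth$polylines, 1)
  invisible(render_scene(truth, p))
  expect_identical(total_vessel_length(truth$polylines, 1), L1)
  expect_gt(L1, 0)
})

test_that("generate_benchmark produces the full grid with recorded truth", {
  grid <- expand.grid(n_seeds = c(2, 4, 6), modality = c("fluorescent", "phase"),
                      stringsAsFactors = FALSE)
  scenes <- generate_benchmark(grid, n_scenes = 2, seed = 5,
                               base_params = small_scene_params())
  expect_length(scenes, 12)
  man <- attr(scenes, "manifest")
  expect_equal(nrow(man), 12)
  expect_true(all(man$truth_length_um > 0))
  expect_equal(man$modality, rep(grid$modality, each = 2))

  one <- generate_benchmark(data.frame(n_seeds = 3), 1, seed = 2,
                            base_params = small_scene_params())
  expect_length(one, 1)
  expect_gt(attr(one, "manifest")$truth_length_um, 0)
})

test_that("mean truth length grows with the seeded vessel count", {
  mean_len <- function(n_seeds) {
    mean(vapply(1:20, function(s) {
      p <- scene_params(n_seeds = n_seeds, n_debris = 0, n_out_of_plane = 0,
                        seed = s)
      total_vessel_length(grow_network(p)$polylines, 1)
    }, numeric(1)))
  }
  lens <- vapply(c(2, 5, 9), mean_len, numeric(1))
  expect_true(all(diff(lens) > 0))
})
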