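#' Parameters of a synthetic microvessel scene
#'
#' Describes a branching bright-on-dark (fluorescent) or dark-on-gray
#' (phase contrast) vessel network together with the nuisance structure
#' real assay images carry: per-vessel brightness variation, debris blobs
#' of vessel-like size, blurred out-of-plane objects, and read noise.
#' Vessels are grown as branching correlated random walks — scaffolding
#' chosen to produce the qualitative features that matter for measurement
#' (variable density, tortuosity, branching, non-uniform intensity), not a
#' biophysical sprouting model.
#'
#' @param field_px `(width, height)` of the field in pixels.
#' @param scale_um_per_px micrometres per pixel (default 1.3, a typical
#'   10x objective sampling).
#' @param n_seeds number of initial vessel fragments.
#' @param n_steps growth steps per fragment.
#' @param branch_prob probability of spawning a branch at each step.
#' @param step_px step length of the growth walk in pixels.
#' @param tortuosity_sd heading perturbation per step, radians.
#' @param vessel_width_px full width of the rendered vessel ridge.
#' @param intensity_cv coefficient of variation of per-vessel brightness
#'   (lognormal), emulating non-uniform lectin labeling.
#' @param n_debris number of debris blobs.
#' @param debris_size_px `(min, max)` debris radius in pixels.
#' @param n_out_of_plane number of out-of-plane (blurred) vessel objects.
#' @param blur_sigma_px Gaussian blur applied to out-of-plane objects.
#' @param noise_sd Gaussian read-noise standard deviation (intensity
#'   units, image range is `[0, 1]`).
#' @param modality `"fluorescent"` or `"phase"`.
#' @param seed RNG seed for the scene.
#' @return A `scene_params` list.
#' @export
scene_params <- function(field_px = c(384, 384), scale_um_per_px = 1.3,
                         n_seeds = 6, n_steps = 60, branch_prob = 0.02,
                         step_px = 4, tortuosity_sd = 0.15,
                         vessel_width_px = 3, intensity_cv = 0.3,
                         n_debris = 5, debris_size_px = c(3, 10),
                         n_out_of_plane = 2, blur_sigma_px = 4,
                         noise_sd = 0.02,
                         modality = c("fluorescent", "phase"), seed = 1) {
  modality <- match.arg(modality)
  assert_scalar_number(n_seeds, "n_seeds", lower = 0)
  assert_scalar_number(branch_prob, "branch_prob", lower = 0, upper = 1)
  assert_scalar_number(step_px, "step_px", lower = 0, strict_lower = TRUE)
  assert_scalar_number(tortuosity_sd, "tortuosity_sd", lower = 0)
  assert_scalar_number(vessel_width_px, "vessel_width_px", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(intensity_cv, "intensity_cv", lower = 0)
  assert_scalar_number(n_debris, "n_debris", lower = 0)
  assert_scalar_number(n_out_of_plane, "n_out_of_plane", lower = 0)
  assert_scalar_number(blur_sigma_px, "blur_sigma_px", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(field_px = field_px, scale_um_per_px = scale_um_per_px,
         n_seeds = n_seeds, n_steps = n_steps, branch_prob = branch_prob,
         step_px = step_px, tortuosity_sd = tortuosity_sd,
         vessel_width_px = vessel_width_px, intensity_cv = intensity_cv,
         n_debris = n_debris, debris_size_px = debris_size_px,
         n_out_of_plane = n_out_of_plane, blur_sigma_px = blur_sigma_px,
         noise_sd = noise_sd, modality = modality, seed = seed),
    class = "scene_params"
  )
}

# Grow one correlated random walk from (x0, y0) with heading theta0;
# returns the point matrix and any spawned branch start states.
grow_walk <- function(x0, y0, theta0, params) {
  w <- params$field_px[1]; h <- params$field_px[2]
  pts <- matrix(c(x0, y0), 1, 2)
  theta <- theta0
  branches <- list()
  x <- x0; y <- y0
  for (s in seq_len(params$n_steps)) {
    theta <- theta + stats::rnorm(1, 0, params$tortuosity_sd)
    nx <- x + params$step_px * cos(theta)
    ny <- y + params$step_px * sin(theta)
    # clip growth to the field: stop at the border
    if (nx < 1 || nx > w - 2 || ny < 1 || ny > h - 2) break
    x <- nx; y <- ny
    pts <- rbind(pts, c(x, y))
    if (stats::runif(1) < params$branch_prob) {
      side <- sample(c(-1, 1), 1)
      branches[[length(branches) + 1L]] <-
        list(x = x, y = y, theta = theta + side * stats::runif(1, pi / 6, pi / 3))
    }
  }
  list(points = pts, branches = branches)
}

#' Grow a synthetic branching vessel network
#'
#' Each of `n_seeds` fragments grows as a correlated random walk (heading
#' perturbed by `Normal(0, tortuosity_sd)` per `step_px` step), branching
#' with probability `branch_prob` per step; branches grow by the same
#' rule. Growth is clipped to the field. Also places `n_out_of_plane`
#' short walks labeled `out_of_plane` and `n_debris` compact blob outlines
#' labeled `debris`. Deterministic given `params$seed`.
#'
#' @param params a [scene_params].
#' @param image_id identifier for the annotation set.
#' @return An [annotation_set] of ground-truth polylines.
#' @export
grow_network <- function(params, image_id = "scene") {
  stopifnot(inherits(params, "scene_params"))
  w <- params$field_px[1]; h <- params$field_px[2]
  polys <- list()
  with_seed(params$seed, {
    grow_from <- function(x, y, theta, label, depth) {
      res <- grow_walk(x, y, theta, params)
      if (nrow(res$points) >= 2) {
        pl <- polyline(res$points, label)
        attr(pl, "depth") <- depth  # 0 = seeded fragment, >0 = branch order
        polys[[length(polys) + 1L]] <<- pl
      }
      if (depth < 2L)  # limit branch recursion: branches may branch once
        for (b in res$branches)
          grow_from(b$x, b$y, b$theta, label, depth + 1L)
    }
    if (params$n_seeds > 0)
      for (i in seq_len(params$n_seeds))
        grow_from(stats::runif(1, 0.15 * w, 0.85 * w),
                  stats::runif(1, 0.15 * h, 0.85 * h),
                  stats::runif(1, 0, 2 * pi), "vessel", 0L)
    if (params$n_out_of_plane > 0)
      for (i in seq_len(params$n_out_of_plane)) {
        short <- params
        short$n_steps <- max(5L, round(params$n_steps / 3))
        res <- grow_walk(stats::runif(1, 0.2 * w, 0.8 * w),
                         stats::runif(1, 0.2 * h, 0.8 * h),
                         stats::runif(1, 0, 2 * pi), short)
        if (nrow(res$points) >= 2)
          polys[[length(polys) + 1L]] <- polyline(res$points, "out_of_plane")
      }
    if (params$n_debris > 0)
      for (i in seq_len(params$n_debris)) {
        r <- stats::runif(1, params$debris_size_px[1], params$debris_size_px[2])
        cx <- stats::runif(1, 0.1 * w, 0.9 * w)
        cy <- stats::runif(1, 0.1 * h, 0.9 * h)
        ang <- stats::runif(1, 0, pi)
        # debris recorded as its major axis, an elongated-blob outline
        polys[[length(polys) + 1L]] <- polyline(
          rbind(c(cx - r * cos(ang), cy - r * sin(ang)),
                c(cx + r * cos(ang), cy + r * sin(ang))), "debris")
      }
  })
  annotation_set(image_id, polys, params$scale_um_per_px, author = "synthetic")
}

# Stamp a Gaussian-profile ridge along a polyline into canvas (max-combine).
stamp_polyline <- function(canvas, p, sigma, amplitude) {
  L <- polyline_length(p)
  pts <- arc_point(p, seq(0, L, by = max(0.5, sigma / 3)))
  rad <- ceiling(3 * sigma)
  nr <- nrow(canvas); nc <- ncol(canvas)
  off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  for (k in seq_len(nrow(pts))) {
    c0 <- round(pts[k, 1]) + 1L; r0 <- round(pts[k, 2]) + 1L
    rr <- r0 + off$dr; cc <- c0 + off$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    d2 <- (rr - 1 - pts[k, 2])^2 + (cc - 1 - pts[k, 1])^2
    v <- amplitude * exp(-d2[ok] / (2 * sigma^2))
    idx <- cbind(rr[ok], cc[ok])
    canvas[idx] <- pmax(canvas[idx], v)
  }
  canvas
}

#' Render a synthetic scene to an image
#'
#' Fluorescent mode draws vessels as bright ridges of Gaussian
#' cross-section on a dark background, with per-vessel brightness drawn
#' from a lognormal with coefficient of variation `intensity_cv`, debris
#' as bright compact blobs, out-of-plane objects blurred with
#' `blur_sigma_px`, plus Gaussian read noise. Phase mode renders
#' dark ridges on a mid-gray background with a faint bright halo and
#' lower contrast. Deterministic given `params$seed`.
#'
#' @param truth an [annotation_set] from [grow_network()].
#' @param params the matching [scene_params].
#' @return An [image2d] with `id = truth$image_id`.
#' @export
render_scene <- function(truth, params) {
  stopifnot(inherits(truth, "annotation_set"), inherits(params, "scene_params"))
  w <- params$field_px[1]; h <- params$field_px[2]
  sigma <- params$vessel_width_px / 2
  with_seed(derive_seed(params$seed, 2), {
    sharp <- matrix(0, h, w)   # in-focus structures
    hazy <- matrix(0, h, w)    # out-of-plane structures, blurred below
    sdlog <- sqrt(log(1 + params$intensity_cv^2))
    for (p in truth$polylines) {
      amp <- min(1, stats::rlnorm(1, log(0.8) - sdlog^2 / 2, sdlog))
      if (p$label == "vessel") {
        sharp <- stamp_polyline(sharp, p, sigma, amp)
      } else if (p$label == "debris") {
        # debris: wider, roughly isotropic blob along its short axis
        sharp <- stamp_polyline(sharp, p, max(sigma, polyline_length(p) / 3),
                                amp)
      } else {
        hazy <- stamp_polyline(hazy, p, sigma, amp)
      }
    }
    if (any(hazy > 0)) {
      ks <- 2 * ceiling(2 * params$blur_sigma_px) + 1
      if (ks < min(dim(hazy))) {
        brush <- EBImage::makeBrush(ks, shape = "Gaussian",
                                    sigma = params$blur_sigma_px)
        hazy <- EBImage::filter2(hazy, brush)
      }
      hazy <- hazy * 0.6
    }
    px <- if (params$modality == "fluorescent") {
      0.05 + pmax(sharp, hazy)
    } else {
      # phase: dark ridge on mid-gray with a faint halo
      halo <- if (min(dim(sharp)) > 9)
        EBImage::filter2(sharp, EBImage::makeBrush(9, "Gaussian", sigma = 2))
      else sharp
      0.55 - 0.35 * pmax(sharp, hazy * 0.7) + 0.08 * halo
    }
    if (params$noise_sd > 0)
      px <- px + matrix(stats::rnorm(w * h, 0, params$noise_sd), h, w)
    px <- pmin(pmax(px, 0), 1)
    image2d(px, params$scale_um_per_px, params$modality, truth$image_id)
  })
}

#' Generate one synthetic scene
#'
#' Convenience wrapper: [grow_network()] then [render_scene()].
#'
#' @param params a [scene_params].
#' @param image_id scene identifier.
#' @return A `synthetic_scene`: list with `image` ([image2d]), `truth`
#'   ([annotation_set]) and `params`.
#' @export
generate_scene <- function(params, image_id = "scene") {
  truth <- grow_network(params, image_id)
  structure(list(image = render_scene(truth, params), truth = truth,
                 params = params),
            class = "synthetic_scene")
}

#' Generate a benchmark collection of scenes
#'
#' Crosses a grid of parameter overrides (by default three vessel-count
#' levels emulating low, medium and high density groups) with `n_scenes`
#' replicates per grid cell. Each scene's RNG stream is derived from the
#' master seed and the scene index, so the collection is reproducible and
#' insensitive to generation order.
#'
#' @param params_grid data frame of parameter overrides, one row per grid
#'   cell; column names must be [scene_params()] argument names.
#' @param n_scenes scenes per grid cell.
#' @param seed master seed.
#' @param base_params defaults for parameters not in the grid.
#' @return List of `synthetic_scene` objects; each carries its ground
#'   truth, so true total length is known by construction. The manifest
#'   data frame is attached as attribute `"manifest"` (columns `scene_id`,
#'   `modality`, `truth_length_um`, `seed`).
#' @export
generate_benchmark <- function(params_grid = data.frame(n_seeds = c(3, 6, 10)),
                               n_scenes = 2, seed = 1,
                               base_params = scene_params()) {
  params_grid <- as.data.frame(params_grid)
  if (nrow(params_grid) == 0L)
    stop_validation("params_grid must have at least one row")
  assert_scalar_number(n_scenes, "n_scenes", lower = 1)
  scenes <- list()
  rows <- list()
  idx <- 0L
  for (g in seq_len(nrow(params_grid))) {
    for (r in seq_len(n_scenes)) {
      idx <- idx + 1L
      p <- base_params
      for (nm in names(params_grid)) p[[nm]] <- params_grid[[nm]][g]
      p$seed <- derive_seed(seed, idx)
      sid <- sprintf("scene_%03d", idx)
      sc <- generate_scene(scene_params_from_list(p), sid)
      scenes[[idx]] <- sc
      rows[[idx]] <- data.frame(
        scene_id = sid, modality = p$modality,
        truth_length_um = total_vessel_length(sc$truth$polylines,
                                              p$scale_um_per_px),
        seed = p$seed, stringsAsFactors = FALSE)
    }
  }
  attr(scenes, "manifest") <- do.call(rbind, rows)
  scenes
}

scene_params_from_list <- function(p) {
  do.call(scene_params, p[setdiff(names(p), NULL)])
}
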