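test_that("identical seeds give bit-identical stacks", {
  cfg <- simulation_config(diameter = 60, n_nuclei = 12, seed = 42,
                           margin = 6)
  a <- generate_spheroid(cfg)
  b <- generate_spheroid(cfg)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$label_volume, b$truth$label_volume)
  expect_identical(a$truth$positive_flags, b$truth$positive_flags)
})

test_that("no-attenuation, noise-free, blur-free nuclei equal amplitude + offset", {
  cfg <- simulation_config(diameter = 60, n_nuclei = 10, seed = 7,
                           attenuation_length = Inf, background_sd = 0,
                           psf_sigma = c(0, 0, 0), margin = 6)
  sim <- generate_spheroid(cfg)
  nuc <- get_channel(sim$stack, "nuclei")
  inside <- sim$truth$label_volume > 0
  expect_true(all(nuc[inside] == cfg$amplitude[[1]] + cfg$background_offset))
  expect_true(all(nuc[!inside] == cfg$background_offset))
})

test_that("shrink_factor scales the ground-truth extent isotropically", {
  for (s in c(0.5, 1.0)) {
    cfg <- simulation_config(diameter = 80, n_nuclei = 0, seed = 1,
                             shrink_factor = s, background_sd = 0,
                             psf_sigma = c(0, 0, 0), margin = 10)
    sim <- generate_spheroid(cfg)
    trk <- get_channel(sim$stack, "tracker")
    fg <- which(trk > cfg$background_offset, arr.ind = TRUE)
    ext_y <- diff(range(fg[, 2])) * cfg$pixel_size
    ext_x <- diff(range(fg[, 3])) * cfg$pixel_size
    ext_z <- diff(range(fg[, 1])) * cfg$z_step
    expect_lt(abs(ext_y - 80 * s), 2 * cfg$pixel_size)
    expect_lt(abs(ext_x - 80 * s), 2 * cfg$pixel_size)
    expect_lt(abs(ext_z - 80 * s), 2 * cfg$z_step)
  }
})

test_that("truth labels and marker flags obey the configured counts", {
  sim <- small_sim(seed = 3)
  cfg <- sim$truth$config
  labs <- sort(unique(as.integer(sim$truth$label_volume)))
  expect_equal(setdiff(labs, 0L), seq_len(cfg$n_nuclei))
  ctr <- rep(cfg$margin + cfg$diameter / 2 * cfg$shrink_factor, 3)
  d_pre <- sqrt(rowSums(sweep(sim$truth$centers, 2, ctr)^2)) /
    cfg$shrink_factor
  n_rim <- sum(d_pre >= cfg$diameter / 2 - cfg$rim_thickness -
                 cfg$nucleus_radius - 1e-6)
  expect_equal(sum(sim$truth$positive_flags),
               round(cfg$rim_fraction * n_rim))
})

test_that("in-nucleus intensity follows the exponential attenuation law", {
  # noise-free phantom: profile(d) / profile(0) = exp(-d / L) within 3%
  L <- 120
  ph <- generate_uniform_phantom(attenuation_length = L, n_slices = 100,
                                 side_px = 16, background_offset = 0,
                                 background_sd = 0)
  v <- get_channel(ph, 1)
  prof <- apply(v, 1, mean)
  d <- slice_depths(ph)
  expect_true(all(abs(prof / prof[1] - exp(-d / L)) /
                    exp(-d / L) < 0.03))
})

test_that("compound z-compensation cancels attenuation (slice-mean drift < 5%)", {
  L <- 80
  ph <- generate_uniform_phantom(attenuation_length = L, n_slices = 120,
                                 side_px = 16, background_offset = 0,
                                 background_sd = 0.5, seed = 5,
                                 zcomp_slope = zcomp_slope_for(L))
  prof <- apply(get_channel(ph, 1), 1, mean)
  expect_lt(max(abs(prof / prof[1] - 1)), 0.05)
})

test_that("protocol panels share geometry and respond to optics", {
  base <- simulation_config(diameter = 60, n_nuclei = 15, seed = 9,
                            margin = 6, background_sd = 0)
  panel <- generate_protocol_panel(base, list(
    list(name = "A", attenuation_length = 60),
    list(name = "B", attenuation_length = 60),
    list(name = "C", attenuation_length = 300)))
  expect_equal(names(panel), c("A", "B", "C"))
  # identical parameters -> identical stacks
  expect_identical(panel$A$stack$voxels, panel$B$stack$voxels)
  # same geometry across arms
  expect_identical(panel$A$truth$centers, panel$C$truth$centers)
  # Beer-Lambert monotonicity: short L is dimmer at matched depth
  k <- round(40 / base$z_step)  # ~40 um deep
  expect_lt(mean(panel$A$stack$voxels[1, k, , ]),
            mean(panel$C$stack$voxels[1, k, , ]))
  expect_error(generate_protocol_panel(base, list(list(name = "A"),
                                                  list(name = "A"))),
               "duplicate")
})

test_that("unplaceable configurations fail with a clear error", {
  cfg <- simulation_config(diameter = 20, n_nuclei = 500, seed = 1)
  expect_error(generate_spheroid(cfg), "could not place")
})
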