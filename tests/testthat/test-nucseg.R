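test_that("median filtering removes isolated impulses", {
  vox <- array(50, c(1, 1, 32, 32))
  vox[1, 1, 10, 10] <- 255
  vox[1, 1, 20, 25] <- 0
  s <- make_stack(vox, bit_depth = 8L)
  pp <- preprocess(s, 1, small_params())
  expect_equal(length(unique(as.numeric(pp$filtered))), 1L)
})

test_that("interior holes up to the configured radius are filled", {
  vox <- array(0, c(1, 1, 40, 40))
  vox[1, 1, 10:30, 10:30] <- 200
  vox[1, 1, 20, 20] <- 0  # radius-1 hole
  s <- make_stack(vox, bit_depth = 8L)
  pp <- preprocess(s, 1, small_params())
  expect_true(pp$mask[1, 20, 20])
})

test_that("local thresholding keeps objects under an illumination ramp", {
  # two small disks under a 3x illumination ramp: the bright-side
  # background outshines the dim-side disk, so no global threshold can
  # separate both, while the local threshold keeps them
  side <- 101
  ramp <- matrix(rep(seq(1, 3, length.out = side), each = side), side, side,
                 byrow = TRUE)
  base <- matrix(50, side, side)
  mkdisk <- function(cx) {
    d <- matrix(0, side, side)
    for (y in seq_len(side)) for (x in seq_len(side))
      if ((y - 51)^2 + (x - cx)^2 <= 8^2) d[y, x] <- 1
    d
  }
  dim_disk <- mkdisk(20)
  bright_disk <- mkdisk(80)
  img <- (base + 40 * (dim_disk + bright_disk)) * ramp
  s <- make_stack(array(img, c(1, 1, side, side)))
  pp <- preprocess(s, 1, small_params())
  truth <- (dim_disk + bright_disk) > 0
  local_recall <- sum(pp$mask[1, , ] & truth) / sum(truth)
  x01 <- (img - min(img)) / diff(range(img))
  glob <- x01 > EBImage::otsu(x01, range = c(0, 1))
  # global threshold either loses the dim disk or floods bright background;
  # either way its IoU with the truth collapses, the local mask's does not
  global_iou <- sum(glob & truth) / sum(glob | truth)
  local_iou <- sum(pp$mask[1, , ] & truth) / sum(pp$mask[1, , ] | truth)
  expect_gte(local_recall, 0.9)
  expect_gt(local_iou, global_iou)
  expect_lt(global_iou, 0.5)
  expect_gte(local_iou, 0.8)
})

test_that("LoG seed detection finds matched blobs and rejects tiny ones", {
  p <- segmentation_params()  # default seed range 9-25 px
  blob <- render_ball(c(31, 48, 48), c(16, 24, 24), 7.5)  # diameter 15
  seeds <- detect_seeds(blob, p)
  expect_equal(nrow(seeds), 1L)
  expect_lt(sqrt(sum((unlist(seeds[1, c("z", "y", "x")]) -
                        c(16, 24, 24))^2)), 2)
  tiny <- render_ball(c(31, 48, 48), c(16, 24, 24), 2)  # diameter 4
  expect_equal(nrow(detect_seeds(tiny, p)), 0L)
})

test_that("two blobs 30 px apart give exactly two seeds", {
  v <- render_ball(c(25, 80, 48), c(13, 25, 24), 7.5) +
    render_ball(c(25, 80, 48), c(13, 55, 24), 7.5)
  seeds <- detect_seeds(pmin(v, 1), segmentation_params())
  expect_equal(nrow(seeds), 2L)
  expect_setequal(seeds$y, c(25, 55))
})

test_that("watershed floods one connected mask to one label and conserves voxels", {
  v <- render_ball(c(21, 30, 30), c(11, 15, 15), 8)
  mask <- v > 0
  seeds <- data.frame(z = 11, y = 15, x = 15)
  lv <- watershed_3d(v, mask, seeds, small_params())
  expect_equal(lv$n_objects, 1L)
  expect_equal(sum(lv$labels > 0), sum(mask))
  expect_equal(sum(lv$labels > 0) + lv$removed_voxels, sum(mask))
  expect_error(watershed_3d(v, mask, seeds[0, , drop = FALSE],
                            small_params()),
               "no seeds")
  expect_warning(
    expect_error(watershed_3d(v, mask, data.frame(z = 1, y = 1, x = 1),
                              small_params()),
                 "no seeds inside"),
    "dropped")
})

test_that("touching spheres split into two catchments of similar volume", {
  r <- 8
  v <- pmin(render_ball(c(25, 48, 32), c(13, 17, 16), r) +
              render_ball(c(25, 48, 32), c(13, 32, 16), r), 1)
  mask <- v > 0
  seeds <- data.frame(z = c(13, 13), y = c(17, 32), x = c(16, 16))
  lv <- watershed_3d(v, mask, seeds, small_params(relief = "distance"))
  expect_equal(lv$n_objects, 2L)
  single <- sum(render_ball(c(25, 48, 32), c(13, 17, 16), r))
  vols <- lv$per_object$volume_voxels
  expect_true(all(abs(vols - single) / single < 0.15))
  # conservation: every mask voxel is assigned exactly once
  expect_equal(sum(vols) + lv$removed_voxels, sum(mask))
})

test_that("the pipeline is deterministic and recovers simulated nuclei", {
  sim <- small_sim(seed = 2)
  p <- small_params()
  seg1 <- segment_channel(sim$stack, "nuclei", p)
  seg2 <- segment_channel(sim$stack, "nuclei", p)
  expect_identical(seg1$labels, seg2$labels)
  ev <- evaluate_segmentation(seg1, sim$truth)
  expect_gte(ev$f_score, 0.9)
  # conservation on real pipeline output
  expect_equal(sum(seg1$labels > 0) + seg1$removed_voxels,
               sum(preprocess(sim$stack, "nuclei", p)$mask))
})

test_that("counting finds the configured totals and marker positives", {
  cfg <- simulation_config(diameter = 130, n_nuclei = 50, rim_thickness = 18,
                           seed = 5, zcomp_slope = zcomp_slope_for(150),
                           margin = 8)
  sim <- generate_spheroid(cfg)
  n_pos_truth <- sum(sim$truth$positive_flags)
  cr <- count_nuclei(sim$stack, "nuclei", "marker", small_params())
  expect_lte(abs(cr$n_total - 50), 2)
  expect_lte(abs(cr$n_positive - n_pos_truth), 1)
  expect_equal(cr$positive_fraction, cr$n_positive / cr$n_total)
})

test_that("an all-background marker channel yields zero positives", {
  sim <- small_sim(seed = 6, rim_fraction = 0)
  expect_equal(sum(sim$truth$positive_flags), 0L)
  cr <- count_nuclei(sim$stack, "nuclei", "marker", small_params())
  expect_equal(cr$n_positive, 0L)
  expect_equal(cr$positive_fraction, 0)
})

test_that("zero detected nuclei flags the fraction as undefined", {
  set.seed(20)
  vox <- array(pmax(rnorm(2 * 8 * 40 * 40, 10, 3), 0), c(2, 8, 40, 40))
  s <- make_stack(vox, channel_names = c("nuclei", "marker"))
  cr <- count_nuclei(s, "nuclei", "marker", small_params())
  expect_equal(cr$n_total, 0L)
  expect_true(is.na(cr$positive_fraction))
})

test_that("evaluation metrics follow the matching formulae", {
  sim <- small_sim(seed = 2)
  truth <- sim$truth$label_volume
  # identical volumes -> perfect scores
  ev <- evaluate_segmentation(truth, sim$truth)
  expect_equal(c(ev$precision, ev$recall, ev$f_score), c(1, 1, 1))
  # drop half the objects (keep labels contiguous) -> R = 0.5, P = 1
  n <- max(truth)
  half <- truth
  drop_ids <- seq(2, n, by = 2)
  half[half %in% drop_ids] <- 0L
  remap <- integer(n)
  kept <- setdiff(seq_len(n), drop_ids)
  remap[kept] <- seq_along(kept)
  half[half > 0] <- remap[half[half > 0]]
  ev <- evaluate_segmentation(half, sim$truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, length(kept) / n)
  expect_equal(ev$f_score, 2 * ev$precision * ev$recall /
                 (ev$precision + ev$recall))
  expect_error(evaluate_segmentation(array(0L, c(2, 2, 2)), sim$truth),
               "shape")
})

test_that("split objects match once per truth object at IoU 0.5", {
  # every truth object split into two equal halves: each half has IoU ~0.5
  # with its truth object; exactly one half matches -> P = 0.5, R = 1
  truth <- array(0L, c(4, 6, 6))
  truth[1:4, 1:6, 1:3] <- 1L
  truth[1:4, 1:6, 4:6] <- 2L
  split <- array(0L, c(4, 6, 6))
  split[1:2, , 1:3] <- 1L
  split[3:4, , 1:3] <- 2L
  split[1:2, , 4:6] <- 3L
  split[3:4, , 4:6] <- 4L
  ev <- evaluate_segmentation(split, truth, match_iou = 0.5)
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$recall, 1)
})
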