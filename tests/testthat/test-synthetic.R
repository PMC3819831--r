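test_that("phantom generation is deterministic, bounded and leaves the RNG alone", {
  before <- withr::with_seed(1, runif(1))
  set.seed(1)
  p1 <- generate_phantom(c(64, 64), n_blobs = 4, seed = 99)
  after <- runif(1)
  expect_identical(before, after)  # caller RNG stream undisturbed
  p2 <- generate_phantom(c(64, 64), n_blobs = 4, seed = 99)
  expect_identical(p1$data, p2$data)
  expect_gte(min(p1$data), 0)
  expect_lte(max(p1$data), 255)
  expect_error(generate_phantom(c(16, 64), 4, 1), ">= 32")
  expect_error(generate_phantom(c(64, 64), 0, 1), "n_blobs")
})

test_that("a one-blob phantom has exactly one bright connected component", {
  for (seed in c(2, 5, 11)) {
    p <- generate_phantom(c(64, 64), n_blobs = 1, seed = seed)
    # background stays <= 80, blobs >= 140: threshold between separates them
    expect_identical(count_components(p$data > 110), 1L)
  }
})

test_that("truth deformations respect the magnitude bound and pin the border", {
  def <- generate_truth_deformation(c(96, 96), 16, 4, seed = 7)
  f <- render_dense_field(def)
  expect_lte(max(abs(f)), 4)
  expect_true(any(def$levels[[1]]$displacements != 0))
  # border voxels essentially stay put: every control point within one cell
  # of the boundary is pinned, so only the tail of an interior point's
  # basis (weight < 1e-4 at distance ~2 cells) reaches the border
  expect_lt(max(abs(f[1, , ])), 2e-3)
  expect_lt(max(abs(f[96, , ])), 2e-3)
  expect_lt(max(abs(f[, 1, ])), 2e-3)
  expect_lt(max(abs(f[, 96, ])), 2e-3)
  # identity at zero magnitude; determinism; folding guard
  expect_true(all(render_dense_field(
    generate_truth_deformation(c(96, 96), 16, 0, seed = 7)) == 0))
  d2 <- generate_truth_deformation(c(96, 96), 16, 4, seed = 7)
  expect_identical(def$levels[[1]]$displacements, d2$levels[[1]]$displacements)
  expect_error(generate_truth_deformation(c(96, 96), 16, 8, seed = 7), "folding")
})

test_that("two-level truth deformations keep the summed magnitude bound", {
  def <- generate_truth_deformation(c(96, 96), 16, 4, seed = 8, levels = 2)
  expect_length(def$levels, 2L)
  expect_lte(max(abs(render_dense_field(def))), 4)
})

test_that("synthetic cases link reference and transformed by the stored truth", {
  cs <- make_case(c(64, 64), spacing = 16, max_magnitude = 3, seed = 21)
  expect_gt(ssd(cs$reference, cs$transformed), 0)
  redo <- warp_image(cs$reference, cs$truth, "linear")
  expect_identical(cs$transformed$data, redo$image$data)
  expect_identical(cs$valid, redo$valid)
  # regeneration with the same seed is bit-identical
  cs2 <- make_case(c(64, 64), spacing = 16, max_magnitude = 3, seed = 21)
  expect_identical(cs$transformed$data, cs2$transformed$data)
  # zero-magnitude case is already registered
  cs0 <- make_case(c(64, 64), spacing = 16, max_magnitude = 0, seed = 21)
  expect_identical(ssd(cs0$reference, cs0$transformed), 0)
})

test_that("an integer uniform displacement is recovered to machine zero", {
  # no interpolation happens at integer offsets, so replaying the truth
  # session inverts the warp exactly on the overlap
  withr::with_seed(141, ref <- scalar_image(matrix(runif(96 * 96) * 255, 96, 96)))
  def <- multilevel_deformation(c(96, 96), 16)
  lat <- def$levels[[1]]
  n_int <- lat$grid_shape - 3L
  evs <- list()
  for (i in (-1):(n_int[1] + 1L)) for (j in (-1):(n_int[2] + 1L)) {
    lat <- move_control_point(lat, c(i, j), c(4, -3))
    evs <- c(evs, list(drag_event(1, c(i, j), c(4, -3))))
  }
  def$levels[[1]] <- lat
  w <- warp_image(ref, def, "linear")
  res <- replay(ref, w$image, revision_session(16, evs))
  mask <- res$valid & w$valid
  expect_lt(ssd(ref, res$image, mask), 1e-20)
})

test_that("ground-truth replay strongly reduces SSD and misregistered area", {
  cs <- make_case(c(96, 96), spacing = 16, max_magnitude = 4, seed = 31)
  sess <- session_from_truth(cs)
  res <- replay(cs$reference, cs$transformed, sess, roi = cs$valid)
  n <- nrow(res$trace)
  # recovery leaves a residual dominated by resampling blur at sharp edges;
  # the regression baseline for these conditions is ~15-20% of baseline SSD
  expect_lt(res$trace$ssd[n], 0.25 * res$trace$ssd[1])
  # the area comparison is only meaningful above the resampling-halo
  # amplitude: re-interpolating the transformed image leaves faint ghosts
  # along every sharp edge, so low-threshold masks can grow even as the
  # registration improves. Strong misregistration (near the full edge
  # contrast, 80/255 display units) must collapse.
  thr <- 80
  area_before <- sum(misregistration_mask(cs$reference, cs$transformed, thr))
  area_after <- sum(misregistration_mask(cs$reference, res$image, thr))
  expect_lt(area_after, 0.25 * area_before)
})
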