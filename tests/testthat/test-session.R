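test_that("drag events store the negated content motion; refine appends a level", {
  state <- multilevel_deformation(c(64, 64), 16)
  s2 <- apply_event(state, drag_event(1, c(2, 2), c(4, 0)))
  expect_equal(control_point(s2$levels[[1]], c(2, 2)), c(-4, 0))
  expect_equal(sum(s2$levels[[1]]$displacements != 0), 1L)
  # refine keeps the dense field
  f_before <- render_dense_field(s2)
  s3 <- apply_event(s2, refine_event())
  expect_length(s3$levels, 2L)
  expect_identical(render_dense_field(s3), f_before)
  # opposite drags cancel exactly
  s4 <- apply_event(apply_event(state, drag_event(1, c(3, 1), c(2, -1))),
                    drag_event(1, c(3, 1), c(-2, 1)))
  expect_identical(s4$levels[[1]]$displacements,
                   state$levels[[1]]$displacements)
  # invalid events carry the ordinal
  expect_error(apply_event(state, drag_event(2, c(0, 0), c(1, 0)), ordinal = 4),
               "event 4")
  expect_error(apply_event(state, drag_event(1, c(99, 0), c(1, 0)), ordinal = 2),
               "event 2")
  # coarse-level drags after refinement warn but proceed
  expect_warning(apply_event(s3, drag_event(1, c(2, 2), c(1, 0))), "coarse level")
})

test_that("dragging content in a direction moves image content that way", {
  withr::with_seed(91, img <- matrix(runif(64 * 64) * 255, 64, 64))
  def <- multilevel_deformation(c(64, 64), 16)
  n_int <- def$levels[[1]]$grid_shape - 3L
  rng <- (-1):(n_int[1] + 1L)
  for (i in rng) for (j in rng)
    def <- apply_event(def, drag_event(1, c(i, j), c(3, 0)))
  w <- warp_image(scalar_image(img), def, "linear")
  # content displaced toward +x by 3 voxels
  expect_equal(w$image$data, oracle_integer_shift(img, c(3, 0)), tolerance = 1e-12)
})

test_that("an empty session leaves the image untouched with a baseline-only trace", {
  withr::with_seed(92, {
    ref <- scalar_image(matrix(runif(256) * 255, 16, 16))
    trn <- scalar_image(matrix(runif(256) * 255, 16, 16))
  })
  res <- replay(ref, trn, revision_session(4))
  expect_identical(res$image$data, trn$data)
  expect_identical(nrow(res$trace), 1L)
  expect_equal(res$trace$ssd[1], ssd(ref, trn))
})

test_that("replay is deterministic and equals warping once with the final deformation", {
  cs <- make_case(c(64, 64), spacing = 8, max_magnitude = 3, seed = 13)
  sess <- session_from_truth(cs)
  r1 <- replay(cs$reference, cs$transformed, sess, roi = cs$valid)
  r2 <- replay(cs$reference, cs$transformed, sess, roi = cs$valid)
  expect_identical(r1$image$data, r2$image$data)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$deformation, r2$deformation)
  # no compounding resampling: final image = one warp with the accumulated state
  once <- warp_image(cs$transformed, r1$deformation, "linear")
  expect_identical(r1$image$data, once$image$data)
  # SSD trace has baseline + one entry per event
  expect_identical(nrow(r1$trace), length(sess$events) + 1L)
})

test_that("suggest_direction points where content must move and is side-effect free", {
  # content must move +x: transformed equals a smooth reference shifted by
  # -2 in x (smooth so fractional probe displacements reduce SSD monotonically)
  x <- outer(0:63, rep(1, 64))
  y <- outer(rep(1, 64), 0:63)
  ref <- 100 + 60 * sin(x / 7) * cos(y / 9)
  trn <- oracle_integer_shift(ref, c(-2, 0))
  trn[63:64, ] <- ref[63:64, ]  # fill the wrap band so only the shift differs
  state <- multilevel_deformation(c(64, 64), 16)
  snap <- state
  dir <- suggest_direction(state, ref, trn, 1, c(2, 2), probe_step = 2)
  expect_identical(dir[1], 1L)
  expect_identical(state, snap)
  # swapping the images flips the suggested x-direction
  dir_sw <- suggest_direction(state, trn, ref, 1, c(2, 2), probe_step = 2)
  expect_identical(dir_sw[1], -1L)
  # perfectly registered images suggest no move
  expect_identical(suggest_direction(state, ref, ref, 1, c(2, 2), probe_step = 2),
                   c(0L, 0L))
  expect_error(suggest_direction(state, ref, trn, 1, c(2, 2), probe_step = 0),
               "positive")
  expect_error(suggest_direction(state, ref, trn, 1, c(50, 2), probe_step = 1),
               "out of bounds")
})

test_that("greedy probing never worsens the support-region SSD it tracks", {
  cs <- make_case(c(64, 64), spacing = 16, max_magnitude = 3, seed = 17)
  g <- greedy_revise(cs$reference, cs$transformed, 16, sweeps = 1,
                     initial_step = 1.5, max_moves = 4)
  # the global trace is non-increasing at probe resolution
  expect_true(all(diff(g$ssd_trace) <= 1e-9))
  # every committed event is a drag on level 1
  expect_true(all(vapply(g$session$events, `[[`, "", "kind") == "drag"))
})

test_that("sessions round-trip through JSON with full precision", {
  sess <- revision_session(c(16, 16),
                           list(drag_event(1, c(2, 2), c(4.125, -0.7)),
                                refine_event(),
                                drag_event(2, c(5, 3), c(1 / 3, 2))),
                           metadata = list(interpolation = "linear",
                                           threshold = 10))
  path <- withr::local_tempfile(fileext = ".json")
  write_session(sess, path)
  back <- read_session(path)
  expect_identical(back$initial_spacing, sess$initial_spacing)
  expect_identical(length(back$events), length(sess$events))
  for (k in seq_along(sess$events))
    expect_identical(back$events[[k]], sess$events[[k]])
  expect_identical(back$metadata$interpolation, "linear")
  # replaying original and round-tripped sessions is bit-identical
  cs <- make_case(c(48, 48), spacing = 16, max_magnitude = 3, seed = 3)
  sess2 <- session_from_truth(cs)
  path2 <- withr::local_tempfile(fileext = ".json")
  write_session(sess2, path2)
  r1 <- replay(cs$reference, cs$transformed, sess2)
  r2 <- replay(cs$reference, cs$transformed, read_session(path2))
  expect_identical(r1$image$data, r2$image$data)
  expect_error(read_session(withr::local_tempfile(fileext = ".json")), "not found")
})
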