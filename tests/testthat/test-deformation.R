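test_that("total displacement sums the per-level evaluations", {
  withr::with_seed(21, {
    def <- multilevel_deformation(c(40, 40), 10)
    def$levels[[1]] <- random_lattice(c(40, 40), 10)
    def <- refine(def)
    def$levels[[2]] <- random_lattice(c(40, 40), 5, level = 2L)
    expect_equal(def$levels[[2]]$spacing, c(5, 5))
    for (r in 1:20) {
      p <- runif(2, 0, 39.99)
      per_level <- evaluate_level_displacement(def$levels[[1]], p) +
        evaluate_level_displacement(def$levels[[2]], p)
      expect_equal(total_displacement(def, p), per_level, tolerance = 1e-12)
    }
    # only one nonzero level: total equals that level alone
    solo <- multilevel_deformation(c(40, 40), 10)
    solo$levels[[1]] <- def$levels[[1]]
    solo <- refine(solo)
    p <- c(17.3, 22.8)
    expect_equal(total_displacement(solo, p),
                 evaluate_level_displacement(def$levels[[1]], p))
  })
})

test_that("dense rendering equals the voxelwise sum of per-level fields", {
  withr::with_seed(31, {
    def <- multilevel_deformation(c(32, 36), 8)
    def$levels[[1]] <- random_lattice(c(32, 36), 8)
    def <- refine(def)
    def$levels[[2]] <- random_lattice(c(32, 36), 4, sd = 1, level = 2L)
    def <- refine(def)
    def$levels[[3]] <- random_lattice(c(32, 36), 2, sd = 0.5, level = 3L)
    total <- render_dense_field(def)
    per <- render_dense_field(def, level = 1) + render_dense_field(def, level = 2) +
      render_dense_field(def, level = 3)
    expect_lt(max(abs(total - per)), 1e-10)
  })
})

test_that("separable dense rendering matches pointwise evaluation", {
  withr::with_seed(41, {
    def <- multilevel_deformation(c(28, 44), c(7, 11))
    def$levels[[1]] <- random_lattice(c(28, 44), c(7, 11))
    f <- render_dense_field(def)
    for (r in 1:100) {
      v <- c(sample(0:27, 1), sample(0:43, 1))
      expect_lt(max(abs(f[v[1] + 1, v[2] + 1, ] - total_displacement(def, v))),
                1e-12)
    }
    # 3-D spot check
    def3 <- multilevel_deformation(c(12, 10, 14), 4)
    def3$levels[[1]] <- random_lattice(c(12, 10, 14), 4)
    f3 <- render_dense_field(def3)
    for (r in 1:25) {
      v <- c(sample(0:11, 1), sample(0:9, 1), sample(0:13, 1))
      expect_lt(max(abs(f3[v[1] + 1, v[2] + 1, v[3] + 1, ] -
                        total_displacement(def3, v))), 1e-12)
    }
  })
})

test_that("the dense field is linear in the control displacements", {
  withr::with_seed(51, {
    def <- multilevel_deformation(c(30, 30), 6)
    def$levels[[1]] <- random_lattice(c(30, 30), 6)
    f1 <- render_dense_field(def)
    def2 <- def
    def2$levels[[1]]$displacements <- 2.5 * def$levels[[1]]$displacements
    expect_equal(render_dense_field(def2), 2.5 * f1, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(render_dense_field(multilevel_deformation(c(30, 30), 6)) == 0))
  })
})

test_that("a single level's field is numerically smooth (bounded second differences)", {
  withr::with_seed(61, {
    def <- multilevel_deformation(c(64, 64), 16)
    def$levels[[1]] <- random_lattice(c(64, 64), 16, sd = 3)
    f <- render_dense_field(def)[, , 1]
    d2 <- f[1:62, ] - 2 * f[2:63, ] + f[3:64, ]
    cmax <- max(abs(def$levels[[1]]$displacements))
    # second difference of a cubic spline with spacing s is O(cmax / s^2);
    # 6/s^2 is a generous closed-form bound for the cardinal cubic basis
    expect_lt(max(abs(d2)), 6 * cmax / 16^2)
  })
})

test_that("voxel-to-mm conversion scales components by the voxel spacing", {
  def <- multilevel_deformation(c(32, 32), 8)
  def$levels[[1]] <- move_control_point(def$levels[[1]], c(2, 2), c(4, 2))
  f <- render_dense_field(def)
  g <- field_voxels_to_mm(f, c(0.5, 2))
  expect_equal(g[, , 1], 0.5 * f[, , 1])
  expect_equal(g[, , 2], 2 * f[, , 2])
})
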