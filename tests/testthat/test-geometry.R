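test_that("severity-to-a mapping reproduces the printed clinical values", {
  # printed severity/a pairs for the circular subglottal section
  expect_equal(round(severity_to_a(0.50), 4), 0.2929)
  expect_equal(round(severity_to_a(0.75), 4), 0.5)
  expect_equal(round(severity_to_a(0.90), 4), 0.6838)
  expect_equal(round(severity_to_a(0.96), 4), 0.8)
  expect_equal(severity_to_a(0), 0)
  expect_error(severity_to_a(1), "severity")
  expect_error(severity_to_a(-0.1), "severity")
  expect_error(a_to_severity(1.2), "a")
})

test_that("polygon-area bisection agrees with the closed form", {
  for (s in c(0.36, 0.5, 0.75, 0.9, 0.96)) {
    expect_equal(sgs_calibrate_a(s), severity_to_a(s), tolerance = 1e-9)
  }
  # analytic check for severity 0.36: a = 1 - sqrt(0.64) = 0.2
  expect_equal(sgs_calibrate_a(0.36), 0.2, tolerance = 1e-9)
})

test_that("severity/a round trip is exact", {
  for (s in c(0, 0.25, 0.5, 0.75, 0.9, 0.96)) {
    expect_equal(a_to_severity(severity_to_a(s)), s, tolerance = 1e-10)
  }
})

test_that("cosine stenosis deformation has the stated local structure", {
  tube <- make_capped_cylinder(r = 0.005, y0 = 0, y1 = 0.06)
  spec0 <- sgs_spec(a = 0, L = 0.01, location = 0.03, rotation_deg = 0)
  expect_equal(apply_sgs(tube, spec0)$vertices, tube$vertices)

  spec <- sgs_spec(a = 0.5, L = 0.01, location = 0.03, rotation_deg = 0)
  def <- apply_sgs(tube, spec)
  # nodes outside the axial window are untouched
  outside <- tube$vertices[, 2] < 0.025 - 1e-12 |
    tube$vertices[, 2] > 0.035 + 1e-12
  expect_equal(def$vertices[outside, ], tube$vertices[outside, ])
  # axial coordinate unchanged everywhere
  expect_equal(def$vertices[, 2], tube$vertices[, 2])
  # at the narrowest plane the radius scales by exactly (1 - a)
  ring <- which(abs(tube$vertices[, 2] - 0.03) < 1e-9)
  r_def <- sqrt(def$vertices[ring, 1]^2 + def$vertices[ring, 3]^2)
  expect_equal(r_def, rep(0.005 * 0.5, length(ring)), tolerance = 1e-12)
})

test_that("deformed circular section area matches (1-a)^2 on a fine polygon", {
  # shoelace-area oracle on the cross-section ring at the narrowest plane
  tube <- make_capped_cylinder(r = 0.004, y0 = 0, y1 = 0.04,
                               n_ring = 512L, n_axial = 81L)
  a <- 0.6838
  spec <- sgs_spec(a = a, L = 0.01, location = 0.02, rotation_deg = 0)
  def <- apply_sgs(tube, spec)
  ring <- which(abs(tube$vertices[, 2] - 0.02) < 1e-9)
  area <- abs(polygon_area(def$vertices[ring, c(1, 3)]))
  expect_equal(area / (pi * 0.004^2), (1 - a)^2, tolerance = 1e-3)
})

test_that("tract rotation is applied before and inverted after", {
  tube <- make_capped_cylinder(r = 0.005, y0 = 0, y1 = 0.06)
  # rotate the tube itself by 22 degrees so that rotating by -(-22)...
  # deform the upright tube through a rotated spec frame: rotating by +22
  # maps the tube off the y-axis, so a rotated spec on a rotated tube must
  # equal the unrotated operation mapped through the rotation
  spec_r <- sgs_spec(a = 0.4, L = 0.01, location = 0.03, rotation_deg = 22)
  R <- phonosim:::rotation_matrix_z(-22)  # rotate tube by -22 deg
  tube_r <- transform_surface(tube, function(v) {
    v[, 1:2] <- v[, 1:2] %*% t(R); v
  })
  def_r <- apply_sgs(tube_r, spec_r)
  spec_0 <- sgs_spec(a = 0.4, L = 0.01, location = 0.03, rotation_deg = 0)
  def_0 <- apply_sgs(tube, spec_0)
  back <- transform_surface(def_0, function(v) {
    v[, 1:2] <- v[, 1:2] %*% t(R); v
  })
  expect_equal(def_r$vertices, back$vertices, tolerance = 1e-12)
})

test_that("idealized larynx fixture is structurally complete and deterministic", {
  fix <- make_idealized_larynx()
  expect_s3_class(fix$channel, "phs_surface")
  expect_true(all(c("wall") %in% fix$channel$tags))
  expect_true(all(fix$folds$tags == "fsi"))
  expect_true(all(c("inlet", "outlet", "probe", "p_sub", "p_sup") %in%
                  fix$markers$name))
  expect_gt(length(fix$solid$left$fixed), 0)
  expect_gt(length(fix$solid$left$fsi), 0)
  expect_silent(validate_surface(fix$folds))
  expect_silent(validate_surface(fix$channel))

  # requested initial gap is realized by the medial surfaces
  g <- 0.0012
  fix2 <- make_idealized_larynx(list(folds = list(gap = g)))
  wetL <- fix2$solid$left$nodes[fix2$solid$left$fsi, ]
  wetR <- fix2$solid$right$nodes[fix2$solid$right$fsi, ]
  expect_equal(min(wetR[, 1]) - max(wetL[, 1]), g, tolerance = 1e-12)

  # determinism: bit-identical geometry for identical configs
  fix3 <- make_idealized_larynx()
  expect_identical(fix$channel$vertices, fix3$channel$vertices)
  expect_identical(fix$solid$left$nodes, fix3$solid$left$nodes)

  expect_error(make_idealized_larynx(list(channel = list(width = -1))),
               "positive")
  expect_error(make_idealized_larynx(list(bogus_key = 1)), "unknown config")
})

test_that("fixture channel survives severe stenosis without degenerating", {
  for (a in c(0.3, 0.8)) {
    cfgl <- list(geometry = list(sgs = list(severity = a_to_severity(a))))
    cfg <- validate_config(cfgl)
    setup <- phonosim:::simulation_setup(cfg)
    expect_silent(validate_surface(setup$channel_deformed))
    # wall curves must not cross the axis: positive residual lumen
    v <- setup$channel_deformed$vertices
    lumen <- v[abs(v[, 1]) < 0.011 & v[, 1] != 0, ]
    expect_true(min(abs(lumen[, 1])) > 0)
  }
})
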