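test_that("the angle-doubling projection matches its worked values", {
  m <- local_map(0 + 0i, k = 2, chirality = 1)
  expect_equal(global_to_local(1 + 0i, m), 0 + 0.5i)
  expect_equal(local_to_global(0 + 0.5i, m, branch = "+"), 1 + 0i)
  expect_equal(global_to_local(0 + 0i, m, center_policy = "collapse"),
               0 + 0i)
  expect_error(global_to_local(0 + 0i, m), "singular-center")
  expect_error(local_to_global(0 + 0i, m), "singular-center")
  expect_error(local_map(k = 0), "k must be")
  expect_error(local_map(chirality = 2), "chirality")
})

test_that("modulus scaling, angle doubling and the 90-degree rotation hold", {
  set.seed(3)
  P <- complex(real = rnorm(200), imaginary = rnorm(200))
  P <- P[Mod(P) > 1e-6]
  for (k in c(0.5, 1, 3)) {
    m <- local_map(1 + 2i, k = k, chirality = 1)
    p <- global_to_local(P, m)
    expect_equal(Mod(p - m$p0), Mod(P - m$p0) / k, tolerance = 1e-12)
    dang <- (Arg(p - m$p0) - 2 * Arg(P - m$p0)) * 180 / pi
    w <- ((dang - 90) %% 360 + 360) %% 360
    expect_lt(max(pmin(w, 360 - w)), 1e-9)
  }
})

test_that("global-local round trips are the identity on the matching branch", {
  set.seed(4)
  P <- complex(real = rnorm(100, sd = 2), imaginary = rnorm(100, sd = 2))
  P <- P[Mod(P - (0.5 + 0.5i)) > 1e-3][1:50]
  for (chir in c(1, -1)) {
    m <- local_map(0.5 + 0.5i, k = 1.7, chirality = chir)
    p <- global_to_local(P, m)
    Pp <- local_to_global(p, m, branch = "+")
    Pm <- local_to_global(p, m, branch = "-")
    err <- pmin(Mod(Pp - P), Mod(Pm - P)) / Mod(P - m$p0)
    expect_lt(max(err), 1e-12)
    # the two branches differ by 180 degrees in global angle
    dth <- abs(((Arg(Pp - m$p0) - Arg(Pm - m$p0)) * 180 / pi) %% 360)
    expect_true(all(abs(dth - 180) < 1e-9))
  }
})

test_that("one physical circuit spans one full orientation period", {
  sp <- op_circuit_span(local_map())
  expect_equal(sp$span, 180)
  expect_equal(sp$signed_span, 180)
  sn <- op_circuit_span(local_map(chirality = -1), radius = 2.5)
  expect_equal(sn$span, 180)
  expect_equal(sn$signed_span, -180)
  # orientation values wrap mod 180
  expect_true(all(sp$op >= 0 & sp$op < 180))
})

test_that("synthesized maps have one pinwheel per column with chirality-matched winding", {
  om <- synthesize_op_map(local_map(0 + 0i, 1, 1), 0.1)
  sing <- om$features[om$features$type == "singularity", ]
  expect_equal(nrow(sing), 1)
  expect_lt(abs(sing$x) + abs(sing$y), 0.15)
  expect_equal(sing$winding, 0.5)

  maps <- list(local_map(0 + 0i, 1, 1), local_map(4 + 0i, 1, -1),
               local_map(0 + 4i, 1, -1), local_map(4 + 4i, 1, 1))
  om4 <- synthesize_op_map(map_atlas(maps), 0.1)
  s4 <- om4$features[om4$features$type == "singularity", ]
  expect_equal(nrow(s4), 4)
  expect_setequal(round(s4$winding * 2) / 2, c(0.5, -0.5))
  chir <- sapply(maps, function(m) m$chirality)
  near <- sapply(seq_len(4), function(i) {
    d <- Mod(complex(real = s4$x, imaginary = s4$y) -
               sapply(maps, function(m) m$p0)[i])
    which.min(d)
  })
  expect_equal(s4$winding[order(near)] * 2, chir)
})

test_that("chirality flip mirrors the orientation raster", {
  dom <- c(-2.1, 2, -2.1, 2)     # pixel centers symmetric about zero
  om_p <- synthesize_op_map(local_map(0 + 0i, 1, 1), 0.2, classify = FALSE,
                            domain = dom)
  om_m <- synthesize_op_map(local_map(0 + 0i, 1, -1), 0.2, classify = FALSE,
                            domain = dom)
  # the opposite-handed map is the positional mirror image about the
  # axis through the center: orientation values at mirrored positions
  # coincide (the conjugate preimage direction is the conjugate angle),
  # while the pinwheel winding flips sign
  mirrored <- om_p$raster[rev(seq_len(nrow(om_p$raster))), ]
  dif <- abs(((om_m$raster - mirrored) %% 180 + 180) %% 180)
  dif <- pmin(dif, 180 - dif)
  expect_lt(max(dif), 1e-9)
})

test_that("a 2x2 alternating-chirality atlas contains an interior saddle", {
  maps <- list(local_map(0 + 0i, 1, 1), local_map(4 + 0i, 1, -1),
               local_map(0 + 4i, 1, -1), local_map(4 + 4i, 1, 1))
  om <- synthesize_op_map(map_atlas(maps), 0.1, blend = "soft")
  sad <- om$features[om$features$type == "saddle", ]
  expect_gte(nrow(sad), 1)
  expect_true(any(sad$x > 1 & sad$x < 3 & sad$y > 1 & sad$y < 3))
})

test_that("image dispersal conserves samples and applies metric delays", {
  atl <- map_atlas(list(local_map(0 + 0i, k = 1, support = 10)))
  pat <- global_pattern(c(1 + 0i, 2 + 0i, 3 + 0i), t = 0)
  li <- project_image(pat, atl, v = Inf)
  expect_length(li, 1)
  expect_equal(nrow(li[[1]]), 3)
  expect_true(all(li[[1]]$delay == 0))

  # finite conduction speed: delay = |P - p| / v
  one <- project_image(global_pattern(1 + 0i), atl, v = 2)[[1]]
  p <- global_to_local(1 + 0i, atl$maps[[1]])
  expect_equal(one$delay, Mod((1 + 0i) - p) / 2)

  far <- global_pattern(100 + 100i)
  expect_warning(project_image(far, atl, v = Inf), "empty-projection")

  # topographic consistency: collinear ordering recoverable after
  # projection and inversion
  back <- sapply(li[[1]]$p, function(z)
    Re(local_to_global(z, atl$maps[[1]], "+")))
  expect_identical(order(back), order(c(1, 2, 3)))
})

test_that("rigid moving images pack into exactly twelve points", {
  img <- make_fixture("rigid-image", moving = TRUE, seed = 2)
  fr <- build_representation_frame(img)
  expect_length(fr$points, 12)

  static <- make_fixture("rigid-image", moving = FALSE, seed = 2)
  fs <- build_representation_frame(static)
  expect_length(fs$points, 12)
  expect_true(all(fs$points[7:12] == 0))

  back <- frame_to_image_spec(fr)
  expect_equal(back$scale, img$scale)
  expect_equal(back$rotation, img$rotation)
  expect_equal(back$position, img$position)
  expect_equal(back$velocity_position, img$velocity_position)
  expect_error(rigid_image_spec(rigid = FALSE), "unsupported-image")
})
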