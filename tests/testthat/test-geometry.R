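test_that("every mask partitions the domain and flat depends on z only", {
  for (kind in c("FLAT", "WALL", "PLATEAU", "HOLE", "CONCAVE", "CONVEX")) {
    st <- build_substrate(geometry_spec(kind, domain = c(400, 400, 400),
                                        agar_depth = 200, h = 80, w = 160,
                                        radius = 1000), 20)
    expect_true(all(st$phase %in% c(0L, 1L)), info = kind)
  }
  st <- build_substrate(geometry_spec("FLAT", domain = c(400, 400, 400),
                                      agar_depth = 200), 20)
  for (k in seq_len(st$dims[3])) {
    expect_length(unique(as.vector(st$phase[, , k])), 1)
  }
  # agar layers are exactly agar_depth / dx
  expect_equal(sum(st$phase[1, 1, ] == 1), 10)
})

test_that("reported curvature is the inverse radius in 1/mm", {
  expect_equal(geometry_spec("CONCAVE", radius = 2000)$kappa_per_mm, 0.5)
  expect_equal(geometry_spec("CONVEX", radius = 1000)$kappa_per_mm, 1.0)
  expect_true(is.na(geometry_spec("FLAT")$kappa_per_mm))
})

test_that("plateau heights rasterize to exactly h/dx extra agar layers", {
  for (h in c(200, 400)) {
    spec <- geometry_spec("PLATEAU", domain = c(1200, 1200, 1000),
                          agar_depth = 200, h = h, w = 400)
    st <- build_substrate(spec, 40)
    mid <- st$dims[1] / 2
    n_center <- sum(st$phase[mid, mid, ] == 1)
    n_edge <- sum(st$phase[1, 1, ] == 1)
    expect_equal(n_center - n_edge, h / 40)
  }
})

test_that("the hole floor sits h below the surrounding surface", {
  spec <- geometry_spec("HOLE", domain = c(800, 800, 600), agar_depth = 400,
                        h = 160, w = 240)
  st <- build_substrate(spec, 40)
  mid <- st$dims[1] / 2
  expect_equal(sum(st$phase[1, 1, ] == 1) - sum(st$phase[mid, mid, ] == 1),
               160 / 40)
})

test_that("wall offset places the seed o/dx sites from the wall face", {
  spec <- geometry_spec("WALL", domain = c(800, 400, 400), agar_depth = 160,
                        h = 120, o = 210)
  st <- build_substrate(spec, 10)
  st <- seed_colony(st)
  seed_x <- st$seed_index[1]
  wall_x <- min(which(st$phase[, st$seed_index[2], 17] == 1))  # first raised column
  expect_equal(wall_x - seed_x, 21 + 1)  # 21 sites of gap at dx = 10
  # o = 0: seed column directly adjacent to the wall face
  st0 <- build_substrate(geometry_spec("WALL", domain = c(800, 400, 400),
                                       agar_depth = 160, h = 120, o = 0), 10)
  st0 <- seed_colony(st0)
  expect_equal(min(which(st0$phase[, st0$seed_index[2], 17] == 1)) -
                 st0$seed_index[1], 1)
})

test_that("masks have the expected reflection symmetries", {
  flat <- build_substrate(geometry_spec("FLAT", domain = c(400, 400, 400),
                                        agar_depth = 200), 20)$phase
  expect_equal(flat, flat[dim(flat)[1]:1, , ])
  expect_equal(flat, flat[, dim(flat)[2]:1, ])
  wall <- build_substrate(geometry_spec("WALL", domain = c(400, 400, 400),
                                        agar_depth = 160, h = 80, o = 0),
                          20)$phase
  expect_equal(wall, wall[, dim(wall)[2]:1, ])       # symmetric across y
  expect_false(isTRUE(all.equal(wall, wall[dim(wall)[1]:1, , ])))  # not x
})

test_that("rasterized curvature converges to the analytic cylinder section", {
  spec <- geometry_spec("CONCAVE", domain = c(800, 400, 400),
                        agar_depth = 160, radius = 1000)
  misclass <- function(dx) {
    st <- build_substrate(spec, dx)
    dims <- st$dims
    xc <- (seq_len(dims[1]) - 0.5) * dx
    zc <- (seq_len(dims[3]) - 0.5) * dx
    surf <- colonyfba:::surface_height(spec, xc, rep(200, dims[1]))
    bad <- 0
    for (i in seq_len(dims[1])) {
      # exact classification by the analytic surface at site centers
      exact_agar <- zc < surf[i]
      bad <- bad + sum((st$phase[i, 1, ] == 1) != exact_agar)
    }
    bad / (dims[1] * dims[3])
  }
  # site-center rasterization is exact at centers; instead compare the
  # rasterized surface height to the analytic one as dx shrinks
  surf_err <- function(dx) {
    st <- build_substrate(spec, dx)
    xc <- (seq_len(st$dims[1]) - 0.5) * dx
    exact <- colonyfba:::surface_height(spec, xc, rep(200, st$dims[1]))
    rast <- vapply(seq_len(st$dims[1]),
                   function(i) sum(st$phase[i, 1, ] == 1) * dx, numeric(1))
    mean(abs(rast - exact))
  }
  expect_equal(misclass(20), 0)
  errs <- vapply(c(40, 20, 10), surf_err, numeric(1))
  expect_true(errs[3] < errs[1])
  expect_lt(errs[3], 10 / 2 + 1e-9)  # within half a site at dx = 10
})

test_that("seeding places one cell mass on the surface and validates position", {
  st <- build_substrate(geometry_spec("FLAT", domain = c(400, 400, 400),
                                      agar_depth = 200), 20)
  st <- seed_colony(st)
  si <- st$seed_index
  expect_equal(st$biomass$GLUCOSE_UTILIZER[si[1], si[2], si[3]], 258)
  expect_equal(st$phase[si[1], si[2], si[3]], colonyfba:::PHASE_AIR)
  expect_equal(st$phase[si[1], si[2], si[3] - 1], colonyfba:::PHASE_AGAR)
  expect_equal(phi_total(st)[si[1], si[2], si[3]],
               258 / (20^3 * st$consts$rho))
  # invalid positions are rejected
  expect_error(seed_colony(st, position = c(1, 1, 1)), "not an air site")
  expect_error(seed_colony(st, position = c(1, 1, 20)), "not face-adjacent")
  # hole geometry: default seed sits on the hole floor
  sth <- build_substrate(geometry_spec("HOLE", domain = c(800, 800, 600),
                                       agar_depth = 400, h = 160, w = 240), 40)
  sth <- seed_colony(sth)
  expect_equal(sth$seed_index[3], (400 - 160) / 40 + 1)
})

test_that("unresolvable features and non-divisible spacings are rejected", {
  spec <- geometry_spec("PLATEAU", domain = c(800, 800, 600),
                        agar_depth = 200, h = 60, w = 400)
  expect_error(build_substrate(spec, 40), "not resolvable")
  expect_error(build_substrate(geometry_spec("FLAT"), 37), "does not divide")
})
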