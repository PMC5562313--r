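test_that("phenotype fractions sum to one and match hand summation", {
  st <- air_block_with_mass(c(4, 4, 4), 10,
                            rbind(c(1, 1, 1), c(2, 1, 1), c(3, 1, 1)),
                            c(100, 200, 300))
  st$biomass$ACETATE_UTILIZER[1, 2, 1] <- 60
  fr <- phenotype_fractions(st)
  expect_equal(sum(fr$fraction), 1)
  expect_equal(fr$fraction[fr$phenotype == "ACETATE_UTILIZER"], 60 / 660)
  # all glucose-utilizer mass: acetate fraction 0
  st0 <- air_block_with_mass(c(3, 3, 3), 10, cbind(2, 2, 2), 500)
  expect_equal(
    phenotype_fractions(st0)$fraction[2], 0)
  # equal masses: 0.5 each
  st0$biomass$ACETATE_UTILIZER[1, 1, 1] <- 500
  expect_equal(phenotype_fractions(st0)$fraction, c(0.5, 0.5))
  # zero biomass: sentinel
  ste <- lattice_state(array(colonyfba:::PHASE_AIR, c(3, 3, 3)), 10)
  expect_true(all(is.na(phenotype_fractions(ste)$fraction)))
})

test_that("active-consumer share counts only mass with applied uptake", {
  st <- air_block_with_mass(c(3, 3, 3), 10, cbind(2, 2, 2), 0)
  st$biomass$ACETATE_UTILIZER[2, 2, 2] <- 300
  st$biomass$ACETATE_UTILIZER[1, 1, 1] <- 100
  up <- array(0, c(3, 3, 3))
  up[2, 2, 2] <- -4  # consuming
  st$applied$ace_uptake <- up
  fr <- phenotype_fractions(st)
  expect_equal(fr$active_fraction[2], 0.75)
})

test_that("onset time interpolates linearly and handles edge cases", {
  expect_equal(onset_time(data.frame(time_hr = c(10, 11),
                                     value = c(0.005, 0.015))), 10.5)
  expect_true(is.na(onset_time(data.frame(time_hr = 0:5, value = rep(0, 6)))))
  # crossing exactly at a sample returns that time
  expect_equal(onset_time(data.frame(time_hr = c(1, 2, 3),
                                     value = c(0, 0.01, 0.02))), 2)
  # monotone in the threshold
  ser <- data.frame(time_hr = 0:10, value = seq(0, 0.1, length.out = 11))
  ths <- c(0.005, 0.02, 0.05, 0.09)
  ons <- vapply(ths, function(th) onset_time(ser, th), numeric(1))
  expect_true(all(diff(ons) > 0))
})

test_that("colony dimensions measure the thresholded region in site units", {
  consts <- cell_constants()
  full <- 0.65 * consts$rho * 1000
  st <- air_block_with_mass(c(21, 21, 21), 10, cbind(11, 11, 11), full)
  d <- colony_dimensions(st)
  expect_equal(d$height_um, 10)
  expect_equal(d$width_um, 10)
  expect_equal(d$aspect, 1)
  # rasterized hemisphere of radius 8 sites: width ~ 2x height within one site
  st2 <- lattice_state(array(colonyfba:::PHASE_AIR, c(21, 21, 21)), 10)
  for (i in 1:21) for (j in 1:21) for (k in 1:21) {
    if ((i - 11)^2 + (j - 11)^2 + (k - 1)^2 <= 64 && k >= 1) {
      st2$biomass$GLUCOSE_UTILIZER[i, j, k] <- full
    }
  }
  d2 <- colony_dimensions(st2)
  expect_lte(abs(d2$width_um - 2 * d2$height_um), 10)
  # threshold above the maximum: sentinel
  st3 <- air_block_with_mass(c(5, 5, 5), 10, cbind(3, 3, 3), full * 0.1)
  expect_true(is.na(colony_dimensions(st3)$height_um))
})

test_that("axis profiles report depth relative to the agar surface", {
  ph <- array(colonyfba:::PHASE_AIR, c(5, 5, 10))
  ph[, , 1:4] <- colonyfba:::PHASE_AGAR
  st <- lattice_state(ph, 10)
  # uniform field: constant profile
  pr <- axis_profile(st, "oxygen", column = c(3, 3))
  expect_equal(unique(pr$conc_mM), 0.21)
  expect_equal(pr$depth_um[4], -5)   # last agar site center, 5 um below surface
  expect_equal(pr$depth_um[5], 5)    # first air site center above
  # a linear test field is recovered exactly
  lin <- array(rep(2 * (1:10) + 1, each = 25), c(5, 5, 10))
  st$conc$glucose <- lin
  pr2 <- axis_profile(st, "glucose", column = c(2, 4))
  expect_equal(unname(diff(pr2$conc_mM)), rep(2, 9))
  # fresh substrate: glucose equals the agar value below, zero above
  st0 <- build_substrate(geometry_spec("FLAT", domain = c(200, 200, 200),
                                       agar_depth = 100), 20)
  pr3 <- axis_profile(st0, "glucose", column = c(5, 5))
  expect_true(all(pr3$conc_mM[pr3$depth_um < 0] == 138.8))
  expect_true(all(pr3$conc_mM[pr3$depth_um > 0] == 0))
})

test_that("convergence errors average relative deviations over the window", {
  mk <- function(dx, fac, frac = NULL) {
    ser <- tibble::tibble(
      time_hr = seq(0, 30, 0.5),
      vol_total_fL = fac * exp(0.2 * time_hr),
      vol_glu_fL = 0.9 * vol_total_fL,
      vol_ace_fL = 0.1 * vol_total_fL,
      frac_ace = if (is.null(frac)) rep(0.1, length(time_hr)) else frac
    )
    structure(list(series = ser, config = list(dx = dx)),
              class = "colony_trajectory")
  }
  ref <- mk(10, 1)
  expect_equal(convergence_error(mk(20, 1), ref)$err_total, 0)
  expect_equal(convergence_error(mk(20, 1.1), ref)$err_total, 0.1,
               tolerance = 1e-9)
  # hand-computed two-point deviation
  a <- mk(20, 1)
  a$series$vol_total_fL <- a$series$vol_total_fL *
    ifelse(a$series$time_hr <= 20, 1.2, 1.0)
  win <- seq(0, 30, 0.5)
  hand <- mean(ifelse(win >= 10 & win <= 30,
                      abs(ifelse(win <= 20, 0.2, 0)), NA), na.rm = TRUE)
  expect_equal(convergence_error(a, ref)$err_total, hand, tolerance = 1e-9)
  expect_error(convergence_error(mk(20, 1), ref, t0 = 40, t1 = 50),
               "no sample times")
  # oscillation flag: alternating large swings trip it, smooth series do not
  n <- length(win)
  osc <- mk(20, 1, frac = 0.1 + 0.05 * rep_len(c(-1, 1), n) *
              as.numeric(win > 10))
  expect_true(convergence_error(osc, ref)$oscillating)
  expect_false(convergence_error(mk(20, 1), ref)$oscillating)
})

test_that("acetate turnover has the documented unit arithmetic", {
  st <- air_block_with_mass(c(3, 3, 3), 10, cbind(2, 2, 2), 0)
  st$biomass$ACETATE_UTILIZER[2, 2, 2] <- 258  # phi = 0.001 per 1000 fL site
  up <- array(0, c(3, 3, 3))
  up[2, 2, 2] <- -10
  st$applied$ace_uptake <- up
  # one occupied 1000-fL site: 258 fg * 10 mmol/gDCW/hr / 1000 fL = 2.58 mM/hr
  expect_equal(acetate_turnover(st), 2.58)
  expect_equal(acetate_turnover(st, normalize_to = acetate_turnover(st)), 1)
  # zero uptake: zero; empty colony: sentinel
  st$applied$ace_uptake[] <- 0
  expect_equal(acetate_turnover(st), 0)
  ste <- lattice_state(array(colonyfba:::PHASE_AIR, c(3, 3, 3)), 10)
  expect_true(is.na(acetate_turnover(ste)))
})

test_that("correlations match the t-transform checked by hand", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_characteristics(x, 2 * x + 1)$r, 1)
  expect_equal(correlate_characteristics(x, -x)$r, -1)
  y <- c(2.1, 3.9, 6.3, 7.8, 10.4)
  got <- correlate_characteristics(x, y)
  r_hand <- sum((x - 3) * (y - mean(y))) /
    sqrt(sum((x - 3)^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 3)
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$p_value, p_hand, tolerance = 1e-12)
  expect_true(correlate_characteristics(x, rep(1, 5))$degenerate)
})
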