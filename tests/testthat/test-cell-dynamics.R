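test_that("volume fraction follows phi = m/(V rho)", {
  expect_equal(volume_fraction(258, 1000), 0.001)
  expect_equal(volume_fraction(0, 1000), 0)
  # inverting at the packing cap for a 10-um site
  expect_equal(0.65 * 1000 * cell_constants()$rho, 167700)
  expect_equal(volume_fraction(167700, 1000), 0.65)
})

test_that("biomass growth is the exact exponential and composes", {
  expect_equal(grow_biomass(258, 0.84, 3600), 258 * exp(0.84))
  expect_equal(grow_biomass(100, 0, 3600), 100)
  two_half <- grow_biomass(grow_biomass(50, 0.5, 1800), 0.5, 1800)
  expect_equal(two_half, grow_biomass(50, 0.5, 3600))
})

test_that("uptake bounds combine saturation and supply limits", {
  expect_equal(compute_uptake_bounds(0, 100, 1000, 36, 10, 0.015), 0)
  # C >> Km with ample supply: the saturated table maximum
  expect_equal(compute_uptake_bounds(100, 1, 1000, 36, 10, 0.015),
               10 * 100 / 100.015)
  # C = Km with ample supply: half of the maximum
  expect_equal(compute_uptake_bounds(0.015, 1, 1e6, 36, 10, 0.015), 5)
  # supply-limited branch: exactly the content over one step
  got <- compute_uptake_bounds(10, 1e9, 1000, 36, 10, 0.015)
  expect_equal(got, 10 * 1000 * 3600 / (1e9 * 36))
  expect_equal(compute_uptake_bounds(10, 0, 1000, 36, 10, 0.015), 0)
})

test_that("apply_reaction converts fluxes to mM/hr with correct units", {
  st <- air_block_with_mass(c(5, 5, 5), 10, cbind(3, 3, 3), 258)
  st$conc$glucose[] <- 10
  flux <- array(0, c(5, 5, 5))
  flux[3, 3, 3] <- 258 * (-9.5)  # one cell, fg * mmol/gDCW/hr
  st2 <- apply_reaction(st, list(glucose = flux), dt = 3600)
  expect_equal(st2$conc$glucose[3, 3, 3], 10 - 2.4510, tolerance = 1e-6)
  expect_equal(st2$conc$glucose[1, 1, 1], 10)
  # zero flux: unchanged; secretion mirrors uptake
  st3 <- apply_reaction(st, list(glucose = flux * 0), dt = 3600)
  expect_equal(st3$conc$glucose, st$conc$glucose)
  st4 <- apply_reaction(st, list(glucose = -flux), dt = 3600)
  expect_equal(st4$conc$glucose[3, 3, 3] - 10, 10 - st2$conc$glucose[3, 3, 3])
  # bound violation is a programming error
  flux[3, 3, 3] <- -1e9
  expect_error(apply_reaction(st, list(glucose = flux), dt = 3600), "below zero")
})

test_that("the starvation timer converts exactly at tau and resets on breaks", {
  mk <- function() {
    st <- air_block_with_mass(c(3, 3, 3), 10, cbind(2, 2, 2), 100)
    st$conc$oxygen[] <- 0.21
    st
  }
  starve <- function(st) {
    st$conc$glucose[] <- 0
    st$conc$acetate[] <- 2
    st
  }
  feed <- function(st) {
    st$conc$glucose[] <- 5
    st
  }
  # fed: no timer, no conversion
  st <- feed(mk())
  st <- update_phenotypes(st, 600, tau = 1800)
  expect_equal(st$reg_timer[2, 2, 2], 0)
  expect_equal(st$biomass$ACETATE_UTILIZER[2, 2, 2], 0)
  # held exactly tau: conversion on that step, mass conserved
  st <- starve(mk())
  for (i in 1:3) st <- update_phenotypes(st, 600, tau = 1800)
  expect_equal(st$biomass$ACETATE_UTILIZER[2, 2, 2], 100)
  expect_equal(st$biomass$GLUCOSE_UTILIZER[2, 2, 2], 0)
  expect_equal(sum(colonyfba:::site_mass(st)), 100)
  # tau - dt, break, tau - dt again: never converts (timer automaton)
  st <- starve(mk())
  for (i in 1:2) st <- update_phenotypes(st, 600, tau = 1800)
  st <- update_phenotypes(feed(st), 600, tau = 1800)
  expect_equal(st$reg_timer[2, 2, 2], 0)
  st <- starve(st)
  for (i in 1:2) st <- update_phenotypes(st, 600, tau = 1800)
  expect_equal(st$biomass$ACETATE_UTILIZER[2, 2, 2], 0)
  # anoxic starved site does not convert (aerobic phenotype induction)
  st <- starve(mk())
  st$conc$oxygen[] <- 0
  for (i in 1:5) st <- update_phenotypes(st, 600, tau = 1800)
  expect_equal(st$biomass$ACETATE_UTILIZER[2, 2, 2], 0)
})

test_that("pushing exports excess equally and leaves the donor at the cap", {
  consts <- cell_constants()
  cap <- 0.65 * consts$rho * 1000  # fg for a 10-um site
  st <- air_block_with_mass(c(5, 5, 5), 10, cbind(3, 3, 3), cap * 1.6)
  st2 <- push_biomass(st)
  m <- st2$biomass$GLUCOSE_UTILIZER
  expect_equal(m[3, 3, 3], cap)
  excess <- cap * 0.6
  for (nb in list(c(2, 3, 3), c(4, 3, 3), c(3, 2, 3), c(3, 4, 3),
                  c(3, 3, 2), c(3, 3, 4))) {
    expect_equal(m[nb[1], nb[2], nb[3]], excess / 6)
  }
  expect_equal(sum(m), cap * 1.6)  # conserved away from boundaries
})

test_that("pushing below the cap is a no-op and never enters agar", {
  ph <- array(colonyfba:::PHASE_AIR, c(5, 5, 5))
  ph[, , 1:2] <- colonyfba:::PHASE_AGAR
  st <- lattice_state(ph, 10)
  cap <- 0.65 * st$consts$rho * 1000
  st$biomass$GLUCOSE_UTILIZER[3, 3, 3] <- cap * 0.99
  st2 <- push_biomass(st)
  expect_equal(st2$biomass$GLUCOSE_UTILIZER, st$biomass$GLUCOSE_UTILIZER)
  st$biomass$GLUCOSE_UTILIZER[3, 3, 3] <- cap * 3
  st3 <- push_biomass(st)
  expect_true(all(st3$biomass$GLUCOSE_UTILIZER[ph == colonyfba:::PHASE_AGAR] == 0))
  phi <- phi_total(st3)
  expect_true(all(phi <= 0.65 + 1e-6))
})

test_that("pushing preserves the donor's phenotype proportions", {
  consts <- cell_constants()
  cap <- 0.65 * consts$rho * 1000
  st <- air_block_with_mass(c(5, 5, 5), 10, cbind(3, 3, 3), cap * 1.2)
  st$biomass$ACETATE_UTILIZER[3, 3, 3] <- cap * 0.6  # total 1.8 cap, 1/3 acetate
  st2 <- push_biomass(st)
  received_g <- st2$biomass$GLUCOSE_UTILIZER[2, 3, 3]
  received_a <- st2$biomass$ACETATE_UTILIZER[2, 3, 3]
  expect_equal(received_a / (received_a + received_g), 1 / 3, tolerance = 1e-9)
  expect_equal(sum(colonyfba:::site_mass(st2)), cap * 1.8, tolerance = 1e-9)
})

test_that("mass pushed across the domain boundary is absorbed", {
  consts <- cell_constants()
  cap <- 0.65 * consts$rho * 1000
  st <- air_block_with_mass(c(3, 3, 3), 10, cbind(1, 1, 1), cap * 2)
  st2 <- push_biomass(st)
  expect_lt(sum(colonyfba:::site_mass(st2)), cap * 2)  # corner loses to boundary
  expect_true(all(phi_total(st2) <= 0.65 + 1e-6))
})
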