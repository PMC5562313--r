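# Scaled-down study runs shared between the acceptance blocks (cached per
# session; every run is deterministic). Protocols: the five-strain comparison
# follows the 50-hr flat-surface protocol; geometry comparisons run 30-40 hr;
# the grid-convergence study runs 30 hr at four resolutions.

strain_run <- function(strain) {
  cached_run(paste0("strain_", strain),
             preset_scaled("FLAT", strain, duration = 50,
                           keep_states = FALSE))
}

flat_run_mg <- function() strain_run("MG1655")

wall_run <- function(o) {
  cached_run(paste0("wall_o", o),
             preset_scaled("WALL", "MG1655", duration = 40, o = o, h = 160,
                           keep_states = FALSE))
}

curved_run <- function(kind) {
  cached_run(paste0("curved_", kind),
             preset_scaled(kind, "MG1655", duration = 30, radius = 1000,
                           keep_states = FALSE))
}

convergence_run <- function(dx) {
  if (dx == 40) return(truncate_traj(flat_run_mg(), 30))
  cached_run(paste0("conv_dx", dx),
             preset_scaled("FLAT", "MG1655", dx = dx, duration = 30,
                           keep_states = FALSE))
}

truncate_traj <- function(tr, t_max) {
  keep <- tr$series$time_hr <= t_max + 1e-9
  tr$series <- tr$series[keep, ]
  tr$times_hr <- tr$times_hr[keep]
  tr
}

series_at <- function(tr, t) {
  tr$series[which.min(abs(tr$series$time_hr - t)), ]
}

# steady-state acetate-capable fraction: mean over the final 5 hours
steady_fraction <- function(tr) {
  s <- tr$series
  tail_win <- s$time_hr >= max(s$time_hr) - 5
  mean(s$frac_ace[tail_win], na.rm = TRUE)
}

# mean active-consumer share over the post-onset samples
mean_active_share <- function(tr) {
  s <- tr$series
  post <- !is.na(s$frac_ace) & s$frac_ace >= 0.01 & !is.na(s$frac_ace_active)
  if (!any(post)) return(NA_real_)
  mean(s$frac_ace_active[post])
}

# last common sample time before either colony touches the domain ceiling
last_free_time <- function(tr_a, tr_b, Lz = 720) {
  common <- intersect(tr_a$series$time_hr, tr_b$series$time_hr)
  ok <- vapply(common, function(t) {
    za <- series_at(tr_a, t)$zmax_um
    zb <- series_at(tr_b, t)$zmax_um
    !is.na(za) && !is.na(zb) && za < Lz && zb < Lz
  }, logical(1))
  if (!any(ok)) return(NA_real_)
  max(common[ok])
}
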