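# shared fixtures: all built in code, deterministic, no downloads

# homogeneous all-agar block (for diffusion tests in reflecting mode)
agar_block <- function(n = 24, dx = 10) {
  lattice_state(array(colonyfba:::PHASE_AGAR, c(n, n, n)), dx)
}

# a state with biomass placed by hand at given sites (air phase everywhere)
air_block_with_mass <- function(dims, dx, sites, masses,
                                phenotype = "GLUCOSE_UTILIZER") {
  st <- lattice_state(array(colonyfba:::PHASE_AIR, dims), dx)
  for (k in seq_len(nrow(sites))) {
    st$biomass[[phenotype]][sites[k, 1], sites[k, 2], sites[k, 3]] <-
      masses[k]
  }
  st
}

# miniature flat config for fast engine tests (sub-second per simulated hour)
mini_config <- function(duration = 2, dx = 40, strain = "MG1655", ...) {
  sim_config(
    geometry = geometry_spec("FLAT", domain = c(360, 360, 360),
                             agar_depth = 160),
    strain = strain, dx = dx, duration = duration, output_interval = 0.5,
    ...)
}

# saturating, chemically clamped config: uniform high nutrients everywhere,
# no diffusion or reaction — growth should be exactly exponential
saturating_config <- function(duration = 5, strain = "MG1655") {
  sp <- species_table()
  sp$init_air <- c(138.8, 0, 100)   # glucose everywhere, abundant O2
  sp$init_agar <- c(138.8, 0, 100)
  mini_config(duration = duration, strain = strain, species = sp,
              clamp_chemicals = TRUE)
}

# session-level cache for expensive scaled runs shared across test files
run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, config_expr) {
  if (!exists(name, envir = run_cache)) {
    assign(name, run_simulation(config_expr), envir = run_cache)
  }
  get(name, envir = run_cache)
}

scipy_available <- function() {
  nzchar(Sys.which("python"))
}

# independent LP oracle: solve max c'v s.t. Sv=0, lb<=v<=ub with scipy HiGHS
scipy_fba <- function(model) {
  payload <- jsonlite::toJSON(list(
    S = model$S, lb = model$lb, ub = pmin(model$ub, 1e4),
    c = as.numeric(colnames(model$S) == model$objective)
  ), digits = NA)
  script <- '
import sys, json
import numpy as np
from scipy.optimize import linprog
d = json.load(sys.stdin)
S = np.array(d["S"]); lb = np.array(d["lb"]); ub = np.array(d["ub"])
c = -np.array(d["c"])
r = linprog(c=c, A_eq=S, b_eq=np.zeros(S.shape[0]),
            bounds=list(zip(lb, ub)), method="highs")
print(json.dumps({"status": int(r.status), "obj": (-r.fun if r.success else None),
                  "x": (list(r.x) if r.success else None)}))
'
  out <- system2("python", c("-c", shQuote(script)), input = payload,
                 stdout = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""))
}
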