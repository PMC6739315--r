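# Shared fixtures and lazily-built replicate caches for the test suite.

# tiny configs used throughout the unit tests
tiny_counts <- function(...) {
  cn <- agent_counts()
  cn[] <- 0L
  ov <- c(...)
  cn[names(ov)] <- ov
  cn
}

tiny_config <- function(variant = "SM", duration = 200, seed = 1,
                        counts = tiny_counts(integrin = 2L, FAK = 4L),
                        equilibration = 0, ...) {
  run_config(variant = variant, duration = duration, seed = seed,
             counts = counts, equilibration = equilibration,
             sampling_interval = 50L, ...)
}

# a frozen world where integrin 1 is force-eligible and FAKs are parked at
# chosen positions; motion and basal activity disabled
frozen_cfg <- function(..., counts = tiny_counts(integrin = 2L, FAK = 2L)) {
  kin <- kinetics_params(prime_mean = 0, basal_rate = 0,
                         d_kinase = 0, d_mrna = 0, d_ribosome = 0,
                         d_protein = 0, d_nuclear = 0, ...)
  run_config("SM", duration = 10, seed = 2, counts = counts,
             equilibration = 0, kinetics = kin)
}

# place agent `id` of a world at a position (nm)
place_agent <- function(world, id, x, y, z) {
  world$x[id] <- x; world$y[id] <- y; world$z[id] <- z
  world
}

# ---- replicate caches for the calibration-anchor tests --------------------
# built once per test session on first use; all anchor blocks share them
.anchor_cache <- new.env(parent = emptyenv())

anchor_runs <- function(variant, duration, n = 8, base_seed = 20240101,
                        equilibration = 600) {
  key <- sprintf("%s_%d_%d", variant, duration, n)
  if (!is.null(.anchor_cache[[key]])) return(.anchor_cache[[key]])
  cfg <- run_config(variant, duration = duration, seed = base_seed,
                    equilibration = equilibration)
  rs <- run_replicates(cfg, n = n)
  .anchor_cache[[key]] <- rs
  rs
}

sm_runs <- function() anchor_runs("SM", 28800)
usm_runs <- function() anchor_runs("USM", 28800)
hm1_runs <- function() anchor_runs("HM1", 36000)

# per-replicate scalar metrics, skipping failed runs
rep_metric <- function(repset, f) {
  vals <- vapply(repset$runs, function(r)
    if (inherits(r, "mech_abm_sim")) f(r) else NA_real_, numeric(1))
  vals[!is.na(vals)]
}

# first post-peak sample time (min) at which the series reads zero
first_zero_min <- function(s, col) {
  peak <- which.max(s[[col]])
  z <- which(s[[col]] == 0 & seq_along(s[[col]]) > peak)
  if (!length(z)) return(NA_real_)
  s$time[z[1]] / 60
}

# first sample (min) after which the series stays at zero
silence_min <- function(s, col) {
  v <- s[[col]]
  nz <- which(v > 0)
  if (!length(nz)) return(0)
  if (max(nz) == length(v)) return(NA_real_)
  s$time[max(nz) + 1] / 60
}

# decline onset (min): last time the trailing 10-sample median is at or
# above 90% of the series maximum, plus one sample
decline_onset_min <- function(s, col) {
  v <- s[[col]]
  emax <- max(v)
  rmed <- vapply(seq_along(v), function(i)
    stats::median(v[max(1, i - 9):i]), numeric(1))
  ok <- which(rmed >= 0.9 * emax)
  if (!length(ok) || max(ok) == length(v)) return(NA_real_)
  s$time[max(ok) + 1] / 60
}
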