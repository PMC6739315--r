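# Reaction rules on constructed miniature worlds: priming, pair reactions,
# dormancy gating, nearest-partner choice, expression and deposition.

# membrane point of integrin `i` (nm)
integrin_pos <- function(w, i) c(w$x[i], w$y[i], w$z[i])

test_that("an eligible integrin activates a receptive FAK within reach", {
  cfg <- frozen_cfg()
  w <- init_world(cfg)
  # integrin with the larger stress factor is eligible under SM thresholds
  i <- which.max(w$Xpat)
  p <- integrin_pos(w, i) * 0.99   # just inside the membrane
  w <- place_agent(w, 3, p[1], p[2], p[3])
  w <- place_agent(w, 4, -p[1], -p[2], -p[3])  # far side: out of reach
  res <- step_world(w, cfg, n = 1)
  expect_identical(res$world$state[i], 1L)           # integrin active
  expect_identical(res$world$state[3], 1L)           # pFAK produced
  expect_identical(res$world$state[4], 0L)           # distant FAK untouched
  expect_gt(res$world$acs[i], 0)                     # catalyst dormancy set
})

test_that("a dormant participant takes part in no reaction", {
  cfg <- frozen_cfg()
  w <- init_world(cfg)
  i <- which.max(w$Xpat)
  p <- integrin_pos(w, i) * 0.99
  w <- place_agent(w, 3, p[1], p[2], p[3])
  w <- place_agent(w, 4, 0, 0, 7000)
  w$acs[3] <- 10   # dormancy blocks the encounter
  res <- step_world(w, cfg, n = 2)
  expect_identical(res$world$state[3], 0L)
})

test_that("the nearest eligible partner is chosen, independent of order", {
  cfg <- frozen_cfg(counts = tiny_counts(integrin = 1L, FAK = 2L))
  w0 <- init_world(cfg)
  stopifnot(w0$Xpat[1] > 0.1)  # the single integrin must be eligible
  p <- integrin_pos(w0, 1)
  inward <- p / sqrt(sum(p^2))
  w0 <- place_agent(w0, 2, p[1] - 100 * inward[1], p[2] - 100 * inward[2],
                    p[3] - 100 * inward[3])   # 100 nm away
  w0 <- place_agent(w0, 3, p[1] - 60 * inward[1], p[2] - 60 * inward[2],
                    p[3] - 60 * inward[3])    # 60 nm away: nearer
  fwd <- step_world(w0, cfg, n = 1)
  rev <- step_world(w0, cfg, n = 1, reverse_order = TRUE)
  expect_identical(fwd$world$state[3], 1L)  # nearest FAK wins
  expect_identical(fwd$world$state[2], 0L)
  expect_identical(fwd$world$state, rev$world$state)
})

test_that("forces below threshold mean no activation and zero signalling", {
  kin <- kinetics_params(basal_rate = 0)
  hi <- variant_spec("SM", mt_sensitive = 2)  # MT at 200% of the peak force
  cfg <- run_config(hi, duration = 1500, seed = 4, equilibration = 0,
                    kinetics = kin)
  sim <- run_sim(cfg)
  expect_true(all(sim$series$active_integrins == 0))
  expect_true(all(sim$series$pERK == 0))
  expect_true(all(sim$series$pFAK == 0))
  # the transcript pool stays at the census baseline (2 per gene)
  expect_true(all(sim$series$mrna_live == 8))
  # only the 4 baseline proteins ever deposit
  expect_true(all(sim$series$dep_total <= 4))
  expect_identical(max(sim$series$dep_total), 4)
})

test_that("deactivation follows the dormancy timescale, not the instant", {
  # two integrins under strong stress, then the stress is removed
  cfg <- frozen_cfg()
  cfg$kinetics[["off_delay"]] <- 60
  w <- init_world(cfg)
  res <- step_world(w, cfg, n = 5, sigma_on = TRUE)
  expect_gte(sum(res$world$state[1:2]), 1L)  # activated under load
  st <- res$world$state[1:2]
  off <- step_world(res$world, cfg, n = 30, sigma_on = FALSE)
  expect_identical(off$world$state[1:2], st)  # still engaged mid-dormancy
  off2 <- step_world(off$world, cfg, n = 40, sigma_on = FALSE)
  expect_identical(sum(off2$world$state[1:2]), 0L)  # released after ~60 s
})

test_that("translation yield and dormancy follow the drawn Gaussian", {
  # one cytoplasmic mRNA co-located with a ribosome, degenerate yield
  cfg <- frozen_cfg(yield_mean = 1, yield_sd = 0, acs_mrna = 50,
                    mrna_lifetime = 0,
                    counts = tiny_counts(integrin = 1L, ribosome = 1L,
                                         mRNA_per_gene = 0L))
  w <- init_world(cfg)
  w <- place_agent(w, 2, 6000, 0, 0)  # the ribosome
  # add a live cytoplasmic mRNA agent by hand (gene 2 = OCN)
  w$species <- c(w$species, species_codes()[["mRNA"]])
  w$state <- c(w$state, 0L); w$gene <- c(w$gene, 2L)
  w$x <- c(w$x, 6010); w$y <- c(w$y, 0); w$z <- c(w$z, 0)
  w$acs <- c(w$acs, 0); w$life <- c(w$life, 0); w$aux <- c(w$aux, 0)
  mrna_id <- length(w$species)
  res <- step_world(w, cfg, n = 1)
  expect_identical(sum(res$world$cum_tl), 1)       # exactly one protein
  expect_gt(res$world$acs[2], 0)                   # ribosome dormant
  expect_gt(res$world$acs[mrna_id], 0)             # mRNA dormant
  # zero yield still applies dormancy
  cfg0 <- frozen_cfg(yield_mean = 0, yield_sd = 0, mrna_lifetime = 0,
                     counts = tiny_counts(integrin = 1L, ribosome = 1L,
                                          mRNA_per_gene = 0L))
  res0 <- step_world(w, cfg0, n = 1)
  expect_identical(sum(res0$world$cum_tl), 0)
  expect_gt(res0$world$acs[2], 0)
})

test_that("every deposit removes one protein agent and feeds the ECM state", {
  cfg <- frozen_cfg(secretion_delay = 3,
                    counts = tiny_counts(integrin = 1L,
                                         protein_per_gene = 1L))
  w <- init_world(cfg)
  prot <- which(w$species == species_codes()[["ECMp"]])
  expect_length(prot, 4)
  res <- step_world(w, cfg, n = 3)
  expect_identical(res$world$n_dep, 4)
  expect_true(all(res$world$state[prot] == state_codes()[["dead"]]))
  expect_identical(sum(res$world$dep_gene), 4)
  # the coupling exchange sees the stiffened matrix
  ft0 <- coupling_exchange(w, cfg)
  ft1 <- coupling_exchange(res$world, cfg)
  expect_true(all(abs(ft1$force_N) <= abs(ft0$force_N)))
})

test_that("transcription events pick genes near-uniformly", {
  rs <- usm_runs()
  run <- Filter(function(r) inherits(r, "mech_abm_sim"), rs$runs)[[1]]
  tx <- run$world$cum_tx
  expect_gt(sum(tx), 200)
  p <- stats::chisq.test(tx)$p.value
  expect_gt(p, 1e-4)
})
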