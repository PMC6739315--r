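# The particle world: initialisation, Brownian motion, compartments,
# activation-cycle timers and neighbour search.

test_that("the default world matches the census (8892 agents)", {
  cfg <- run_config("SM", duration = 100)
  w <- init_world(cfg)
  expect_identical(length(w$species), 8892L)
  expect_identical(sum(w$species == 0L), 500L)  # integrins
  # integrins sit exactly on the membrane
  r <- sqrt(w$x[1:500]^2 + w$y[1:500]^2 + w$z[1:500]^2)
  expect_true(all(abs(r - 1e4) < 1e-6))
  # compartment homes at t0
  comp <- compartment_of(w$x, w$y, w$z, tol = 1e-3)
  sp <- names(species_codes())[w$species + 1L]
  expect_true(all(comp[sp %in% c("FAK", "Ras", "Raf", "MEK", "ERK",
                                 "ribosome", "ECMp")] == "cytoplasm"))
  expect_true(all(comp[sp %in% c("Runx2", "complex", "mRNA")] == "nucleus"))
})

test_that("same seed gives a bit-identical world; variants share placement", {
  cfg <- run_config("HM1", duration = 100, seed = 11)
  w1 <- init_world(cfg)
  w2 <- init_world(cfg)
  expect_identical(w1, w2)
  # a different variant from the same seed differs only in thresholds
  w3 <- init_world(run_config("USM", duration = 100, seed = 11))
  expect_identical(w1$x, w3$x)
  expect_identical(w1$species, w3$species)
  expect_false(identical(w1$mt, w3$mt))
})

test_that("Brownian steps have the right statistics and respect bounds", {
  pos <- matrix(0, 10000, 3)
  r <- brownian_step(pos, D = 1e6, dt = 1, lower = 0, upper = 1e9)
  d2 <- rowSums(r$pos^2)
  # mean squared displacement 6 D dt within sampling error
  expect_equal(mean(d2), 6e6, tolerance = 0.05)
  # D = 0 leaves positions unchanged
  r0 <- brownian_step(pos + 5, D = 0, dt = 1, upper = 1e9)
  expect_identical(r0$pos[, 1], pos[, 1] + 5)
  # reflection keeps agents strictly inside a thin shell
  shell <- matrix(rnorm(300), 100, 3)
  shell <- shell / sqrt(rowSums(shell^2)) * 9990
  rs <- brownian_step(shell, D = 1e6, dt = 1, lower = 4000, upper = 1e4)
  rr <- sqrt(rowSums(rs$pos^2))
  expect_true(all(rr <= 1e4 & rr >= 4000))
})

test_that("activation-cycle tick decrements and releases dormancy", {
  w <- make_fixture("toy_world_20_agents")
  w$acs[3] <- 5
  w$acs[4] <- 1
  w$state[4] <- state_codes()[["refractory"]]
  st3 <- w$state[3]
  w1 <- acs_tick(w)
  expect_identical(w1$acs[3], 4)        # 5 -> 4, state unchanged
  expect_identical(w1$state[3], st3)
  expect_identical(w1$acs[4], 0)        # 1 -> 0 and back to receptive
  expect_identical(w1$state[4], state_codes()[["basal"]])
  w2 <- acs_tick(w1)
  expect_identical(w2$acs[4], 0)        # 0 stays 0, no-op
})

test_that("neighbour queries: tiny worlds and index-vs-scan equivalence", {
  w <- make_fixture("two_integrin_world")
  # place two agents 1 nm apart, far from everyone else
  w <- place_agent(w, 3, 5000, 0, 0)
  w <- place_agent(w, 4, 5001, 0, 0)
  expect_identical(neighbours_within(w, 3, 2), 4L)
  expect_identical(neighbours_within(w, 4, 2), 3L)
  expect_length(neighbours_within(w, 3, 0.5), 0)
  # random 200-agent world: grid equals brute force for 100 queries
  cfg <- tiny_config(counts = tiny_counts(integrin = 20L, FAK = 60L,
                                          Ras = 60L, MEK = 60L))
  w <- init_world(cfg)
  set.seed(99)
  for (id in sample(seq_along(w$species), 100)) {
    rad <- runif(1, 50, 2000)
    expect_identical(neighbours_within(w, id, rad, "grid"),
                     neighbours_within(w, id, rad, "brute"))
  }
})

test_that("species stay in their compartments and kinases are conserved", {
  cfg <- run_config("USM", duration = 300, seed = 5, equilibration = 0)
  w <- init_world(cfg)
  counts0 <- table(w$species)
  for (k in 1:6) {
    res <- step_world(w, cfg, n = 50)
    w <- res$world
    cen <- world_census(w)
    # conservation: per-kinase state sums equal the initial census
    for (spn in c("FAK", "Ras", "Raf", "MEK", "ERK", "Runx2"))
      expect_identical(sum(cen[spn, ]),
                       as.integer(counts0[[as.character(species_codes()[[spn]])]]))
    # containment
    alive <- w$state != state_codes()[["dead"]]
    r <- sqrt(w$x^2 + w$y^2 + w$z^2)
    spc <- ifelse(w$species < 0, NA_integer_, w$species + 1L)
    sp <- names(species_codes())[spc]
    expect_true(all(r[alive] <= 1e4 + 1e-6))
    cyto <- alive & sp %in% c("FAK", "Ras", "Raf", "MEK", "ribosome", "ECMp")
    expect_true(all(r[cyto] >= 4000 - 1e-6))
    nuc <- alive & sp %in% c("Runx2", "complex")
    expect_true(all(r[nuc] <= 4000 + 1e-6))
  }
})
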