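test_that("zero-rate channels are exact no-ops", {
  p <- quiet_params(n_mcdA = 10)
  st <- init_state(p, seed = 1)
  set.seed(99)
  expect_identical(hop_mcdA(st, p)$mcda_site, st$mcda_site)
  expect_identical(rebind_mcdA(st, p)$mcda_site, st$mcda_site)
  expect_identical(unbind_mcdA_intrinsic(st, p)$mcda_site, st$mcda_site)
  expect_identical(form_bonds(st, p)$bond_mcda, st$bond_mcda)
  expect_identical(break_bonds(st, p)$bond_mcda, st$bond_mcda)
})

test_that("lattice random walk reproduces MSD = 4*D*t", {
  p <- quiet_params(n_mcdA = 1)
  p$geometry$nucleoid_length <- 4.0
  p$geometry$nucleoid_width <- 2.0
  p$kinetics$D_mcdA_nucleoid <- 0.01
  st0 <- init_state(p, seed = 8)
  st0 <- place_mcda(st0, 1, site_at(p, 2000, 1000))
  set.seed(101)
  n_blocks <- 120
  steps_per_block <- 100
  disp2 <- numeric(n_blocks)
  st <- st0
  for (b in seq_len(n_blocks)) {
    from <- site_pos(p, st$mcda_site[1])
    for (k in seq_len(steps_per_block)) st <- hop_mcdA(st, p)
    to <- site_pos(p, st$mcda_site[1])
    disp2[b] <- sum((to - from)^2)
  }
  expected <- 4 * p$kinetics$D_mcdA_nucleoid * 1e6 * p$run$dt * steps_per_block
  se <- sd(disp2) / sqrt(n_blocks)
  expect_lt(abs(mean(disp2) - expected), 3 * se)
})

test_that("a fully occupied lattice rejects every hop", {
  p <- quiet_params(n_mcdA = 800)  # 40 x 20 sites, all filled
  p$kinetics$D_mcdA_nucleoid <- 0.01
  st <- init_state(p, seed = 4)
  expect_equal(sum(st$mcda_site > 0), 800)
  set.seed(5)
  st2 <- hop_mcdA(st, p)
  expect_identical(st2$mcda_site, st$mcda_site)
})

test_that("nucleoid occupancy relaxes to the two-state equilibrium", {
  p <- quiet_params(n_mcdA = 200)
  p$kinetics$k_rebind <- 0.05
  p$kinetics$k_off_intrinsic <- 0.03
  p$run$dt <- 0.01
  p$run$record_interval <- 1
  st <- init_state(p, seed = 6)
  res <- advance_state(st, p, n_steps = 20000, record_every = 100)
  t <- res$records[, 1]
  frac <- res$records[, 2] / p$kinetics$n_mcdA
  keep <- t > 50
  bm <- vapply(split(frac[keep], floor((t[keep] - 50) / 25)), mean, numeric(1))
  expected <- 0.05 / 0.08
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(bm) - expected), 3 * se)
})

test_that("unbonded McdA survival follows the exponential law", {
  p <- quiet_params(n_mcdA = 500)
  p$geometry$nucleoid_length <- 2.0
  p$geometry$nucleoid_width <- 1.0
  p$kinetics$k_off_intrinsic <- 0.5
  p$run$dt <- 1e-3
  st <- init_state(p, seed = 9)
  # k_rebind = 0 would start everyone in the cytoplasm; place all on lattice
  for (i in 1:500) st <- place_mcda(st, i, i)
  set.seed(42)
  for (k in 1:1000) st <- unbind_mcdA_intrinsic(st, p)
  surv_p <- exp(-0.5 * 1)
  expected <- 500 * surv_p
  se <- sqrt(500 * surv_p * (1 - surv_p))
  expect_lt(abs(sum(st$mcda_site > 0) - expected), 3 * se)
})

test_that("rebinding fills only empty sites and respects capacity", {
  p <- quiet_params(n_mcdA = 800)
  p$kinetics$k_rebind <- 100   # near-certain rebinding per step at dt = 5e-4
  p$run$dt <- 0.05
  p$kinetics$D_mcdA_nucleoid <- 0
  st <- init_state(p, seed = 2)   # all 800 on the 800-site lattice
  st <- place_mcda(st, 1, 0L)     # one particle to the cytoplasm; site 1 free
  set.seed(7)
  st2 <- rebind_mcdA(st, p)
  expect_equal(sum(st2$mcda_site > 0), 800)
  expect_length(check_state(st2, p), 0)
  # now zero capacity: the cytoplasmic particle must stay cytoplasmic
  st3 <- place_mcda(st2, 2, 0L)
  st3 <- place_mcda(st3, 2, setdiff(1:800, st3$mcda_site)[1])  # refill gap
  expect_equal(sum(st3$occupancy > 0), 800)
  st3 <- place_mcda(st3, 3, 0L)
  st3$occupancy[st3$mcda_site[3]] <- 0L
  expect_length(check_state(st3, p), 0)
})

test_that("bond formation matches the nearest available McdA and is gated by range", {
  p <- quiet_params(n_mcdA = 1, n_mcdB = 2)
  p$kinetics$k_bond_on <- 1e5  # p ~ 1 within dt
  st <- init_state(p, seed = 3)
  st <- set_offset(st, 1, 1, c(0, 0))
  st <- set_offset(st, 1, 2, c(10, 0))
  centre <- st$carb[1, ]
  s <- site_at(p, centre[1] + 12, centre[2] - 12)
  st <- place_mcda(st, 1, s)
  a <- site_pos(p, s)
  d1 <- sqrt(sum((centre - a)^2))
  d2 <- sqrt(sum((centre + c(10, 0) - a)^2))
  expect_true(d1 <= 25 && d2 <= 25 && d2 < d1)  # both in range, site 2 nearer
  set.seed(1)
  st2 <- form_bonds(st, p)
  expect_equal(sum(st2$bond_mcda > 0), 1)       # exactly one bond
  expect_equal(st2$bond_mcda[2, 1], 1L)         # to the nearer McdB site
  expect_equal(st2$mcda_bond_site[1], 2L)

  # out of range: no bond
  st3 <- place_mcda(st, 1, site_at(p, centre[1] + 200, centre[2]))
  set.seed(1)
  expect_equal(sum(form_bonds(st3, p)$bond_mcda > 0), 0)
})

test_that("bond breaking obeys the extension guard and the exponential lifetime", {
  p <- quiet_params(n_mcdA = 1, n_mcdB = 1)
  p$kinetics$k_bond_off <- 0
  st <- init_state(p, seed = 5)
  st <- set_offset(st, 1, 1, c(0, 0))
  s <- site_at(p, st$carb[1, 1], st$carb[1, 2])
  st <- place_mcda(st, 1, s)
  st <- install_bond(st, 1, 1, 1)
  # extension below guard, zero rate: nothing breaks
  set.seed(1)
  expect_equal(sum(break_bonds(st, p)$bond_mcda > 0), 1)
  # force extension beyond the 200 nm guard: breaks with certainty, McdA ejected
  st_far <- st
  st_far$carb[1, ] <- site_pos(p, s) + c(250, 0)
  st_far2 <- break_bonds(st_far, p)
  expect_equal(sum(st_far2$bond_mcda > 0), 0)
  expect_equal(st_far2$mcda_site[1], 0L)

  # lifetimes: 30 parallel bonds, repeated rounds; mean ~ 1/k_bond_off
  p2 <- quiet_params(n_mcdA = 30, n_mcdB = 30)
  p2$kinetics$k_bond_off <- 2
  p2$run$dt <- 1e-3
  p2$springs$max_extension_AB <- 1e6
  st0 <- init_state(p2, seed = 6)
  for (j in 1:30) st0 <- set_offset(st0, 1, j, c(0, 0))
  for (i in 1:30) st0 <- place_mcda(st0, i, i)
  for (i in 1:30) st0 <- install_bond(st0, i, 1, i)
  set.seed(33)
  lifetimes <- numeric(0)
  for (round in 1:10) {
    st <- st0
    alive <- rep(TRUE, 30)
    steps <- 0L
    while (any(alive) && steps < 20000L) {
      st <- break_bonds(st, p2)
      steps <- steps + 1L
      now <- st$bond_mcda[, 1] > 0
      died <- alive & !now
      lifetimes <- c(lifetimes, rep(steps * p2$run$dt, sum(died)))
      alive <- now
    }
  }
  expect_length(lifetimes, 300)
  se <- sd(lifetimes) / sqrt(length(lifetimes))
  expect_lt(abs(mean(lifetimes) - 1 / p2$kinetics$k_bond_off), 3 * se)
})
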