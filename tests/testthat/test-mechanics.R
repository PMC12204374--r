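test_that("bond force follows Hooke's law toward the anchor", {
  p <- quiet_params(n_mcdA = 2, n_mcdB = 2)
  p$springs$k_AB <- 0.6
  st <- init_state(p, seed = 1)
  st <- set_offset(st, 1, 1, c(0, 0))
  s <- site_at(p, st$carb[1, 1], st$carb[1, 2])
  st <- place_mcda(st, 1, s)
  st <- install_bond(st, 1, 1, 1)
  anchor <- site_pos(p, s)
  # zero extension: site coincident with anchor
  st$carb[1, ] <- anchor
  expect_equal(unname(bond_forces(st, p)[1, ]), c(0, 0))
  # 10 nm extension at 0.6 pN/nm: 6 pN toward the anchor
  st$carb[1, ] <- anchor + c(10, 0)
  expect_equal(unname(bond_forces(st, p)[1, ]), c(-6, 0))
  expect_equal(sqrt(sum(bond_forces(st, p)^2)), 6)
  # two equal and opposite extensions cancel
  st <- set_offset(st, 1, 2, c(0, 0))
  s2 <- site_at(p, anchor[1] + 20, anchor[2])
  st <- place_mcda(st, 2, s2)
  st <- install_bond(st, 2, 1, 2)
  st$carb[1, ] <- (anchor + site_pos(p, s2)) / 2
  expect_equal(unname(bond_forces(st, p)[1, ]), c(0, 0))
})

test_that("self-association spring obeys rest length, cutoff, and symmetry", {
  p <- quiet_params(n_carb = 2)
  p$springs$k_self <- 0.6
  p$springs$self_range <- 300
  st <- init_state(p, seed = 1)
  place_pair <- function(st, r) {
    st$carb[1, ] <- c(400, 250); st$carb[2, ] <- c(400 + r, 250); st
  }
  # at rest length (contact): zero force
  f <- self_association_forces(place_pair(st, 150), p)
  expect_equal(unname(f), matrix(0, 2, 2), ignore_attr = TRUE)
  # r = 250 nm: 0.6 * 100 = 60 pN each, attractive, equal and opposite
  f <- self_association_forces(place_pair(st, 250), p)
  expect_equal(unname(f[1, ]), c(60, 0))
  expect_equal(unname(f[2, ]), c(-60, 0))
  # beyond the cutoff: zero
  f <- self_association_forces(place_pair(st, 350), p)
  expect_equal(unname(f), matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("overdamped displacement has exact drift and hard-core exclusion", {
  p <- quiet_params(n_carb = 2)
  p$kinetics$D_carb <- 1e-3
  st <- init_state(p, seed = 1)
  st$carb[1, ] <- c(300, 250)
  st$carb[2, ] <- c(700, 250)
  # drift velocity F/gamma exactly, noise off
  f <- matrix(c(2, 0, 0, 0), 2, 2)  # 2 pN on carb 1 along x
  mob <- p$kinetics$D_carb * 1e6 / p$kinetics$kBT
  st2 <- displace_carboxysomes(st, f, p, noise = FALSE)
  expect_equal(st2$carb[1, 1] - st$carb[1, 1], 2 * mob * p$run$dt)
  expect_equal(st2$carb[1, 2], st$carb[1, 2])
  expect_equal(st2$carb[2, ], st$carb[2, ])
  # zero force, zero noise: no motion
  st3 <- displace_carboxysomes(st, matrix(0, 2, 2), p, noise = FALSE)
  expect_identical(st3$carb, st$carb)
  # overlapping disks are separated symmetrically to contact
  st$carb[1, ] <- c(500, 250)
  st$carb[2, ] <- c(600, 250)
  st4 <- displace_carboxysomes(st, matrix(0, 2, 2), p, noise = FALSE)
  expect_equal(st4$carb[2, 1] - st4$carb[1, 1], 150)
  expect_equal(st4$carb[1, 1] + st4$carb[2, 1], 1100)  # symmetric push
  # reflection keeps centers inside the domain
  st$carb[1, ] <- c(2, 250)
  st$carb[2, ] <- c(700, 250)
  f5 <- matrix(c(-100, 0, 0, 0), 2, 2)
  st5 <- displace_carboxysomes(st, f5, p, noise = FALSE)
  expect_true(st5$carb[1, 1] >= 0)
})

test_that("carboxysomes never overlap under noisy dynamics", {
  p <- fast_params(duration = 1)
  st <- init_state(p, seed = 21)
  for (i in 1:200) {
    st <- step(st, p)
    d <- sqrt(sum((st$carb[1, ] - st$carb[2, ])^2))
    expect_gte(d, p$geometry$carboxysome_diameter - 1)
  }
})

test_that("self-association forces satisfy Newton's third law under fuzzing", {
  p <- quiet_params(n_carb = 3)
  p$geometry$nucleoid_length <- 2.0
  p$springs$k_self <- 0.6
  st <- init_state(p, seed = 2)
  set.seed(17)
  for (i in 1:200) {
    st$carb[, 1] <- runif(3, 0, 2000)
    st$carb[, 2] <- runif(3, 0, 500)
    expect_true(newton_third_law_check(st, p))
  }
  # negative control: a corrupted force table fails the check
  f <- self_association_forces(st, p)
  f[1, 1] <- f[1, 1] + 1e-6
  expect_false(newton_third_law_check(st, p, forces = f))
})

test_that("tethered bond extension satisfies 2D equipartition", {
  p <- quiet_params(n_mcdA = 1, n_mcdB = 1)
  p$kinetics$D_carb <- 1e-3
  p$springs$k_AB <- 0.5
  p$springs$max_extension_AB <- 1e6
  st <- init_state(p, seed = 13)
  st <- set_offset(st, 1, 1, c(0, 0))
  s <- site_at(p, st$carb[1, 1], st$carb[1, 2])
  st <- place_mcda(st, 1, s)
  st <- install_bond(st, 1, 1, 1)
  anchor <- site_pos(p, s)
  set.seed(29)
  res <- advance_state(st, p, n_steps = 120000, record_every = 100)
  keep <- res$records[, 1] > 0.5
  ext2 <- (res$records[keep, 3] - anchor[1])^2 + (res$records[keep, 4] - anchor[2])^2
  expected <- 2 * p$kinetics$kBT / p$springs$k_AB
  se <- sd(ext2) / sqrt(sum(keep))
  expect_lt(abs(mean(ext2) - expected), 3 * se)
})
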