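test_that("clustered_fraction counts samples within the self-association range", {
  p <- default_params()
  n <- 100
  # both centers constant at contact: always in range
  traj <- make_traj(seq_len(n) * 0.1,
                    cbind(rep(1.0, n), rep(1.15, n)),
                    cbind(rep(0.25, n), rep(0.25, n)))
  expect_equal(clustered_fraction(traj, p), 1.0)
  # constant separation beyond the range: never
  traj2 <- make_traj(seq_len(n) * 0.1,
                     cbind(rep(0.5, n), rep(1.5, n)),
                     cbind(rep(0.25, n), rep(0.25, n)))
  expect_equal(clustered_fraction(traj2, p), 0.0)
  # exactly 30 of 100 samples in range
  x2 <- rep(1.0 + 0.5, n)
  x2[1:30] <- 1.0 + p$springs$self_range / 2000  # within range
  traj3 <- make_traj(seq_len(n) * 0.1, cbind(rep(1.0, n), x2),
                     cbind(rep(0.25, n), rep(0.25, n)))
  expect_equal(clustered_fraction(traj3, p), 0.30)
  # pair statistic: wrong carboxysome count errors
  traj1 <- make_traj(1:2, cbind(c(0, 1)), cbind(c(0, 0)))
  expect_error(clustered_fraction(traj1, p), "2 carboxysomes")
})

test_that("movement range: endpoints, stationarity, and hull/brute agreement", {
  still <- make_traj(1:10, cbind(rep(0.7, 10)), cbind(rep(0.2, 10)))
  expect_equal(movement_range(still), 0)
  line <- make_traj(1:11, cbind(seq(0, 1, 0.1)), cbind(rep(0.2, 11)))
  expect_equal(movement_range(line), 1.0)
  set.seed(123)
  for (rep in 1:5) {
    n <- 200
    walk <- make_traj(seq_len(n),
                      cbind(cumsum(rnorm(n, 0, 0.01)), cumsum(rnorm(n, 0, 0.01))),
                      cbind(cumsum(rnorm(n, 0, 0.01)), cumsum(rnorm(n, 0, 0.01))))
    expect_equal(movement_range(walk, method = "hull"),
                 movement_range(walk, method = "brute"), tolerance = 1e-12)
  }
  # max over carboxysomes: per-carboxysome access
  two <- make_traj(1:2, cbind(c(0, 0.1), c(0, 2)), cbind(c(0, 0), c(0, 0)))
  expect_equal(movement_range(two), 2)
  expect_equal(movement_range(two, per_carboxysome = TRUE), c(0.1, 2))
})

test_that("regime classification matches the threshold rules", {
  p <- default_params()
  L <- p$geometry$nucleoid_length
  mk <- function(cf_target, range_um) {
    n <- 100
    x2 <- rep(1.0 + 0.5, n)                       # out of range
    n_in <- round(cf_target * n)
    if (n_in > 0) x2[1:n_in] <- 1.0 + 0.15        # contact
    x1 <- rep(1.0, n); x1[n] <- 1.0 - range_um    # sets the movement range
    make_traj(seq_len(n) * 0.1, cbind(x1, x2),
              cbind(rep(0.25, n), rep(0.25, n)))
  }
  expect_equal(classify_trajectory(mk(1.0, 0.9 * L), p)$regime, "clustered_diffuse")
  expect_equal(classify_trajectory(mk(1.0, 0.1 * L), p)$regime, "clustered_positioned")
  expect_equal(classify_trajectory(mk(0.2, 0.1 * L), p)$regime, "partitioned_positioned")
  cls4 <- classify_trajectory(mk(0.2, 0.9 * L), p)
  expect_equal(cls4$regime, "partitioned_diffuse")
  expect_equal(cls4$regime3, "partitioned_positioned")  # three-regime fold
  # classification is a pure function: idempotent
  expect_identical(classify_trajectory(mk(0.2, 0.9 * L), p),
                   classify_trajectory(mk(0.2, 0.9 * L), p))
})

test_that("ensembles aggregate votes and are deterministic in the seed schedule", {
  p <- fast_params(duration = 2)
  ens <- run_ensemble(p, base_seed = 100, n = 3)
  expect_equal(ens$n, 3)
  expect_equal(ens$seeds, 100:102)
  expect_equal(sum(ens$regime_votes), 3)
  expect_equal(sum(ens$regime3_votes), 3)
  expect_equal(ens$mean_clustered_fraction, mean(ens$clustered_fractions))
  ens2 <- run_ensemble(p, base_seed = 100, n = 3)
  expect_identical(ens[setdiff(names(ens), "seeds")],
                   ens2[setdiff(names(ens2), "seeds")])
  # n = 1: the majority is that trajectory's (folded) regime
  one <- run_ensemble(p, base_seed = 100, n = 1)
  fold <- ifelse(one$regimes[1] == "partitioned_diffuse",
                 "partitioned_positioned", one$regimes[1])
  expect_equal(one$majority_regime, fold)
})

test_that("phase-diagram sweep follows the grid and its seed schedule", {
  p <- fast_params(duration = 2)
  pd <- sweep_phase_diagram(p, k_self_values = 0.6, k_AB_values = c(0.1, 0.3),
                            n = 2, base_seed = 50)
  expect_equal(nrow(pd$grid), 2)
  expect_equal(pd$grid$k_AB, c(0.1, 0.3))
  expect_equal(pd$grid$k_self, c(0.6, 0.6))
  expect_true(all(pd$grid$votes_clustered_diffuse + pd$grid$votes_clustered_positioned +
                    pd$grid$votes_partitioned_positioned + pd$grid$votes_partitioned_diffuse == 2))
  # a 1x1 grid reduces to run_ensemble with the same seed schedule
  pd1 <- sweep_phase_diagram(p, 0.6, 0.1, n = 2, base_seed = 50)
  p01 <- p; p01$springs$k_AB <- 0.1; p01$springs$k_self <- 0.6
  ens <- run_ensemble(p01, base_seed = 50, n = 2)
  expect_equal(pd1$cells[[1]]$clustered_fractions, ens$clustered_fractions)
  expect_equal(pd1$cells[[1]]$majority_regime, ens$majority_regime)
  # requested grid order is preserved in the cell labels
  pd_swap <- sweep_phase_diagram(p, 0.6, c(0.3, 0.1), n = 2, base_seed = 50)
  expect_equal(pd_swap$grid$k_AB, c(0.3, 0.1))
})

test_that("clustered-fraction curve is deterministic and input-checked", {
  p <- fast_params(duration = 2)
  expect_error(clustered_fraction_curve(p, c(0.3, 0.1), n = 1), "sorted")
  cur <- clustered_fraction_curve(p, c(0.1, 0.3), n = 2, base_seed = 9)
  expect_equal(cur$k_AB, c(0.1, 0.3))
  expect_true(all(cur$mean_clustered_fraction >= 0 & cur$mean_clustered_fraction <= 1))
  cur2 <- clustered_fraction_curve(p, c(0.1, 0.3), n = 2, base_seed = 9)
  expect_identical(cur, cur2)
})
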