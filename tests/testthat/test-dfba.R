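# Engine-level behaviour: uptake kinetics, Euler updates, whole
# trajectories and fed-batch feeding on the toy fixtures.

cfg_products <- sim_config(products = c("EX_p1_e", "EX_p2_e"))

test_that("uptake bounds follow min(availability, Michaelis-Menten)", {
  k <- uptake_kinetics()
  expect_equal(uptake_bound(10, 0.01, 0.1, k),
               min(10 / (0.01 * 0.1), 20 * 10 / (0.05 + 10)))
  expect_equal(uptake_bound(10, 0.01, 0.1, k), 19.9005, tolerance = 1e-4)
  expect_equal(uptake_bound(0.001, 1.0, 0.1, k), 0.01)   # availability-limited
  expect_identical(uptake_bound(0, 0.5, 0.1, k), 0)
  expect_identical(uptake_bound(5, 0, 0.1, k), 0)        # absent species
  ## monotone in S and capped by V_max
  S_grid <- c(0.01, 0.1, 1, 5, 10, 100)
  b <- vapply(S_grid, uptake_bound, numeric(1), X_i = 1e-4, dt = 0.1,
              kinetics = k)
  expect_true(all(diff(b) >= 0))
  expect_true(all(b <= 20))
  ## per-metabolite overrides win
  k2 <- uptake_kinetics(overrides = list(ac_e = list(V_max = 5)))
  expect_equal(uptake_bound(10, 1e-4, 0.1, k2, met_id = "ac_e"),
               5 * 10 / 10.05)
})

test_that("the Euler update matches hand arithmetic and clips at zero", {
  X <- c(sp = 0.01)
  S <- c(glc__D_e = 10)
  P <- matrix(0, 1, 1, dimnames = list("EX_p", "sp"))
  fx <- matrix(-10, 1, 1, dimnames = list("sp", "glc__D_e"))
  up <- advance_state(X, S, P, mu = c(sp = 0), fluxes = fx,
                      product_flux = P, dt = 0.1)
  expect_equal(unname(up$S), 10 - 10 * 0.01 * 0.1)  # 9.99
  ## product accrual P = v_p * X * dt
  up2 <- advance_state(c(sp = 0.5), S, P, mu = c(sp = 0), fluxes = 0 * fx,
                       product_flux = matrix(2, 1, 1), dt = 0.1)
  expect_equal(unname(up2$P[1, 1]), 0.1)
  ## zero fluxes leave the state unchanged
  up3 <- advance_state(X, S, P, mu = c(sp = 0), fluxes = 0 * fx,
                       product_flux = 0 * P, dt = 0.1)
  expect_identical(up3$S, S)
  expect_identical(up3$X, X)
  ## oversubscribed flux is clipped and reported
  up4 <- advance_state(c(sp = 20), S, P, mu = c(sp = 0), fluxes = fx,
                       product_flux = 0 * P, dt = 1)
  expect_equal(unname(up4$S), 0)
  expect_equal(up4$clipped, 190)
  expect_error(advance_state(X, S, P, c(sp = 0), fx, 0 * P, dt = -1),
               "positive")
})

test_that("a community of one is bit-identical to the monoculture run", {
  t1 <- simulate_community(toy_fix$models$toyA, toy_minimal_anaerobic,
                           cfg_products)
  t2 <- simulate_community(list(toy_fix$models$toyA),
                           toy_minimal_anaerobic, cfg_products)
  expect_identical(t1$X, t2$X)
  expect_identical(t1$S, t2$S)
  expect_identical(t1$P, t2$P)
  expect_identical(t1$terminal, t2$terminal)
})

test_that("pool mass balance holds and state stays non-negative", {
  traj <- simulate_community(toy_fix$models[c("toyA", "toyC")],
                             toy_minimal_anaerobic, sim_config())
  nsteps <- dim(traj$exchange_flux)[3]
  predicted <- traj$S[1, ]
  for (s in seq_len(nsteps)) {
    dS <- colSums(traj$exchange_flux[, , s] * traj$X[s, ]) *
      traj$config$dt
    predicted <- predicted + dS
  }
  expect_equal(predicted, traj$S[nsteps + 1, ], tolerance = 1e-6)
  expect_equal(sum(traj$clip_log), 0, tolerance = 1e-6)
  expect_true(all(traj$S >= 0))
  expect_true(all(traj$X >= 0))
  ## abundances sum to one
  expect_equal(sum(traj$terminal$abundance), 1, tolerance = 1e-9)
  ## cumulative products never decrease
  trAB <- simulate_community(toy_fix$models[c("toyA", "toyB")],
                             toy_minimal_anaerobic, cfg_products)
  for (k in seq_along(trAB$products)) {
    for (i in seq_along(trAB$species)) {
      expect_true(all(diff(trAB$P[k, i, ]) >= -1e-12))
    }
  }
})

test_that("ToyA consumes its glucose within the batch and converges under dt refinement", {
  t1 <- simulate_community(toy_fix$models$toyA, toy_minimal_anaerobic,
                           sim_config(dt = 0.1))
  expect_lt(t1$terminal$S["glc__D_e"], 1e-6)
  t2 <- simulate_community(toy_fix$models$toyA, toy_minimal_anaerobic,
                           sim_config(dt = 0.05))
  rel <- abs(t2$terminal$X - t1$terminal$X) / t1$terminal$X
  expect_lt(rel, 0.02)
})

test_that("acetate cross-feeding lets ToyB grow only next to ToyA", {
  trB <- simulate_community(toy_fix$models$toyB, toy_minimal_anaerobic,
                            sim_config())
  expect_equal(unname(trB$terminal$X), 0.01, tolerance = 1e-9)
  trAB <- simulate_community(toy_fix$models[c("toyA", "toyB")],
                             toy_minimal_anaerobic, sim_config())
  expect_gt(trAB$terminal$X["toyB"], trB$terminal$X * 5)
})

test_that("growth_step flags infeasibility while idle species remain feasible", {
  gB <- growth_step(toy_fix$models$toyB, c(EX_ac_e = 0))
  expect_true(gB$feasible)        # zero growth, but the LP is feasible
  expect_equal(gB$mu, 0)
  ## a truly infeasible step: forced flux with closed uptake
  mets <- data.frame(id = c("s_e", "s_c"), compartment = c("e", "c"),
                     formula = NA, stringsAsFactors = FALSE)
  S <- matrix(c(-1, 0, -1, 1, 0, -1), nrow = 2,
              dimnames = list(mets$id, c("EX_s_e", "St", "MAINT")))
  rx <- data.frame(id = colnames(S), lb = c(-10, 0, 1), ub = c(10, 10, 1))
  mm <- metabolic_model("forced", mets, S, rx, objective = "MAINT")
  g <- growth_step(mm, c(EX_s_e = 0))
  expect_false(g$feasible)
  expect_equal(g$mu, 0)
  expect_true(all(g$v == 0))
})

test_that("fed-batch feeding fires on the trigger and restores the target", {
  ## glucose watched in g/L (molar mass 180.156): trigger 0.9 g/L ~ 5 mmol/L
  traj <- simulate_fed_batch(list(toy_fix$models$toyA),
                             toy_minimal_anaerobic,
                             watch_id = "glc__D_e", trigger = 0.9,
                             target = 1.8, config = sim_config(horizon = 8))
  expect_gt(nrow(traj$feed_log), 1)
  mm <- molar_mass("C6H12O6")
  i_feed <- match(traj$feed_log$time, traj$times)
  expect_true(all(abs(traj$S[i_feed, "glc__D_e"] - 1.8 * 1000 / mm) < 1e-9))
  ## total feed bookkeeping: initial + fed - consumed = final
  consumed_by_A <- -sum(traj$exchange_flux[1, "glc__D_e", ] *
                          traj$X[seq_len(dim(traj$exchange_flux)[3]), 1]) *
    traj$config$dt
  final <- traj$S[nrow(traj$S), "glc__D_e"]
  expect_equal(traj$S[1, "glc__D_e"] + sum(traj$feed_log$added_mmol_per_L) -
                 consumed_by_A, final, tolerance = 1e-6)
  ## a trigger that is never reached leaves the run identical to batch
  quiet <- simulate_fed_batch(list(toy_fix$models$toyC),
                              toy_minimal_anaerobic,
                              watch_id = "glc__D_e", trigger = 0.5,
                              target = 1.9, config = sim_config(horizon = 2))
  expect_identical(nrow(quiet$feed_log), 0L)
  batch <- simulate_community(list(toy_fix$models$toyC),
                              toy_minimal_anaerobic,
                              sim_config(horizon = 2))
  expect_identical(quiet$X, batch$X)
  expect_identical(quiet$S, batch$S)
  ## invalid feed rule
  expect_error(simulate_fed_batch(list(toy_fix$models$toyA),
                                  toy_minimal_anaerobic, "glc__D_e",
                                  trigger = 3, target = 1),
               "below the target")
})

test_that("terminal state averages the trailing feasible window", {
  cfg <- sim_config(horizon = 1, averaging_window = 3)
  traj <- simulate_community(toy_fix$models$toyA, toy_minimal_anaerobic,
                             cfg)
  n <- nrow(traj$X)
  expect_equal(unname(traj$terminal$X),
               mean(traj$X[(n - 2):n, 1]), tolerance = 1e-12)
})
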