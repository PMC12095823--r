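# Decision-layer behaviour: metrics, classification, viability,
# cross-feeding and the scans.

test_that("productivity is terminal product over horizon", {
  traj <- list(products = "EX_p1_e",
               terminal = list(P = matrix(0.768, 1, 1,
                                          dimnames = list("EX_p1_e", "a"))),
               config = list(horizon = 12))
  expect_equal(productivity(traj, "EX_p1_e"), 0.064)
  expect_error(productivity(traj, "EX_p9_e"), "not tracked")
  traj$config$horizon <- 24
  expect_equal(productivity(traj, "EX_p1_e"), 0.032)
})

test_that("productivity ratio benchmarks against the best monoculture", {
  r <- productivity_ratio(0.0640, 0, 0.0519)
  expect_equal(r$delta, 0.0121, tolerance = 1e-9)
  expect_equal(r$ratio, 0.2331, tolerance = 1e-3)
  expect_equal(productivity_ratio(0.5, 0.2, 0.1)$ratio, 1.5)
  expect_equal(productivity_ratio(0.3, 0.3, 0.1)$ratio, 0)
  ## scale invariance
  a <- productivity_ratio(0.4, 0.25, 0.1)$ratio
  b <- productivity_ratio(40, 25, 10)$ratio
  expect_equal(a, b)
  ## sentinel and degenerate categories
  expect_identical(productivity_ratio(0.05, 0, 0)$category, "High")
  expect_identical(productivity_ratio(0, 0, 0)$category, "no-production")
})

test_that("interaction signs map onto the six ecological labels", {
  expect_identical(classify_interaction(0.6, 0.3, 1, 1)$label, "parasitism")
  expect_identical(classify_interaction(0.5, 0.5, 1, 1)$label, "neutralism")
  expect_identical(classify_interaction(0.44, 0.44, 1, 1)$label,
                   "competition")
  expect_identical(classify_interaction(0.6, 0.5, 1, 1)$label,
                   "commensalism")
  expect_identical(classify_interaction(0.6, 0.6, 1, 1)$label, "mutualism")
  expect_identical(classify_interaction(0.44, 0.5, 1, 1)$label,
                   "amensalism")
  ## symmetric under swapping the pair (mirrored signs)
  for (case in list(c(0.6, 0.3), c(0.44, 0.5), c(0.7, 0.7))) {
    f <- classify_interaction(case[1], case[2], 1, 1)
    g <- classify_interaction(case[2], case[1], 1, 1)
    expect_identical(f$label, g$label)
    expect_identical(sort(f$signs), sort(g$signs))
  }
  ## a non-growing monoculture is unclassifiable on that side
  expect_identical(classify_interaction(0.5, 0.5, 0, 1)$label, "undefined")
  expect_identical(classify_interaction(0.5, 0.5, 0, 1)$signs[1], "?")
  ## the band is a total function over random inputs
  set.seed(7)
  labs <- replicate(100, classify_interaction(runif(1), runif(1),
                                              runif(1) + 0.1,
                                              runif(1) + 0.1)$label)
  expect_true(all(labs %in% c("competition", "amensalism", "parasitism",
                              "neutralism", "commensalism", "mutualism")))
})

test_that("viability needs both abundance and growth from every member", {
  mk <- function(X, X0) {
    list(species = names(X), terminal = list(X = X, abundance = X / sum(X)),
         initial_biomass = X0)
  }
  t1 <- mk(c(a = 0.30, b = 0.02), c(a = 0.01, b = 0.01))
  v1 <- check_viability(t1)
  expect_false(v1$viable)
  expect_true(any(grepl("abundance:b", v1$failed)))
  t2 <- mk(c(a = 0.30, b = 0.10), c(a = 0.01, b = 0.01))
  expect_true(check_viability(t2)$viable)
  t3 <- mk(c(a = 0.0105, b = 0.0101), c(a = 0.01, b = 0.01))
  v3 <- check_viability(t3)
  expect_false(v3$viable)
  expect_true(all(grepl("growth", v3$failed)))
})

test_that("cross-feeding roles integrate exchange fluxes with correct signs", {
  cfg <- sim_config()
  trAB <- simulate_community(toy_fix$models[c("toyA", "toyB")],
                             toy_minimal_anaerobic, cfg)
  cf <- cross_feeding_roles(trAB)
  ac <- cf$roles[cf$roles$metabolite == "ac_e", ]
  expect_identical(ac$role[ac$species == "toyA"], "Producer")
  expect_identical(ac$role[ac$species == "toyB"], "Consumer")
  expect_true("ac_e" %in% cf$cross_fed)
  ## monoculture: no metabolite can have both roles
  trA <- simulate_community(toy_fix$models["toyA"],
                            toy_minimal_anaerobic, cfg)
  expect_length(cross_feeding_roles(trA)$cross_fed, 0)
  ## a non-growing culture exchanges nothing
  trB <- simulate_community(toy_fix$models["toyB"],
                            toy_minimal_anaerobic, cfg)
  rolesB <- cross_feeding_roles(trB)$roles
  expect_true(all(rolesB$role == "none"))
})

test_that("screen_pairs emits monoculture and pair records with consistent counts", {
  cfg <- sim_config(horizon = 4)
  res <- screen_pairs(toy_fix$models[c("toyA", "toyB")],
                      list(toy_minimal_anaerobic),
                      products = c("EX_p1_e", "EX_p2_e"), config = cfg)
  expect_equal(nrow(res), 6)           # 2 monocultures x 2 + 1 pair x 2
  expect_equal(sum(res$type == "monoculture"), 4)
  expect_equal(sum(res$type == "co-culture"), 2)
  ## monoculture baselines match standalone runs bit for bit
  cfg2 <- cfg; cfg2$products <- c("EX_p1_e", "EX_p2_e")
  solo <- simulate_community(list(toy_fix$models$toyA),
                             toy_minimal_anaerobic, cfg2)
  expect_equal(res$productivity[res$system == "toyA" &
                                  res$product == "EX_p1_e"],
               productivity(solo, "EX_p1_e"))
  ## single model: monoculture records only
  res1 <- screen_pairs(toy_fix$models["toyA"],
                       list(toy_minimal_anaerobic), "EX_p1_e", cfg)
  expect_true(all(res1$type == "monoculture"))
  ## ranking keeps at most `top` rows per product/environment
  rk <- rank_systems(res, top = 2)
  expect_true(all(table(rk$product) <= 2))
})

test_that("obligate-regime flags exclude models from incompatible environments", {
  strict <- toy_fix$models$toyA
  strict$regime <- "anaerobe"
  aerobic <- build_environment("minimal", "aerobic", toy_fix$media_table)
  expect_message(
    res <- screen_pairs(list(strict, toy_fix$models$toyC), list(aerobic),
                        "EX_p1_e", sim_config(horizon = 2)),
    "excluded")
  expect_false("toyA" %in% res$system)
  expect_true(all(res$type == "monoculture"))   # only toyC left, no pairs
})

test_that("inoculum scans split the total inoculum and report coherent tables", {
  cfg <- sim_config(horizon = 6, products = "EX_p1_e")
  ratios <- list(c(0.9, 0.1), c(0.5, 0.5), c(0.1, 0.9))
  tab <- scan_inoculum(toy_fix$models[c("toyA", "toyC")], ratios,
                       total_inoculum = 0.02, toy_minimal_anaerobic,
                       cfg, product_id = "EX_p1_e")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$total_biomass, tab$biomass_A + tab$biomass_B,
               tolerance = 1e-9)
  ab <- do.call(rbind, lapply(strsplit(tab$abundance, ","), as.numeric))
  expect_equal(rowSums(ab), rep(1, 3), tolerance = 0.01)
  expect_equal(ab[, 1], tab$biomass_A / tab$total_biomass,
               tolerance = 0.01)
  ## ToyC's terminal abundance grows with its inoculum share
  expect_true(all(diff(ab[, 2]) > 0))
  expect_error(scan_inoculum(toy_fix$models[c("toyA", "toyC")],
                             list(c(0.6, 0.3)), 0.02,
                             toy_minimal_anaerobic, cfg, "EX_p1_e"),
               "sum to 1")
})

test_that("abundance bookkeeping reproduces Eq-10 style tables", {
  ## printed-table arithmetic: biomasses (0.67, 0.03) give abundances
  ## (0.96, 0.04) at two decimals
  X <- c(0.67, 0.03)
  expect_equal(round(X / sum(X), 2), c(0.96, 0.04))
})

test_that("yield accounting converts mmol to gram ratios", {
  traj <- list(products = "EX_p_e",
               terminal = list(P = matrix(10, 1, 1,
                                          dimnames = list("EX_p_e", "a")),
                               S = c(sub_e = 0)),
               S = matrix(20, 1, 1, dimnames = list(NULL, "sub_e")),
               feed_log = data.frame())
  y <- yield_per_substrate(traj, "EX_p_e", "sub_e",
                           product_mass = 90, substrate_mass = 180)
  expect_equal(y$yield_g_per_g, 0.25)
  expect_equal(y$consumed_mmol_per_L, 20)
  ## nothing consumed: undefined
  traj$terminal$S <- c(sub_e = 20)
  expect_true(is.na(yield_per_substrate(traj, "EX_p_e", "sub_e",
                                        90, 180)$yield_g_per_g))
})

test_that("LHS sensitivity is seed-reproducible and stratified", {
  setup <- toy_saturated_setup()
  s1 <- lhs_sensitivity(setup$models, setup$medium, setup$config,
                        n = 10, seed = 11)
  s2 <- lhs_sensitivity(setup$models, setup$medium, setup$config,
                        n = 10, seed = 11)
  expect_identical(s1$draws, s2$draws)
  expect_identical(s1$coefficients, s2$coefficients)
  expect_equal(nrow(s1$draws), 10)
  ## one draw per stratum per parameter
  strat_v <- floor((s1$draws$V_max - 1) / 49 * 10)
  strat_k <- floor((s1$draws$K_m - 0.01) / 0.99 * 10)
  expect_setequal(pmin(strat_v, 9), 0:9)
  expect_setequal(pmin(strat_k, 9), 0:9)
})
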