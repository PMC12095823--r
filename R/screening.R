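## Screening analytics: productivity metrics, interaction classification,
## viability, cross-feeding roles and the pairwise / inoculum / carbon /
## kinetics-sensitivity scans.

HIGH_RATIO_FLOOR <- 1e-6   # mmol/L/h below which a monoculture counts as
                           # a non-producer for the "High" ratio sentinel

#' System productivity for one product
#'
#' Terminal averaged product concentration (summed over the producing
#' species) divided by the simulation horizon, in mmol/L/h.
#'
#' @param traj a `community_trajectory`.
#' @param product_id tracked product exchange id.
#' @return productivity in mmol/L/h.
#' @export
productivity <- function(traj, product_id) {
  if (!product_id %in% traj$products)
    stop("product '", product_id, "' was not tracked during simulation")
  sum(traj$terminal$P[product_id, ]) / traj$config$horizon
}

#' Productivity gain of a community over its best monoculture
#'
#' The community is benchmarked against the *highest-performing*
#' monoculture: `delta = comm - max(monoA, monoB)` and
#' `ratio = delta / |max(monoA, monoB)|`.  When neither monoculture
#' produces (best monoculture below `1e-6` mmol/L/h) but the community
#' does, the ratio is reported as the `"High"` sentinel category.
#'
#' @param comm community productivity (mmol/L/h).
#' @param monoA,monoB monoculture productivities (mmol/L/h).
#' @return list with `delta`, `ratio` (NA when sentinel or no production),
#'   and `category` (`"ratio"`, `"High"`, or `"no-production"`).
#' @export
productivity_ratio <- function(comm, monoA, monoB) {
  stopifnot(comm >= 0, monoA >= 0, monoB >= 0)
  best <- max(monoA, monoB)
  if (comm == 0 && best == 0)
    return(list(delta = 0, ratio = NA_real_, category = "no-production"))
  if (best < HIGH_RATIO_FLOOR && comm > 10 * HIGH_RATIO_FLOOR)
    return(list(delta = comm - best, ratio = NA_real_, category = "High"))
  list(delta = comm - best, ratio = (comm - best) / abs(best),
       category = "ratio")
}

#' Classify a pairwise interaction
#'
#' Each member's growth measure in co-culture is compared against half its
#' monoculture growth with a relative band of `threshold` (default 10%):
#' above the band is `+`, below is `-`, inside is `0`.  The unordered sign
#' pair maps onto the six ecological interaction types.
#'
#' @param commA,commB growth measure of each member in the co-culture
#'   (default measure: terminal averaged biomass, g/L).
#' @param monoA,monoB monoculture growth measures under identical
#'   conditions; must be positive for a member to be classifiable.
#' @param threshold relative band width, in (0, 1).
#' @return list with `signs` (character pair in `+`/`0`/`-`, or `"?"` when
#'   a monoculture measure is not positive) and `label` (one of
#'   competition, amensalism, parasitism, neutralism, commensalism,
#'   mutualism, or `"undefined"`).
#' @export
classify_interaction <- function(commA, commB, monoA, monoB,
                                 threshold = 0.1) {
  stopifnot(threshold > 0, threshold < 1)
  one_sign <- function(comm, mono) {
    if (!is.finite(mono) || mono <= 0) return("?")
    half <- mono / 2
    if (comm > (1 + threshold) * half) "+"
    else if (comm < (1 - threshold) * half) "-"
    else "0"
  }
  s <- c(one_sign(commA, monoA), one_sign(commB, monoB))
  ord <- c("+" = 1L, "0" = 2L, "-" = 3L, "?" = 4L)
  key <- paste(s[order(ord[s])], collapse = "")
  label <- switch(key,
                  "++" = "mutualism",
                  "+0" = "commensalism",
                  "+-" = "parasitism",
                  "00" = "neutralism",
                  "0-" = "amensalism",
                  "--" = "competition",
                  "undefined")
  list(signs = s, label = label, threshold = threshold)
}

#' Community viability check
#'
#' A community is viable when every member keeps a terminal abundance of at
#' least `min_abundance` and has grown by at least `min_growth` (relative
#' biomass increase) over its inoculum.
#'
#' @param traj a `community_trajectory`.
#' @param min_abundance abundance floor (default 0.1).
#' @param min_growth relative growth floor (default 0.10, i.e. +10%).
#' @return list with `viable`, per-species `abundance` and `growth_fold`
#'   (terminal/inoculum), and `failed` (character vector of failed
#'   criteria).
#' @export
check_viability <- function(traj, min_abundance = 0.1, min_growth = 0.10) {
  ab <- traj$terminal$abundance
  fold <- traj$terminal$X / traj$initial_biomass
  failed <- character(0)
  low_ab <- ab < min_abundance
  if (any(low_ab))
    failed <- c(failed, paste0("abundance:", traj$species[low_ab]))
  low_g <- fold < 1 + min_growth
  if (any(low_g))
    failed <- c(failed, paste0("growth:", traj$species[low_g]))
  list(viable = length(failed) == 0, abundance = ab, growth_fold = fold,
       failed = failed)
}

#' Cross-feeding role table
#'
#' Integrates each species' exchange fluxes over the trajectory
#' (`sum_t v * X * dt`, mmol/L): net positive integrated exchange makes a
#' species a Producer of that metabolite, net negative a Consumer.  A
#' metabolite is a cross-feeding row when at least one Producer and one
#' Consumer coexist.
#'
#' @param traj a `community_trajectory`.
#' @param tolerance absolute mmol/L below which a net exchange counts as
#'   none (default 1e-6).
#' @return list with `roles` (data.frame metabolite/species/role/net) and
#'   `cross_fed` (metabolite ids with both roles present).
#' @export
cross_feeding_roles <- function(traj, tolerance = 1e-6) {
  dt <- traj$config$dt
  nsteps <- dim(traj$exchange_flux)[3]
  net <- matrix(0, length(traj$species), length(traj$pool_ids),
                dimnames = list(traj$species, traj$pool_ids))
  for (s in seq_len(nsteps)) {
    net <- net + traj$exchange_flux[, , s, drop = FALSE][, , 1] *
      traj$X[s, ] * dt
  }
  roles <- expand.grid(species = traj$species, metabolite = traj$pool_ids,
                       stringsAsFactors = FALSE)
  roles$net_mmol_per_L <- mapply(function(sp, met) net[sp, met],
                                 roles$species, roles$metabolite)
  roles$role <- ifelse(roles$net_mmol_per_L > tolerance, "Producer",
                       ifelse(roles$net_mmol_per_L < -tolerance,
                              "Consumer", "none"))
  cross <- vapply(unique(roles$metabolite), function(met) {
    r <- roles$role[roles$metabolite == met]
    any(r == "Producer") && any(r == "Consumer")
  }, logical(1))
  list(roles = roles[, c("metabolite", "species", "role",
                         "net_mmol_per_L")],
       cross_fed = names(cross)[cross])
}

#' Yield of product per substrate consumed
#'
#' Mass yield (g product per g substrate): terminal product concentration
#' times its molar mass over consumed substrate (initial - terminal + any
#' fed amounts) times its molar mass.
#'
#' @param traj a `community_trajectory`.
#' @param product_id tracked product exchange id.
#' @param substrate_id pool metabolite id of the substrate.
#' @param product_mass,substrate_mass molar masses in g/mol (looked up
#'   nowhere: the trajectory does not carry metabolite tables, so they must
#'   be supplied or derivable via [molar_mass()] upstream).
#' @return list with `yield_g_per_g` (NA when no substrate was consumed)
#'   and `consumed_mmol_per_L`.
#' @export
yield_per_substrate <- function(traj, product_id, substrate_id,
                                product_mass, substrate_mass) {
  if (!product_id %in% traj$products)
    stop("product '", product_id, "' was not tracked")
  prod_mmol <- sum(traj$terminal$P[product_id, ])
  fed <- if (nrow(traj$feed_log) > 0)
    sum(traj$feed_log$added_mmol_per_L) else 0
  consumed <- traj$S[1, substrate_id] + fed -
    traj$terminal$S[substrate_id]
  consumed <- unname(consumed)
  if (consumed <= LP_TOL)
    return(list(yield_g_per_g = NA_real_, consumed_mmol_per_L = consumed))
  list(yield_g_per_g = unname((prod_mmol * product_mass) /
                                (consumed * substrate_mass)),
       consumed_mmol_per_L = consumed)
}

## growth measure used by the screening layer for interaction calls
growth_measure <- function(traj, species) traj$terminal$X[species]

#' Screen all pairs (and monocultures) across environments
#'
#' For every unordered model pair and environment, simulates both
#' monocultures and the co-culture under identical configuration and
#' emits, per product: a productivity record, the productivity ratio
#' against the best monoculture, the interaction call and the viability
#' verdict.  Models whose oxygen-regime flag excludes them from an
#' environment (obligate anaerobes from aerobic runs and vice versa) are
#' skipped with a message.
#'
#' @param models list of `metabolic_model`s (>= 1).
#' @param environments list of [medium()] objects.
#' @param products product exchange ids to track.
#' @param config a [sim_config()] (its `products` field is overridden).
#' @return data.frame with one row per (system, environment, product);
#'   co-culture rows carry interaction and viability columns.
#' @export
screen_pairs <- function(models, environments, products,
                         config = sim_config()) {
  config$products <- products
  if (inherits(environments, "medium")) environments <- list(environments)
  records <- list()
  for (env in environments) {
    eligible <- Filter(function(m) {
      ok <- !(m$regime == "anaerobe" && env$oxygen_regime == "aerobic") &&
        !(m$regime == "aerobe" && env$oxygen_regime == "anaerobic")
      if (!ok) message("model '", m$id, "' excluded from ", env$name,
                       " (", m$regime, ")")
      ok
    }, models)
    if (length(eligible) == 0) next
    mono <- lapply(eligible, function(m)
      simulate_community(list(m), env, config))
    names(mono) <- vapply(eligible, `[[`, character(1), "id")
    for (i in seq_along(eligible)) {
      for (k in products) {
        records[[length(records) + 1]] <- data.frame(
          system = names(mono)[i], type = "monoculture",
          environment = env$name, product = k,
          productivity = productivity(mono[[i]], k),
          delta = NA_real_, ratio = NA_real_, ratio_category = NA_character_,
          interaction = NA_character_, viable = NA,
          abundance = "1", stringsAsFactors = FALSE)
      }
    }
    if (length(eligible) >= 2) {
      idx <- utils::combn(length(eligible), 2)
      for (p in seq_len(ncol(idx))) {
        a <- idx[1, p]; b <- idx[2, p]
        co <- simulate_community(eligible[c(a, b)], env, config)
        ia <- classify_interaction(
          growth_measure(co, co$species[1]),
          growth_measure(co, co$species[2]),
          growth_measure(mono[[a]], co$species[1]),
          growth_measure(mono[[b]], co$species[2]))
        vi <- check_viability(co)
        for (k in products) {
          pr <- productivity(co, k)
          rr <- productivity_ratio(pr, productivity(mono[[a]], k),
                                   productivity(mono[[b]], k))
          records[[length(records) + 1]] <- data.frame(
            system = paste(co$species, collapse = "+"),
            type = "co-culture", environment = env$name, product = k,
            productivity = pr, delta = rr$delta, ratio = rr$ratio,
            ratio_category = rr$category, interaction = ia$label,
            viable = vi$viable,
            abundance = paste(sprintf("%.2f", co$terminal$abundance),
                              collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' Rank systems by productivity
#'
#' @param screen data.frame from [screen_pairs()].
#' @param top number of systems reported per (product, environment).
#' @return data.frame of the `top` best systems per product/environment.
#' @export
rank_systems <- function(screen, top = 5) {
  parts <- split(screen, list(screen$environment, screen$product),
                 drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d) {
    d <- d[order(-d$productivity), , drop = FALSE]
    utils::head(d, top)
  }))
  rownames(out) <- NULL
  out
}

#' Inoculum-ratio scan for a pair
#'
#' One simulation per inoculum split `(fA, fB)` of a fixed total inoculum;
#' reports terminal biomasses, total, abundances and the terminal product
#' concentration, mirroring standard inoculum-optimisation tables.
#'
#' @param pair list of two `metabolic_model`s.
#' @param ratios list of numeric pairs `(fA, fB)`, each summing to 1.
#' @param total_inoculum total inoculum, g/L.
#' @param medium a [medium()].
#' @param config a [sim_config()].
#' @param product_id tracked product (must be in `config$products`).
#' @return data.frame with one row per ratio.
#' @export
scan_inoculum <- function(pair, ratios, total_inoculum, medium,
                          config = sim_config(), product_id) {
  stopifnot(length(pair) == 2, total_inoculum > 0)
  has_product <- !missing(product_id)
  rows <- lapply(ratios, function(r) {
    if (abs(sum(r) - 1) > 1e-9)
      stop("inoculum ratio (", paste(r, collapse = ","),
           ") does not sum to 1")
    cfg <- config
    cfg$initial_biomass <- stats::setNames(
      r * total_inoculum, vapply(pair, `[[`, character(1), "id"))
    traj <- simulate_community(pair, medium, cfg)
    data.frame(
      ratio = paste(r, collapse = ","),
      biomass_A = traj$terminal$X[1], biomass_B = traj$terminal$X[2],
      total_biomass = sum(traj$terminal$X),
      abundance = paste(sprintf("%.2f", traj$terminal$abundance),
                        collapse = ","),
      product_mmol_per_L = if (has_product)
        sum(traj$terminal$P[product_id, ]) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Carbon-source scan
#'
#' Replaces the primary carbon source by each candidate in turn (via
#' [swap_carbon_source()]) and screens the given models in the resulting
#' media.
#'
#' @param models list of `metabolic_model`s.
#' @param base_medium a [medium()] containing the primary carbon source.
#' @param carbon_ids candidate carbon source pool ids.
#' @param products tracked products.
#' @param config a [sim_config()].
#' @return data.frame: [screen_pairs()] output with a `carbon` column.
#' @export
scan_carbon_sources <- function(models, base_medium, carbon_ids, products,
                                config = sim_config()) {
  out <- do.call(rbind, lapply(carbon_ids, function(cid) {
    med <- swap_carbon_source(base_medium, cid)
    res <- screen_pairs(models, list(med), products, config)
    if (is.null(res)) return(NULL)
    res$carbon <- cid
    res
  }))
  rownames(out) <- NULL
  out
}

#' Latin-hypercube sensitivity of growth to uptake kinetics
#'
#' Draws `n` stratified (one per stratum and parameter) samples of
#' `(V_max, K_m)` within the given ranges, runs one community simulation
#' per draw, and regresses terminal total community biomass on the raw
#' parameters by ordinary least squares.
#'
#' @param models list of `metabolic_model`s.
#' @param medium a [medium()].
#' @param config a [sim_config()] (its kinetics are overridden per draw).
#' @param V_max_range,K_m_range sampling ranges (defaults [1, 50]
#'   mmol/gDW/h and [0.01, 1] mmol/L).
#' @param n number of draws (default 10, >= 3).
#' @param seed RNG seed for the hypercube (same seed, same draws).
#' @return list with `draws` (data.frame V_max, K_m, biomass),
#'   `coefficients` (raw OLS: intercept, V_max, K_m),
#'   `std_coefficients` (on unit-variance standardised inputs) and
#'   `r_squared`.
#' @export
lhs_sensitivity <- function(models, medium, config = sim_config(),
                            V_max_range = c(1, 50),
                            K_m_range = c(0.01, 1), n = 10, seed = 42) {
  stopifnot(n >= 3)
  set.seed(seed)
  u <- lhs::randomLHS(n, 2)
  vmax <- V_max_range[1] + u[, 1] * diff(V_max_range)
  km <- K_m_range[1] + u[, 2] * diff(K_m_range)
  if (stats::sd(vmax) == 0 || stats::sd(km) == 0)
    stop("degenerate design: all draws equal")
  biomass <- vapply(seq_len(n), function(i) {
    cfg <- config
    cfg$kinetics <- uptake_kinetics(V_max = vmax[i], K_m = km[i])
    traj <- simulate_community(models, medium, cfg)
    sum(traj$terminal$X)
  }, numeric(1))
  draws <- data.frame(V_max = vmax, K_m = km, biomass = biomass)
  fit <- stats::lm(biomass ~ V_max + K_m, data = draws)
  co <- stats::coef(fit)
  ## standardised inputs (response left raw, as in raw-coefficient
  ## reporting); guard the constant-response case
  sy <- stats::sd(biomass)
  std <- c(V_max = unname(co["V_max"]) * stats::sd(vmax),
           K_m = unname(co["K_m"]) * stats::sd(km))
  r2 <- if (sy < 1e-12) 0 else summary(fit)$r.squared
  list(draws = draws,
       coefficients = c(intercept = unname(co[1]),
                        V_max = unname(co["V_max"]),
                        K_m = unname(co["K_m"])),
       std_coefficients = std, r_squared = r2, seed = seed)
}
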