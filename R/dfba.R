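## Dynamic FBA engine: static-optimisation loop for N species over a shared
## extracellular pool, with per-step parsimonious growth LPs and per-step
## product FVA.

#' Substrate uptake kinetics
#'
#' Uniform Michaelis-Menten transport parameters applied to every pool
#' metabolite, with optional per-metabolite overrides.
#'
#' @param V_max maximal transport rate, mmol/gDW/h (default 20).
#' @param K_m half-saturation concentration, mmol/L (default 0.05).
#' @param overrides optional named list: pool id -> list(V_max=, K_m=).
#' @return object of class `uptake_kinetics`.
#' @export
uptake_kinetics <- function(V_max = 20, K_m = 0.05, overrides = list()) {
  stopifnot(V_max > 0, K_m > 0)
  structure(list(V_max = V_max, K_m = K_m, overrides = overrides),
            class = "uptake_kinetics")
}

kin_param <- function(kinetics, met_id, which) {
  ov <- kinetics$overrides[[met_id]]
  if (!is.null(ov) && !is.null(ov[[which]])) ov[[which]] else kinetics[[which]]
}

#' Simulation configuration
#'
#' @param dt Euler step, h (default 0.1).
#' @param horizon batch duration, h (default 12).
#' @param initial_biomass inoculum per species, g/L; scalar (recycled) or
#'   vector named by model id (default 0.01).
#' @param kinetics an [uptake_kinetics()].
#' @param products character vector of product exchange reaction ids
#'   tracked by per-step FVA (e.g. `"EX_p1_e"`).
#' @param fva_growth_fraction biomass retention fraction for product FVA
#'   (default 0.999).
#' @param averaging_window number of trailing feasible time points averaged
#'   into the terminal state (default 5).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.1, horizon = 12, initial_biomass = 0.01,
                       kinetics = uptake_kinetics(),
                       products = character(0),
                       fva_growth_fraction = 0.999,
                       averaging_window = 5) {
  stopifnot(dt > 0, horizon >= dt, all(initial_biomass > 0),
            averaging_window >= 1,
            fva_growth_fraction > 0, fva_growth_fraction <= 1)
  structure(list(dt = dt, horizon = horizon,
                 initial_biomass = initial_biomass, kinetics = kinetics,
                 products = products,
                 fva_growth_fraction = fva_growth_fraction,
                 averaging_window = averaging_window),
            class = "sim_config")
}

#' Per-step substrate uptake bound
#'
#' The uptake limit for one metabolite is the smaller of the availability
#' term (all of `S_j` shared out per gram biomass over one step) and the
#' Michaelis-Menten transport term:
#' `min(S_j / (X_i * dt), V_max * S_j / (K_m + S_j))`.
#'
#' @param S_j extracellular concentration, mmol/L.
#' @param X_i biomass of the consuming species, g/L; a bound of 0 is
#'   returned for an absent species (`X_i = 0`).
#' @param dt step length, h.
#' @param kinetics an [uptake_kinetics()].
#' @param met_id pool metabolite id (for per-metabolite overrides).
#' @return non-negative uptake limit, mmol/gDW/h.
#' @export
uptake_bound <- function(S_j, X_i, dt, kinetics = uptake_kinetics(),
                         met_id = NULL) {
  stopifnot(S_j >= 0, dt > 0)
  if (S_j == 0 || X_i <= 0) return(0)
  vmax <- if (is.null(met_id)) kinetics$V_max else
    kin_param(kinetics, met_id, "V_max")
  km <- if (is.null(met_id)) kinetics$K_m else
    kin_param(kinetics, met_id, "K_m")
  min(S_j / (X_i * dt), vmax * S_j / (km + S_j))
}

#' Parsimonious growth LP for one step
#'
#' Applies per-exchange uptake limits as (negative) lower bounds and solves
#' the parsimonious FBA.  An infeasible LP yields zero growth and zero
#' fluxes with `feasible = FALSE` (the species stays in the pool).
#'
#' @param model a `metabolic_model`.
#' @param uptake_limits named non-negative vector, exchange reaction id ->
#'   maximal uptake (mmol/gDW/h); exchanges not listed get limit 0.
#' @return list with `mu` (1/h), flux vector `v`, and `feasible`.
#' @export
growth_step <- function(model, uptake_limits) {
  b <- step_bounds(model, uptake_limits)
  sol <- pfba(model, b$lb, b$ub)
  if (sol$status != "optimal") {
    list(mu = 0,
         v = stats::setNames(numeric(nrow(model$reactions)),
                             model$reactions$id),
         feasible = FALSE)
  } else {
    list(mu = sol$mu, v = sol$v, feasible = TRUE)
  }
}

## Exchange lower bounds from uptake limits (uptake = negative direction).
step_bounds <- function(model, uptake_limits) {
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  for (ex in model$exchanges) {
    j <- match(ex, model$reactions$id)
    lim <- if (ex %in% names(uptake_limits))
      unname(uptake_limits[[ex]]) else 0
    lb[j] <- max(lb[j], -lim)
  }
  list(lb = lb, ub = ub)
}

#' Maximum product secretion flux at the growth optimum
#'
#' Per-step FVA: maximises the product exchange flux with the biomass flux
#' constrained to at least `growth_fraction * mu`.  Returns 0 when the
#' product exchange is absent from the model or the constrained LP is
#' infeasible.
#'
#' @inheritParams growth_step
#' @param mu the step's growth optimum (from [growth_step()]).
#' @param product_id product exchange reaction id.
#' @param growth_fraction biomass retention fraction (default 0.999).
#' @return maximal product flux, mmol/gDW/h (>= 0).
#' @export
product_fva <- function(model, uptake_limits, mu, product_id,
                        growth_fraction = 0.999) {
  b <- step_bounds(model, uptake_limits)
  res <- fva_max(model, product_id, mu, b$lb, b$ub, growth_fraction)
  max(0, res$flux)
}

#' Forward-Euler state update
#'
#' Applies one step of the static-optimisation scheme: biomass grows as
#' `X * (1 + mu*dt)`, pool concentrations accrue the biomass-weighted
#' exchange fluxes (uptake negative, secretion positive) and are clipped at
#' zero, and cumulative product concentrations accrue
#' `v_p * X * dt` from the FVA fluxes.
#'
#' @param X named biomass vector, g/L.
#' @param S named pool concentration vector, mmol/L.
#' @param P product matrix (products x species), mmol/L.
#' @param mu named growth-rate vector, 1/h.
#' @param fluxes exchange-flux matrix (species x pool ids), mmol/gDW/h.
#' @param product_flux FVA flux matrix (products x species), mmol/gDW/h.
#' @param dt step, h (must be positive).
#' @return list with updated `X`, `S`, `P` and `clipped` (total mmol/L
#'   removed by the non-negativity clip).
#' @export
advance_state <- function(X, S, P, mu, fluxes, product_flux, dt) {
  if (dt <= 0) stop("dt must be positive")
  X_new <- X * (1 + mu * dt)
  dS <- as.vector(X %*% fluxes) * dt
  S_new <- S + dS
  clipped <- -sum(pmin(S_new, 0))
  S_new <- pmax(S_new, 0)
  P_new <- P + product_flux * rep(X * dt, each = nrow(P))
  list(X = X_new, S = S_new, P = P_new, clipped = clipped)
}

#' Simulate a community (or monoculture) batch culture
#'
#' Static-optimisation dynamic FBA: the batch is discretised into steps of
#' `dt`; at each step every species independently solves a parsimonious
#' growth LP against the current shared pool (uptake limits from
#' [uptake_bound()]), product secretion potential is measured by FVA, and
#' the state advances by forward Euler.  No collective community objective
#' exists; interaction emerges from the shared pool.  If aggregate demand
#' for a metabolite exceeds its availability, every claimant's allocation
#' is tightened proportionally to its requested share and its LP re-solved
#' once, conserving pool mass.
#'
#' The terminal state is the mean over the last `averaging_window` feasible
#' time points (steps where at least one species' LP was feasible), and
#' species abundances are terminal biomass fractions.
#'
#' @param models list of `metabolic_model` objects (length 1 = monoculture).
#' @param medium a [medium()].
#' @param config a [sim_config()].
#' @param feed optional fed-batch rule, see [simulate_fed_batch()].
#' @return object of class `community_trajectory`.
#' @export
simulate_community <- function(models, medium, config = sim_config(),
                               feed = NULL) {
  if (inherits(models, "metabolic_model")) models <- list(models)
  nsp <- length(models)
  species <- vapply(models, `[[`, character(1), "id")
  if (anyDuplicated(species)) stop("duplicate model ids")
  nmap <- harmonize_extracellular(models)
  pool_ids <- sort(unique(c(nmap$pool_ids, names(medium$concentrations))))
  npool <- length(pool_ids)

  ## per-species exchange wiring: exchange rxn id -> pool id
  ex_pool <- lapply(models, function(m) {
    loc <- exchange_metabolites(m)           # exchange id -> local met id
    stats::setNames(unname(nmap$maps[[m$id]][loc]), names(loc))
  })

  X0 <- config$initial_biomass
  if (length(X0) == 1) X0 <- rep(X0, nsp)
  if (!is.null(names(X0)) && all(species %in% names(X0))) X0 <- X0[species]
  X <- stats::setNames(as.numeric(X0), species)

  S <- stats::setNames(numeric(npool), pool_ids)
  S[names(medium$concentrations)] <- medium$concentrations

  products <- config$products
  nprod <- length(products)
  P <- matrix(0, nprod, nsp, dimnames = list(products, species))

  dt <- config$dt
  nsteps <- max(1L, round(config$horizon / dt))
  times <- seq(0, by = dt, length.out = nsteps + 1)

  X_rec <- matrix(NA_real_, nsteps + 1, nsp, dimnames = list(NULL, species))
  S_rec <- matrix(NA_real_, nsteps + 1, npool,
                  dimnames = list(NULL, pool_ids))
  P_rec <- array(0, c(nprod, nsp, nsteps + 1),
                 dimnames = list(products, species, NULL))
  feas <- matrix(FALSE, nsteps, nsp, dimnames = list(NULL, species))
  mu_rec <- matrix(0, nsteps, nsp, dimnames = list(NULL, species))
  flux_rec <- array(0, c(nsp, npool, nsteps),
                    dimnames = list(species, pool_ids, NULL))
  X_rec[1, ] <- X
  S_rec[1, ] <- S
  P_rec[, , 1] <- P

  clip_log <- numeric(0)
  feed_log <- data.frame(time = numeric(0), added_mmol_per_L = numeric(0))
  if (!is.null(feed)) feed <- validate_feed(feed, models)

  for (s in seq_len(nsteps)) {
    mu <- stats::setNames(numeric(nsp), species)
    fx <- matrix(0, nsp, npool, dimnames = list(species, pool_ids))
    sols <- vector("list", nsp)
    limits <- vector("list", nsp)
    for (i in seq_len(nsp)) {
      lim <- vapply(ex_pool[[i]], function(pid)
        uptake_bound(S[pid], X[i], dt, config$kinetics, pid), numeric(1))
      limits[[i]] <- lim
      sols[[i]] <- growth_step(models[[i]], lim)
    }

    ## oversubscription passes: each species' availability term uses its
    ## own biomass, so aggregate demand can exceed the pool; claimants are
    ## tightened proportionally to their requested share and re-solved.
    ## Re-solved species may shift demand onto other metabolites, so the
    ## pass repeats (bounds only shrink, so it terminates) until aggregate
    ## demand respects every pool, conserving mass without clipping.
    for (pass in 1:10) {
      demand <- numeric(npool)
      names(demand) <- pool_ids
      for (i in seq_len(nsp)) {
        v_ex <- sols[[i]]$v[names(ex_pool[[i]])]
        up <- pmax(0, -v_ex) * X[i] * dt        # mmol/L claimed this step
        demand[ex_pool[[i]]] <- demand[ex_pool[[i]]] + up
      }
      over <- which(demand > S + LP_TOL)
      if (length(over) == 0) break
      scale <- S[over] / demand[over]
      redo <- logical(nsp)
      for (i in seq_len(nsp)) {
        hit <- ex_pool[[i]] %in% pool_ids[over]
        if (!any(hit)) next
        for (ex in names(ex_pool[[i]])[hit]) {
          pid <- ex_pool[[i]][ex]
          req <- max(0, -sols[[i]]$v[ex])
          if (req > 0) {
            limits[[i]][ex] <- min(limits[[i]][ex], req * scale[pid])
            redo[i] <- TRUE
          }
        }
      }
      if (!any(redo)) break
      for (i in which(redo)) sols[[i]] <- growth_step(models[[i]],
                                                      limits[[i]])
    }

    pflux <- matrix(0, nprod, nsp, dimnames = list(products, species))
    for (i in seq_len(nsp)) {
      mu[i] <- sols[[i]]$mu
      feas[s, i] <- sols[[i]]$feasible
      v_ex <- sols[[i]]$v[names(ex_pool[[i]])]
      fx[i, ex_pool[[i]]] <- fx[i, ex_pool[[i]]] + unname(v_ex)
      if (nprod > 0 && sols[[i]]$feasible) {
        for (k in seq_len(nprod)) {
          pflux[k, i] <- product_fva(models[[i]], limits[[i]], mu[i],
                                     products[k],
                                     config$fva_growth_fraction)
        }
      }
    }
    mu_rec[s, ] <- mu
    flux_rec[, , s] <- fx

    upd <- advance_state(X, S, P, mu, fx, pflux, dt)
    X <- upd$X; S <- upd$S; P <- upd$P
    if (upd$clipped > LP_TOL) clip_log <- c(clip_log,
                                            stats::setNames(upd$clipped,
                                                            times[s + 1]))
    if (!is.null(feed)) {
      conc_gL <- S[feed$watch_id] * feed$molar_mass / 1000
      if (!is.na(conc_gL) && conc_gL < feed$trigger) {
        target_mmol <- feed$target * 1000 / feed$molar_mass
        added <- target_mmol - S[feed$watch_id]
        S[feed$watch_id] <- target_mmol
        feed_log <- rbind(feed_log,
                          data.frame(time = times[s + 1],
                                     added_mmol_per_L = added))
      }
    }
    X_rec[s + 1, ] <- X
    S_rec[s + 1, ] <- S
    P_rec[, , s + 1] <- P
  }

  step_feasible <- apply(feas, 1, any)
  if (!any(step_feasible))
    stop("empty trajectory: no species was ever feasible")

  ## terminal state: mean over the last `averaging_window` feasible points
  ok_states <- which(step_feasible) + 1     # state recorded after each step
  w <- utils::tail(ok_states, config$averaging_window)
  term_X <- colMeans(X_rec[w, , drop = FALSE])
  term_S <- colMeans(S_rec[w, , drop = FALSE])
  term_P <- if (nprod > 0)
    apply(P_rec[, , w, drop = FALSE], c(1, 2), mean) else P
  abund <- if (sum(term_X) > 0) term_X / sum(term_X) else term_X

  structure(
    list(species = species, pool_ids = pool_ids, products = products,
         times = times, X = X_rec, S = S_rec, P = P_rec,
         growth_rates = mu_rec, feasible = feas,
         step_feasible = step_feasible, exchange_flux = flux_rec,
         terminal = list(X = term_X, S = term_S, P = term_P,
                         abundance = abund),
         initial_biomass = stats::setNames(as.numeric(X0), species),
         clip_log = clip_log, feed_log = feed_log,
         medium = medium$name, config = config),
    class = "community_trajectory")
}

#' @export
print.community_trajectory <- function(x, ...) {
  cat(sprintf("<community_trajectory> %s on %s: %.1f h, dt %.3g h\n",
              paste(x$species, collapse = " + "), x$medium,
              max(x$times), x$config$dt))
  cat("  terminal biomass (g/L): ",
      paste(sprintf("%s %.4g", x$species, x$terminal$X), collapse = ", "),
      "\n", sep = "")
  if (length(x$products))
    cat("  terminal product (mmol/L): ",
        paste(sprintf("%s %.4g", x$products, rowSums(x$terminal$P)),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

validate_feed <- function(feed, models) {
  stopifnot(is.list(feed), !is.null(feed$watch_id),
            !is.null(feed$trigger), !is.null(feed$target))
  if (feed$trigger >= feed$target)
    stop("feed trigger (", feed$trigger,
         " g/L) must be below the target (", feed$target, " g/L)")
  if (is.null(feed$molar_mass)) {
    mm <- NA_real_
    for (m in models) {
      i <- match(feed$watch_id, m$metabolites$id)
      if (!is.na(i)) mm <- m$metabolites$molar_mass[i]
      if (!is.na(mm)) break
    }
    if (is.na(mm))
      stop("no molar mass known for feed metabolite '", feed$watch_id, "'")
    feed$molar_mass <- mm
  }
  feed
}

#' Simulate a fed-batch culture
#'
#' Identical to [simulate_community()] except that after each step the
#' watched metabolite's concentration (in g/L, converted via its molar
#' mass) is topped back up to `target` whenever it falls below `trigger`;
#' feed events are time-stamped in the trajectory's `feed_log`.
#'
#' @inheritParams simulate_community
#' @param watch_id pool metabolite id monitored for feeding.
#' @param trigger concentration (g/L) below which feeding fires.
#' @param target concentration (g/L) restored by each feed event; must
#'   exceed `trigger`.
#' @param molar_mass optional g/mol override for the watched metabolite
#'   (default: looked up in the models).
#' @return a `community_trajectory` with a populated `feed_log`.
#' @export
simulate_fed_batch <- function(models, medium, watch_id, trigger, target,
                               config = sim_config(), molar_mass = NULL) {
  simulate_community(models, medium, config,
                     feed = list(watch_id = watch_id, trigger = trigger,
                                 target = target, molar_mass = molar_mass))
}

#' Tidy trajectory export
#'
#' @param traj a `community_trajectory`.
#' @return data.frame with columns `time`, `series` (`biomass`, `pool`, or
#'   `product`), `species`, `variable`, `value`.
#' @export
trajectory_df <- function(traj) {
  tt <- traj$times
  bio <- do.call(rbind, lapply(seq_along(traj$species), function(i)
    data.frame(time = tt, series = "biomass", species = traj$species[i],
               variable = "X", value = traj$X[, i])))
  pool <- do.call(rbind, lapply(seq_along(traj$pool_ids), function(j)
    data.frame(time = tt, series = "pool", species = NA_character_,
               variable = traj$pool_ids[j], value = traj$S[, j])))
  prod <- NULL
  if (length(traj$products) > 0) {
    prod <- do.call(rbind, lapply(seq_along(traj$products), function(k)
      do.call(rbind, lapply(seq_along(traj$species), function(i)
        data.frame(time = tt, series = "product",
                   species = traj$species[i],
                   variable = traj$products[k],
                   value = traj$P[k, i, ])))))
  }
  out <- rbind(bio, pool, prod)
  rownames(out) <- NULL
  out
}
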