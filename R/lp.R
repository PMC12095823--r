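## Linear-programming core: FBA, parsimonious FBA and single-reaction FVA.
##
## All three problems share the feasible region
##   { v : S v = 0,  lb <= v <= ub }
## and are solved with a dense bounded-variable two-phase simplex with
## Bland's anti-cycling rule.  Networks handled here are small (toy
## fixtures, up to a few hundred reactions), where a dense implementation
## with explicit basis re-solves is both fast and numerically transparent.

LP_BIG <- 1000            # conventional "unbounded" flux bound (mmol/gDW/h)
LP_TOL <- 1e-7            # feasibility / optimality tolerance used throughout

#' Solve a bounded linear program
#'
#' Maximises (or minimises) `obj %*% v` subject to `Aeq %*% v = beq` and
#' `lb <= v <= ub`, via a two-phase primal simplex on bounded variables
#' (artificial variables for phase 1, Bland's rule for entering/leaving
#' choices, basic values recomputed from the factorised basis each
#' iteration).
#'
#' @param obj numeric objective vector.
#' @param Aeq,beq equality constraint matrix and right-hand side.
#' @param lb,ub variable bounds; non-finite entries are clamped to
#'   plus/minus `LP_BIG`.
#' @param maximize logical; maximise when `TRUE`.
#' @return list with `status` (`"optimal"`, `"infeasible"` or `"failed"`),
#'   `objective` and the solution vector `v`.
#' @keywords internal
solve_lp <- function(obj, Aeq, beq, lb, ub, maximize = TRUE) {
  n <- length(obj)
  lb <- pmax(lb, -LP_BIG)
  ub <- pmin(ub, LP_BIG)
  if (any(lb > ub + LP_TOL))
    return(list(status = "infeasible", objective = NA_real_, v = rep(0, n)))
  ub <- pmax(ub, lb)
  if (!maximize) obj <- -obj
  A <- as.matrix(Aeq)
  b <- as.vector(beq)
  m <- nrow(A)

  ## augment with artificial variables forming the phase-1 basis
  x_nb <- lb                               # all structural vars at lower bound
  r <- b - as.vector(A %*% x_nb)
  art_sign <- ifelse(r >= 0, 1, -1)
  A_ext <- cbind(A, diag(art_sign, m))
  lb_ext <- c(lb, rep(0, m))
  ub_ext <- c(ub, rep(Inf, m))
  N <- n + m
  basis <- n + seq_len(m)
  at_upper <- rep(FALSE, N)                # nonbasic status of structurals

  run_phase <- function(cvec, basis, at_upper, maxit) {
    repeat_count <- 0
    while (TRUE) {
      B <- A_ext[, basis, drop = FALSE]
      Binv <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Binv)) return(list(status = "failed"))
      nonbasic <- setdiff(seq_len(N), basis)
      xN <- ifelse(at_upper[nonbasic], ub_ext[nonbasic], lb_ext[nonbasic])
      xB <- as.vector(Binv %*% (b - A_ext[, nonbasic, drop = FALSE] %*% xN))
      y <- as.vector(crossprod(Binv, cvec[basis]))
      d <- cvec[nonbasic] - as.vector(crossprod(A_ext[, nonbasic,
                                                      drop = FALSE], y))
      enter_lower <- !at_upper[nonbasic] & d > LP_TOL
      enter_upper <- at_upper[nonbasic] & d < -LP_TOL
      cand <- nonbasic[enter_lower | enter_upper]
      if (length(cand) == 0) {
        xfull <- numeric(N)
        xfull[nonbasic] <- xN
        xfull[basis] <- xB
        return(list(status = "optimal", x = xfull, basis = basis,
                    at_upper = at_upper))
      }
      j <- min(cand)                       # Bland's rule
      dirj <- if (at_upper[j]) -1 else 1   # movement direction of x_j
      w <- as.vector(Binv %*% A_ext[, j])
      step_basic <- dirj * w               # xB changes by -step_basic * t
      tmax <- ub_ext[j] - lb_ext[j]        # bound-to-bound move
      leave <- 0L                          # 0 = bound flip
      leave_to_upper <- FALSE
      for (i in seq_len(m)) {
        if (step_basic[i] > LP_TOL) {
          ti <- (xB[i] - lb_ext[basis[i]]) / step_basic[i]
          if (ti < tmax - LP_TOL ||
              (ti < tmax + LP_TOL && leave > 0L && basis[i] < basis[leave])) {
            tmax <- max(ti, 0); leave <- i; leave_to_upper <- FALSE
          }
        } else if (step_basic[i] < -LP_TOL) {
          ti <- (ub_ext[basis[i]] - xB[i]) / (-step_basic[i])
          if (ti < tmax - LP_TOL ||
              (ti < tmax + LP_TOL && leave > 0L && basis[i] < basis[leave])) {
            tmax <- max(ti, 0); leave <- i; leave_to_upper <- TRUE
          }
        }
      }
      if (!is.finite(tmax)) return(list(status = "unbounded"))
      if (leave == 0L) {
        at_upper[j] <- !at_upper[j]        # bound-to-bound flip
      } else {
        old <- basis[leave]
        at_upper[old] <- leave_to_upper
        basis[leave] <- j
        at_upper[j] <- FALSE               # basic vars carry explicit values
      }
      repeat_count <- repeat_count + 1
      if (repeat_count > maxit) return(list(status = "failed"))
    }
  }

  maxit <- 200 + 50 * N
  ## phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(-1, m))
  p1 <- run_phase(c1, basis, at_upper, maxit)
  if (p1$status != "optimal")
    return(list(status = "failed", objective = NA_real_, v = rep(0, n)))
  if (sum(p1$x[n + seq_len(m)]) > 1e-6)
    return(list(status = "infeasible", objective = NA_real_, v = rep(0, n)))
  ## phase 2: real objective, artificials pinned at zero
  ub_ext <- c(ub, rep(0, m))
  c2 <- c(obj, rep(0, m))
  p2 <- run_phase(c2, p1$basis, p1$at_upper, maxit)
  if (p2$status == "unbounded")
    return(list(status = "failed", objective = NA_real_, v = rep(0, n)))
  if (p2$status != "optimal")
    return(list(status = "failed", objective = NA_real_, v = rep(0, n)))
  v <- p2$x[seq_len(n)]
  val <- sum(obj * v)
  list(status = "optimal", objective = if (maximize) val else -val, v = v)
}

## Objective indicator vector for a model's biomass reaction.
objective_vector <- function(model) {
  c_vec <- numeric(nrow(model$reactions))
  c_vec[match(model$objective, model$reactions$id)] <- 1
  c_vec
}

#' Flux balance analysis
#'
#' Maximises the biomass objective over the steady-state flux polytope
#' `{S v = 0, lb <= v <= ub}`.
#'
#' @param model a `metabolic_model`.
#' @param lb,ub optional replacement bound vectors (defaults: the model's).
#' @return list with `status`, `mu` (objective optimum, 0 when infeasible)
#'   and flux vector `v` (named by reaction id).
#' @export
fba <- function(model, lb = NULL, ub = NULL) {
  if (is.null(lb)) lb <- model$reactions$lb
  if (is.null(ub)) ub <- model$reactions$ub
  sol <- solve_lp(objective_vector(model), model$stoichiometry,
                  rep(0, nrow(model$stoichiometry)), lb, ub)
  v <- sol$v
  names(v) <- model$reactions$id
  mu <- if (sol$status == "optimal") max(0, sol$objective) else 0
  list(status = sol$status, mu = mu, v = v)
}

#' Parsimonious flux balance analysis
#'
#' Two-stage LP: first the biomass optimum `mu` is found, then total
#' absolute flux is minimised with biomass held at `mu` (split-variable
#' formulation `v = p - q`).  The parsimonious solution removes degenerate
#' flux loops so that secreted amounts entering the shared pool are
#' well-defined.
#'
#' @inheritParams fba
#' @return list with `status` (`"optimal"` or `"infeasible"`), `mu` and
#'   parsimonious flux vector `v`.
#' @export
pfba <- function(model, lb = NULL, ub = NULL) {
  if (is.null(lb)) lb <- model$reactions$lb
  if (is.null(ub)) ub <- model$reactions$ub
  first <- fba(model, lb, ub)
  if (first$status != "optimal") {
    return(list(status = first$status, mu = 0,
                v = stats::setNames(numeric(length(lb)), model$reactions$id)))
  }
  mu <- first$mu
  n <- length(lb)
  S <- model$stoichiometry
  ## pin the biomass flux (tiny slack guards simplex round-off)
  i_obj <- match(model$objective, model$reactions$id)
  lb2 <- lb
  lb2[i_obj] <- max(lb[i_obj], mu - 1e-8)
  ## split v = p - q: positive part p in [max(lb,0), max(ub,0)], negative
  ## part q in [max(-ub,0), max(-lb,0)] encodes lb <= p - q <= ub for
  ## every sign pattern of (lb, ub)
  Ssplit <- cbind(S, -S)
  lb2c <- pmax(lb2, -LP_BIG); ubc <- pmin(ub, LP_BIG)
  lbp <- pmax(lb2c, 0); ubp <- pmax(ubc, 0)
  lbq <- pmax(-ubc, 0); ubq <- pmax(-lb2c, 0)
  sol <- solve_lp(obj = rep(-1, 2 * n), Aeq = Ssplit,
                  beq = rep(0, nrow(S)),
                  lb = c(lbp, lbq), ub = c(ubp, ubq),
                  maximize = TRUE)
  if (sol$status != "optimal") {
    ## fall back to the plain FBA solution rather than failing the step
    return(list(status = "optimal", mu = mu, v = first$v))
  }
  v <- sol$v[seq_len(n)] - sol$v[n + seq_len(n)]
  names(v) <- model$reactions$id
  list(status = "optimal", mu = mu, v = v)
}

#' Maximum flux of one reaction near the growth optimum
#'
#' Flux variability analysis restricted to a single (product exchange)
#' reaction: maximises `v[reaction]` subject to the stoichiometric
#' constraints, the supplied bounds, and biomass flux at or above
#' `growth_fraction * mu`.
#'
#' @inheritParams fba
#' @param reaction_id reaction whose flux is maximised; if absent from the
#'   model the function returns 0.
#' @param mu biomass optimum of the current step.
#' @param growth_fraction fraction of `mu` the biomass flux must retain
#'   (default 0.999).
#' @return list with `flux` (0 when the constrained problem is infeasible or
#'   the reaction is absent) and `status`.
#' @export
fva_max <- function(model, reaction_id, mu, lb = NULL, ub = NULL,
                    growth_fraction = 0.999) {
  idx <- match(reaction_id, model$reactions$id)
  if (is.na(idx)) return(list(flux = 0, status = "absent"))
  if (is.null(lb)) lb <- model$reactions$lb
  if (is.null(ub)) ub <- model$reactions$ub
  i_obj <- match(model$objective, model$reactions$id)
  lb2 <- lb
  lb2[i_obj] <- max(lb[i_obj], growth_fraction * mu - 1e-9)
  obj <- numeric(length(lb))
  obj[idx] <- 1
  sol <- solve_lp(obj, model$stoichiometry,
                  rep(0, nrow(model$stoichiometry)), lb2, ub)
  if (sol$status != "optimal") return(list(flux = 0, status = sol$status))
  list(flux = sol$objective, status = "optimal")
}
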