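# Independent brute-force LP oracle: enumerates every basic solution of
# { S v = 0, lb <= v <= ub } (basis columns solved against non-basic
# variables pinned at a bound) and reports the feasible vertices.  Only
# usable on tiny fixture networks; deliberately independent of the
# package's simplex.

enumerate_vertices <- function(S, lb, ub, big = 1000) {
  lb <- pmax(lb, -big)
  ub <- pmin(ub, big)
  m <- nrow(S)
  n <- ncol(S)
  stopifnot(n >= m)
  verts <- list()
  for (basis in utils::combn(n, m, simplify = FALSE)) {
    nonb <- setdiff(seq_len(n), basis)
    SB <- S[, basis, drop = FALSE]
    if (abs(det(SB)) < 1e-10) next
    k <- length(nonb)
    for (mask in seq_len(2^k) - 1) {
      at_ub <- as.logical(bitwAnd(rep(mask, k), 2^(seq_len(k) - 1)))
      xN <- ifelse(at_ub, ub[nonb], lb[nonb])
      rhs <- -S[, nonb, drop = FALSE] %*% xN
      xB <- tryCatch(solve(SB, rhs), error = function(e) NULL)
      if (is.null(xB)) next
      v <- numeric(n)
      v[nonb] <- xN
      v[basis] <- xB
      if (all(v >= lb - 1e-7) && all(v <= ub + 1e-7)) {
        verts[[length(verts) + 1]] <- v
      }
    }
  }
  verts
}

# Maximum of obj over the vertex set (the LP optimum when the polytope is
# bounded, which clamped bounds guarantee).
oracle_lp_max <- function(obj, S, lb, ub) {
  verts <- enumerate_vertices(S, lb, ub)
  if (length(verts) == 0) return(NULL)
  vals <- vapply(verts, function(v) sum(obj * v), numeric(1))
  list(value = max(vals), vertex = verts[[which.max(vals)]], all = verts,
       values = vals)
}

# Bounds with uptake limits applied the way the engine applies them.
bounds_with_uptake <- function(model, limits) {
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  for (ex in model$exchanges) {
    j <- match(ex, model$reactions$id)
    lim <- if (ex %in% names(limits)) unname(limits[[ex]]) else 0
    lb[j] <- max(lb[j], -lim)
  }
  list(lb = lb, ub = ub)
}

# Shared fixtures used across test files.
toy_fix <- generate_toy_community(1)
toy_minimal_anaerobic <- build_environment("minimal", "anaerobic",
                                           toy_fix$media_table)
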