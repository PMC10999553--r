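# Brute-force LP oracle by vertex enumeration. Independent of the simplex
# back-end: candidate vertices are built by pinning subsets of variables at
# their bounds and solving the steady-state equations directly, so the
# generators can plant ground truth that does not trust the LP engine.

#' Enumerate the vertices of a flux polytope
#'
#' The feasible set `{v : S v = 0, lb <= v <= ub}` is a bounded polytope.
#' Every vertex has at least `n - rank(S)` variables at a bound; all
#' candidate pinnings are enumerated, each remaining linear system solved
#' directly, and feasible unique solutions collected. Exponential in the
#' number of reactions — intended for networks of at most ~10 reactions.
#'
#' @param S stoichiometric matrix (metabolites x reactions)
#' @param lb,ub flux bounds
#' @param tol feasibility tolerance
#' @return matrix with one vertex per row (possibly 0 rows)
#' @export
enumerate_flux_vertices <- function(S, lb, ub, tol = 1e-8) {
  n <- ncol(S)
  r <- qr(S)$rank
  nfree <- n - r
  verts <- list()
  add_vertex <- function(v) {
    for (w in verts) if (max(abs(w - v)) < 1e-7) return(invisible())
    verts[[length(verts) + 1L]] <<- v
  }
  if (nfree == 0L) {
    sets <- list(integer())
  } else {
    sets <- utils::combn(n, nfree, simplify = FALSE)
  }
  for (J in sets) {
    k <- length(J)
    picks <- if (k == 0L) list(numeric()) else {
      grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))
      lapply(seq_len(nrow(grid)), function(i) {
        ifelse(unlist(grid[i, ]), ub[J], lb[J])
      })
    }
    for (vals in picks) {
      E <- matrix(0, k, n)
      if (k) E[cbind(seq_len(k), J)] <- 1
      A <- rbind(S, E)
      b <- c(rep(0, nrow(S)), vals)
      qa <- qr(A)
      if (qa$rank < n) next  # pinning does not determine a unique point
      v <- tryCatch(qr.coef(qr(crossprod(A)), crossprod(A, b)),
                    error = function(e) NULL)
      if (is.null(v) || anyNA(v)) next
      v <- as.vector(v)
      if (max(abs(A %*% v - b)) > tol) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      add_vertex(pmin(pmax(v, lb), ub))
    }
  }
  if (!length(verts)) return(matrix(numeric(), 0, n))
  do.call(rbind, verts)
}

#' Brute-force FBA objective by vertex enumeration
#'
#' Oracle counterpart of [fba()] for tiny networks: the LP optimum is the
#' best vertex of the flux polytope.
#'
#' @param model a `metabolic_model` with few (<= ~10) reactions
#' @param objective reaction id; default the model objective
#' @param direction `"max"` or `"min"`
#' @return list with `objective_value` and `vertex` (a flux vector), or
#'   `NULL` when the polytope is empty
#' @export
oracle_fba <- function(model, objective = model$objective,
                       direction = c("max", "min")) {
  direction <- match.arg(direction)
  S <- stoichiometric_matrix(model)
  V <- enumerate_flux_vertices(S, model$reactions$lower_bound,
                               model$reactions$upper_bound)
  if (nrow(V) == 0) return(NULL)
  j <- match(objective, model$reactions$id)
  i <- if (direction == "max") which.max(V[, j]) else which.min(V[, j])
  list(objective_value = V[i, j],
       vertex = stats::setNames(V[i, ], model$reactions$id))
}

#' Brute-force blocked-reaction oracle
#'
#' A reaction is blocked iff its flux is zero at every vertex of the
#' polytope (with exchanges opened, as in [find_blocked_reactions()]).
#'
#' @inheritParams oracle_fba
#' @param open_exchanges open exchange bounds first (default `TRUE`)
#' @param tol zero tolerance
#' @return character vector of blocked reaction ids (all classes)
#' @export
oracle_blocked <- function(model, open_exchanges = TRUE, tol = 1e-7) {
  if (open_exchanges) {
    ex <- reactions_of_class(model, "exchange")
    if (length(ex)) model <- set_bounds(model, ex, lower = -BIG_BOUND, upper = BIG_BOUND)
  }
  S <- stoichiometric_matrix(model)
  V <- enumerate_flux_vertices(S, model$reactions$lower_bound,
                               model$reactions$upper_bound)
  if (nrow(V) == 0) return(model$reactions$id)
  blocked <- apply(abs(V) <= tol, 2, all)
  model$reactions$id[blocked]
}
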