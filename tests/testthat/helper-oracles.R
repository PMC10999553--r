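# Independent oracles used across the suite. These never call the code
# paths they check: GPR truth via R's own boolean evaluator, LP via the
# vertex enumerator, MOMA via exhaustive active-set enumeration.

# Evaluate a GPR *string* with R's parser: gene ids are substituted by
# logical literals and the expression evaluated after mapping and/or to
# &/|. Independent of parse_gpr/evaluate_gpr.
oracle_gpr_eval <- function(text, states) {
  expr <- text
  for (g in names(states)) {
    expr <- gsub(paste0("\\b", g, "\\b"), as.character(states[[g]]), expr)
  }
  expr <- gsub("\\band\\b", "&", expr, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "|", expr, ignore.case = TRUE)
  eval(parse(text = expr))
}

# All 2^k gene-state assignments for gene set `genes`.
gene_state_grid <- function(genes) {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(genes)))
  names(grid) <- genes
  grid
}

# Exhaustive MOMA oracle: enumerate every active-set pattern (each
# variable free / at lb / at ub), solve the equality-constrained
# projection on the free block, and keep the feasible candidate with the
# smallest distance. Exponential (3^n); fixtures stay tiny.
oracle_moma <- function(model, ref, tol = 1e-7) {
  S <- stoichiometric_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  n <- length(lb)
  ref <- ref[model$reactions$id]
  best <- NULL; best_d <- Inf
  patterns <- expand.grid(rep(list(0:2), n))  # 0 free, 1 at lb, 2 at ub
  for (i in seq_len(nrow(patterns))) {
    p <- unlist(patterns[i, ])
    fixed <- which(p > 0)
    free <- which(p == 0)
    vfix <- ifelse(p[fixed] == 1, lb[fixed], ub[fixed])
    rhs <- if (length(fixed)) -as.vector(S[, fixed, drop = FALSE] %*% vfix) else rep(0, nrow(S))
    Sf <- S[, free, drop = FALSE]
    # project ref_free onto {Sf vf = rhs} (least-squares KKT via pseudo-inverse)
    G <- Sf %*% t(Sf)
    h <- as.vector(Sf %*% ref[free]) - rhs
    lam <- tryCatch(qr.coef(qr(G, tol = 1e-10), h), error = function(e) NULL)
    if (is.null(lam)) next
    lam[is.na(lam)] <- 0
    vf <- ref[free] - as.vector(t(Sf) %*% lam)
    v <- numeric(n); v[fixed] <- vfix; v[free] <- vf
    if (max(abs(S %*% v)) > tol) next
    if (any(v < lb - tol) || any(v > ub + tol)) next
    d <- sum((v - ref)^2)
    if (d < best_d - 1e-12) { best_d <- d; best <- v }
  }
  if (is.null(best)) return(NULL)
  list(x = stats::setNames(best, model$reactions$id), distance_sq = best_d)
}

# Seeded random small networks for LP property tests: always feasible
# (zero flux allowed) and bounded.
make_random_network <- function(seed) {
  set.seed(seed)
  n_met <- sample(2:4, 1)
  n_rxn <- sample(4:7, 1)
  mids <- paste0("m", seq_len(n_met))
  rids <- paste0("r", seq_len(n_rxn))
  mets <- data.frame(id = mids, name = mids, formula = "",
                     charge = NA_integer_, compartment = "c",
                     stringsAsFactors = FALSE)
  st <- lapply(seq_len(n_rxn), function(j) {
    k <- sample(1:min(3, n_met), 1)
    who <- sample(mids, k)
    stats::setNames(sample(c(-2, -1, 1, 2), k, replace = TRUE), who)
  })
  lb <- sample(c(-10, -5, 0), n_rxn, replace = TRUE)
  ub <- sample(c(0, 5, 10), n_rxn, replace = TRUE)
  ub <- pmax(ub, lb)
  rxns <- data.frame(id = rids, name = rids, lower_bound = lb, upper_bound = ub,
                     subsystem = "", class = NA_character_,
                     stringsAsFactors = FALSE)
  rxns$stoichiometry <- I(st)
  rxns$gpr <- I(rep(list(NULL), n_rxn))
  suppressWarnings(
    metabolic_model(paste0("rand", seed), mets, rxns, genes = character(),
                    objective = sample(rids, 1))
  )
}
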