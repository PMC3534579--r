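# Linear programming over steady-state flux spaces. Fluxes are shifted
# to nonnegative variables x = v - lb: equality rows S x = -S lb keep
# the steady state, slack rows x + s = ub - lb cap capacities, and the
# optional FVA optimality constraint gets a surplus variable. All model
# bounds are finite, so the LP is never unbounded.

solveLP <- function(S, lb, ub, obj, maximise = TRUE,
                    extraRow = NULL, extraRhs = NULL) {
  n <- length(lb)
  S <- as.matrix(S)
  b3 <- as.numeric(-S %*% lb)
  # all-zero rows (metabolites touched by no reaction) carry no
  # constraint; a nonzero RHS on one would be an inconsistency
  zero <- rowSums(abs(S)) == 0
  if (any(zero)) {
    if (any(abs(b3[zero]) > 1e-9))
      return(list(status = "infeasible", fluxes = NULL,
                  objective = NA_real_))
    S <- S[!zero, , drop = FALSE]
    b3 <- b3[!zero]
  }
  # reduce to a linearly independent set of equality rows; dependent
  # rows must be consistent with the kept ones, else the system has
  # no solution at all
  if (nrow(S) > 1L) {
    qt <- qr(t(S))
    if (qt$rank < nrow(S)) {
      aug <- qr(t(cbind(S, b3)))
      if (aug$rank > qt$rank)
        return(list(status = "infeasible", fluxes = NULL,
                    objective = NA_real_))
      keep <- sort(qt$pivot[seq_len(qt$rank)])
      S <- S[keep, , drop = FALSE]
      b3 <- b3[keep]
    }
  }
  if (nrow(S) == 0L) {
    # box-constrained: optimum at the bound matching the sense
    v <- ifelse(if (maximise) obj > 0 else obj < 0, ub, lb)
    v[obj == 0] <- lb[obj == 0]
    return(list(status = "optimal", fluxes = v, objective = sum(obj * v)))
  }
  # simplex() copes with signed RHS, but normalising equalities keeps
  # the tableau well scaled
  neg <- b3 < 0
  if (any(neg)) {
    S[neg, ] <- -S[neg, , drop = FALSE]
    b3[neg] <- -b3[neg]
  }
  # standard form: z = [x, slacks, surplus]; rows = equalities,
  # capacity rows x_i + s_i = ub_i - lb_i, optional extra >= row
  mS <- nrow(S)
  extra <- !is.null(extraRow)
  N <- 2L * n + as.integer(extra)
  A <- matrix(0, mS + n + as.integer(extra), N)
  bvec <- numeric(nrow(A))
  if (mS) {
    A[seq_len(mS), seq_len(n)] <- S
    bvec[seq_len(mS)] <- b3
  }
  A[mS + seq_len(n), seq_len(n)] <- diag(n)
  A[mS + seq_len(n), n + seq_len(n)] <- diag(n)
  bvec[mS + seq_len(n)] <- ub - lb
  if (extra) {
    A[mS + n + 1L, seq_len(n)] <- extraRow
    A[mS + n + 1L, N] <- -1
    bvec[mS + n + 1L] <- extraRhs - sum(extraRow * lb)
  }
  cost <- c(obj, numeric(N - n))
  res <- simplexStandard(A, bvec, cost, maximise = maximise)
  if (res$status != "optimal") {
    return(list(status = res$status, fluxes = NULL, objective = NA_real_))
  }
  v <- res$x[seq_len(n)] + lb
  list(status = "optimal", fluxes = v, objective = sum(obj * v))
}

#' Flux balance analysis
#'
#' Maximises (or minimises) the flux of one reaction over the
#' steady-state flux polytope \eqn{\{v : S v = 0, lb \le v \le ub\}},
#' where the steady-state constraint covers non-boundary metabolites
#' only.
#'
#' @param model a [MetabolicModel-class].
#' @param reaction id of the objective reaction.
#' @param sense \code{"max"} (default) or \code{"min"}.
#' @return list with \code{fluxes} (named numeric, one flux per
#'   reaction), \code{objective} (the optimum) and \code{reaction}.
#' @examples
#' toy <- makeToyNetwork(1, 2, 0, 0, seed = 1)$model
#' fba(toy, reactions(toy)$id[1])$objective
#' @seealso [fva()], [maxProduction()]
#' @export
fba <- function(model, reaction, sense = c("max", "min")) {
  sense <- match.arg(sense)
  ri <- model@rxnInfo
  j <- match(reaction, ri$id)
  if (is.na(j)) stop("unknown reaction: ", reaction)
  S <- model@stoich[!model@metInfo$boundary, , drop = FALSE]
  obj <- numeric(nrow(ri)); obj[j] <- 1
  sol <- solveLP(S, ri$lb, ri$ub, obj, maximise = (sense == "max"))
  if (sol$status == "infeasible")
    stop("infeasible: no steady-state flux distribution satisfies the bounds")
  if (sol$status != "optimal")
    stop("LP solver failed (", sol$status, ") for objective ", reaction)
  v <- sol$fluxes
  names(v) <- ri$id
  res <- abs(as.numeric(S %*% v))
  if (length(res) && max(res) > 1e-6)
    stop("steady-state residual above tolerance for objective ", reaction)
  list(fluxes = v, objective = sol$objective, reaction = reaction)
}

#' Flux variability analysis
#'
#' For each reaction, computes the minimal and maximal steady-state
#' flux subject to the bounds and to the objective reaction attaining
#' at least \code{optimalityFraction} of its FBA optimum. With the
#' default fraction 0 the envelope describes the whole flux space
#' reachable while the production objective is merely available — the
#' setting used to establish per-reaction flux boundaries for the
#' knockdown scan.
#'
#' @param model a [MetabolicModel-class].
#' @param reaction id of the objective reaction.
#' @param optimalityFraction fraction of the optimum enforced
#'   (in \code{[0, 1]}; default 0).
#' @param reactions optional character vector restricting which
#'   reactions are ranged (default: all).
#' @return a [FluxEnvelope-class].
#' @examples
#' toy <- makeToyNetwork(1, 2, 0, 0, seed = 1)$model
#' fva(toy, reactions(toy)$id[1], optimalityFraction = 1)
#' @seealso [fba()], [applyKnockdown()]
#' @export
fva <- function(model, reaction, optimalityFraction = 0, reactions = NULL) {
  stopifnot(optimalityFraction >= 0, optimalityFraction <= 1)
  ri <- model@rxnInfo
  if (is.null(reactions)) reactions <- ri$id
  miss <- setdiff(reactions, ri$id)
  if (length(miss)) stop("unknown reactions: ", paste(miss, collapse = ", "))
  opt <- fba(model, reaction)$objective
  S <- model@stoich[!model@metInfo$boundary, , drop = FALSE]
  jobj <- match(reaction, ri$id)
  row <- numeric(nrow(ri)); row[jobj] <- 1
  rng <- matrix(NA_real_, nrow = length(reactions), ncol = 2,
                dimnames = list(reactions, c("min", "max")))
  for (r in reactions) {
    j <- match(r, ri$id)
    obj <- numeric(nrow(ri)); obj[j] <- 1
    lo <- solveLP(S, ri$lb, ri$ub, obj, maximise = FALSE,
                  extraRow = row, extraRhs = optimalityFraction * opt)
    hi <- solveLP(S, ri$lb, ri$ub, obj, maximise = TRUE,
                  extraRow = row, extraRhs = optimalityFraction * opt)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem failed for reaction ", r)
    rng[r, ] <- c(lo$objective, hi$objective)
  }
  # clip solver noise so min <= max exactly
  flip <- rng[, "min"] > rng[, "max"]
  if (any(flip)) {
    mid <- rowMeans(rng[flip, , drop = FALSE])
    rng[flip, "min"] <- mid; rng[flip, "max"] <- mid
  }
  new("FluxEnvelope", ranges = rng, objective = reaction, optimum = opt,
      optimalityFraction = optimalityFraction)
}

#' Maximal production rate of a metabolite
#'
#' The FBA optimum of the single-metabolite export objective created
#' (or reused) by [addProductionObjective()]: the fastest rate at
#' which the network can synthesise the metabolite at steady state.
#'
#' @param model a [MetabolicModel-class].
#' @param met id of a non-boundary metabolite.
#' @return nonnegative numeric scalar.
#' @examples
#' toy <- makeToyNetwork(1, 3, 0, 0, seed = 1)$model
#' maxProduction(toy, metabolites(toy)$id[2])
#' @seealso [geneImpact()]
#' @export
maxProduction <- function(model, met) {
  po <- addProductionObjective(model, met)
  val <- fba(po$model, po$reaction)$objective
  max(val, 0)
}

#' Export a flux envelope as a TSV table
#'
#' @param envelope a [FluxEnvelope-class].
#' @param path output file.
#' @return invisibly, the written data.frame.
#' @export
writeEnvelope <- function(envelope, path) {
  d <- data.frame(reaction = rownames(envelope@ranges),
                  vmin = envelope@ranges[, "min"],
                  vmax = envelope@ranges[, "max"])
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(d)
}
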