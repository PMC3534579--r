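# Two-phase primal simplex with Bland's anti-cycling rule, for the
# small dense LPs of desk-scale flux analysis. Standard form:
# max c'z subject to A z = b, z >= 0 (b is sign-normalised here).
# Bland's rule trades speed for guaranteed termination, which is the
# right trade at these problem sizes.

simplexStandard <- function(A, b, cost, maximise = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  if (!maximise) cost <- -cost

  # phase 1: artificial basis, minimise artificial sum
  Tb <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  phaseCost <- c(numeric(n), rep(1, m))
  runSimplex <- function(Tb, basis, cvec, ncols) {
    repeat {
      cb <- cvec[basis]
      # reduced costs (minimisation): c_j - cb' B^{-1} A_j; tableau is
      # already B^{-1}[A | b]
      red <- cvec[seq_len(ncols)] -
        as.numeric(crossprod(cb, Tb[, seq_len(ncols), drop = FALSE]))
      ent <- which(red < -tol)
      if (!length(ent)) return(list(Tb = Tb, basis = basis,
                                    status = "optimal"))
      j <- min(ent)                        # Bland: smallest index
      col <- Tb[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(Tb = Tb, basis = basis,
                                    status = "unbounded"))
      ratio <- Tb[pos, ncols + 1L] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      i <- cand[which.min(basis[cand])]    # Bland on the leaving side
      piv <- Tb[i, j]
      Tb[i, ] <- Tb[i, ] / piv
      oth <- setdiff(seq_len(nrow(Tb)), i)
      Tb[oth, ] <- Tb[oth, ] - outer(Tb[oth, j], Tb[i, ])
      basis[i] <- j
    }
  }
  r1 <- runSimplex(Tb, basis, phaseCost, n + m)
  Tb <- r1$Tb; basis <- r1$basis
  artVal <- sum(Tb[basis > n, ncol(Tb)])
  if (artVal > 1e-7 * (1 + max(abs(b))))
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  # drive leftover zero-level artificials out, dropping redundant rows
  dropRows <- integer()
  for (i in which(basis > n)) {
    row <- Tb[i, seq_len(n)]
    j <- which(abs(row) > tol)
    if (length(j)) {
      j <- j[1]
      piv <- Tb[i, j]
      Tb[i, ] <- Tb[i, ] / piv
      oth <- setdiff(seq_len(nrow(Tb)), i)
      Tb[oth, ] <- Tb[oth, ] - outer(Tb[oth, j], Tb[i, ])
      basis[i] <- j
    } else {
      dropRows <- c(dropRows, i)
    }
  }
  if (length(dropRows)) {
    Tb <- Tb[-dropRows, , drop = FALSE]
    basis <- basis[-dropRows]
  }
  # phase 2 on original columns only
  Tb2 <- Tb[, c(seq_len(n), n + m + 1L), drop = FALSE]
  r2 <- runSimplex(Tb2, basis, -cost, n)   # maximise cost == minimise -cost
  if (r2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  Tb2 <- r2$Tb; basis <- r2$basis
  x <- numeric(n)
  x[basis] <- Tb2[, n + 1L]
  val <- sum(cost * x)
  list(status = "optimal", x = x, value = if (maximise) val else -val)
}
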