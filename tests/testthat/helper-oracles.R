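# Independent oracles, kept deliberately separate from the package's
# own code paths.

# Enumerate basic feasible solutions of max c'v s.t. S v = 0,
# lb <= v <= ub: fix n - rank(S) variables at a bound, solve for the
# rest, keep feasible points, return the best objective.
bruteForceLP <- function(S, lb, ub, obj, maximise = TRUE) {
  S <- as.matrix(S)
  n <- ncol(S)
  r <- qr(S)$rank
  nf <- n - r
  best <- NA_real_
  better <- if (maximise) function(a, b) is.na(b) || a > b
            else function(a, b) is.na(b) || a < b
  fixedSets <- if (nf == 0) list(integer(0)) else
    asplit(utils::combn(n, nf), 2)
  for (F in fixedSets) {
    F <- as.integer(F)
    B <- setdiff(seq_len(n), F)
    SB <- S[, B, drop = FALSE]
    if (qr(SB)$rank < r) next
    grid <- if (length(F))
      expand.grid(rep(list(c(1, 2)), length(F))) else
      data.frame(row.names = "1")
    for (gi in seq_len(nrow(grid))) {
      v <- numeric(n)
      if (length(F))
        v[F] <- ifelse(unlist(grid[gi, ]) == 1, lb[F], ub[F])
      rhs <- -S[, F, drop = FALSE] %*% v[F]
      vB <- suppressWarnings(qr.coef(qr(SB), rhs))
      if (anyNA(vB)) next
      v[B] <- vB
      if (max(abs(S %*% v)) > 1e-7) next
      if (any(v < lb - 1e-9) || any(v > ub + 1e-9)) next
      val <- sum(obj * v)
      if (better(val, best)) best <- val
    }
  }
  best
}

# Window-by-window Hamming scan for TTAAAA (forward) / TTTTAA
# (reverse-strand site), N counting as a mismatch.
bruteHexScan <- function(s, maxMismatch = 1) {
  s <- toupper(s)
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  empty <- data.frame(position = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  if (n < 6) return(empty)
  W <- vapply(0:5, function(k) ch[seq_len(n - 5) + k],
              character(n - 5))
  if (is.null(dim(W))) W <- matrix(W, nrow = 1)
  rows <- list()
  for (pat in list(c("TTAAAA", "+"), c("TTTTAA", "-"))) {
    pc <- strsplit(pat[1], "")[[1]]
    mm <- rowSums(W != matrix(pc, nrow(W), 6, byrow = TRUE))
    hit <- which(mm <= maxMismatch)
    if (length(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        position = hit, strand = pat[2], mismatches = as.integer(mm[hit]),
        stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Evaluate a GPR rule string through R's own boolean machinery:
# substitute gene tokens by TRUE/FALSE and and/or by &/|, then parse
# and eval. Independent of the package's recursive-descent parser.
gprEvalOracle <- function(ruleText, present, genes) {
  txt <- gsub("([()])", " \\1 ", ruleText)
  toks <- strsplit(trimws(txt), "\\s+")[[1]]
  toks <- vapply(toks, function(tk) {
    lt <- tolower(tk)
    if (lt == "and") "&" else if (lt == "or") "|"
    else if (tk %in% c("(", ")")) tk
    else if (tk %in% present) "TRUE" else "FALSE"
  }, character(1))
  eval(parse(text = paste(toks, collapse = " ")))
}

# Random boolean rule over the given genes (depth-limited).
randomGPRText <- function(genes, depth = 2) {
  if (depth == 0 || stats::runif(1) < 0.35)
    return(sample(genes, 1))
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  args <- vapply(seq_len(k), function(i)
    randomGPRText(genes, depth - 1), character(1))
  paste0("(", paste(args, collapse = paste0(" ", op, " ")), ")")
}

# Random small flux network: always feasible at v = 0 (lb <= 0).
randomNetwork <- function(nRxn = NULL, nMet = NULL) {
  n <- if (is.null(nRxn)) sample(3:6, 1) else nRxn
  m <- if (is.null(nMet)) sample(2:4, 1) else nMet
  S <- matrix(sample(c(-2, -1, 0, 0, 1, 2), m * n, replace = TRUE), m, n)
  lb <- sample(c(-5, 0), n, replace = TRUE)
  ub <- sample(3:10, n, replace = TRUE)
  model <- MetabolicModel(
    S,
    metInfo = data.frame(id = paste0("x", seq_len(m)), compartment = "c",
                         boundary = FALSE, stringsAsFactors = FALSE),
    rxnInfo = data.frame(id = paste0("r", seq_len(n)), lb = lb, ub = ub,
                         stringsAsFactors = FALSE))
  list(model = model, S = S, lb = lb, ub = ub, n = n)
}
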