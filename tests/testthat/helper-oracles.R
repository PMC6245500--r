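# Independent oracles used to cross-check package computations.

# Exhaustive vertex enumeration for max c'x s.t. A x = b, lb <= x <= ub.
# Valid for tiny problems (n choose m basis candidates); the optimum of a
# bounded feasible LP is attained at a vertex, i.e. with n - m variables at
# a bound and the rest solved from the equalities.
oracleLP <- function(obj, A, rhs, lb, ub, tol = 1e-7) {
  A <- as.matrix(A)
  n <- ncol(A); m <- nrow(A)
  stopifnot(n >= m, all(is.finite(lb)), all(is.finite(ub)))
  best <- -Inf; bestx <- NULL
  fixCount <- n - m
  combos <- if (fixCount == 0) list(integer(0))
            else asplit(utils::combn(n, fixCount), 2)
  for (fix in combos) {
    free <- setdiff(seq_len(n), fix)
    Af <- A[, free, drop = FALSE]
    if (abs(det(Af)) < 1e-10) next
    nb <- length(fix)
    for (mask in seq_len(2^nb) - 1) {
      atUpper <- as.logical(bitwAnd(mask, 2^(seq_len(nb) - 1)))
      xf <- ifelse(atUpper, ub[fix], lb[fix])
      x <- numeric(n)
      x[fix] <- xf
      rhsf <- rhs - if (nb) A[, fix, drop = FALSE] %*% xf else 0
      x[free] <- solve(Af, rhsf)
      if (all(x >= lb - tol & x <= ub + tol)) {
        val <- sum(obj * x)
        if (val > best) { best <- val; bestx <- x }
      }
      if (nb == 0) break
    }
  }
  list(objective = best, x = bestx)
}

# Lexicographic oracle: F* by vertex enumeration, then the secondary optimum
# over the face f'v >= (1-eps)F* (slack column bounded by the largest
# attainable |f'v| so vertices stay finite).
oracleBilevel <- function(S, f, g, lb, ub, eps = 0) {
  lp1 <- oracleLP(f, S, rep(0, nrow(S)), lb, ub)
  Fstar <- lp1$objective
  thr <- if (Fstar >= 0) (1 - eps) * Fstar else (1 + eps) * Fstar
  bigS <- sum(abs(f) * pmax(abs(lb), abs(ub))) + 1
  A2 <- cbind(rbind(S, f), c(rep(0, nrow(S)), -1))
  lp2 <- oracleLP(c(g, 0), A2, c(rep(0, nrow(S)), thr),
                  c(lb, 0), c(ub, bigS))
  list(primary = Fstar, secondary = lp2$objective,
       x = lp2$x[seq_along(f)])
}

# Brute-force double-loop age silhouette.
oracleSilhouette <- function(ages, labels) {
  labels <- as.character(labels)
  n <- length(ages)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(abs(ages[i] - ages[own]))
    l <- Inf
    for (cl in setdiff(unique(labels), labels[i]))
      l <- min(l, mean(abs(ages[i] - ages[labels == cl])))
    s[i] <- if (max(a, l) == 0) 0 else (l - a) / max(a, l)
  }
  s
}

# Shunting-yard GPR evaluator (independent of the recursive-descent parser).
oracleGPR <- function(rule, env, missing = 1) {
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^()[:space:]]+", rule))[[1]]
  prec <- c(and = 2, or = 1)
  out <- character(0); ops <- character(0)
  for (tk in toks) {
    lt <- tolower(tk)
    if (lt %in% c("and", "or")) {
      while (length(ops) && ops[1] %in% c("and", "or") &&
             prec[[ops[1]]] >= prec[[lt]]) {
        out <- c(out, ops[1]); ops <- ops[-1]
      }
      ops <- c(lt, ops)
    } else if (tk == "(") {
      ops <- c("(", ops)
    } else if (tk == ")") {
      while (ops[1] != "(") { out <- c(out, ops[1]); ops <- ops[-1] }
      ops <- ops[-1]
    } else out <- c(out, tk)
  }
  out <- c(out, ops)
  st <- numeric(0)
  for (tk in out) {
    if (tk %in% c("and", "or")) {
      v <- if (tk == "and") min(st[1], st[2]) else max(st[1], st[2])
      st <- c(v, st[-(1:2)])
    } else {
      v <- unname(env[tk])
      if (is.na(v)) v <- missing
      st <- c(v, st)
    }
  }
  st[1]
}

# Random GPR rule from the grammar (for parser/evaluator property tests).
randomGPR <- function(genes, depth = 3) {
  if (depth == 0 || runif(1) < 0.4) return(sample(genes, 1))
  op <- sample(c(" AND ", " OR "), 1)
  nargs <- sample(2:3, 1)
  parts <- replicate(nargs, randomGPR(genes, depth - 1))
  wrap <- runif(length(parts)) < 0.5
  parts[wrap] <- paste0("(", parts[wrap], ")")
  paste(parts, collapse = op)
}

# ECDF-based two-sample KS statistic.
oracleKS <- function(x, y) {
  pooled <- sort(unique(c(x, y)))
  max(abs(vapply(pooled, function(t) mean(x <= t) - mean(y <= t),
                 numeric(1))))
}
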