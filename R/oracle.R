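# Exact vertex-enumeration oracle for small LPs.
#
# Independent verification route for the simplex solver: enumerates the
# basic feasible solutions of {S v = 0, G v <= h, v >= 0} by brute force
# over active-constraint subsets, in exact rational arithmetic (integer
# numerators/denominators stored in doubles; exact below 2^53, far beyond
# what the bundled toy models produce). Used by the test-suite and the
# acceptance script; refuses problems with more than `max_vars` variables.

gcdd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- b; b <- a %% b; a <- t }
  a
}

rat_reduce <- function(n, d) {
  if (d == 0) stop("zero denominator in rational arithmetic")
  if (d < 0) { n <- -n; d <- -d }
  if (n == 0) return(c(0, 1))
  g <- gcdd(n, d)
  c(n / g, d / g)
}

rat_add <- function(a, b) rat_reduce(a[1] * b[2] + b[1] * a[2], a[2] * b[2])
rat_sub <- function(a, b) rat_reduce(a[1] * b[2] - b[1] * a[2], a[2] * b[2])
rat_mul <- function(a, b) rat_reduce(a[1] * b[1], a[2] * b[2])
rat_div <- function(a, b) {
  if (b[1] == 0) stop("rational division by zero")
  rat_reduce(a[1] * b[2], a[2] * b[1])
}
rat_cmp <- function(a, b) sign(a[1] * b[2] - b[1] * a[2])

# double -> exact small rational via continued fractions
as_rat <- function(x, max_den = 1e9, tol = 1e-12) {
  if (x == round(x)) return(c(x, 1))
  sgn <- sign(x); x <- abs(x)
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1; b <- x
  repeat {
    a <- floor(b)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > max_den) break
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    if (abs(x - h1 / k1) < tol * max(1, x)) break
    if (b == a) break
    b <- 1 / (b - a)
  }
  c(sgn * h1, k1)
}

# Solve M x = rhs exactly (M: m >= n rows). Returns list(status, x) where
# x is a 2-column (num, den) matrix; status "unique", "singular" (rank
# deficient) or "inconsistent".
rat_solve <- function(Mnum, Mden, rnum, rden) {
  m <- nrow(Mnum); n <- ncol(Mnum)
  A <- cbind(Mnum, rnum); D <- cbind(Mden, rden)
  row <- 1L
  pivots <- integer(0)
  for (col in seq_len(n)) {
    piv <- which(A[row:m, col] != 0)
    if (!length(piv)) next
    p <- row + piv[1L] - 1L
    if (p != row) { A[c(row, p), ] <- A[c(p, row), ]; D[c(row, p), ] <- D[c(p, row), ] }
    pv <- c(A[row, col], D[row, col])
    for (i in seq_len(m)) {
      if (i == row || A[i, col] == 0) next
      f <- rat_div(c(A[i, col], D[i, col]), pv)
      for (j in col:(n + 1L)) {
        t <- rat_sub(c(A[i, j], D[i, j]), rat_mul(f, c(A[row, j], D[row, j])))
        A[i, j] <- t[1]; D[i, j] <- t[2]
      }
    }
    pivots <- c(pivots, col)
    names(pivots)[length(pivots)] <- row
    row <- row + 1L
    if (row > m) break
  }
  # consistency of remaining rows
  if (row <= m) {
    for (i in row:m) {
      if (any(A[i, seq_len(n)] != 0)) next  # shouldn't happen post-elimination
      if (A[i, n + 1L] != 0) return(list(status = "inconsistent"))
    }
  }
  if (length(pivots) < n) return(list(status = "singular"))
  x <- matrix(c(rep(0, n), rep(1, n)), n, 2)
  for (k in seq_along(pivots)) {
    r <- as.integer(names(pivots)[k]); cl <- pivots[k]
    v <- rat_div(c(A[r, n + 1L], D[r, n + 1L]), c(A[r, cl], D[r, cl]))
    x[cl, ] <- v
  }
  list(status = "unique", x = x)
}

rationalize_matrix <- function(M, max_den = 1e9) {
  if (!length(M))
    return(list(num = matrix(0, nrow(M), ncol(M)),
                den = matrix(1, nrow(M), ncol(M))))
  num <- apply(M, c(1, 2), function(v) as_rat(v, max_den)[1])
  den <- apply(M, c(1, 2), function(v) as_rat(v, max_den)[2])
  list(num = num, den = den)
}

#' Exact vertex-enumeration LP oracle
#'
#' Brute-force enumeration of the polytope vertices of a (small) FBA
#' problem in exact rational arithmetic, independent of the simplex path.
#' Variables with a zero upper bound are eliminated first; the oracle then
#' refuses problems with more than `max_vars` remaining variables — it is
#' a verification tool, not a solver.
#'
#' @param model A model or an `lp_problem`.
#' @param objective Objective reaction id (when `model` is a model).
#' @param max_vars Refusal threshold on the reduced variable count.
#' @param max_combos Refusal threshold on active-set combinations.
#' @return `list(objective, objective_rat = c(num, den), vertices` (matrix,
#'   one row per optimal vertex over the full variable space),
#'   `n_feasible_vertices, n_combinations)`.
#' @export
vertex_oracle <- function(model, objective = NULL, max_vars = 15,
                          max_combos = 2e5) {
  problem <- if (inherits(model, "lp_problem")) model
             else build_lp(model, objective, enzyme = TRUE)
  keep <- which(problem$ub > 0)
  vars <- problem$vars[keep]
  n <- length(vars)
  if (n > max_vars)
    stop("vertex_oracle refuses ", n, " variables (> ", max_vars,
         "); it is intended for toy-scale verification only")
  S <- problem$S[, keep, drop = FALSE]
  S <- S[rowSums(S != 0) > 0, , drop = FALSE]
  ub <- problem$ub[keep]
  # inequality rows: enzyme pools, finite upper bounds, nonnegativity
  G <- matrix(0, 0, n); h <- numeric()
  for (row in problem$enz) {
    r <- stats::setNames(numeric(n), vars)
    hit <- intersect(names(row$coef), vars)
    if (!length(hit)) next
    r[hit] <- row$coef[hit]
    G <- rbind(G, r); h <- c(h, row$rhs)
  }
  fin <- which(is.finite(ub))
  for (i in fin) {
    r <- numeric(n); r[i] <- 1
    G <- rbind(G, r); h <- c(h, ub[i])
  }
  for (i in seq_len(n)) {
    r <- numeric(n); r[i] <- -1
    G <- rbind(G, r); h <- c(h, 0)
  }
  E <- rationalize_matrix(S)
  Gr <- rationalize_matrix(G)
  hr <- rationalize_matrix(matrix(h, ncol = 1))
  cr <- rationalize_matrix(matrix(problem$c[keep], nrow = 1))

  # rank of the equality block (exact)
  m_eq <- nrow(S)
  r_eq <- if (m_eq == 0) 0L else rank_rat(E$num, E$den)
  k <- n - r_eq
  m_in <- nrow(G)
  if (k < 0 || (k > 0 && choose(m_in, k) > max_combos))
    stop("vertex_oracle: ", choose(m_in, k),
         " active-set combinations exceed the enumeration budget")
  combos <- if (k == 0) matrix(integer(), nrow = 0, ncol = 1)
            else utils::combn(m_in, k)
  n_combo <- ncol(combos)

  best <- NULL; best_x <- list(); n_feas <- 0L
  eval_combo <- function(sel) {
    Mnum <- rbind(E$num, Gr$num[sel, , drop = FALSE])
    Mden <- rbind(E$den, Gr$den[sel, , drop = FALSE])
    rnum <- rbind(matrix(0, m_eq, 1), hr$num[sel, , drop = FALSE])
    rden <- rbind(matrix(1, m_eq, 1), hr$den[sel, , drop = FALSE])
    sol <- rat_solve(Mnum, Mden, rnum, rden)
    if (sol$status != "unique") return(NULL)
    sol$x
  }
  feasible_exact <- function(x) {
    for (i in seq_len(m_in)) {
      acc <- c(0, 1)
      for (j in seq_len(n)) {
        if (Gr$num[i, j] == 0) next
        acc <- rat_add(acc, rat_mul(c(Gr$num[i, j], Gr$den[i, j]), x[j, ]))
      }
      if (rat_cmp(acc, c(hr$num[i, 1], hr$den[i, 1])) > 0) return(FALSE)
    }
    TRUE
  }
  objective_exact <- function(x) {
    acc <- c(0, 1)
    for (j in seq_len(n)) {
      if (cr$num[1, j] == 0) next
      acc <- rat_add(acc, rat_mul(c(cr$num[1, j], cr$den[1, j]), x[j, ]))
    }
    acc
  }
  handle <- function(x) {
    if (is.null(x) || !feasible_exact(x)) return()
    n_feas <<- n_feas + 1L
    z <- objective_exact(x)
    if (is.null(best) || rat_cmp(z, best) > 0) {
      best <<- z; best_x <<- list(x)
    } else if (rat_cmp(z, best) == 0) {
      dup <- any(vapply(best_x, function(y)
        all(y[, 1] == x[, 1] & y[, 2] == x[, 2]), logical(1)))
      if (!dup) best_x[[length(best_x) + 1L]] <<- x
    }
  }
  if (k == 0) handle(eval_combo(integer())) else
    for (ci in seq_len(n_combo)) handle(eval_combo(combos[, ci]))
  if (is.null(best))
    stop("vertex_oracle found no feasible vertex (inconsistent model?)")
  full <- matrix(0, length(best_x), length(problem$vars),
                 dimnames = list(NULL, problem$vars))
  for (i in seq_along(best_x)) full[i, vars] <- best_x[[i]][, 1] / best_x[[i]][, 2]
  list(objective = best[1] / best[2], objective_rat = best,
       vertices = full, n_feasible_vertices = n_feas,
       n_combinations = max(n_combo, 1L))
}

# exact rank via elimination on a copy
rank_rat <- function(Anum, Aden) {
  m <- nrow(Anum); n <- ncol(Anum)
  row <- 1L; rank <- 0L
  A <- Anum; D <- Aden
  for (col in seq_len(n)) {
    if (row > m) break
    piv <- which(A[row:m, col] != 0)
    if (!length(piv)) next
    p <- row + piv[1L] - 1L
    if (p != row) { A[c(row, p), ] <- A[c(p, row), ]; D[c(row, p), ] <- D[c(p, row), ] }
    pv <- c(A[row, col], D[row, col])
    if (row < m) {
      for (i in (row + 1L):m) {
        if (A[i, col] == 0) next
        f <- rat_div(c(A[i, col], D[i, col]), pv)
        for (j in col:n) {
          t <- rat_sub(c(A[i, j], D[i, j]), rat_mul(f, c(A[row, j], D[row, j])))
          A[i, j] <- t[1]; D[i, j] <- t[2]
        }
      }
    }
    rank <- rank + 1L
    row <- row + 1L
  }
  rank
}
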