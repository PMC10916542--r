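# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# Solves   maximize c'x   s.t.  A_eq x = b_eq,  A_ub x <= b_ub,  x >= 0.
#
# Written for the desk-scale LPs this package builds (tens of variables):
# a deterministic, dependency-free solver whose pivoting rule guarantees
# termination. Bland's rule (smallest eligible index enters, smallest
# basis index breaks ratio ties) makes repeated solves bit-identical.

simplex_core <- function(tab, basis, n_real, tol = 1e-9) {
  m <- nrow(tab)
  repeat {
    red <- tab[m, -ncol(tab)]
    enter <- which(red > tol)
    if (!length(enter)) return(list(tab = tab, basis = basis, status = "optimal"))
    j <- enter[1L]  # Bland: smallest index
    col <- tab[-m, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(tab = tab, basis = basis, status = "unbounded"))
    ratios <- tab[pos, ncol(tab)] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol * max(1, abs(rmin))]
    i <- cand[which.min(basis[cand])]  # Bland tie-break on basis index
    piv <- tab[i, j]
    tab[i, ] <- tab[i, ] / piv
    for (k in seq_len(m)) {
      if (k != i && abs(tab[k, j]) > 0)
        tab[k, ] <- tab[k, ] - tab[k, j] * tab[i, ]
    }
    basis[i] <- j
  }
}

#' Solve a linear program with the built-in simplex
#'
#' @param c_obj Objective coefficients (maximized).
#' @param A_eq,b_eq Equality block (may have zero rows).
#' @param A_ub,b_ub Inequality block `A_ub x <= b_ub` (may have zero rows).
#' @param tol Feasibility/optimality tolerance.
#' @return `list(status, objective, x)`; `status` is `"optimal"`,
#'   `"infeasible"`, or `"unbounded"`.
#' @keywords internal
simplex_solve <- function(c_obj, A_eq = NULL, b_eq = NULL,
                          A_ub = NULL, b_ub = NULL, tol = 1e-9) {
  n <- length(c_obj)
  if (is.null(A_eq)) { A_eq <- matrix(0, 0, n); b_eq <- numeric() }
  if (is.null(A_ub)) { A_ub <- matrix(0, 0, n); b_ub <- numeric() }
  m_eq <- nrow(A_eq); m_ub <- nrow(A_ub)
  A <- rbind(A_eq, A_ub)
  b <- c(b_eq, b_ub)
  m <- length(b)
  # slack columns for inequality rows
  S <- rbind(matrix(0, m_eq, m_ub), diag(1, m_ub))
  A <- cbind(A, S)
  # flip rows with negative rhs (turns some slacks into surplus columns)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  # a slack can start in the basis only if its row was not flipped
  slack_ok <- logical(m)
  if (m_ub) slack_ok[(m_eq + 1):m] <- !neg[(m_eq + 1):m]
  need_art <- which(!slack_ok)
  n_art <- length(need_art)
  Art <- matrix(0, m, n_art)
  if (n_art) Art[cbind(need_art, seq_len(n_art))] <- 1
  A <- cbind(A, Art)
  ncols <- ncol(A)
  basis <- integer(m)
  basis[!slack_ok] <- n + m_ub + seq_len(n_art)
  if (any(slack_ok)) basis[slack_ok] <- n + which(slack_ok[(m_eq + 1):m])
  # ---- phase 1: maximize -(sum of artificials)
  obj1 <- c(rep(0, n + m_ub), rep(-1, n_art))
  tab <- rbind(cbind(A, b), c(obj1, 0))
  # make reduced costs consistent with the starting basis
  for (i in seq_len(m)) {
    cb <- obj1[basis[i]]
    if (cb != 0) tab[m + 1, ] <- tab[m + 1, ] - cb * tab[i, ]
  }
  res <- simplex_core(tab, basis, n, tol)
  phase1_sum <- res$tab[m + 1, ncols + 1]  # minimized sum of artificials
  if (res$status != "optimal" ||
      phase1_sum > tol * max(1, if (length(b)) max(abs(b)) else 0))
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  tab <- res$tab; basis <- res$basis
  # drive remaining artificials out of the basis (degenerate at zero)
  art_cols <- if (n_art) n + m_ub + seq_len(n_art) else integer()
  for (i in seq_len(m)) {
    if (basis[i] %in% art_cols) {
      piv_j <- which(abs(tab[i, seq_len(n + m_ub)]) > tol)
      if (length(piv_j)) {
        j <- piv_j[1L]
        piv <- tab[i, j]
        tab[i, ] <- tab[i, ] / piv
        for (k in seq_len(nrow(tab))) {
          if (k != i && abs(tab[k, j]) > 0)
            tab[k, ] <- tab[k, ] - tab[k, j] * tab[i, ]
        }
        basis[i] <- j
      }
    }
  }
  # ---- phase 2: drop artificial columns, restore the real objective
  keep <- c(seq_len(n + m_ub), ncols + 1L)
  tab <- tab[, keep, drop = FALSE]
  obj2 <- c(c_obj, rep(0, m_ub))
  tab[m + 1, ] <- c(obj2, 0)
  for (i in seq_len(m)) {
    if (basis[i] <= n + m_ub) {
      cb <- obj2[basis[i]]
      if (cb != 0) tab[m + 1, ] <- tab[m + 1, ] - cb * tab[i, ]
    }
  }
  res <- simplex_core(tab, basis, n, tol)
  if (res$status == "unbounded")
    return(list(status = "unbounded", objective = Inf, x = rep(NA_real_, n)))
  tab <- res$tab; basis <- res$basis
  x <- numeric(n + m_ub)
  for (i in seq_len(m)) if (basis[i] <= n + m_ub) x[basis[i]] <- tab[i, ncol(tab)]
  list(status = "optimal",
       objective = unname(-tab[m + 1, ncol(tab)]),
       x = unname(x[seq_len(n)]))
}
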