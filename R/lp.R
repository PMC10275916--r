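## Dense two-phase primal simplex over box-bounded variables.
##
## Every flux program in this package (FBA, pFBA, gap-filling, the sampler's
## interior-point seed) reduces to
##     min  c'x   s.t.  A_eq x = b_eq,  A_le x <= b_le,  lb <= x <= ub
## with all bounds finite (flux bounds are +/-1000 by convention).  Problems
## are small and dense (tens of variables), so a tableau simplex is adequate
## and keeps the solver dependency-free and fully deterministic: Dantzig
## pricing with lowest-index tie-breaks, switching to Bland's rule after a
## fixed iteration budget so cycling cannot occur.

#' Feasibility/optimality tolerance shared by all linear programs
#'
#' Single named constant used for LP pivoting, steady-state residual checks
#' and nonzero-flux reporting throughout the package.
#' @export
FLUX_TOL <- 1e-6

.lp_pivot_tol <- 1e-9

#' Solve a linear program with box bounds
#'
#' Minimises (or maximises) \code{obj \%*\% x} subject to equality rows
#' \code{A_eq x = b_eq}, inequality rows \code{A_le x <= b_le} and finite
#' variable bounds \code{lb <= x <= ub}, using a deterministic two-phase
#' primal simplex.
#'
#' @param obj numeric objective coefficient vector.
#' @param A_eq,b_eq equality constraint matrix and right-hand side (or NULL).
#' @param A_le,b_le inequality (\code{<=}) constraint matrix and right-hand
#'   side (or NULL).
#' @param lb,ub finite lower and upper variable bounds, recycled to
#'   \code{length(obj)}.
#' @param maximize maximise instead of minimise.
#' @param max_iter simplex iteration cap.
#' @return list with \code{status} ("optimal", "infeasible", "unbounded" or
#'   "maxiter"), the primal solution \code{x} and \code{objval}.
#' @export
solve_lp <- function(obj, A_eq = NULL, b_eq = NULL, A_le = NULL, b_le = NULL,
                     lb, ub, maximize = FALSE, max_iter = 20000L) {
  n <- length(obj)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite variable bounds")
  if (any(ub < lb - .lp_pivot_tol))
    return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
  cvec <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  ## shift x = lb + y, 0 <= y <= u
  u <- ub - lb
  A <- NULL; b <- NULL; type <- character(0)
  if (!is.null(A_eq) && nrow(A_eq) > 0) {
    A_eq <- matrix(as.numeric(A_eq), nrow = nrow(A_eq))
    A <- A_eq
    b <- as.numeric(b_eq) - as.numeric(A_eq %*% lb)
    type <- rep("E", nrow(A_eq))
  }
  if (!is.null(A_le) && nrow(A_le) > 0) {
    A_le <- matrix(as.numeric(A_le), nrow = nrow(A_le))
    A <- rbind(A, A_le)
    b <- c(b, as.numeric(b_le) - as.numeric(A_le %*% lb))
    type <- c(type, rep("L", nrow(A_le)))
  }
  ## upper bounds as rows y_i <= u_i
  ubi <- which(is.finite(u))
  if (length(ubi)) {
    Ub <- matrix(0, length(ubi), n)
    Ub[cbind(seq_along(ubi), ubi)] <- 1
    A <- rbind(A, Ub)
    b <- c(b, u[ubi])
    type <- c(type, rep("L", length(ubi)))
  }
  m <- length(b)
  if (m == 0L) { # pure box problem
    x <- ifelse(cvec > 0, 0, u)
    x <- lb + x
    val <- sum(obj * x)
    return(list(status = "optimal", x = x, objval = val))
  }

  ## normalise rhs >= 0; L rows with negative rhs become G rows
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    type[neg] <- ifelse(type[neg] == "L", "G", type[neg])
  }

  ## columns: structural, slack/surplus, artificial
  n_slack <- sum(type != "E")
  art_rows <- which(type != "L")
  n_art <- length(art_rows)
  N <- n + n_slack + n_art
  Tm <- matrix(0, m, N + 1L)
  Tm[, seq_len(n)] <- A
  Tm[, N + 1L] <- b
  basis <- integer(m)
  sc <- n
  for (i in seq_len(m)) {
    if (type[i] == "L") {
      sc <- sc + 1L; Tm[i, sc] <- 1; basis[i] <- sc
    } else if (type[i] == "G") {
      sc <- sc + 1L; Tm[i, sc] <- -1
    }
  }
  ac <- n + n_slack
  for (i in art_rows) { ac <- ac + 1L; Tm[i, ac] <- 1; basis[i] <- ac }
  art_cols <- seq.int(n + n_slack + 1L, length.out = n_art)
  allowed <- rep(TRUE, N)

  run_simplex <- function(Tm, basis, objrow, allowed, iter_used) {
    bland_after <- 4L * (m + N)
    it <- iter_used
    repeat {
      it <- it + 1L
      if (it > max_iter)
        return(list(Tm = Tm, basis = basis, objrow = objrow,
                    status = "maxiter", iter = it))
      red <- objrow[seq_len(N)]
      red[!allowed] <- 0
      if (it <= bland_after) {
        j <- which.min(red)
        if (red[j] >= -.lp_pivot_tol)
          return(list(Tm = Tm, basis = basis, objrow = objrow,
                      status = "optimal", iter = it))
      } else {
        cand <- which(red < -.lp_pivot_tol)
        if (!length(cand))
          return(list(Tm = Tm, basis = basis, objrow = objrow,
                      status = "optimal", iter = it))
        j <- cand[1L]
      }
      col <- Tm[, j]
      pos <- which(col > .lp_pivot_tol)
      if (!length(pos))
        return(list(Tm = Tm, basis = basis, objrow = objrow,
                    status = "unbounded", iter = it))
      ratio <- Tm[pos, N + 1L] / col[pos]
      rmin <- min(ratio)
      ties <- pos[ratio <= rmin + .lp_pivot_tol]
      r <- ties[which.min(basis[ties])]
      ## pivot on (r, j)
      prow <- Tm[r, ] / Tm[r, j]
      colv <- Tm[, j]; colv[r] <- 0
      Tm <- Tm - outer(colv, prow)
      Tm[r, ] <- prow
      objrow <- objrow - objrow[j] * prow
      basis[r] <- j
    }
  }

  canonical_objrow <- function(costs, Tm, basis) {
    objrow <- c(costs, 0)
    bc <- costs[basis]
    nz <- which(bc != 0)
    for (i in nz) objrow <- objrow - bc[i] * Tm[i, ]
    objrow
  }

  ## phase 1
  c1 <- rep(0, N); c1[art_cols] <- 1
  res <- run_simplex(Tm, basis, canonical_objrow(c1, Tm, basis), allowed, 0L)
  if (res$status == "maxiter")
    return(list(status = "maxiter", x = rep(NA_real_, n), objval = NA_real_))
  phase1_val <- -res$objrow[N + 1L]
  if (phase1_val > 1e-7)
    return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
  Tm <- res$Tm; basis <- res$basis

  ## drive remaining artificials out of the basis
  if (n_art) {
    for (i in seq_len(m)) {
      if (basis[i] %in% art_cols) {
        row <- Tm[i, seq_len(n + n_slack)]
        j <- which(abs(row) > .lp_pivot_tol)[1L]
        if (!is.na(j)) {
          prow <- Tm[i, ] / Tm[i, j]
          colv <- Tm[, j]; colv[i] <- 0
          Tm <- Tm - outer(colv, prow)
          Tm[i, ] <- prow
          basis[i] <- j
        } # else redundant row; its artificial stays basic at zero
      }
    }
    allowed[art_cols] <- FALSE
  }

  ## phase 2
  c2 <- rep(0, N); c2[seq_len(n)] <- cvec
  res <- run_simplex(Tm, basis, canonical_objrow(c2, Tm, basis), allowed, 0L)
  if (res$status %in% c("maxiter", "unbounded"))
    return(list(status = res$status, x = rep(NA_real_, n), objval = NA_real_))
  y <- rep(0, n)
  bstruct <- res$basis <= n
  y[res$basis[bstruct]] <- res$Tm[bstruct, N + 1L]
  y <- pmin(pmax(y, 0), u)
  x <- lb + y
  val <- sum(obj * x)
  list(status = "optimal", x = x, objval = val)
}
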