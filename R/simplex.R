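#' @keywords internal
#' @noRd
NULL

# Two-phase full-tableau simplex for box-constrained linear programs:
#
#   maximize  obj' v   subject to   S v = b,   lb <= v <= ub
#
# All bounds must be finite. Variables are shifted (w = v - lb >= 0) and the
# upper bounds d = ub - lb become explicit rows w_j + s_j = d_j, so the
# working system has m + n rows, 2n structural/slack columns and m artificial
# columns. Phase 1 drives the artificials to zero; phase 2 optimizes obj.
# Dantzig pricing with a switch to Bland's rule after `bland_after`
# iterations guarantees termination on the (heavily degenerate) flux
# balance LPs this package solves.
#
# Returns list(status = "optimal" | "infeasible", objective, solution).
lp_solve <- function(obj, S, b = NULL, lb, ub, maximize = TRUE,
                     tol = 1e-9, bland_after = 500L, max_iter = 50000L) {
  S <- as.matrix(S)
  m <- nrow(S)
  n <- ncol(S)
  if (is.null(b)) b <- numeric(m)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n, length(b) == m)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("lp_solve() requires finite variable bounds", call. = FALSE)
  }
  if (any(lb > ub + tol)) {
    stop("lp_solve(): some lower bound exceeds its upper bound", call. = FALSE)
  }
  cc <- if (maximize) obj else -obj

  d  <- pmax(ub - lb, 0)
  b0 <- as.numeric(b - S %*% lb)

  # Row layout: m mass-balance rows then n upper-bound rows.
  # Column layout: n shifted variables w, n bound slacks s, m artificials a.
  M <- m + n
  N <- 2L * n + m
  A <- matrix(0, M, N)
  A[seq_len(m), seq_len(n)] <- S
  idx <- seq_len(n)
  A[cbind(m + idx, idx)]      <- 1   # w_j
  A[cbind(m + idx, n + idx)]  <- 1   # s_j
  rhs <- c(b0, d)

  # Normalize equality rows to non-negative rhs, then seat the artificials.
  neg <- which(rhs[seq_len(m)] < 0)
  if (length(neg)) {
    A[neg, ]  <- -A[neg, ]
    rhs[neg]  <- -rhs[neg]
  }
  A[cbind(seq_len(m), 2L * n + seq_len(m))] <- 1

  basis  <- c(2L * n + seq_len(m), n + idx)  # artificials, then bound slacks
  barred <- rep(FALSE, N)                    # phase-2 lockout of artificials

  # Objective row convention: red[j] = c_B' (B^-1 A)_j - c_j; pivot while
  # some admissible red[j] < -tol.
  pivot_loop <- function(cvec) {
    red <- as.numeric(crossprod(cvec[basis], A)) - cvec
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("simplex iteration limit reached", call. = FALSE)
      cand <- which(red < -tol & !barred)
      if (!length(cand)) break
      j <- if (it > bland_after) cand[1L] else cand[which.min(red[cand])]
      col <- A[, j]
      pos <- which(col > tol)
      if (!length(pos)) {
        stop("simplex: unbounded direction in a bounded LP (numerical failure)",
             call. = FALSE)
      }
      ratio <- rhs[pos] / col[pos]
      rmin  <- min(ratio)
      ties  <- pos[ratio <= rmin + tol]
      r     <- ties[which.min(basis[ties])]    # Bland-compatible tie-break
      piv   <- A[r, j]
      A[r, ]  <<- A[r, ] / piv
      rhs[r]  <<- rhs[r] / piv
      colr    <- A[, j]
      colr[r] <- 0
      nz <- which(abs(colr) > 0)
      if (length(nz)) {
        A[nz, ]  <<- A[nz, ] - outer(colr[nz], A[r, ])
        rhs[nz]  <<- rhs[nz] - colr[nz] * rhs[r]
      }
      red <- red - red[j] * A[r, ]
      basis[r] <<- j
      rhs[rhs < 0 & rhs > -tol] <<- 0
    }
    invisible(NULL)
  }

  # Phase 1: maximize -sum(artificials).
  c1 <- c(rep(0, 2L * n), rep(-1, m))
  pivot_loop(c1)
  art_basic <- which(basis > 2L * n)
  infeas <- if (length(art_basic)) sum(rhs[art_basic]) else 0
  scale <- max(1, abs(b0), d)
  if (infeas > 1e-7 * scale) {
    return(list(status = "infeasible", objective = NA_real_,
                solution = rep(NA_real_, n)))
  }

  # Pivot residual artificials out of the basis where possible; rows whose
  # non-artificial entries are all zero are redundant and stay inert.
  barred[2L * n + seq_len(m)] <- TRUE
  for (r in which(basis > 2L * n)) {
    row <- A[r, seq_len(2L * n)]
    j <- which(abs(row) > 1e-7)
    if (length(j)) {
      j <- j[1L]
      piv <- A[r, j]
      A[r, ] <- A[r, ] / piv
      rhs[r] <- rhs[r] / piv
      colr <- A[, j]; colr[r] <- 0
      nz <- which(abs(colr) > 0)
      if (length(nz)) {
        A[nz, ] <- A[nz, ] - outer(colr[nz], A[r, ])
        rhs[nz] <- rhs[nz] - colr[nz] * rhs[r]
      }
      basis[r] <- j
    }
  }
  rhs[rhs < 0 & rhs > -tol] <- 0

  # Phase 2 on the real objective.
  c2 <- c(cc, rep(0, n + m))
  pivot_loop(c2)

  w <- numeric(N)
  w[basis] <- rhs
  v <- w[seq_len(n)] + lb
  list(status = "optimal",
       objective = sum(obj * v),
       solution = v)
}
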