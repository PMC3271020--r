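#' Dense two-phase simplex linear-programming solver
#'
#' Solves `max/min obj' x` subject to `A x (dir) rhs` and `lb <= x <= ub`.
#' This is the package's LP kernel: all flux balance, variability and
#' multilevel solves are assembled on top of it. It is a textbook full-tableau
#' two-phase primal simplex with Bland's-rule fallback for anti-cycling,
#' written for the dense, small (tens to low hundreds of variables) problems
#' that arise from desk-scale community models.
#'
#' Row duals are returned for the constraint rows (`duals[i]` is the change in
#' the optimal objective per unit increase of `rhs[i]`, in the orientation of
#' the problem as given), which downstream code uses for optimality
#' certification.
#'
#' @param obj numeric objective coefficients (length `n`).
#' @param A constraint matrix (`m x n`), or `NULL` for a box-only problem.
#' @param rhs right-hand sides (length `m`).
#' @param dir character vector of `"<="`, `">="`, `"=="` per row.
#' @param lb,ub variable bounds; `-Inf`/`Inf` allowed.
#' @param maximize logical; maximize (default) or minimize.
#' @param var_names optional variable names used in solutions and error
#'   messages.
#' @param tol pivot/feasibility tolerance.
#' @param max_iter simplex iteration cap.
#'
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (named primal solution), `objective`, `duals` (length `m`), and for
#'   unbounded problems `unbounded_var`, the name of a variable on an
#'   improving ray.
#' @keywords internal
lp_solve <- function(obj, A = NULL, rhs = NULL, dir = NULL,
                     lb = rep(0, length(obj)), ub = rep(Inf, length(obj)),
                     maximize = TRUE, var_names = NULL,
                     tol = 1e-9, max_iter = 20000L) {
  n <- length(obj)
  if (is.null(var_names)) var_names <- paste0("x", seq_len(n))
  if (is.null(A)) {
    A <- matrix(0, 0L, n)
    rhs <- numeric(0)
    dir <- character(0)
  }
  A <- as.matrix(A)
  stopifnot(ncol(A) == n, nrow(A) == length(rhs), length(dir) == length(rhs),
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_,
                duals = rep(NA_real_, nrow(A))))
  }
  cmin <- if (maximize) -obj else obj

  # --- variable transform to s >= 0 -----------------------------------------
  # each original variable maps to one shifted/mirrored column, or two columns
  # (positive/negative part) when fully free
  col_var   <- integer(0)  # owning original variable of each working column
  col_sign  <- numeric(0)
  col_shift <- numeric(0)  # x = shift + sign * s
  col_ub    <- numeric(0)  # upper bound of the working column
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) {
      col_var <- c(col_var, j); col_sign <- c(col_sign, 1)
      col_shift <- c(col_shift, lb[j]); col_ub <- c(col_ub, ub[j] - lb[j])
    } else if (is.finite(ub[j])) {
      col_var <- c(col_var, j); col_sign <- c(col_sign, -1)
      col_shift <- c(col_shift, ub[j]); col_ub <- c(col_ub, Inf)
    } else {
      col_var <- c(col_var, j, j); col_sign <- c(col_sign, 1, -1)
      col_shift <- c(col_shift, 0, 0); col_ub <- c(col_ub, Inf, Inf)
    }
  }
  ns <- length(col_var)
  As <- A[, col_var, drop = FALSE] * rep(col_sign, each = nrow(A))
  cs <- cmin[col_var] * col_sign
  shift_per_var <- numeric(n)
  shift_per_var[col_var[!duplicated(col_var)]] <- col_shift[!duplicated(col_var)]
  bs <- rhs - as.vector(A %*% shift_per_var)
  dirs <- dir

  # working-column upper bounds become extra rows
  ub_cols <- which(is.finite(col_ub))
  if (length(ub_cols)) {
    Ub <- matrix(0, length(ub_cols), ns)
    Ub[cbind(seq_along(ub_cols), ub_cols)] <- 1
    As <- rbind(As, Ub)
    bs <- c(bs, col_ub[ub_cols])
    dirs <- c(dirs, rep("<=", length(ub_cols)))
  }
  m <- nrow(As)
  m_user <- nrow(A)

  finish <- function(s_val, status, unb_var = NULL, duals = NULL) {
    x <- numeric(n)
    for (k in seq_len(ns)) {
      x[col_var[k]] <- x[col_var[k]] + col_sign[k] * s_val[k]
    }
    # apply shifts once per variable (each var has exactly one shifted column)
    x <- x + shift_per_var
    names(x) <- var_names
    list(status = status, x = x, objective = sum(obj * x),
         duals = duals, unbounded_var = unb_var)
  }

  if (m == 0L) {
    # pure box problem: no finite column bounds remain (they would be rows)
    bad <- which(cs < -tol)
    if (length(bad)) {
      return(list(status = "unbounded", x = NULL, objective = NA_real_,
                  duals = numeric(0),
                  unbounded_var = var_names[col_var[bad[1]]]))
    }
    return(finish(rep(0, ns), "optimal", duals = numeric(0)))
  }

  # flip rows to make rhs nonnegative
  flip <- bs < 0
  As[flip, ] <- -As[flip, , drop = FALSE]
  bs[flip] <- -bs[flip]
  dirs[flip] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[dirs[flip]]

  # build full working matrix: structural | slack/surplus | artificial
  n_slack <- sum(dirs != "==")
  W <- cbind(As, matrix(0, m, n_slack + m))
  slack_of_row <- rep(NA_integer_, m)
  art_of_row <- integer(m)
  sc <- ns
  for (i in seq_len(m)) {
    if (dirs[i] != "==") {
      sc <- sc + 1L
      W[i, sc] <- if (dirs[i] == "<=") 1 else -1
      slack_of_row[i] <- sc
    }
  }
  for (i in seq_len(m)) {
    art_of_row[i] <- ns + n_slack + i
    W[i, art_of_row[i]] <- 1
  }
  N <- ncol(W)
  art_cols <- (ns + n_slack + 1L):N
  is_art <- seq_len(N) %in% art_cols

  # initial basis: slack for <=, artificial otherwise
  basis <- integer(m)
  for (i in seq_len(m)) {
    basis[i] <- if (dirs[i] == "<=") slack_of_row[i] else art_of_row[i]
  }
  Tb <- cbind(W, bs)
  row_kept <- rep(TRUE, m)
  row_of <- seq_len(m)  # original working row for each current tableau row

  run_simplex <- function(Tb, basis, cost, allow, bland_after, max_iter) {
    mm <- nrow(Tb); NN <- ncol(Tb) - 1L
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) stop("simplex iteration limit exceeded")
      cB <- cost[basis]
      r <- cost - as.vector(cB %*% Tb[, seq_len(NN), drop = FALSE])
      r[basis] <- 0
      r[!allow] <- Inf
      if (iter > bland_after) {
        cand <- which(r < -tol)
        if (!length(cand)) break
        e <- cand[1]
      } else {
        e <- which.min(r)
        if (r[e] >= -tol) break
      }
      colv <- Tb[, e]
      pos <- which(colv > tol)
      if (!length(pos)) {
        return(list(Tb = Tb, basis = basis, status = "unbounded", entering = e))
      }
      ratios <- Tb[pos, NN + 1L] / colv[pos]
      p <- pos[which(ratios <= min(ratios) + 1e-12)]
      if (length(p) > 1L) p <- p[which.min(basis[p])]
      piv <- Tb[p, e]
      prow <- Tb[p, ] / piv
      Tb <- Tb - outer(Tb[, e], prow)
      Tb[p, ] <- prow
      basis[p] <- e
    }
    list(Tb = Tb, basis = basis, status = "optimal")
  }

  bland_after <- 200L + 5L * (m + N)

  # ---- phase 1 -------------------------------------------------------------
  c1 <- as.numeric(is_art)
  res1 <- run_simplex(Tb, basis, c1, allow = rep(TRUE, N), bland_after, max_iter)
  Tb <- res1$Tb; basis <- res1$basis
  p1_obj <- sum(c1[basis] * Tb[, N + 1L])
  if (p1_obj > 1e-7) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_,
                duals = rep(NA_real_, m_user)))
  }
  # drive artificials out of the basis (or drop redundant rows)
  drop_rows <- integer(0)
  for (i in seq_len(nrow(Tb))) {
    if (is_art[basis[i]]) {
      piv_col <- which(!is_art[seq_len(N)] & abs(Tb[i, seq_len(N)]) > 1e-7 &
                         !(seq_len(N) %in% basis))
      if (length(piv_col)) {
        e <- piv_col[1]
        piv <- Tb[i, e]
        prow <- Tb[i, ] / piv
        Tb <- Tb - outer(Tb[, e], prow)
        Tb[i, ] <- prow
        basis[i] <- e
      } else {
        drop_rows <- c(drop_rows, i)
      }
    }
  }
  if (length(drop_rows)) {
    keep <- setdiff(seq_len(nrow(Tb)), drop_rows)
    row_of <- row_of[keep]
    Tb <- Tb[keep, , drop = FALSE]
    basis <- basis[keep]
  }

  # ---- phase 2 -------------------------------------------------------------
  c2 <- c(cs, rep(0, N - ns))
  res2 <- run_simplex(Tb, basis, c2, allow = !is_art, bland_after, max_iter)
  Tb <- res2$Tb; basis <- res2$basis
  if (res2$status == "unbounded") {
    e <- res2$entering
    unb <- if (e <= ns) var_names[col_var[e]] else paste0("row_slack_", e - ns)
    return(list(status = "unbounded", x = NULL, objective = NA_real_,
                duals = rep(NA_real_, m_user), unbounded_var = unb))
  }

  s_val <- rep(0, ns)
  bcol <- Tb[, N + 1L]
  str_basic <- which(basis <= ns)
  s_val[basis[str_basic]] <- bcol[str_basic]
  s_val[s_val < 0 & s_val > -1e-9] <- 0

  # duals: y_i = c_B' * (B^-1 e_i); the artificial column of each row is that
  # identity column in the final tableau
  cB <- c2[basis]
  y_work <- rep(0, m)
  for (wr in seq_len(m)) {
    tr <- match(wr, row_of)
    if (is.na(tr)) next  # dropped redundant row: dual 0
    y_work[wr] <- sum(cB * Tb[, art_of_row[wr]])
  }
  y_work[flip] <- -y_work[flip]
  duals <- y_work[seq_len(m_user)]
  if (maximize) duals <- -duals

  out <- finish(s_val, "optimal", duals = duals)
  out
}

#' @keywords internal
lp_infeasible <- function(res) identical(res$status, "infeasible")
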