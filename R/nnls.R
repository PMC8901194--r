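#' General linear model with non-negative nuisance weights
#'
#' Minimizes `||y - X beta||^2` with `beta >= 0` on the columns flagged by the
#' design's non-negativity mask (the short-channel nuisance regressors) and
#' unconstrained elsewhere (task regressors, derivatives, constant). Solved by
#' an active-set scheme in the Lawson-Hanson style: the unconstrained block is
#' always in the solve, constrained columns enter/leave a positive active set
#' by gradient sign, with feasibility line steps on each re-solve. At
#' termination the solution equals ordinary least squares on the unconstrained
#' columns plus the active nuisance columns.
#'
#' The residual variance uses `dof = n - (n_unconstrained + n_active)`,
#' counting only nuisance columns that carry nonzero weight.
#'
#' @param y Response vector (one channel's concentration series).
#' @param design A design from [build_design()], or any list with elements
#'   `X` (matrix) and `nonneg_mask` (logical per column).
#' @return List of class `glm_fit`: `beta` (named, full length), `sigma2`,
#'   `dof`, `active_set` (indices of nuisance columns with nonzero weight),
#'   `residuals`, `tag`.
#' @export
fit_glm_nnls <- function(y, design) {
  X <- design$X
  mask <- design$nonneg_mask
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, length(mask) == p)
  if (n <= p) stop("more columns than samples")
  U <- which(!mask)
  C <- which(mask)
  tol <- sqrt(.Machine$double.eps) * max(abs(crossprod(X, y)), 1)

  ls_solve <- function(cols) {
    q <- qr(X[, cols, drop = FALSE])
    if (q$rank < length(cols)) {
      stop("singular unconstrained block in design")
    }
    qr.coef(q, y)
  }

  P <- integer(0)
  beta <- numeric(p)
  for (iter in seq_len(10 * (length(C) + 1) + 50)) {
    cols <- c(U, P)
    b <- ls_solve(cols)
    # feasibility steps: pull the iterate toward b, dropping clamped columns
    while (length(P) > 0) {
      bP <- b[match(P, cols)]
      viol <- which(bP < -tol)
      if (length(viol) == 0) break
      cur <- beta[P[viol]]
      alpha <- min(cur / (cur - bP[viol]))
      beta[cols] <- beta[cols] + alpha * (b - beta[cols])
      drop <- P[beta[P] <= tol]
      beta[drop] <- 0
      P <- setdiff(P, drop)
      cols <- c(U, P)
      b <- ls_solve(cols)
    }
    beta[] <- 0
    beta[cols] <- b
    r <- y - X[, cols, drop = FALSE] %*% b
    out <- setdiff(C, P)
    if (length(out) == 0) break
    w <- as.numeric(crossprod(X[, out, drop = FALSE], r))
    if (all(w <= tol)) break
    P <- c(P, out[which.max(w)])
  }
  active <- P[beta[P] > tol]
  dof <- n - (length(U) + length(active))
  if (dof <= 0) stop("no residual degrees of freedom")
  rss <- sum(r^2)
  fit <- list(beta = stats::setNames(beta, colnames(X)),
              sigma2 = rss / dof, dof = dof,
              active_set = sort(active),
              residuals = as.numeric(r),
              tag = design$tag %||% NA_character_)
  class(fit) <- "glm_fit"
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' t-value of the canonical task regressor
#'
#' `t = beta_canonical / sqrt(sigma2 * [(X'X)^-1]_cc)` on the design
#' restricted to the unconstrained columns plus the active nuisance columns.
#' Zero-residual fits return a capped value of 1e6 with a warning.
#'
#' @param fit A `glm_fit` from [fit_glm_nnls()].
#' @param design The design the fit came from.
#' @param condition Task condition (`"left"` or `"right"`).
#' @return Scalar t-value.
#' @export
t_value <- function(fit, design, condition) {
  if (fit$dof <= 0) stop("non-positive degrees of freedom")
  cname <- design$canonical_cols[[condition]]
  if (is.null(cname)) stop("no canonical column for condition ", condition)
  U <- which(!design$nonneg_mask)
  cols <- sort(c(U, fit$active_set))
  Xr <- design$X[, cols, drop = FALSE]
  ci <- match(match(cname, colnames(design$X)), cols)
  xtx_inv <- chol2inv(chol(crossprod(Xr)))
  se <- sqrt(fit$sigma2 * xtx_inv[ci, ci])
  if (se == 0 || fit$sigma2 < .Machine$double.eps * mean(design$X[, ci]^2)) {
    warning("zero-residual fit; t capped at 1e6")
    return(sign(fit$beta[[cname]]) * 1e6)
  }
  tval <- fit$beta[[cname]] / se
  if (!is.finite(tval) || abs(tval) > 1e6) {
    warning("t exceeded cap; clipped to +/-1e6")
    tval <- sign(tval) * 1e6
  }
  tval
}
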