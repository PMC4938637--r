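# Spatial adjustment of augmented field trials with a separable
# AR1(row) x AR1(col) residual model:
#
#   y = X beta + s + e,   s ~ N(0, sigma_s^2 R_row (x) R_col),
#                         e ~ N(0, sigma_n^2 I)
#
# Fixed effects: intercept plus one mean per repeated check entry; unreplicated
# test entries enter only through the intercept (their genetic deviation is
# confounded with the nugget in an unreplicated design). Estimation maximizes
# the restricted likelihood over (rho_row, rho_col, h) with
# h = sigma_s^2 / (sigma_s^2 + sigma_n^2) and the total variance profiled out;
# a coarse grid seeds a bounded quasi-Newton refinement. On a complete grid
# the Kronecker eigenstructure makes each likelihood evaluation O(n_r^3 +
# n_c^3 + n); incomplete grids fall back to dense Cholesky on the observed
# plots.

# REML criterion pieces shared by both paths: given transformed ytil, Xtil and
# variance weights d (V = sigma2 * diag(d) in that basis), return -2*restricted
# loglik (up to a constant) with sigma2 profiled.
reml_neg2ll <- function(ytil, Xtil, d) {
  n <- length(ytil); p <- ncol(Xtil)
  XtDX <- crossprod(Xtil / d, Xtil)
  XtDy <- crossprod(Xtil / d, ytil)
  ch <- tryCatch(chol(XtDX), error = function(e) NULL)
  if (is.null(ch)) return(list(value = Inf))
  beta <- backsolve(ch, backsolve(ch, XtDy, transpose = TRUE))
  r <- ytil - Xtil %*% beta
  rss <- sum(r^2 / d)
  sigma2 <- rss / (n - p)
  val <- (n - p) * log(sigma2) + sum(log(d)) + 2 * sum(log(diag(ch))) + (n - p)
  list(value = val, beta = beta, sigma2 = sigma2)
}

# Evaluate the REML criterion at (rho_r, rho_c, h) for a complete grid.
# Y and X are in plot order (row-major, col fastest).
reml_eval_kron <- function(theta, y, X, rows, cols) {
  rho_r <- theta[1]; rho_c <- theta[2]; h <- theta[3]
  er <- eigen(ar1_corr(rows, rho_r), symmetric = TRUE)
  ec <- eigen(ar1_corr(cols, rho_c), symmetric = TRUE)
  kap <- as.vector(outer(ec$values, er$values))        # col index fastest
  d <- h * kap + (1 - h)
  # vec ordering: index = (r-1)*cols + c  ->  y = vec(Y) with Y[c, r]
  Ymat <- matrix(y, nrow = cols, ncol = rows)
  ytil <- as.vector(crossprod(ec$vectors, Ymat) %*% er$vectors)
  Xtil <- apply(X, 2, function(xc)
    as.vector(crossprod(ec$vectors, matrix(xc, cols, rows)) %*% er$vectors))
  out <- reml_neg2ll(ytil, Xtil, d)
  out$eig <- list(er = er, ec = ec, kap = kap, d = d)
  out
}

# Dense path for incomplete grids.
reml_eval_dense <- function(theta, y, X, row_i, col_i) {
  rho_r <- theta[1]; rho_c <- theta[2]; h <- theta[3]
  R <- (rho_r ^ abs(outer(row_i, row_i, "-"))) *
       (rho_c ^ abs(outer(col_i, col_i, "-")))
  V <- h * R + diag(1 - h, length(y))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(value = Inf))
  ytil <- backsolve(ch, y, transpose = TRUE)
  Xtil <- backsolve(ch, X, transpose = TRUE)
  out <- reml_neg2ll(ytil, Xtil, rep(1, length(y)))
  out$value <- out$value + 2 * sum(log(diag(ch)))
  out$R <- R
  out
}

#' Fit a separable AR1 x AR1 spatial model to a field trial
#'
#' Restricted-maximum-likelihood estimates of the row/column AR1 correlations
#' and the spatial and nugget variances, with check entries as fixed means.
#'
#' @param trial a [simulate_field_trial()] object or data.frame with columns
#'   `row`, `col`, `entry`, `is_check`, `value` (1-based grid coordinates).
#' @param rho_grid coarse grid of AR1 correlations used to seed the optimizer.
#' @return An object of class `spatial_fit`: `rho_row`, `rho_col`,
#'   `sigma_spatial2`, `sigma_nugget2`, `loglik` (-0.5 times the minimized
#'   REML criterion), `beta`, and `surface` (per-plot BLUP of the spatial
#'   effect, aligned with `trial`).
#' @export
fit_ar1xar1 <- function(trial, rho_grid = c(-0.5, 0, 0.3, 0.6, 0.85)) {
  stopifnot(is.data.frame(trial),
            all(c("row", "col", "entry", "is_check", "value") %in% names(trial)))
  if (anyDuplicated(trial[, c("row", "col")]))
    stop_genpred("duplicated (row, col) plot coordinates")
  rows <- max(trial$row); cols <- max(trial$col)
  if (length(unique(trial$row)) < 2)
    stop_genpred("degenerate grid: fewer than 2 distinct rows")
  if (length(unique(trial$col)) < 2)
    stop_genpred("degenerate grid: fewer than 2 distinct columns")
  complete <- nrow(trial) == rows * cols
  # order plots row-major (col fastest) for the Kronecker path
  ord <- order(trial$row, trial$col)
  tr <- trial[ord, , drop = FALSE]
  y <- tr$value
  checks <- sort(unique(tr$entry[tr$is_check]))
  X <- cbind(`(Intercept)` = rep(1, nrow(tr)))
  for (ck in checks) X <- cbind(X, as.numeric(tr$entry == ck))
  if (length(checks)) colnames(X)[-1] <- checks
  evalfun <- if (complete) {
    function(th) reml_eval_kron(th, y, X, rows, cols)$value
  } else {
    function(th) reml_eval_dense(th, y, X, tr$row, tr$col)$value
  }
  hs <- c(0.05, 0.3, 0.6, 0.9)
  grid <- expand.grid(rho_r = rho_grid, rho_c = rho_grid, h = hs)
  vals <- apply(grid, 1, evalfun)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- stats::nlminb(start, evalfun,
                       lower = c(-0.98, -0.98, 1e-6),
                       upper = c(0.98, 0.98, 1 - 1e-6))
  th <- opt$par
  # Parsimony guard: with rho ~ 0 the "spatial" field is white noise and
  # (rho_r, rho_c, h) are unidentified, so an arbitrary split would be
  # reported and the BLUP surface would soak up genuine residual. Keep the
  # spatial terms only if they beat the pure-nugget model by a 5% LRT on
  # their 3 parameters.
  null_val <- evalfun(c(0, 0, 1e-6))
  objective <- opt$objective
  if (null_val - opt$objective < stats::qchisq(0.95, df = 3)) {
    th <- c(0, 0, 1e-6)
    objective <- null_val
  }
  full <- if (complete) reml_eval_kron(th, y, X, rows, cols)
          else reml_eval_dense(th, y, X, tr$row, tr$col)
  sigma2 <- full$sigma2
  # BLUP of the spatial surface: s_hat = h R V^{-1} (y - X beta)
  resid <- y - X %*% full$beta
  if (complete) {
    er <- full$eig$er; ec <- full$eig$ec
    Rm <- matrix(resid, cols, rows)
    rt <- crossprod(ec$vectors, Rm) %*% er$vectors
    st <- (th[3] * full$eig$kap / full$eig$d) * as.vector(rt)
    surface <- as.vector(ec$vectors %*% matrix(st, cols, rows) %*% t(er$vectors))
  } else {
    V <- th[3] * full$R + diag(1 - th[3], length(y))
    surface <- drop(th[3] * full$R %*% solve(V, resid))
  }
  # map back to the original row order of `trial`
  surf_df <- data.frame(row = trial$row, col = trial$col,
                        effect = surface[match(seq_len(nrow(trial)), ord)])
  structure(list(rho_row = th[1], rho_col = th[2],
                 sigma_spatial2 = th[3] * sigma2,
                 sigma_nugget2 = (1 - th[3]) * sigma2,
                 loglik = -0.5 * objective,
                 beta = drop(full$beta), checks = checks,
                 surface = surf_df, complete_grid = complete),
            class = "spatial_fit")
}

#' @export
print.spatial_fit <- function(x, ...) {
  cat(sprintf("AR1xAR1 fit: rho_row = %.3f, rho_col = %.3f, sigma_s2 = %.4f, sigma_n2 = %.4f\n",
              x$rho_row, x$rho_col, x$sigma_spatial2, x$sigma_nugget2))
  invisible(x)
}

#' Spatially adjust plot values
#'
#' Subtracts the fitted spatial surface from each plot value and returns one
#' record per non-check plot as a long-format trait table (checks are used to
#' estimate the surface and then dropped).
#'
#' @param trial the field trial the fit was produced from.
#' @param fit a [fit_ar1xar1()] result on `trial`.
#' @return data.frame with `accession`, `environment`, `value`.
#' @export
adjust_phenotypes <- function(trial, fit) {
  stopifnot(inherits(fit, "spatial_fit"))
  m <- match(paste(trial$row, trial$col),
             paste(fit$surface$row, fit$surface$col))
  if (anyNA(m))
    stop_genpred("plot(s) in trial absent from the spatial fit")
  adjusted <- trial$value - fit$surface$effect[m]
  keep <- !trial$is_check
  env <- attr(trial, "environment") %||% "OPT"
  data.frame(accession = as.character(trial$entry[keep]),
             environment = rep(env, sum(keep)),
             value = adjusted[keep], stringsAsFactors = FALSE)
}
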