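#' Quantile level grids
#'
#' Standard grids of quantile levels used throughout the package: the
#' 19-level mapping grid (tau = 0.05, 0.10, ..., 0.95) used for quantile QTL
#' scans, and the 99-level weight grid (tau = 0.01, ..., 0.99) used for
#' qTWAS weight estimation.
#'
#' @param taus numeric vector of quantile levels in (0,1), strictly increasing.
#' @return An object of class `quantile_grid` (a validated numeric vector).
#' @export
quantile_grid <- function(taus) {
  taus <- as.numeric(taus)
  if (length(taus) == 0L) stop("quantile grid must contain at least one level")
  if (any(!is.finite(taus)) || any(taus <= 0) || any(taus >= 1))
    stop("quantile levels must lie strictly in (0, 1)")
  if (is.unsorted(taus, strictly = TRUE))
    stop("quantile levels must be strictly increasing")
  structure(taus, class = "quantile_grid")
}

#' @rdname quantile_grid
#' @export
mapping_grid <- function() quantile_grid(seq(0.05, 0.95, by = 0.05))

#' @rdname quantile_grid
#' @export
weight_grid <- function() quantile_grid(seq(0.01, 0.99, by = 0.01))

## Design matrix [1, C] with rank check. C may be NULL, a matrix, or a
## CovariateMatrix.
.null_design <- function(C, n) {
  if (inherits(C, "CovariateMatrix")) C <- C$values
  if (is.null(C)) {
    X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  C <- as.matrix(C)
  if (nrow(C) != n) stop("covariate rows (", nrow(C), ") != length of response (", n, ")")
  X <- cbind("(Intercept)" = 1, C)
  if (qr(X)$rank < ncol(X))
    stop("covariate matrix is rank deficient after adding an intercept")
  X
}

.check_loss <- function(r, tau) sum(r * (tau - (r < 0)))

.rq_solve <- function(X, y, tau, method = c("br", "fn")) {
  method <- match.arg(method)
  fit <- if (method == "fn" && nrow(X) > ncol(X) + 1L) {
    quantreg::rq.fit.fnb(X, y, tau = tau)
  } else {
    suppressWarnings(quantreg::rq.fit.br(X, y, tau = tau))
  }
  if (any(!is.finite(fit$coefficients)))
    stop("quantile regression solver failed to converge at tau = ", tau)
  fit
}

#' Fit the covariate-only quantile regression null model
#'
#' Minimizes the check loss sum_i rho_tau(Y_i - alpha0 - C_i'alpha) for a
#' single quantile level. This is the null model of the rank-score test;
#' it is fitted once per (phenotype, tau) and reused across all variants.
#'
#' @param y numeric response vector.
#' @param C covariate matrix (n x q), `CovariateMatrix`, or NULL.
#' @param tau quantile level in (0,1).
#' @param method `"br"` for the exact simplex solver (default), `"fn"` for the
#'   Frisch-Newton interior point solver (faster for large n; identical
#'   objective to numerical tolerance).
#' @return A `quantile_null_fit`: list with `tau`, `coefficients`
#'   (intercept first), `residuals`, and the achieved check-loss `objective`.
#' @export
fit_quantile_null <- function(y, C = NULL, tau, method = c("br", "fn")) {
  y <- as.numeric(y)
  n <- length(y)
  X <- .null_design(C, n)
  if (n <= ncol(X)) stop("need n > q + 1 observations to fit the null model")
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  fit <- .rq_solve(X, y, tau, method)
  structure(list(
    tau = tau,
    coefficients = stats::setNames(as.numeric(fit$coefficients), colnames(X)),
    residuals = as.numeric(fit$residuals),
    objective = .check_loss(as.numeric(fit$residuals), tau)
  ), class = "quantile_null_fit")
}

## Projection of g onto the orthogonal complement of span([1, C]),
## from a prepared QR decomposition.
.project_out <- function(qrX, g) qr.resid(qrX, g)

#' Quantile rank-score test for a single variant
#'
#' Computes the rank-score statistic
#' S = n^(-1/2) sum_i G*_i phi_tau(e_i), with phi_tau(u) = tau - 1(u < 0),
#' where e are the residuals of the covariate-only quantile fit and G* is the
#' projection of the dosage vector onto the orthogonal complement of the
#' column space of the intercept-augmented covariates. Under the null,
#' S / sigma ~ N(0,1) with sigma^2 = tau (1 - tau) ||G*||^2 / n.
#'
#' @param g dosage vector for one variant.
#' @param null_fit a `quantile_null_fit` from [fit_quantile_null()] computed on
#'   the same response and covariates.
#' @param C covariates used for the null fit (matrix, `CovariateMatrix`, or NULL).
#' @param qr_basis optional prepared `qr(cbind(1, C))`; supply it when testing
#'   many variants against the same null fit.
#' @return list with `S`, `sigma`, `z`, `p` (two-sided), `gstar_norm2`, and
#'   `untestable` (TRUE when the dosage lies in the covariate span, in which
#'   case no p-value is emitted).
#' @export
rank_score_test <- function(g, null_fit, C = NULL, qr_basis = NULL) {
  stopifnot(inherits(null_fit, "quantile_null_fit"))
  g <- as.numeric(g)
  n <- length(g)
  if (n != length(null_fit$residuals)) stop("dosage length does not match the null fit")
  if (is.null(qr_basis)) qr_basis <- qr(.null_design(C, n))
  gstar <- .project_out(qr_basis, g)
  ng2 <- sum(gstar^2)
  if (ng2 <= 1e-10 * max(1, sum(g^2))) {
    return(list(S = NA_real_, sigma = NA_real_, z = NA_real_, p = NA_real_,
                gstar_norm2 = ng2, untestable = TRUE))
  }
  tau <- null_fit$tau
  phi <- tau - (null_fit$residuals < 0)
  S <- sum(gstar * phi) / sqrt(n)
  sigma2 <- tau * (1 - tau) * ng2 / n
  z <- S / sqrt(sigma2)
  list(S = S, sigma = sqrt(sigma2), z = z, p = 2 * stats::pnorm(-abs(z)),
       gstar_norm2 = ng2, untestable = FALSE)
}

#' Cauchy combination of p-values
#'
#' Aggregates p-values via T = sum_i w_i tan((0.5 - p_i) pi) with weights
#' summing to one; the combined p-value is 0.5 - arctan(T)/pi. The transform
#' is robust to dependence between the inputs. Inputs are clipped to
#' [1e-15, 1 - 1e-15] before the tangent transform to avoid overflow.
#'
#' @param p numeric vector of p-values in (0,1); NAs are dropped.
#' @param weights optional non-negative weights (default uniform).
#' @return combined p-value in (0,1).
#' @export
cauchy_combine <- function(p, weights = NULL) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) stop("cauchy_combine: no p-values supplied")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (is.null(weights)) weights <- rep(1, length(p))
  if (length(weights) != length(p) || any(weights < 0))
    stop("weights must be non-negative and match p in length")
  w <- weights / sum(weights)
  pc <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  T_stat <- sum(w * tan((0.5 - pc) * pi))
  out <- 0.5 - atan(T_stat) / pi
  min(max(out, .Machine$double.xmin), 1)
}

#' Chatterjee's rank correlation coefficient and test
#'
#' Computes xi_n of y against x using the tie-corrected general formula
#' xi = 1 - n sum |r_(i+1) - r_(i)| / (2 sum l_i (n - l_i)) where ranks are
#' taken over y ordered by x. For tie-free y this reduces to
#' 1 - 3 sum |r_(i+1) - r_(i)| / (n^2 - 1). The one-sided (right-tail)
#' p-value uses the asymptotic null law sqrt(n) xi ~ N(0, 2/5); the
#' right tail is used because dependence is a positive-xi alternative.
#' Ties in x are broken deterministically by original index.
#'
#' @param x ordered predictor values (e.g. quantile levels).
#' @param y responses (e.g. per-quantile slope estimates).
#' @return list with `xi`, `p` (one-sided), and `n`.
#' @export
chatterjee_xi <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(y)
  if (n < 3L) stop("chatterjee_xi needs at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("x and y must be finite")
  ord <- order(x, seq_along(x))       # deterministic x tie-break
  ys <- y[ord]
  r <- as.numeric(rank(ys, ties.method = "max"))  # #{j : y_j <= y_i}
  l <- as.numeric(rank(-ys, ties.method = "max")) # #{j : y_j >= y_i}
  den <- 2 * sum(l * (n - l))
  if (den == 0) {
    warning("chatterjee_xi: all y values are equal; xi set to 0")
    return(list(xi = 0, p = 1, n = n))
  }
  xi <- 1 - n * sum(abs(diff(r))) / den
  p <- stats::pnorm(sqrt(n) * xi, mean = 0, sd = sqrt(2 / 5), lower.tail = FALSE)
  list(xi = xi, p = p, n = n)
}

#' Joint quantile regression over a grid of levels
#'
#' For each tau in `grid`, minimizes the check loss of Y on an intercept,
#' covariates C, and a block of predictors X fitted jointly. Used for qTWAS
#' weight estimation (99-level grid) and for per-quantile slope profiles.
#'
#' @param y response vector.
#' @param X predictor block (n x p matrix or vector).
#' @param C covariates (matrix, `CovariateMatrix`, or NULL).
#' @param grid a `quantile_grid` or numeric vector of levels.
#' @param method solver, as in [fit_quantile_null()].
#' @return list with `taus`, `coefficients` (full (1+q+p) x K matrix),
#'   and `slopes` (p x K matrix for the X block).
#' @export
fit_quantile_joint <- function(y, X, C = NULL, grid = weight_grid(),
                               method = c("br", "fn")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  n <- length(y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  base <- .null_design(C, n)
  D <- cbind(base, X)
  if (qr(D)$rank < ncol(D))
    stop("joint design is rank deficient (predictor collinear with covariates?)")
  if (ncol(D) >= n) stop("need p + q + 1 < n for the joint fit")
  taus <- as.numeric(grid)
  K <- length(taus)
  coefs <- matrix(NA_real_, ncol(D), K, dimnames = list(colnames(D), NULL))
  for (k in seq_len(K)) {
    fit <- .rq_solve(D, y, taus[k], method)
    coefs[, k] <- fit$coefficients
  }
  xrows <- seq.int(ncol(base) + 1L, ncol(D))
  list(taus = taus, coefficients = coefs,
       slopes = coefs[xrows, , drop = FALSE])
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal scores qnorm((rank - c) / (n - 2c + 1)) with the
#' Blom offset c = 3/8. Ties receive their average rank.
#'
#' @param y numeric vector.
#' @param c offset (default 3/8).
#' @return transformed vector.
#' @export
rint <- function(y, c = 3 / 8) {
  r <- rank(y, ties.method = "average")
  stats::qnorm((r - c) / (length(y) - 2 * c + 1))
}
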