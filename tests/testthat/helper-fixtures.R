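## Shared in-code fixtures. All randomness is seeded per call site.

## Brute-force 1-D check-loss minimizer over a fine grid (independent oracle
## for intercept-only quantile fits).
brute_force_quantile <- function(y, tau, grid = NULL) {
  if (is.null(grid)) grid <- seq(min(y) - 1, max(y) + 1, by = 1e-3)
  loss <- vapply(grid, function(a) {
    r <- y - a
    sum(r * (tau - (r < 0)))
  }, numeric(1))
  grid[which.min(loss)]
}

## Direct evaluation of the rank-score statistic from its definition.
rank_score_direct <- function(g, y, C, alpha_hat, tau) {
  n <- length(y)
  X <- if (is.null(C) || length(C) == 0L) matrix(1, n, 1) else cbind(1, C)
  gstar <- g - X %*% solve(crossprod(X), crossprod(X, g))
  resid <- y - X %*% alpha_hat
  phi <- tau - (resid < 0)
  S <- sum(gstar * phi) / sqrt(n)
  sigma2 <- tau * (1 - tau) * sum(gstar^2) / n
  list(S = S, sigma = sqrt(sigma2))
}

## Small aligned study: genotypes, covariates, and a phenotype generated
## under the requested model for the first variant.
small_study <- function(n = 300, m = 8, q = 2, kind = "null", seed = 42, ...) {
  geno <- gen_genotypes(n, m, maf = c(0.2, 0.5), seed = seed)
  covar <- gen_covariates(n, q, seed = seed + 1)
  spec <- pheno_model_spec(kind, ...)
  y <- gen_phenotype(geno$dosages[, 1], spec, C = covar, seed = seed + 2)
  list(geno = geno, covar = covar, y = as.numeric(y), spec = spec,
       attr_y = attributes(y))
}

## Toy LD matrix from explicit correlations.
toy_ld <- function(ids, r) {
  p <- length(ids)
  S <- diag(p)
  for (nm in names(r)) {
    ij <- as.integer(strsplit(nm, ",")[[1]])
    S[ij[1], ij[2]] <- S[ij[2], ij[1]] <- r[[nm]]
  }
  dimnames(S) <- list(ids, ids)
  ld_matrix(S, ids)
}
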