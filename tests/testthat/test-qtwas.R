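test_that("select_and_prune drops correlated and absent variants", {
  ld <- toy_ld(c("a", "b", "c"), list("1,2" = sqrt(0.95)))
  v <- data.frame(variant_id = c("a", "b", "c"), p = c(1e-8, 1e-6, 1e-4))
  expect_setequal(select_and_prune(v, ld), c("a", "c"))
  ## all pairwise r2 < 0.8: all retained
  ld2 <- toy_ld(c("a", "b", "c"), list("1,2" = 0.5, "2,3" = 0.5))
  expect_setequal(select_and_prune(v, ld2), c("a", "b", "c"))
  ## absent variant dropped with a message
  expect_message(kept <- select_and_prune(
    data.frame(variant_id = c("a", "zz"), p = c(0.1, 0.01)), ld2), "dropped")
  expect_equal(kept, "a")
})

test_that("weight estimation recovers location and scale patterns", {
  set.seed(61)
  n <- 2000
  g <- rbinom(n, 2, 0.3)
  G <- matrix(g, ncol = 1, dimnames = list(NULL, "v1"))
  taus <- quantile_grid(seq(0.05, 0.95, by = 0.05))
  ## location model: flat weights near beta
  y <- 0.5 * g + rnorm(n)
  W <- estimate_weights(y, G, NULL, grid = taus, gene_id = "g1", method = "fn")
  expect_lt(max(abs(W$weights - 0.5)), 0.2)
  ## scale model: weights track s * qnorm(tau), sign change at the median
  y2 <- (1 + 0.5 * g) * rnorm(n)
  W2 <- estimate_weights(y2, G, NULL, grid = taus, method = "fn")
  expected <- 0.5 * qnorm(as.numeric(taus))
  expect_lt(sqrt(mean((W2$weights[1, ] - expected)^2)), 0.1)
  expect_lt(W2$weights[1, 1], 0)
  expect_gt(W2$weights[1, 19], 0)
  ## null: mean weight near zero
  y3 <- rnorm(n)
  W3 <- estimate_weights(y3, G, NULL, grid = taus, method = "fn")
  expect_lt(abs(mean(W3$weights)), 0.05)
})

test_that("collinear variants are dropped deterministically by id order", {
  set.seed(62)
  n <- 200
  g <- rbinom(n, 2, 0.3)
  G <- cbind(v1 = g, v2 = g) # identical columns
  expect_message(W <- estimate_weights(rnorm(n), G, NULL,
                                       grid = quantile_grid(0.5)), "collinear")
  expect_equal(W$variant_ids, "v1")
})

test_that("fixed regions partition the 99-level grid into three 33-level blocks", {
  r <- make_fixed_regions()
  expect_equal(vapply(r$regions, length, integer(1)),
               c(lower = 33L, middle = 33L, upper = 33L))
  expect_equal(unname(sort(unlist(r$regions))), 1:99)
  for (reg in r$regions) expect_equal(reg, seq(min(reg), max(reg)))
})

test_that("dynamic regions: constant weights give one region, sign flips split near the median", {
  taus99 <- weight_grid()
  ## constant weights -> K = 1
  Wc <- structure(list(gene_id = "g", variant_ids = "v1",
                       taus = as.numeric(taus99),
                       weights = matrix(0.4, 1, 99)), class = "WeightMatrix")
  rc <- make_dynamic_regions(Wc)
  expect_equal(length(rc$regions), 1L)
  ## scale-model weight profile: boundary within tau [0.45, 0.55]
  Ws <- structure(list(gene_id = "g", variant_ids = "v1",
                       taus = as.numeric(taus99),
                       weights = matrix(0.5 * qnorm(as.numeric(taus99)), 1, 99)),
                  class = "WeightMatrix")
  rs <- make_dynamic_regions(Ws)
  expect_gte(length(rs$regions), 2L)
  ends <- cumsum(vapply(rs$regions, length, integer(1)))
  boundary_taus <- as.numeric(taus99)[utils::head(ends, -1)]
  expect_true(any(boundary_taus >= 0.40 & boundary_taus <= 0.60))
  ## K never exceeds the cap; regions contiguous, disjoint, covering
  set.seed(63)
  Wn <- structure(list(gene_id = "g", variant_ids = paste0("v", 1:3),
                       taus = as.numeric(taus99),
                       weights = matrix(rnorm(3 * 99), 3, 99)),
                  class = "WeightMatrix")
  rn <- make_dynamic_regions(Wn, k_max = 4)
  expect_lte(length(rn$regions), 4L)
  expect_equal(unname(sort(unlist(rn$regions))), 1:99)
})

test_that("weight integration sums per region and conserves the total", {
  W <- structure(list(gene_id = "g", variant_ids = c("v1", "v2"),
                      taus = c(0.2, 0.4, 0.6, 0.8),
                      weights = matrix(c(1, 2, 3, 4, 10, 20, 30, 40),
                                       2, 4, byrow = TRUE)),
                 class = "WeightMatrix")
  regions <- structure(list(regions = list(a = 1:2, b = 3:4),
                            taus = W$taus, method = "fixed"),
                       class = "QuantileRegionSet")
  om <- integrate_weights(W, regions)
  expect_equal(unname(om[, "a"]), c(1 + 2, 10 + 20))
  expect_equal(unname(om[, "b"]), c(3 + 4, 30 + 40))
  expect_equal(unname(rowSums(om)), unname(rowSums(W$weights)))
})

test_that("region association matches direct matrix arithmetic and is scale invariant", {
  ## single variant identity
  r1 <- region_assoc(1, 3, matrix(1))
  expect_equal(r1$Z, 3)
  ## two-variant derived case: Z = 4 / sqrt(3)
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  r2 <- region_assoc(c(1, 1), c(2, 2), S)
  expect_equal(r2$Z, 4 / sqrt(3), tolerance = 1e-12)
  ## scaling weights by c > 0 leaves Z unchanged
  r3 <- region_assoc(c(7, 7), c(2, 2), S)
  expect_equal(r3$Z, r2$Z, tolerance = 1e-12)
  expect_error(region_assoc(c(1, 1), c(1, 2, 3), S), "dimension")
})

test_that("gene-level combination reduces to the region p for K = 1 and at equal p", {
  one <- gene_assoc(data.frame(region = "r1", Z = 2, p = 0.04))
  expect_equal(one$combined_p, 0.04, tolerance = 1e-12)
  eq <- gene_assoc(data.frame(region = c("a", "b", "c"), Z = 0,
                              p = rep(0.01, 3)))
  expect_equal(eq$combined_p, 0.01, tolerance = 1e-10)
  expect_error(gene_assoc(data.frame()), "no region")
})

test_that("qTWAS region test is calibrated under null GWAS z-scores", {
  set.seed(64)
  gl <- gen_gwas_and_ld(p = 6, rho = 0.6, n_panel = 400, seed = 64)
  S <- gl$ld$sigma
  R <- chol(S + diag(1e-8, 6))
  omega <- rnorm(6)
  hits <- logical(2000)
  for (r in seq_along(hits)) {
    z <- as.numeric(crossprod(R, rnorm(6)))
    hits[r] <- region_assoc(omega, z, S)$p < 0.05
  }
  expect_gte(mean(hits), 0.035)
  expect_lte(mean(hits), 0.065)
})

test_that("allele flips in the GWAS leave qTWAS |Z| unchanged", {
  set.seed(65)
  n <- 600
  geno <- gen_genotypes(n, 5, maf = c(0.2, 0.4), seed = 65)
  y <- 0.4 * geno$dosages[, 2] + rnorm(n)
  ld <- read_ld(panel = geno)
  W <- estimate_weights(y, geno, NULL, grid = quantile_grid(seq(0.1, 0.9, 0.2)),
                        gene_id = "g", method = "fn")
  gl <- gen_gwas_and_ld(p = 5, seed = 66)
  gwas <- gl$gwas
  gwas$id <- geno$variants$id
  gwas$pos <- geno$variants$pos
  z1 <- harmonize_gwas(gwas, geno$variants)
  ## flip alleles and z sign for variants 2 and 4
  gwas2 <- gwas
  flip <- c(2, 4)
  gwas2$a1[flip] <- gwas$a2[flip]
  gwas2$a2[flip] <- gwas$a1[flip]
  gwas2$z[flip] <- -gwas$z[flip]
  z2 <- harmonize_gwas(gwas2, geno$variants)
  expect_equal(z1$z, z2$z)
  r1 <- qtwas_assoc(W, setNames(z1$z, z1$id), ld, regions = "fixed")
  r2 <- qtwas_assoc(W, setNames(z2$z, z2$id), ld, regions = "fixed")
  expect_equal(abs(r1$regions$Z), abs(r2$regions$Z), tolerance = 1e-12)
})

test_that("end-to-end qTWAS flags an injected signal and not a null gene", {
  set.seed(67)
  n <- 1000
  geno <- gen_genotypes(n, 4, maf = c(0.2, 0.4), seed = 67)
  y <- 0.5 * geno$dosages[, 1] + rnorm(n)
  W <- estimate_weights(y, geno, NULL, gene_id = "g",
                        grid = quantile_grid(seq(0.05, 0.95, 0.05)),
                        method = "fn")
  ## GWAS with signal along the gene weights
  gl_sig <- gen_gwas_and_ld(weights = W, rho = 0.5, lambda = 6,
                            n_panel = 500, seed = 68)
  z_sig <- setNames(gl_sig$gwas$z, gl_sig$gwas$id)
  res_sig <- qtwas_assoc(W, z_sig, gl_sig$ld, regions = "fixed")
  expect_lt(res_sig$combined_p, 0.01)
  ## same weights against a null GWAS
  gl_null <- gen_gwas_and_ld(weights = W, rho = 0.5, lambda = 0,
                             n_panel = 500, seed = 69)
  z_null <- setNames(gl_null$gwas$z, gl_null$gwas$id)
  ps <- vapply(1:60, function(r) {
    gl0 <- gen_gwas_and_ld(weights = W, rho = 0.5, lambda = 0,
                           n_panel = 500, seed = 1000 + r)
    qtwas_assoc(W, setNames(gl0$gwas$z, gl0$gwas$id), gl0$ld,
                regions = "fixed")$combined_p
  }, numeric(1))
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.0)
  expect_lte(rate, 0.15)
})
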