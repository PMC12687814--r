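test_that("cis windows follow the whichever-longer rule and contain the gene body", {
  genes <- data.frame(gene_id = "g1", chrom = "1",
                      start = 10000000, end = 10020000)
  ## no TAD: TSS-centered 2 Mb
  w <- build_cis_windows(genes)
  expect_equal(w$start, 9000000)
  expect_equal(w$end, 11000000)
  ## enclosing 3 Mb TAD wins
  tad3 <- data.frame(chrom = "1", start = 8800000, end = 11800000)
  w3 <- build_cis_windows(genes, tadb = tad3)
  expect_equal(w3$start, 8800000)
  expect_equal(w3$end, 11800000)
  ## 1 Mb TAD loses to the 2 Mb span
  tad1 <- data.frame(chrom = "1", start = 9800000, end = 10800000)
  w1 <- build_cis_windows(genes, tadb = tad1)
  expect_equal(w1$end - w1$start, 2e6)
  ## chromosome missing from TAD table falls back with a message
  tadx <- data.frame(chrom = "2", start = 0, end = 5e6)
  expect_message(wx <- build_cis_windows(genes, tadb = tadx), "absent")
  expect_equal(wx$end - wx$start, 2e6)
})

test_that("xQTL scan matches lm() on a single variant and detects an exact signal", {
  set.seed(2)
  n <- 80
  C <- matrix(rnorm(n * 2), n, 2)
  g <- rbinom(n, 2, 0.4)
  y <- 0.4 * g + C %*% c(1, -1) + rnorm(n)
  res <- map_xqtl(y, matrix(g, ncol = 1, dimnames = list(NULL, "v1")), C)
  ref <- summary(lm(y ~ g + C))$coefficients["g", ]
  expect_equal(res$beta, unname(ref["Estimate"]), tolerance = 1e-10)
  expect_equal(res$p_nominal, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
  ## exact linear signal: slope recovered, p at the floor
  y2 <- 2 * g
  res2 <- map_xqtl(y2, matrix(g, ncol = 1, dimnames = list(NULL, "v1")), NULL)
  expect_equal(res2$beta, 2, tolerance = 1e-8)
  expect_lt(res2$p_nominal, 1e-200)
})

test_that("xQTL null p-values are calibrated across many variants", {
  set.seed(9)
  n <- 150
  G <- matrix(rbinom(n * 400, 2, 0.3), n, 400)
  colnames(G) <- paste0("v", 1:400)
  y <- rnorm(n)
  res <- map_xqtl(y, G, NULL)
  expect_gt(mean(res$p_nominal < 0.05), 0.02)
  expect_lt(mean(res$p_nominal < 0.05), 0.09)
})

test_that("qQTL scan detects a scale effect that the linear scan misses", {
  set.seed(31)
  n <- 2000
  g <- rbinom(n, 2, 0.3)
  hits_q <- hits_x <- logical(8)
  for (r in 1:8) {
    y <- (1 + 0.6 * g) * rnorm(n)
    q <- map_qqtl(y, matrix(g, ncol = 1, dimnames = list(NULL, "v1")), NULL,
                  method = "fn")
    x <- map_xqtl(y, matrix(g, ncol = 1, dimnames = list(NULL, "v1")), NULL)
    hits_q[r] <- q$pairs$p_nominal < 1e-4
    hits_x[r] <- x$p_nominal > 0.01
  }
  expect_gte(mean(hits_q), 0.75)
  expect_gte(mean(hits_x), 0.6)
})

test_that("qQTL scan under a location model agrees with the linear scan", {
  set.seed(32)
  n <- 1500
  g <- rbinom(n, 2, 0.3)
  y <- 0.5 * g + rnorm(n)
  q <- map_qqtl(y, matrix(g, ncol = 1, dimnames = list(NULL, "v1")), NULL,
                method = "fn")
  x <- map_xqtl(y, matrix(g, ncol = 1, dimnames = list(NULL, "v1")), NULL)
  expect_lt(q$pairs$p_nominal, 1e-6)
  expect_lt(x$p_nominal, 1e-6)
  ## per-tau slopes approximately constant: refit joint slopes
  sl <- quantile_slopes(y, g, NULL, method = "fn")
  expect_lt(max(sl) - min(sl), 0.25)
})

test_that("qQTL combined p-values are uniform under the null", {
  set.seed(33)
  n <- 300
  G <- matrix(rbinom(n * 150, 2, 0.3), n, 150)
  colnames(G) <- paste0("v", 1:150)
  y <- rnorm(n)
  q <- map_qqtl(y, G, NULL, method = "fn")
  p <- q$pairs$p_nominal
  expect_gt(mean(p < 0.05), 0.01)
  expect_lt(mean(p < 0.05), 0.10)
})

test_that("vQTL shares per-tau rank scores with qQTL bit-for-bit", {
  set.seed(34)
  n <- 400
  g <- rbinom(n, 2, 0.3)
  y <- (1 + 0.4 * g) * rnorm(n)
  scan <- map_qqtl(y, matrix(g, ncol = 1, dimnames = list(NULL, "v1")), NULL)
  v1 <- map_vqtl(scan = scan)
  v2 <- map_vqtl(y, matrix(g, ncol = 1, dimnames = list(NULL, "v1")), NULL)
  expect_identical(v1$V, v2$V)
  expect_identical(v1$p_nominal, v2$p_nominal)
  ## V is the stated contrast of the scan's own S values
  taus <- round(scan$taus, 10)
  lower <- taus[taus < 0.5]
  V_hand <- sum(scan$S[1, match(round(1 - lower, 10), taus)] -
                  scan$S[1, match(lower, taus)])
  expect_equal(v1$V, V_hand, tolerance = 1e-12)
})

test_that("vQTL has power for scale effects and stays calibrated under location shifts", {
  set.seed(35)
  n <- 2000
  g <- rbinom(n, 2, 0.3)
  hits <- logical(6)
  for (r in 1:6) {
    y <- (1 + 0.6 * g) * rnorm(n)
    v <- map_vqtl(y, matrix(g, ncol = 1, dimnames = list(NULL, "v1")), NULL,
                  method = "fn")
    hits[r] <- v$p_nominal < 1e-4
  }
  expect_gte(mean(hits), 0.8)
  ## moderate location-only shift: variance contrast stays near nominal
  ## (the score contrast cancels mean effects to first order; very large
  ## shifts inflate it -- documented limitation)
  set.seed(36)
  n2 <- 1000
  ps <- numeric(300)
  for (r in seq_along(ps)) {
    g2 <- rbinom(n2, 2, 0.3)
    y2 <- 0.3 * g2 + rnorm(n2)
    ps[r] <- map_vqtl(y2, matrix(g2, ncol = 1, dimnames = list(NULL, "v1")),
                      NULL, method = "fn")$p_nominal
  }
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.09)
})

test_that("iQTL detects interactions, is calibrated under the null, and filters by MAF", {
  set.seed(37)
  n <- 400
  hits <- logical(20)
  for (r in 1:20) {
    g <- rbinom(n, 2, 0.3)
    f <- rbinom(n, 2, 0.3)
    y <- 0.3 * g + 0.8 * g * f + rnorm(n)
    res <- map_iqtl(y, matrix(g, ncol = 1, dimnames = list(NULL, "v1")), f, NULL)
    hits[r] <- res$p_nominal < 0.05
  }
  expect_gte(mean(hits), 0.7)
  ## null interaction: uniform p
  ps <- numeric(200)
  for (r in seq_along(ps)) {
    g <- rbinom(n, 2, 0.3)
    f <- rbinom(n, 2, 0.3)
    y <- 0.3 * g + rnorm(n)
    ps[r] <- map_iqtl(y, matrix(g, ncol = 1, dimnames = list(NULL, "v1")), f,
                      NULL)$p_nominal
  }
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
  ## MAF filter: a rare variant is excluded
  g_rare <- c(rep(0, 390), rep(1, 10)) # MAF 0.0125
  G2 <- cbind(v_rare = g_rare, v_ok = rbinom(n, 2, 0.3))
  y <- rnorm(n)
  res2 <- map_iqtl(y, G2, rbinom(n, 2, 0.3), NULL)
  expect_equal(res2$variant_id, "v_ok")
  ## constant factor errors
  expect_error(map_iqtl(y, G2, rep(1, n), NULL), "constant")
})

test_that("iQTL directionality classification follows the sign/significance rules", {
  expect_equal(classify_iqtl_direction(0.3, 0.2, 0.001), "amplifying")
  expect_equal(classify_iqtl_direction(0.3, -0.2, 0.001), "counteracting")
  expect_equal(classify_iqtl_direction(0.3, -0.2, 0.2), "uncertain")
  expect_equal(classify_iqtl_direction(-0.3, -0.2, 0.01), "amplifying")
})

test_that("hierarchical correction reproduces the worked 3-gene example", {
  pairs <- data.frame(
    gene_id = c("A", "A", "B", "C", "C", "C", "C"),
    variant_id = c("a1", "a2", "b1", "c1", "c2", "c3", "c4"),
    p_nominal = c(0.001, 0.5, 0.03, 0.2, 0.9, 0.9, 0.9))
  h <- hierarchical_correct(pairs, fdr = 0.05)
  expect_equal(h$genes$lead_p_bonf, c(0.002, 0.03, 0.8))
  expect_equal(h$genes$q, c(0.006, 0.045, 0.8))
  expect_equal(h$genes$significant, c(TRUE, TRUE, FALSE))
  expect_equal(h$t_star, 0.03)
  sig <- h$pairs[h$pairs$significant, ]
  expect_setequal(paste(sig$gene_id, sig$variant_id), c("A a1", "B b1"))
})

test_that("hierarchical correction handles single pairs and empty significance", {
  one <- hierarchical_correct(data.frame(gene_id = "g", variant_id = "v",
                                         p_nominal = 0.01))
  expect_equal(one$genes$q, 0.01)
  expect_true(one$pairs$significant)
  none <- hierarchical_correct(data.frame(gene_id = c("g1", "g2"),
                                          variant_id = c("v1", "v2"),
                                          p_nominal = c(0.5, 0.9)))
  expect_null(none$t_star)
  expect_false(any(none$pairs$significant))
})

test_that("stage 2 never admits a pair from a non-significant gene", {
  set.seed(40)
  pairs <- data.frame(
    gene_id = rep(paste0("g", 1:20), each = 5),
    variant_id = paste0("v", 1:100),
    p_nominal = runif(100))
  pairs$p_nominal[1:5] <- 1e-6 # one clearly significant gene
  h <- hierarchical_correct(pairs)
  sig <- h$pairs[h$pairs$significant, ]
  expect_true(all(sig$gene_id %in% h$genes$gene_id[h$genes$significant]))
  expect_true(all(sig$p_bonf <= h$t_star))
})

test_that("hierarchical procedure controls gene-level FDR in simulation", {
  ## 200 fast replicates: 20 genes x 8 variants, 90% null, xQTL p-values
  set.seed(41)
  n <- 150
  fdp <- numeric(200)
  for (r in seq_len(200)) {
    G <- matrix(rbinom(n * 160, 2, 0.3), n, 160)
    pnom <- gene <- vector("list", 20)
    for (gi in 1:20) {
      cols <- ((gi - 1) * 8 + 1):(gi * 8)
      causal <- gi <= 2 # 10% non-null genes
      y <- rnorm(n) + if (causal) 0.5 * G[, cols[1]] else 0
      pnom[[gi]] <- .subset2(map_xqtl(y, G[, cols, drop = FALSE], NULL), "p_nominal")
      gene[[gi]] <- rep(paste0("g", gi), 8)
    }
    pairs <- data.frame(gene_id = unlist(gene),
                        variant_id = paste0("v", 1:160),
                        p_nominal = unlist(pnom))
    h <- hierarchical_correct(pairs, fdr = 0.05)
    sig_genes <- h$genes$gene_id[h$genes$significant]
    fdp[r] <- if (length(sig_genes) == 0) 0 else
      mean(!(sig_genes %in% c("g1", "g2")))
  }
  expect_lte(mean(fdp), 0.065)
})
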