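## cis-window construction, the four QTL scans (xQTL / qQTL / vQTL / iQTL),
## and the two-stage hierarchical multiple-testing correction.

#' Build cis testing windows
#'
#' The testing interval for a gene is the topologically associated domain
#' (TAD) interval containing its start coordinate when that interval is
#' longer than `span`, and a `span`-wide window centered on the gene start
#' otherwise ("whichever longer"). The window is always extended to contain
#' the gene body and clipped at chromosome bounds when lengths are supplied.
#' Genes on chromosomes absent from the TAD table fall back to the default
#' span with a message.
#'
#' @param genes data.frame(gene_id, chrom, start, end), BED convention.
#' @param tadb optional data.frame(chrom, start, end) of TAD intervals.
#' @param span default window width in bp (default 2 Mb).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return data.frame(gene_id, chrom, start, end) of 0-based half-open windows.
#' @export
build_cis_windows <- function(genes, tadb = NULL, span = 2e6,
                              chrom_lengths = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (any(genes$end <= genes$start)) stop("invalid gene coordinates")
  n_fallback <- 0L
  out <- lapply(seq_len(nrow(genes)), function(i) {
    chrom <- genes$chrom[i]; tss <- genes$start[i]
    ws <- tss - span / 2; we <- tss + span / 2
    if (!is.null(tadb)) {
      tc <- tadb[.strip_chr(tadb$chrom) == .strip_chr(chrom) &
                   tadb$start <= tss & tss < tadb$end, , drop = FALSE]
      if (nrow(tc) > 0L) {
        tc <- tc[which.max(tc$end - tc$start), ]
        if (tc$end - tc$start > span) { ws <- tc$start; we <- tc$end }
      } else if (!any(.strip_chr(tadb$chrom) == .strip_chr(chrom))) {
        n_fallback <<- n_fallback + 1L
      }
    }
    ws <- min(ws, genes$start[i]); we <- max(we, genes$end[i])
    ws <- max(0, ws)
    if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths))
      we <- min(we, chrom_lengths[[chrom]])
    data.frame(gene_id = genes$gene_id[i], chrom = chrom,
               start = ws, end = we)
  })
  if (n_fallback > 0L)
    message("build_cis_windows: ", n_fallback,
            " gene(s) on chromosomes absent from the TAD table; used the default span")
  do.call(rbind, out)
}

#' Subset variants of a dosage matrix to a cis window
#'
#' A variant (1-based position) lies in a 0-based half-open window
#' iff pos - 1 is in [start, end).
#'
#' @param geno `DosageMatrix`.
#' @param window one row of [build_cis_windows()] output.
#' @return `DosageMatrix` restricted to the window (possibly 0 variants).
#' @export
cis_variants <- function(geno, window) {
  v <- geno$variants
  keep <- .strip_chr(v$chrom) == .strip_chr(window$chrom) &
    (v$pos - 1) >= window$start & (v$pos - 1) < window$end
  dosage_matrix(geno$dosages[, keep, drop = FALSE], v[keep, , drop = FALSE],
                geno$samples)
}

## Fast covariate-adjusted OLS scan by Frisch-Waugh-Lovell: residualize y and
## every dosage column on [1, C] once, then slope t-tests with df = n - q - 2.
.ols_scan <- function(y, G, C = NULL) {
  n <- length(y)
  X <- .null_design(C, n)
  qrX <- qr(X)
  ystar <- qr.resid(qrX, y)
  Gstar <- qr.resid(qrX, as.matrix(G))
  ss <- colSums(Gstar^2)
  untestable <- ss <= 1e-10 * pmax(1, colSums(as.matrix(G)^2))
  beta <- colSums(Gstar * ystar) / ss
  rss <- sum(ystar^2) - beta^2 * ss
  df <- n - ncol(X) - 1L
  se <- sqrt(pmax(rss, 0) / df / ss)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  beta[untestable] <- se[untestable] <- tval[untestable] <- p[untestable] <- NA_real_
  data.frame(beta = beta, se = se, t = tval, p = p, untestable = untestable)
}

#' Linear (mean-effect) QTL scan for one gene
#'
#' Per-variant ordinary least squares slope of the phenotype on dosage,
#' adjusted for covariates, with a two-sided t-test.
#'
#' @param y phenotype vector for the gene.
#' @param G `DosageMatrix` (cis window) or dosage matrix.
#' @param C covariates (matrix, `CovariateMatrix`, or NULL).
#' @return data.frame(variant_id, beta, se, t, p_nominal, untestable).
#' @export
map_xqtl <- function(y, G, C = NULL) {
  dos <- if (inherits(G, "DosageMatrix")) G$dosages else as.matrix(G)
  ids <- if (inherits(G, "DosageMatrix")) G$variants$id else colnames(dos)
  if (is.null(ids)) ids <- paste0("v", seq_len(ncol(dos)))
  res <- .ols_scan(as.numeric(y), dos, C)
  data.frame(variant_id = ids, method = "xqtl", beta = res$beta, se = res$se,
             statistic = res$t, p_nominal = res$p, untestable = res$untestable,
             stringsAsFactors = FALSE)
}

#' Quantile QTL scan for one gene
#'
#' Fits the covariate-only quantile regression null model once per quantile
#' level, then evaluates the rank-score statistic for every variant at every
#' level and aggregates the per-level p-values per variant with the Cauchy
#' combination.
#'
#' @param y phenotype vector.
#' @param G `DosageMatrix` or dosage matrix.
#' @param C covariates.
#' @param grid quantile levels (default the 19-level mapping grid).
#' @param method quantile solver (see [fit_quantile_null()]).
#' @return object of class `qqtl_scan`: list with `pairs`
#'   (variant_id, p_nominal = Cauchy-combined p, untestable), matrices
#'   `S`, `sd`, `p_tau` (variants x levels), `gstar_norm2`, and `taus`.
#' @export
map_qqtl <- function(y, G, C = NULL, grid = mapping_grid(),
                     method = c("br", "fn")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  n <- length(y)
  dos <- if (inherits(G, "DosageMatrix")) G$dosages else as.matrix(G)
  ids <- if (inherits(G, "DosageMatrix")) G$variants$id else colnames(dos)
  if (is.null(ids)) ids <- paste0("v", seq_len(ncol(dos)))
  taus <- as.numeric(grid)
  X <- .null_design(C, n)
  qrX <- qr(X)
  Gstar <- qr.resid(qrX, dos)
  ng2 <- colSums(Gstar^2)
  untestable <- ng2 <= 1e-10 * pmax(1, colSums(dos^2))
  K <- length(taus)
  m <- ncol(dos)
  S <- sdm <- pm <- matrix(NA_real_, m, K, dimnames = list(ids, taus))
  for (k in seq_len(K)) {
    nf <- fit_quantile_null(y, C, taus[k], method = method)
    phi <- taus[k] - (nf$residuals < 0)
    S[, k] <- as.numeric(crossprod(Gstar, phi)) / sqrt(n)
    sdm[, k] <- sqrt(taus[k] * (1 - taus[k]) * ng2 / n)
    z <- S[, k] / sdm[, k]
    pm[, k] <- 2 * stats::pnorm(-abs(z))
  }
  S[untestable, ] <- sdm[untestable, ] <- pm[untestable, ] <- NA_real_
  comb <- rep(NA_real_, m)
  ok <- which(!untestable)
  for (j in ok) comb[j] <- cauchy_combine(pm[j, ])
  structure(list(
    pairs = data.frame(variant_id = ids, method = "qqtl", p_nominal = comb,
                       untestable = untestable, stringsAsFactors = FALSE),
    S = S, sd = sdm, p_tau = pm, gstar_norm2 = ng2, taus = taus, n = n
  ), class = "qqtl_scan")
}

#' Variance QTL scan via a rank-score quantile contrast
#'
#' Aggregates, over grid levels tau < 0.5 paired with 1 - tau, the contrast
#' V = sum (S_{1-tau} - S_tau) of rank-score statistics. Because all S share
#' the projected dosage G*, the exact null covariance
#' Cov(S_a, S_b) = (min(a,b) - ab) ||G*||^2 / n gives a closed-form variance
#' for V; z = V / sqrt(Var V) is standard normal under the null. A variance-
#' increasing variant depresses lower-tail slopes and raises upper-tail
#' slopes, so V is sensitive to symmetric dispersion effects while a pure
#' location shift leaves it centered at zero.
#'
#' @param y,G,C,grid,method as in [map_qqtl()].
#' @param scan optionally, a precomputed `qqtl_scan` on the same inputs (the
#'   per-level statistics are then reused bit-for-bit).
#' @return data.frame(variant_id, V, var_V, statistic = z, p_nominal, untestable).
#' @export
map_vqtl <- function(y = NULL, G = NULL, C = NULL, grid = mapping_grid(),
                     method = c("br", "fn"), scan = NULL) {
  if (is.null(scan)) scan <- map_qqtl(y, G, C, grid = grid, method = method)
  stopifnot(inherits(scan, "qqtl_scan"))
  taus <- scan$taus
  ## pair each tau < 0.5 with 1 - tau, matching to tolerance
  pair_of <- vapply(taus, function(tt) {
    j <- which(abs(taus - (1 - tt)) < 1e-9)
    if (length(j) == 1L) j else NA_integer_
  }, integer(1))
  lower <- which(taus < 0.5 & !is.na(pair_of))
  if (length(lower) == 0L) stop("grid has no tau < 0.5 paired with 1 - tau")
  upper <- pair_of[lower]
  cvec <- numeric(length(taus))
  cvec[lower] <- cvec[lower] - 1
  cvec[upper] <- cvec[upper] + 1
  K0 <- outer(taus, taus, pmin) - outer(taus, taus)
  qf <- as.numeric(t(cvec) %*% K0 %*% cvec) # times ||G*||^2 / n
  V <- as.numeric(scan$S %*% cvec)
  var_V <- qf * scan$gstar_norm2 / scan$n
  z <- V / sqrt(var_V)
  p <- 2 * stats::pnorm(-abs(z))
  un <- scan$pairs$untestable
  V[un] <- var_V[un] <- z[un] <- p[un] <- NA_real_
  data.frame(variant_id = scan$pairs$variant_id, method = "vqtl",
             V = V, var_V = var_V, statistic = z, p_nominal = p,
             untestable = un, stringsAsFactors = FALSE)
}

#' Interaction QTL scan for one gene
#'
#' Fits, per variant, the linear interaction model
#' Y = b0 + bG G + bF F + bI G x F + C'bC + e on the rank-based
#' inverse-normal transformed phenotype, and tests the interaction
#' coefficient bI (two-sided t-test). Variants with MAF <= `maf_min`
#' (default 0.05) are excluded. Each fit is classified as amplifying,
#' counteracting, or uncertain via [classify_iqtl_direction()].
#'
#' @param y phenotype vector.
#' @param G `DosageMatrix` or dosage matrix.
#' @param F_fac per-sample interacting factor (discrete 0/1/2 or continuous).
#' @param C covariates.
#' @param maf_min MAF exclusion threshold (default 0.05).
#' @param quantile_normalize apply the inverse-normal transform (default TRUE).
#' @param main_alpha significance level on the main effect used by the
#'   directionality classification (default 0.05).
#' @return data.frame with per-variant coefficients, p-values (pG, pF, pI),
#'   `p_nominal` (= pI), `direction`, and `untestable`.
#' @export
map_iqtl <- function(y, G, F_fac, C = NULL, maf_min = 0.05,
                     quantile_normalize = TRUE, main_alpha = 0.05) {
  dos <- if (inherits(G, "DosageMatrix")) G$dosages else as.matrix(G)
  ids <- if (inherits(G, "DosageMatrix")) G$variants$id else colnames(dos)
  if (is.null(ids)) ids <- paste0("v", seq_len(ncol(dos)))
  F_fac <- as.numeric(F_fac)
  if (stats::var(F_fac) == 0) stop("interaction factor is constant")
  y <- as.numeric(y)
  if (quantile_normalize) y <- rint(y)
  n <- length(y)
  base <- .null_design(C, n)
  af <- colMeans(dos) / 2
  maf <- pmin(af, 1 - af)
  out <- lapply(seq_along(ids), function(j) {
    rec <- data.frame(variant_id = ids[j], method = "iqtl",
                      beta_g = NA_real_, beta_f = NA_real_, beta_i = NA_real_,
                      p_g = NA_real_, p_f = NA_real_, p_nominal = NA_real_,
                      direction = NA_character_, untestable = NA,
                      stringsAsFactors = FALSE)
    if (maf[j] <= maf_min) { rec$untestable <- NA; return(rec) }
    g <- dos[, j]
    D <- cbind(base[, 1, drop = FALSE], g = g, f = F_fac, gxf = g * F_fac,
               base[, -1, drop = FALSE])
    if (qr(D)$rank < ncol(D)) { rec$untestable <- TRUE; return(rec) }
    fit <- stats::lm.fit(D, y)
    rss <- sum(fit$residuals^2)
    df <- n - ncol(D)
    XtXinv <- chol2inv(chol(crossprod(D)))
    se <- sqrt(diag(XtXinv) * rss / df)
    tt <- fit$coefficients / se
    pp <- 2 * stats::pt(-abs(tt), df)
    rec$beta_g <- fit$coefficients["g"]; rec$beta_f <- fit$coefficients["f"]
    rec$beta_i <- fit$coefficients["gxf"]
    rec$p_g <- pp["g"]; rec$p_f <- pp["f"]; rec$p_nominal <- pp["gxf"]
    rec$direction <- classify_iqtl_direction(rec$beta_g, rec$beta_i, rec$p_g,
                                             alpha = main_alpha)
    rec$untestable <- FALSE
    rec
  })
  res <- do.call(rbind, out)
  res[!(maf <= maf_min), , drop = FALSE]
}

#' Classify interaction QTL directionality
#'
#' `uncertain` when the genotype main effect is not nominally significant
#' (pG > alpha); otherwise `amplifying` when main and interaction effects
#' share a sign (the QTL effect grows with exposure) and `counteracting`
#' when they oppose.
#'
#' @param beta_g genotype main effect.
#' @param beta_i interaction effect.
#' @param p_g main-effect p-value.
#' @param alpha nominal level (default 0.05).
#' @return one of "amplifying", "counteracting", "uncertain".
#' @export
classify_iqtl_direction <- function(beta_g, beta_i, p_g, alpha = 0.05) {
  if (is.na(p_g) || p_g > alpha) return("uncertain")
  if (sign(beta_g) == sign(beta_i)) "amplifying" else "counteracting"
}

#' Two-stage hierarchical multiple-testing correction
#'
#' Stage 1 controls gene-level FDR: within each gene, nominal p-values are
#' Bonferroni-adjusted by the number of testable variants in its cis window;
#' the Benjamini-Hochberg procedure is applied to the per-gene lead (minimum)
#' adjusted p-values. Stage 2 sets a data-driven variant threshold
#' t* = max over significant genes of their lead adjusted p-value; a
#' variant-gene pair is significant iff its gene passed stage 1 and its
#' within-gene Bonferroni p-value is <= t*.
#'
#' @param pairs data.frame with columns gene_id, variant_id, p_nominal
#'   (NA = untestable; untestable variants do not count toward the Bonferroni
#'   multiplier).
#' @param fdr gene-level FDR (default 0.05).
#' @return object of class `hier_call`: list with `genes` (gene_id,
#'   lead_p_bonf, q, significant), `t_star` (NULL if no gene is significant),
#'   and `pairs` (input plus p_bonf and significant).
#' @export
hierarchical_correct <- function(pairs, fdr = 0.05) {
  stopifnot(all(c("gene_id", "variant_id", "p_nominal") %in% names(pairs)))
  sp <- split(seq_len(nrow(pairs)), pairs$gene_id)
  pairs$p_bonf <- NA_real_
  lead <- vapply(sp, function(idx) {
    p <- pairs$p_nominal[idx]
    m_g <- sum(!is.na(p))
    if (m_g == 0L) return(NA_real_)
    pairs$p_bonf[idx] <<- pmin(1, p * m_g)
    min(pairs$p_bonf[idx], na.rm = TRUE)
  }, numeric(1))
  genes <- data.frame(gene_id = names(sp), lead_p_bonf = lead,
                      stringsAsFactors = FALSE)
  genes$q <- NA_real_
  ok <- !is.na(genes$lead_p_bonf)
  genes$q[ok] <- stats::p.adjust(genes$lead_p_bonf[ok], method = "BH")
  genes$significant <- !is.na(genes$q) & genes$q <= fdr
  t_star <- if (any(genes$significant)) max(genes$lead_p_bonf[genes$significant]) else NULL
  sig_genes <- genes$gene_id[genes$significant]
  pairs$significant <- !is.na(pairs$p_bonf) &
    pairs$gene_id %in% sig_genes &
    (if (is.null(t_star)) FALSE else pairs$p_bonf <= t_star)
  rownames(genes) <- NULL
  structure(list(genes = genes, t_star = t_star, pairs = pairs, fdr = fdr),
            class = "hier_call")
}

#' @export
print.hier_call <- function(x, ...) {
  cat("Hierarchical correction: ", sum(x$genes$significant), "/",
      nrow(x$genes), " genes significant at gene FDR ", x$fdr,
      "; t* = ", if (is.null(x$t_star)) "NULL" else format(x$t_star),
      "; ", sum(x$pairs$significant), " significant pairs\n", sep = "")
  invisible(x)
}

#' Flat Benjamini-Hochberg correction over variant-gene pairs
#'
#' Alternative to the hierarchical procedure: BH applied directly to all
#' nominal pair p-values.
#'
#' @param pairs data.frame with p_nominal.
#' @param fdr FDR level.
#' @return `pairs` with columns q and significant added.
#' @export
flat_bh_correct <- function(pairs, fdr = 0.05) {
  pairs$q <- stats::p.adjust(pairs$p_nominal, method = "BH")
  pairs$significant <- !is.na(pairs$q) & pairs$q <= fdr
  pairs
}
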