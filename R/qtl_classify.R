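## Categorize quantile vs linear QTL discoveries, heterogeneity testing,
## the heterogeneity index, and tail-specific labels.

#' Categorize variant-gene pairs by qQTL / xQTL significance
#'
#' Each pair tested by both scans is assigned one of: `qqtl_only`
#' (significant only in the quantile scan), `xqtl_only`, `shared_heterogeneous`
#' (significant in both, with a significant quantile-heterogeneity test),
#' `shared_homogeneous` (significant in both, no heterogeneity), or `none`.
#'
#' @param qqtl_call `hier_call` from the qQTL scan.
#' @param xqtl_call `hier_call` from the xQTL scan on the same pair universe.
#' @param p_xi optional named vector of heterogeneity p-values keyed by
#'   "gene_id:variant_id" (see [test_heterogeneity()]); pairs significant in
#'   both scans but missing from `p_xi` get category `shared_heterogeneous`
#'   = NA and are labelled `shared_unassessed`.
#' @param het_alpha heterogeneity threshold (default 0.05, applied per pair).
#' @return data.frame(gene_id, variant_id, category, p_xi).
#' @export
categorize_pairs <- function(qqtl_call, xqtl_call, p_xi = NULL,
                             het_alpha = 0.05) {
  stopifnot(inherits(qqtl_call, "hier_call"), inherits(xqtl_call, "hier_call"))
  kq <- paste(qqtl_call$pairs$gene_id, qqtl_call$pairs$variant_id, sep = ":")
  kx <- paste(xqtl_call$pairs$gene_id, xqtl_call$pairs$variant_id, sep = ":")
  if (!setequal(kq, kx)) {
    off <- c(setdiff(kq, kx), setdiff(kx, kq))
    stop("pair universes differ between the two calls: ",
         paste(utils::head(off, 10), collapse = ", "))
  }
  q_sig <- stats::setNames(qqtl_call$pairs$significant, kq)
  x_sig <- stats::setNames(xqtl_call$pairs$significant, kx)[kq]
  cat_out <- character(length(kq))
  pxi_out <- rep(NA_real_, length(kq))
  for (i in seq_along(kq)) {
    qs <- isTRUE(q_sig[i]); xs <- isTRUE(x_sig[i])
    if (qs && !xs) cat_out[i] <- "qqtl_only"
    else if (!qs && xs) cat_out[i] <- "xqtl_only"
    else if (!qs && !xs) cat_out[i] <- "none"
    else {
      px <- if (!is.null(p_xi)) p_xi[kq[i]] else NA_real_
      pxi_out[i] <- px
      cat_out[i] <- if (is.na(px)) "shared_unassessed"
        else if (px < het_alpha) "shared_heterogeneous" else "shared_homogeneous"
    }
  }
  data.frame(gene_id = qqtl_call$pairs$gene_id,
             variant_id = qqtl_call$pairs$variant_id,
             category = cat_out, p_xi = pxi_out, stringsAsFactors = FALSE)
}

#' Greedy LD clumping
#'
#' Sorts pairs by p-value (ascending) and keeps a variant unless its squared
#' correlation with an already-kept variant is >= `r2`. Variants absent from
#' the LD matrix are kept with a warning.
#'
#' @param pairs data.frame with variant_id and a p-value column `p`.
#' @param ld an `LdMatrix`.
#' @param r2 squared-correlation threshold (default 0.8).
#' @return the retained rows of `pairs`.
#' @export
ld_clump <- function(pairs, ld, r2 = 0.8) {
  stopifnot(inherits(ld, "LdMatrix"), all(c("variant_id", "p") %in% names(pairs)))
  ord <- order(pairs$p, pairs$variant_id)
  kept <- character(0)
  keep_row <- logical(nrow(pairs))
  missing_ld <- setdiff(pairs$variant_id, ld$ids)
  if (length(missing_ld))
    warning("ld_clump: ", length(missing_ld),
            " variant(s) absent from the LD matrix were kept unchecked")
  for (i in ord) {
    v <- pairs$variant_id[i]
    if (!(v %in% ld$ids)) { keep_row[i] <- TRUE; next }
    in_ld <- intersect(kept, ld$ids)
    if (length(in_ld) == 0L || all(ld$sigma[v, in_ld]^2 < r2)) {
      keep_row[i] <- TRUE
      kept <- c(kept, v)
    }
  }
  pairs[keep_row, , drop = FALSE]
}

#' Quantile-heterogeneity test on per-level slopes
#'
#' Applies the Chatterjee correlation test to the dependence of per-quantile
#' slope estimates on the quantile level. Slopes should come from per-level
#' quantile-regression refits including covariates (rank scores do not yield
#' slopes).
#'
#' @param betas per-quantile slope estimates.
#' @param taus matching quantile levels (default equally spaced over
#'   0.10..0.90).
#' @param alpha flag threshold (default 0.05).
#' @return list(xi, p_xi, flag); flag is NA when any slope is missing.
#' @export
test_heterogeneity <- function(betas, taus = NULL, alpha = 0.05) {
  if (is.null(taus)) taus <- seq(0.10, 0.90, length.out = length(betas))
  if (anyNA(betas)) return(list(xi = NA_real_, p_xi = NA_real_, flag = NA))
  ct <- chatterjee_xi(taus, betas)
  list(xi = ct$xi, p_xi = ct$p, flag = ct$p < alpha)
}

#' Heterogeneity index of per-quantile effects
#'
#' Natural log of |sd(beta(tau)) / mean(beta(tau))|. Returns `-Inf` when the
#' slopes are constant (sd = 0) and `+Inf` when the mean is within 1e-12 of
#' zero (maximal heterogeneity: effects cancel).
#'
#' @param betas per-quantile slope estimates (>= 2 values).
#' @return real number (possibly +/- Inf).
#' @export
heterogeneity_index <- function(betas) {
  if (length(betas) < 2L) stop("need at least 2 per-quantile effects")
  s <- stats::sd(betas); m <- mean(betas)
  if (s == 0) return(-Inf)
  if (abs(m) < 1e-12) return(Inf)
  log(abs(s / m))
}

#' Label tail-specific quantile effects
#'
#' `lower_only` when every significant level lies below 0.3 (and at least one
#' level is significant), `upper_only` symmetrically above 0.7, otherwise
#' `none`.
#'
#' @param p_tau per-level p-values.
#' @param taus matching quantile levels.
#' @param threshold variant-level significance threshold (e.g. the stage-2
#'   t* divided by the within-gene multiplier).
#' @param lower,upper tail boundaries (defaults 0.3 and 0.7).
#' @return one of "lower_only", "upper_only", "none".
#' @export
label_tail_specific <- function(p_tau, taus, threshold,
                                lower = 0.3, upper = 0.7) {
  stopifnot(length(p_tau) == length(taus))
  sig <- which(!is.na(p_tau) & p_tau <= threshold)
  if (length(sig) == 0L) return("none")
  st <- taus[sig]
  if (all(st < lower)) return("lower_only")
  if (all(st > upper)) return("upper_only")
  "none"
}

#' Per-quantile slope profile for one variant
#'
#' Per-level quantile regression refits of the phenotype on one dosage vector
#' plus covariates, returning the slope at each level. Used as input to
#' [test_heterogeneity()] and [heterogeneity_index()].
#'
#' @param y phenotype vector.
#' @param g dosage vector.
#' @param C covariates.
#' @param taus quantile levels (default 0.10..0.90 step 0.05, the mapping grid
#'   restricted to the central range).
#' @param method quantile solver.
#' @return numeric vector of slopes named by tau.
#' @export
quantile_slopes <- function(y, g, C = NULL, taus = seq(0.10, 0.90, by = 0.05),
                            method = c("br", "fn")) {
  method <- match.arg(method)
  fit <- fit_quantile_joint(y, matrix(g, ncol = 1), C,
                            grid = quantile_grid(taus), method = method)
  stats::setNames(as.numeric(fit$slopes[1, ]), taus)
}
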