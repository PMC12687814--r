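## Quantile TWAS: weight training over the 99-level grid, quantile-region
## integration (fixed and data-driven), LD-aware association against GWAS
## z-scores, and gene-level Cauchy combination.

#' Select and prune qTWAS variants against an LD panel
#'
#' Restricts significant qQTL variants for a gene to those present in the LD
#' panel (absences are dropped with a message), then greedily prunes highly
#' correlated variants: sorted by p-value ascending, a variant is kept unless
#' its r^2 with an already-kept variant is >= `r2`.
#'
#' @param variants data.frame(variant_id, p) of significant qQTL variants.
#' @param ld `LdMatrix` of the reference panel.
#' @param r2 pruning threshold (default 0.8).
#' @return character vector of retained variant ids (possibly empty).
#' @export
select_and_prune <- function(variants, ld, r2 = 0.8) {
  stopifnot(inherits(ld, "LdMatrix"))
  absent <- setdiff(variants$variant_id, ld$ids)
  if (length(absent))
    message("select_and_prune: dropped ", length(absent),
            " variant(s) absent from the LD panel")
  v <- variants[variants$variant_id %in% ld$ids, , drop = FALSE]
  if (nrow(v) == 0L) return(character(0))
  ord <- order(v$p, v$variant_id)
  kept <- character(0)
  for (i in ord) {
    vid <- v$variant_id[i]
    if (length(kept) == 0L || all(ld$sigma[vid, kept]^2 < r2))
      kept <- c(kept, vid)
  }
  kept
}

#' Estimate quantile-specific prediction weights for one gene
#'
#' Joint quantile regression of the phenotype on the pruned variant set plus
#' covariates at each level of the 99-point grid, by check-loss minimization.
#' Rank-deficient designs are repaired by dropping offending variants
#' deterministically (later ids dropped first), with a message.
#'
#' @param y phenotype vector.
#' @param G `DosageMatrix` or dosage matrix restricted to the pruned variants.
#' @param C covariates.
#' @param grid quantile levels (default [weight_grid()], 99 levels).
#' @param gene_id optional label.
#' @param method quantile solver (default `"fn"`; 99 fits per gene).
#' @return object of class `WeightMatrix`: list(gene_id, variant_ids, taus,
#'   weights [p x K], gamma [covariate coefficients x K]).
#' @export
estimate_weights <- function(y, G, C = NULL, grid = weight_grid(),
                             gene_id = NA_character_,
                             method = c("fn", "br")) {
  method <- match.arg(method)
  dos <- if (inherits(G, "DosageMatrix")) G$dosages else as.matrix(G)
  ids <- if (inherits(G, "DosageMatrix")) G$variants$id else colnames(dos)
  n <- length(y)
  base <- .null_design(C, n)
  ## drop collinear variants deterministically, in id order
  keep <- integer(0)
  cur <- base
  for (j in order(ids)) {
    cand <- cbind(cur, dos[, j])
    if (qr(cand)$rank == ncol(cand)) { keep <- c(keep, j); cur <- cand }
  }
  keep <- sort(keep)
  if (length(keep) < ncol(dos))
    message("estimate_weights: dropped ", ncol(dos) - length(keep),
            " collinear variant(s)")
  if (length(keep) == 0L) stop("no linearly independent variants to fit")
  dos <- dos[, keep, drop = FALSE]
  ids <- ids[keep]
  fit <- fit_quantile_joint(y, dos, C, grid = grid, method = method)
  gamma_rows <- seq_len(ncol(base))
  weights <- fit$slopes
  rownames(weights) <- ids
  if (anyNA(weights)) stop("weight estimation produced NA weights")
  structure(list(gene_id = gene_id, variant_ids = ids, taus = fit$taus,
                 weights = weights,
                 gamma = fit$coefficients[gamma_rows, , drop = FALSE]),
            class = "WeightMatrix")
}

#' Fixed quantile regions
#'
#' Partitions the quantile grid into lower (tau in [0.01, 0.33]),
#' middle ([0.34, 0.66]) and upper ([0.67, 0.99]) regions; on the default
#' 99-level grid each region holds exactly 33 levels.
#'
#' @param taus quantile levels of the weight grid (default [weight_grid()]).
#' @return object of class `QuantileRegionSet`: list(regions = list of index
#'   vectors into the grid, taus, method = "fixed").
#' @export
make_fixed_regions <- function(taus = weight_grid()) {
  taus <- as.numeric(taus)
  regions <- list(lower = which(taus < 1 / 3),
                  middle = which(taus >= 1 / 3 & taus < 2 / 3),
                  upper = which(taus >= 2 / 3))
  regions <- regions[vapply(regions, length, integer(1)) > 0]
  structure(list(regions = regions, taus = taus, method = "fixed"),
            class = "QuantileRegionSet")
}

## Contiguity-constrained average-linkage agglomeration over quantile levels.
## Returns the list of partitions (boundary index sets) along the merge path,
## indexed by K.
.contiguous_agglomerate <- function(D) {
  K <- ncol(D)
  ## clusters as integer ranges; store partition for each k
  bounds <- vector("list", K)     # bounds[[k]] = end indices of the k clusters
  ends <- seq_len(K)
  bounds[[K]] <- ends
  starts <- seq_len(K)
  cl <- lapply(seq_len(K), function(i) i)
  for (k in seq.int(K - 1L, 1L)) {
    ## average linkage between adjacent clusters
    nb <- length(cl) - 1L
    dd <- vapply(seq_len(nb), function(i) {
      mean(D[cl[[i]], cl[[i + 1L]], drop = FALSE])
    }, numeric(1))
    i <- which.min(dd)
    cl[[i]] <- c(cl[[i]], cl[[i + 1L]])
    cl[[i + 1L]] <- NULL
    bounds[[k]] <- vapply(cl, max, integer(1))
  }
  bounds
}

#' Data-driven quantile regions from a weight matrix
#'
#' Clusters the 99 per-level weight vectors into contiguous quantile regions.
#' Similarity between levels is the Pearson correlation of their weight
#' columns (for a single-variant gene, a rescaled negative absolute weight
#' difference). Contiguity-constrained average-linkage agglomeration produces
#' candidate partitions for K = 1..`k_max`; K is chosen to maximize the graph
#' modularity of the positive-similarity graph, subject to a minimum region
#' width. Degenerate (constant) weights give a single region.
#'
#' @param W a `WeightMatrix`.
#' @param k_max maximum number of regions (default 10).
#' @param min_width minimum region width in levels (default 3).
#' @return a `QuantileRegionSet` with method = "dynamic".
#' @export
make_dynamic_regions <- function(W, k_max = 10L, min_width = 3L) {
  stopifnot(inherits(W, "WeightMatrix"))
  wm <- W$weights
  K <- ncol(wm)
  if (max(wm) - min(wm) < 1e-12) {
    return(structure(list(regions = list(region1 = seq_len(K)), taus = W$taus,
                          method = "dynamic"), class = "QuantileRegionSet"))
  }
  if (nrow(wm) >= 2L) {
    S <- suppressWarnings(stats::cor(wm))
    S[!is.finite(S)] <- 0
    diag(S) <- 1
  } else {
    d <- abs(outer(wm[1, ], wm[1, ], "-"))
    S <- 1 - 2 * d / max(d)
  }
  D <- 1 - S
  bounds <- .contiguous_agglomerate(D)
  A <- pmax(S, 0); diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  best_k <- 1L; best_q <- -Inf
  for (k in seq_len(min(k_max, K))) {
    ends <- bounds[[k]]
    widths <- diff(c(0L, ends))
    if (k > 1L && any(widths < min_width)) next
    membership <- rep(seq_len(k), widths)
    q <- if (k == 1L) 0 else igraph::modularity(g, membership,
                                                weights = igraph::E(g)$weight)
    if (q > best_q + 1e-12) { best_q <- q; best_k <- k }
  }
  ends <- bounds[[best_k]]
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  regions <- mapply(function(s, e) seq.int(s, e), starts, ends,
                    SIMPLIFY = FALSE)
  names(regions) <- paste0("region", seq_along(regions))
  structure(list(regions = regions, taus = W$taus, method = "dynamic"),
            class = "QuantileRegionSet")
}

#' Integrate quantile weights over regions
#'
#' Elementwise sums of per-level weights over the members of each region:
#' omega_k = sum over tau in region k of omega(tau).
#'
#' @param W a `WeightMatrix`.
#' @param regions a `QuantileRegionSet`.
#' @return matrix p x K of integrated weights (columns named by region).
#' @export
integrate_weights <- function(W, regions) {
  stopifnot(inherits(W, "WeightMatrix"), inherits(regions, "QuantileRegionSet"))
  out <- vapply(regions$regions,
                function(idx) rowSums(W$weights[, idx, drop = FALSE]),
                numeric(nrow(W$weights)))
  out <- matrix(out, nrow = nrow(W$weights),
                dimnames = list(W$variant_ids, names(regions$regions)))
  out
}

#' Region-level qTWAS association statistic
#'
#' Z_k = omega_k' z / sqrt(omega_k' Sigma omega_k), asymptotically standard
#' normal under the null of no association. When the denominator quadratic
#' form is <= 1e-10, Sigma is ridge-regularized (Sigma + 1e-6 I) with a
#' message.
#'
#' @param omega_k integrated weight vector for one region.
#' @param z_gwas GWAS z-scores aligned to the weight variants.
#' @param Sigma `LdMatrix` or correlation matrix aligned the same way.
#' @return list(Z, p).
#' @export
region_assoc <- function(omega_k, z_gwas, Sigma) {
  S <- if (inherits(Sigma, "LdMatrix")) Sigma$sigma else as.matrix(Sigma)
  p <- length(omega_k)
  if (length(z_gwas) != p || nrow(S) != p || ncol(S) != p)
    stop("dimension mismatch between weights, z-scores, and LD matrix")
  denom <- as.numeric(t(omega_k) %*% S %*% omega_k)
  if (denom <= 1e-10) {
    message("region_assoc: near-singular quadratic form; ridging Sigma")
    S <- S + diag(1e-6, p)
    denom <- as.numeric(t(omega_k) %*% S %*% omega_k)
  }
  Z <- sum(omega_k * z_gwas) / sqrt(denom)
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)))
}

#' Gene-level qTWAS association
#'
#' Combines the region p-values of one gene with the Cauchy combination; the
#' gene is flagged significant when the combined p falls below the Bonferroni
#' threshold alpha / n_tests for the configured testing family.
#'
#' @param region_results data.frame(region, Z, p) from [region_assoc()].
#' @param n_tests size of the Bonferroni family (default 1).
#' @param alpha family-wise level (default 0.05).
#' @param gene_id optional label.
#' @return object of class `QtwasResult`: list(gene_id, regions, combined_p,
#'   significant).
#' @export
gene_assoc <- function(region_results, n_tests = 1L, alpha = 0.05,
                       gene_id = NA_character_) {
  if (nrow(region_results) == 0L) stop("no region results to combine")
  combined <- cauchy_combine(region_results$p)
  structure(list(gene_id = gene_id, regions = region_results,
                 combined_p = combined,
                 significant = combined < alpha / n_tests),
            class = "QtwasResult")
}

#' Train qTWAS weights for one gene (wrapper)
#'
#' Prunes the gene's significant qQTL variants against the LD panel, then
#' estimates the 99-level weight matrix.
#'
#' @param y,C phenotype and covariates.
#' @param geno `DosageMatrix` holding at least the candidate variants.
#' @param sig_variants data.frame(variant_id, p) of significant qQTL variants.
#' @param ld `LdMatrix` reference panel.
#' @param r2 pruning threshold.
#' @param gene_id label.
#' @param method quantile solver.
#' @return `WeightMatrix`, or NULL when no variant survives pruning.
#' @export
qtwas_train <- function(y, geno, C, sig_variants, ld, r2 = 0.8,
                        gene_id = NA_character_, method = "fn") {
  kept <- select_and_prune(sig_variants, ld, r2 = r2)
  if (length(kept) == 0L) {
    message("qtwas_train: no variant survives pruning for ", gene_id)
    return(NULL)
  }
  j <- match(kept, geno$variants$id)
  G <- geno$dosages[, j, drop = FALSE]
  colnames(G) <- kept
  estimate_weights(y, G, C, gene_id = gene_id, method = method)
}

#' Test one gene's qTWAS weights against GWAS summary statistics (wrapper)
#'
#' Integrates the weights over fixed or dynamic regions, aligns GWAS z-scores
#' and the LD matrix to the weight variants, and combines region-level
#' statistics into a gene-level p-value.
#'
#' @param W `WeightMatrix`.
#' @param z named vector of harmonized GWAS z-scores (see [harmonize_gwas()]).
#' @param ld `LdMatrix` covering the weight variants.
#' @param regions "fixed", "dynamic", or a `QuantileRegionSet`.
#' @param n_tests,alpha Bonferroni family for the significance flag.
#' @return `QtwasResult`, or NULL if no weight variant has a z-score.
#' @export
qtwas_assoc <- function(W, z, ld, regions = c("fixed", "dynamic"),
                        n_tests = 1L, alpha = 0.05) {
  if (!inherits(regions, "QuantileRegionSet")) {
    regions <- match.arg(regions)
    regions <- if (regions == "fixed") make_fixed_regions(W$taus)
               else make_dynamic_regions(W)
  }
  keep <- W$variant_ids %in% names(z) & W$variant_ids %in% ld$ids
  if (!any(keep)) return(NULL)
  if (!all(keep)) {
    W$weights <- W$weights[keep, , drop = FALSE]
    W$variant_ids <- W$variant_ids[keep]
  }
  omega <- integrate_weights(W, regions)
  zv <- z[W$variant_ids]
  S <- ld$sigma[W$variant_ids, W$variant_ids, drop = FALSE]
  res <- do.call(rbind, lapply(seq_len(ncol(omega)), function(k) {
    ra <- region_assoc(omega[, k], zv, S)
    data.frame(region = colnames(omega)[k], Z = ra$Z, p = ra$p,
               stringsAsFactors = FALSE)
  }))
  gene_assoc(res, n_tests = n_tests, alpha = alpha, gene_id = W$gene_id)
}
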