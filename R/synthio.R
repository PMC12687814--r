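## Synthetic-data generation for every pipeline stage: HWE genotypes,
## covariates, phenotypes under five generative models, GWAS z-scores
## consistent with an LD panel, and complete fixture bundles on disk.
## Every generator is a pure function of (parameters, seed).

#' Generate Hardy-Weinberg genotype dosages
#'
#' Draws, per variant, n genotypes in {0,1,2} with HWE probabilities
#' {(1-p)^2, 2p(1-p), p^2} (a Binomial(2, p) draw). Empirical MAF and MAC are
#' recorded in the variant table.
#'
#' @param n samples.
#' @param m variants.
#' @param maf scalar, length-m vector, or range c(lo, hi) sampled uniformly;
#'   values must lie in (0, 0.5].
#' @param seed RNG seed.
#' @param chrom chromosome label(s) recycled over variants.
#' @param pos_start first variant position (1-based); spacing `pos_step`.
#' @param pos_step spacing between consecutive variants.
#' @return a [dosage_matrix()] (zero-variance draws are kept only if
#'   `drop_monomorphic = FALSE`).
#' @param drop_monomorphic drop variants that came out monomorphic (default TRUE).
#' @export
gen_genotypes <- function(n, m, maf = c(0.05, 0.5), seed = 1L, chrom = "1",
                          pos_start = 10000L, pos_step = 1000L,
                          drop_monomorphic = TRUE) {
  set.seed(seed)
  if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
  p <- if (length(maf) == m) maf
       else if (length(maf) == 2L && m != 2L) stats::runif(m, maf[1], maf[2])
       else rep_len(maf, m)
  dos <- vapply(p, function(pp) stats::rbinom(n, 2L, pp), numeric(n))
  chromv <- rep_len(chrom, m)
  variants <- data.frame(
    id = paste0("v", seq_len(m)),
    chrom = chromv,
    pos = pos_start + pos_step * (ave(seq_len(m), chromv, FUN = seq_along) - 1L),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  if (drop_monomorphic) {
    keep <- apply(dos, 2, stats::var) > 0
    dos <- dos[, keep, drop = FALSE]
    variants <- variants[keep, , drop = FALSE]
  }
  dosage_matrix(dos, variants, paste0("S", seq_len(n)))
}

#' Generate standard-normal covariates
#' @param n samples; @param q covariates; @param seed RNG seed.
#' @return a [covariate_matrix()].
#' @export
gen_covariates <- function(n, q, seed = 1L) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * q), n, q,
              dimnames = list(paste0("S", seq_len(n)), paste0("c", seq_len(q))))
  covariate_matrix(m)
}

#' Phenotype model specification
#'
#' The five generative models used throughout the package:
#' * `null`: Y = C'betaC + e — no genetic effect.
#' * `location`: Y = beta g + C'betaC + e — a pure mean shift.
#' * `scale`: Y = C'betaC + (1 + s g) e — a variance effect; the per-quantile
#'   slope has the closed form s qnorm(tau) sigma_e, antisymmetric around the
#'   median. Requires s > -1/2 so the multiplier stays positive for dosages
#'   up to 2.
#' * `tail_specific`: a latent binary context B ~ Bernoulli(pi); carriers
#'   (B = 1) have a down-shifted baseline (`mu_tail`, in residual-sd units)
#'   and are the only individuals in whom the genetic effect beta g acts.
#'   Because carriers populate the lower tail of the mixture, the genetic
#'   signal concentrates at lower quantiles (set beta and mu_tail positive
#'   with `mu_tail > 0` flipped to an upper-tail effect by symmetry).
#' * `interaction`: Y = beta0 + betaG g + betaF F + betaI g F + C'betaC + e,
#'   with F an observed interacting factor.
#'
#' @param kind one of the five model names.
#' @param beta genetic effect (location, tail_specific).
#' @param s scale effect (scale model), s > -1/2.
#' @param pi_tail P(B = 1) for the tail_specific model, in (0,1).
#' @param mu_tail carrier baseline shift for the tail_specific model, in
#'   residual-sd units (default -1.5: carriers sit in the lower tail).
#' @param beta0,beta_g,beta_f,beta_i interaction-model coefficients.
#' @param noise_sd residual standard deviation (default 1).
#' @return a `PhenoModelSpec` list.
#' @export
pheno_model_spec <- function(kind = c("null", "location", "scale",
                                      "tail_specific", "interaction"),
                             beta = 0.5, s = 0.5, pi_tail = 0.3,
                             mu_tail = -1.5,
                             beta0 = 0, beta_g = 0.3, beta_f = 0, beta_i = 0.5,
                             noise_sd = 1) {
  kind <- match.arg(kind)
  if (kind == "scale" && s <= -0.5) stop("scale effect must satisfy s > -1/2")
  if (kind == "tail_specific" && (pi_tail <= 0 || pi_tail >= 1))
    stop("pi_tail must lie in (0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(kind = kind, beta = beta, s = s, pi_tail = pi_tail,
                 mu_tail = mu_tail, beta0 = beta0, beta_g = beta_g,
                 beta_f = beta_f, beta_i = beta_i, noise_sd = noise_sd),
            class = "PhenoModelSpec")
}

#' Generate a phenotype under a model specification
#'
#' @param g dosage vector of the causal variant (ignored for `null`).
#' @param spec a [pheno_model_spec()].
#' @param C covariates (matrix or `CovariateMatrix`) or NULL.
#' @param beta_c covariate coefficients (default zeros).
#' @param F_fac interacting factor for the interaction model.
#' @param seed RNG seed.
#' @return numeric phenotype vector; for `tail_specific` the latent flag is
#'   attached as `attr(, "latent")`, for `interaction` the factor as
#'   `attr(, "factor")`.
#' @export
gen_phenotype <- function(g, spec, C = NULL, beta_c = NULL, F_fac = NULL,
                          seed = 1L) {
  stopifnot(inherits(spec, "PhenoModelSpec"))
  set.seed(seed)
  g <- as.numeric(g)
  n <- length(g)
  Cm <- if (inherits(C, "CovariateMatrix")) C$values else C
  cov_term <- if (is.null(Cm)) 0 else {
    if (is.null(beta_c)) beta_c <- rep(0, ncol(Cm))
    as.numeric(as.matrix(Cm) %*% beta_c)
  }
  eps <- stats::rnorm(n, sd = spec$noise_sd)
  y <- switch(spec$kind,
    null = cov_term + eps,
    location = spec$beta * g + cov_term + eps,
    scale = cov_term + (1 + spec$s * g) * eps,
    tail_specific = {
      B <- stats::rbinom(n, 1L, spec$pi_tail)
      out <- (spec$mu_tail * spec$noise_sd + spec$beta * g) * B +
        cov_term + eps
      attr(out, "latent") <- B
      out
    },
    interaction = {
      if (is.null(F_fac)) stop("interaction model requires F_fac")
      out <- spec$beta0 + spec$beta_g * g + spec$beta_f * F_fac +
        spec$beta_i * g * F_fac + cov_term + eps
      attr(out, "factor") <- F_fac
      out
    })
  y
}

#' Generate an LD panel, LD matrix, and GWAS z-scores
#'
#' The panel is built from a latent AR(1) Gaussian process across variants
#' (correlation rho between adjacent variants), thresholded per variant into
#' HWE dosages at the stated MAF. The LD matrix Sigma is the Pearson
#' correlation of the panel dosages. GWAS z-scores are drawn from
#' MVN(Sigma mu, Sigma) with mu = lambda * u, where u is the normalized
#' direction of the supplied weights (summed over quantile levels) or the
#' first coordinate axis; lambda = 0 gives an exact null.
#'
#' @param p number of variants (ignored when `weights` given).
#' @param weights optional `WeightMatrix`; its variants define the panel.
#' @param rho AR(1) latent correlation in [0, 1) (default 0.6).
#' @param maf per-variant MAF (scalar or vector, default 0.25).
#' @param lambda gene signal strength (default 0 = null).
#' @param n_panel panel size (default 500).
#' @param seed RNG seed.
#' @param chrom,pos_start,pos_step variant coordinates for the panel.
#' @return list(gwas = `GwasSummary`, ld = `LdMatrix`, panel = `DosageMatrix`).
#' @export
gen_gwas_and_ld <- function(p = NULL, weights = NULL, rho = 0.6, maf = 0.25,
                            lambda = 0, n_panel = 500L, seed = 1L,
                            chrom = "1", pos_start = 10000L, pos_step = 1000L) {
  if (rho < 0 || rho >= 1) stop("AR(1) parameter rho must lie in [0, 1)")
  set.seed(seed)
  ids <- NULL
  if (!is.null(weights)) {
    stopifnot(inherits(weights, "WeightMatrix"))
    ids <- weights$variant_ids
    p <- length(ids)
  }
  if (is.null(p) || p < 1L) stop("need the number of variants")
  maf <- rep_len(maf, p)
  ## latent AR(1) per sample, thresholded to HWE dosages per variant
  L <- matrix(stats::rnorm(n_panel * p), n_panel, p)
  if (p > 1L) for (j in 2:p) L[, j] <- rho * L[, j - 1] + sqrt(1 - rho^2) * L[, j]
  lo <- stats::qnorm((1 - maf)^2)      # below: dosage 0
  hi <- stats::qnorm(1 - maf^2)        # above: dosage 2
  dos <- vapply(seq_len(p), function(j) {
    (L[, j] >= lo[j]) + (L[, j] > hi[j])
  }, numeric(n_panel))
  ## guard against monomorphic draws at small n_panel: flip one sample
  for (j in seq_len(p)) if (stats::var(dos[, j]) == 0)
    dos[1, j] <- if (dos[1, j] == 0) 1 else dos[1, j] - 1
  if (is.null(ids)) ids <- paste0("v", seq_len(p))
  variants <- data.frame(id = ids, chrom = chrom,
                         pos = pos_start + pos_step * (seq_len(p) - 1L),
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  panel <- dosage_matrix(dos, variants)
  Sigma <- stats::cor(panel$dosages)
  ld <- ld_matrix(Sigma, ids)
  u <- if (!is.null(weights)) {
    w <- rowSums(weights$weights)
    if (sqrt(sum(w^2)) < 1e-12) c(1, rep(0, p - 1)) else w / sqrt(sum(w^2))
  } else c(1, rep(0, p - 1))
  mu <- lambda * as.numeric(Sigma %*% u)
  R <- chol(Sigma + diag(1e-8, p))
  z <- mu + as.numeric(crossprod(R, stats::rnorm(p)))
  gwas <- data.frame(id = ids, chrom = chrom,
                     pos = variants$pos, a1 = "G", a2 = "A", z = z,
                     stringsAsFactors = FALSE)
  class(gwas) <- c("GwasSummary", "data.frame")
  list(gwas = gwas, ld = ld, panel = panel)
}

#' Write a complete miniature study to disk
#'
#' Generates a self-contained fixture bundle in the package's file dialects:
#' genotypes (TSV + sidecar), a BED-style phenotype table with planted causal
#' genes (location, scale, and interaction effects; the rest null), a
#' covariate TSV, an interaction-factor covariate, TAD intervals, annotation
#' BEDs, a gene-set GMT, a GWAS TSV with LD panel, and a truth TSV recording
#' every planted effect.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed.
#' @param n samples (default 400).
#' @param n_genes genes (default 50).
#' @param m variants (default 5000), split over `n_chrom` chromosomes.
#' @param q covariates (default 10).
#' @param n_chrom chromosomes (default 2).
#' @param n_loc,n_scale,n_inter planted location / scale / interaction genes
#'   (defaults 10 / 5 / 5).
#' @param beta_loc,s_scale,beta_inter planted effect sizes.
#' @param lambda_gwas GWAS signal strength injected at the causal variants of
#'   planted location genes (default 4; 0 gives an all-null GWAS).
#' @return invisibly, a named list of the file paths written.
#' @export
make_fixture_bundle <- function(outdir, seed = 1L, n = 400L, n_genes = 50L,
                                m = 5000L, q = 10L, n_chrom = 2L,
                                n_loc = 10L, n_scale = 5L, n_inter = 5L,
                                beta_loc = 0.6, s_scale = 0.6,
                                beta_inter = 0.8, lambda_gwas = 4) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir)
  }
  if (file.access(outdir, 2L) != 0L) stop("output directory is not writable: ", outdir)
  stopifnot(n_loc + n_scale + n_inter <= n_genes)
  set.seed(seed)
  chroms <- as.character(seq_len(n_chrom))
  per_chrom <- ceiling(m / n_chrom)
  geno <- gen_genotypes(n, m, maf = c(0.05, 0.5), seed = seed + 1L,
                        chrom = rep(chroms, each = per_chrom)[seq_len(m)],
                        pos_start = 100000L, pos_step = 2000L)
  covar <- gen_covariates(n, q, seed = seed + 2L)
  ## genes spread evenly across each chromosome's variant span,
  ## one causal cis variant each
  genes_per_chrom <- ceiling(n_genes / n_chrom)
  gene_chrom <- rep(chroms, each = genes_per_chrom)[seq_len(n_genes)]
  span_of <- vapply(chroms, function(cc) {
    pos <- geno$variants$pos[geno$variants$chrom == cc]
    c(min(pos), max(pos))
  }, numeric(2))
  genes <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    idx_on_chrom <- sum(gene_chrom[seq_len(i)] == gene_chrom[i])
    lo <- span_of[1, gene_chrom[i]]; hi <- span_of[2, gene_chrom[i]]
    start <- round(lo + idx_on_chrom / (genes_per_chrom + 1) * (hi - lo))
    data.frame(gene_id = sprintf("gene%02d", i), chrom = gene_chrom[i],
               start = start, end = start + 20000L, stringsAsFactors = FALSE)
  }))
  kinds <- c(rep("location", n_loc), rep("scale", n_scale),
             rep("interaction", n_inter), rep("null", n_genes - n_loc - n_scale - n_inter))
  kinds <- sample(kinds) # shuffle which genes carry effects
  F_fac <- stats::rbinom(n, 2L, 0.3) # observed interacting factor
  beta_c <- stats::rnorm(q, 0, 0.3)
  truth <- vector("list", n_genes)
  values <- matrix(NA_real_, n_genes, n)
  for (i in seq_len(n_genes)) {
    ## causal variant: the common (MAF >= 0.1) cis variant nearest the gene
    ## start, so planted effects have adequate power at this sample size
    v <- geno$variants
    on_chrom <- which(v$chrom == genes$chrom[i] & v$maf >= 0.1)
    if (length(on_chrom) == 0L) on_chrom <- which(v$chrom == genes$chrom[i])
    causal_j <- on_chrom[which.min(abs(v$pos[on_chrom] - genes$start[i]))]
    g <- geno$dosages[, causal_j]
    spec <- switch(kinds[i],
      null = pheno_model_spec("null"),
      location = pheno_model_spec("location", beta = beta_loc),
      scale = pheno_model_spec("scale", s = s_scale),
      interaction = pheno_model_spec("interaction", beta_g = 0.3,
                                     beta_i = beta_inter))
    values[i, ] <- gen_phenotype(g, spec, C = covar, beta_c = beta_c,
                                 F_fac = F_fac, seed = seed + 100L + i)
    truth[[i]] <- data.frame(gene_id = genes$gene_id[i], kind = kinds[i],
                             causal_variant = if (kinds[i] == "null") NA_character_
                                              else v$id[causal_j],
                             stringsAsFactors = FALSE)
  }
  pheno <- phenotype_table(genes, values, geno$samples)
  truth <- do.call(rbind, truth)
  truth$gwas_signal <- truth$kind == "location" & lambda_gwas != 0
  ## TADs: alternating 1.0 and 3.0 Mb intervals per chromosome
  tadb <- do.call(rbind, lapply(chroms, function(cc) {
    starts <- cumsum(c(0, rep(c(1e6, 3e6), 3)))
    data.frame(chrom = cc, start = utils::head(starts, -1), end = starts[-1])
  }))
  ## annotations: 3 BED tracks tiling parts of the variant range
  anns <- lapply(1:3, function(k) {
    v <- geno$variants
    hit <- v[seq(k, nrow(v), by = 5L), ]
    data.frame(chrom = hit$chrom, start = hit$pos - 1L, end = hit$pos + 499L)
  })
  ## gene sets: one enriched in planted genes, two random
  sets <- list(
    planted = truth$gene_id[truth$kind != "null"],
    random_a = sample(genes$gene_id, min(10L, n_genes)),
    random_b = sample(genes$gene_id, min(15L, n_genes)))
  ## GWAS + LD over the study's cis variants around every gene, with signal
  ## injected at the causal variants of planted location genes (the genes a
  ## qTWAS should flag); z ~ MVN(Sigma mu, Sigma) with Sigma from the study
  ## genotypes serving as their own reference panel.
  causal_ids <- truth$causal_variant[!is.na(truth$causal_variant)]
  near_gene <- unlist(lapply(seq_len(n_genes), function(i) {
    v <- geno$variants
    on_chrom <- which(v$chrom == genes$chrom[i])
    j <- on_chrom[order(abs(v$pos[on_chrom] - genes$start[i]))]
    v$id[utils::head(j, 5L)]
  }))
  sel <- geno$variants$id %in% union(causal_ids, near_gene)
  panel_ids <- geno$variants$id[sel]
  Sigma <- stats::cor(geno$dosages[, sel, drop = FALSE])
  gwas_causal <- truth$causal_variant[truth$kind == "location"]
  mu <- ifelse(panel_ids %in% gwas_causal, lambda_gwas, 0)
  R <- chol(Sigma + diag(1e-6, length(panel_ids)))
  zv <- as.numeric(Sigma %*% mu) + as.numeric(crossprod(R, stats::rnorm(length(panel_ids))))
  vsel <- geno$variants[sel, ]
  gwas <- data.frame(id = vsel$id, chrom = vsel$chrom, pos = vsel$pos,
                     a1 = vsel$alt, a2 = vsel$ref, z = zv,
                     stringsAsFactors = FALSE)
  class(gwas) <- c("GwasSummary", "data.frame")
  gl <- list(gwas = gwas,
             ld = ld_matrix((Sigma + t(Sigma)) / 2, panel_ids))
  paths <- list(
    genotypes = file.path(outdir, "genotypes.tsv"),
    phenotypes = file.path(outdir, "phenotypes.bed.tsv"),
    covariates = file.path(outdir, "covariates.tsv"),
    factor = file.path(outdir, "interaction_factor.tsv"),
    tadb = file.path(outdir, "tadb.bed"),
    gwas = file.path(outdir, "gwas.tsv"),
    ld = file.path(outdir, "ld.tsv"),
    gmt = file.path(outdir, "genesets.gmt"),
    truth = file.path(outdir, "truth.tsv"))
  write_genotypes_tsv(geno, paths$genotypes)
  write_phenotypes(pheno, paths$phenotypes)
  write_covariates(covar, paths$covariates)
  data.table::fwrite(data.frame(sample = geno$samples, factor = F_fac),
                     paths$factor, sep = "\t")
  write_bed(tadb, paths$tadb)
  for (k in 1:3) {
    paths[[paste0("annotation", k)]] <- file.path(outdir, sprintf("annotation%d.bed", k))
    write_bed(anns[[k]], paths[[paste0("annotation", k)]])
  }
  write_gwas(gl$gwas, paths$gwas)
  write_ld(gl$ld, paths$ld)
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), ""), paths$gmt)
  data.table::fwrite(truth, paths$truth, sep = "\t", na = "NA")
  invisible(paths)
}
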