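## End-to-end orchestration over a study directory in the package's file
## dialects: load/align -> QTL scans -> hierarchical correction ->
## classification -> qTWAS -> enrichment, with a manifest recording stage
## status, seeds, and input checksums. Every stage failure is recorded and
## downstream stages are skipped; earlier outputs stay intact.

#' Pipeline run configuration
#'
#' @param paths named list of input paths: genotypes (TSV dialect),
#'   phenotypes, covariates; optional factor (two-column sample/factor TSV),
#'   tadb, gwas, ld, annotations (character vector of BED paths), gmt.
#' @param out_dir output directory.
#' @param fdr gene-level FDR (default 0.05).
#' @param iqtl_fdr FDR tier for the interaction scan (default 0.05 for
#'   continuous factors; use 0.25 for discrete factors per the lenient tier).
#' @param grid quantile levels for mapping (default 19-level grid).
#' @param r2 LD pruning/clumping threshold (default 0.8).
#' @param span cis-window span (default 2 Mb).
#' @param regions qTWAS region method, "fixed" or "dynamic".
#' @param seed master seed (controls nothing stochastic in mapping itself,
#'   recorded for provenance).
#' @param solver quantile solver for the scans ("fn" default).
#' @param qc_rule variant QC rule, see [qc_variants()].
#' @return a `RunConfig` list.
#' @export
run_config <- function(paths, out_dir, fdr = 0.05, iqtl_fdr = 0.05,
                       grid = mapping_grid(), r2 = 0.8, span = 2e6,
                       regions = "fixed", seed = 1L, solver = "fn",
                       qc_rule = "either") {
  stopifnot(all(c("genotypes", "phenotypes", "covariates") %in% names(paths)))
  structure(list(paths = paths, out_dir = out_dir, fdr = fdr,
                 iqtl_fdr = iqtl_fdr, grid = grid, r2 = r2, span = span,
                 regions = regions, seed = seed, solver = solver,
                 qc_rule = qc_rule),
            class = "RunConfig")
}

.stage <- function(manifest, name, expr) {
  if (any(manifest$status == "failed")) {
    manifest <- rbind(manifest, data.frame(stage = name, status = "skipped",
                                           reason = "upstream failure"))
    return(list(manifest = manifest, value = NULL))
  }
  res <- tryCatch(list(value = expr, err = NULL),
                  error = function(e) list(value = NULL, err = conditionMessage(e)))
  manifest <- rbind(manifest, data.frame(
    stage = name,
    status = if (is.null(res$err)) "ok" else "failed",
    reason = if (is.null(res$err)) "" else res$err))
  list(manifest = manifest, value = res$value)
}

#' Run the full pipeline on a study directory
#'
#' Executes, in order: input loading and sample alignment; per-gene xQTL,
#' qQTL, and vQTL scans over cis windows (plus iQTL when a factor file is
#' configured); the two-stage hierarchical correction per method;
#' qQTL-vs-xQTL classification with per-pair heterogeneity tests; qTWAS
#' weight training and GWAS association (when GWAS and LD inputs are
#' configured); and EOO annotation enrichment of the qQTL-only versus xQTL
#' link sets (when annotations are configured). Results are written as TSV
#' files under `config$out_dir` together with a `manifest.tsv` recording
#' stage status, package version, seed, and MD5 checksums of the inputs.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest data.frame.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(stage = character(), status = character(),
                         reason = character())
  env <- new.env()

  st <- .stage(manifest, "load", {
    geno <- qc_variants(read_genotypes(config$paths$genotypes),
                        rule = config$qc_rule)
    pheno <- read_phenotypes(config$paths$phenotypes)
    covar <- read_covariates(config$paths$covariates)
    al <- align_samples(geno, pheno, covar)
    env$geno <- al$geno; env$pheno <- al$pheno; env$covar <- al$covar
    env$tadb <- if (!is.null(config$paths$tadb)) read_bed(config$paths$tadb) else NULL
    if (!is.null(config$paths$factor)) {
      f <- data.table::fread(config$paths$factor, data.table = FALSE)
      env$factor <- f[[2]][match(al$geno$samples, f[[1]])]
      if (anyNA(env$factor)) stop("factor file misses aligned samples")
    }
    TRUE
  })
  manifest <- st$manifest

  st <- .stage(manifest, "map", {
    windows <- build_cis_windows(env$pheno$genes, tadb = env$tadb,
                                 span = config$span)
    xp <- qp <- vp <- ip <- list()
    env$scans <- list()
    for (i in seq_len(nrow(windows))) {
      gid <- windows$gene_id[i]
      Gw <- cis_variants(env$geno, windows[i, ])
      if (nrow(Gw$variants) == 0L) next
      y <- env$pheno$values[gid, ]
      xres <- map_xqtl(y, Gw, env$covar)
      qscan <- map_qqtl(y, Gw, env$covar, grid = config$grid,
                        method = config$solver)
      vres <- map_vqtl(scan = qscan)
      xp[[gid]] <- cbind(gene_id = gid, xres)
      qp[[gid]] <- cbind(gene_id = gid, qscan$pairs)
      vp[[gid]] <- cbind(gene_id = gid, vres)
      env$scans[[gid]] <- qscan
      if (!is.null(env$factor))
        ip[[gid]] <- cbind(gene_id = gid,
                           map_iqtl(y, Gw, env$factor, env$covar))
    }
    env$pairs <- list(xqtl = do.call(rbind, xp), qqtl = do.call(rbind, qp),
                      vqtl = do.call(rbind, vp),
                      iqtl = if (length(ip)) do.call(rbind, ip) else NULL)
    TRUE
  })
  manifest <- st$manifest

  st <- .stage(manifest, "correct", {
    env$calls <- list()
    for (m in c("xqtl", "qqtl", "vqtl")) {
      env$calls[[m]] <- hierarchical_correct(env$pairs[[m]], fdr = config$fdr)
      data.table::fwrite(env$calls[[m]]$pairs,
                         file.path(config$out_dir, paste0(m, "_pairs.tsv")),
                         sep = "\t")
      data.table::fwrite(env$calls[[m]]$genes,
                         file.path(config$out_dir, paste0(m, "_genes.tsv")),
                         sep = "\t")
    }
    if (!is.null(env$pairs$iqtl)) {
      env$calls$iqtl <- hierarchical_correct(env$pairs$iqtl,
                                             fdr = config$iqtl_fdr)
      data.table::fwrite(env$calls$iqtl$pairs,
                         file.path(config$out_dir, "iqtl_pairs.tsv"), sep = "\t")
    }
    TRUE
  })
  manifest <- st$manifest

  st <- .stage(manifest, "classify", {
    qq <- env$calls$qqtl; xx <- env$calls$xqtl
    shared <- qq$pairs$significant & xx$pairs$significant
    p_xi <- stats::setNames(rep(NA_real_, sum(shared)),
                            paste(qq$pairs$gene_id, qq$pairs$variant_id,
                                  sep = ":")[shared])
    for (k in which(shared)) {
      gid <- qq$pairs$gene_id[k]; vid <- qq$pairs$variant_id[k]
      y <- env$pheno$values[gid, ]
      g <- env$geno$dosages[, vid]
      sl <- quantile_slopes(y, g, env$covar, method = config$solver)
      p_xi[paste(gid, vid, sep = ":")] <- chatterjee_xi(
        seq(0.10, 0.90, by = 0.05), sl)$p
    }
    cats <- categorize_pairs(qq, xx, p_xi = p_xi)
    data.table::fwrite(cats, file.path(config$out_dir, "categories.tsv"),
                       sep = "\t")
    env$categories <- cats
    TRUE
  })
  manifest <- st$manifest

  st <- .stage(manifest, "qtwas", {
    if (is.null(config$paths$gwas) || is.null(config$paths$ld))
      stop("qtwas stage requires gwas and ld paths")
    gwas <- read_gwas(config$paths$gwas)
    ld <- read_ld(config$paths$ld)
    z <- harmonize_gwas(gwas, env$geno$variants)
    zv <- stats::setNames(z$z, z$id)
    qq <- env$calls$qqtl
    sig <- qq$pairs[qq$pairs$significant, ]
    rows <- list()
    for (gid in unique(sig$gene_id)) {
      sv <- sig[sig$gene_id == gid, c("variant_id", "p_nominal")]
      names(sv)[2] <- "p"
      W <- suppressMessages(
        qtwas_train(env$pheno$values[gid, ], env$geno, env$covar, sv, ld,
                    r2 = config$r2, gene_id = gid, method = config$solver))
      if (is.null(W)) next
      res <- qtwas_assoc(W, zv, ld, regions = config$regions,
                         n_tests = length(unique(sig$gene_id)))
      if (is.null(res)) next
      rows[[gid]] <- data.frame(gene_id = gid, combined_p = res$combined_p,
                                significant = res$significant,
                                n_regions = nrow(res$regions),
                                stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      out <- do.call(rbind, rows)
      data.table::fwrite(out, file.path(config$out_dir, "qtwas.tsv"), sep = "\t")
      env$qtwas <- out
    }
    TRUE
  })
  manifest <- st$manifest

  st <- .stage(manifest, "enrichment", {
    if (is.null(config$paths$annotations)) stop("no annotations configured")
    qq <- env$calls$qqtl$pairs; xx <- env$calls$xqtl$pairs
    v <- env$geno$variants[match(qq$variant_id, env$geno$variants$id), ]
    qqtl_only <- qq$significant & !xx$significant
    xqtl_sig <- xx$significant
    ## EOO is undefined when a link set is empty (small studies may yield no
    ## qQTL-only pairs); such annotations get NA rows rather than failing
    safe_eoo <- function(flags, in_ann, chrom) {
      tryCatch(eoo_loco_se(flags, in_ann, chrom),
               error = function(e) list(eoo = NA_real_, se = NA_real_))
    }
    rows <- lapply(config$paths$annotations, function(bed) {
      ann <- read_bed(bed)
      in_ann <- overlap_annotation(v, ann)
      e1 <- safe_eoo(qqtl_only, in_ann, v$chrom)
      e2 <- safe_eoo(xqtl_sig, in_ann, v$chrom)
      data.frame(annotation = basename(bed), eoo_qqtl_only = e1$eoo,
                 se_qqtl_only = e1$se, eoo_xqtl = e2$eoo, se_xqtl = e2$se)
    })
    enr <- do.call(rbind, rows)
    enr <- cbind(enr, eoo_diff_test(enr$eoo_qqtl_only, enr$se_qqtl_only,
                                    enr$eoo_xqtl, enr$se_xqtl))
    data.table::fwrite(enr, file.path(config$out_dir, "enrichment.tsv"),
                       sep = "\t")
    TRUE
  })
  manifest <- st$manifest

  input_files <- unlist(config$paths, use.names = FALSE)
  meta <- data.frame(stage = "meta", status = "info",
                     reason = paste0("nlqtl ",
                                     as.character(utils::packageVersion("nlqtl")),
                                     "; seed=", config$seed, "; md5=",
                                     paste(substr(tools::md5sum(input_files), 1, 8),
                                           collapse = ",")))
  manifest <- rbind(manifest, meta)
  data.table::fwrite(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t")
  invisible(manifest)
}
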