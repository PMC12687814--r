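## IO for the fixed dialects used across the pipeline.
## Conventions, centralized here:
##   * variants:   1-based positions (VCF convention)
##   * intervals:  0-based half-open (BED convention)
##   * dosages:    minor-allele counts in [0,2]; missing imputed to column mean
##   * TSV everywhere, tab-separated with headers, written by data.table::fwrite

.strip_chr <- function(x) sub("^chr", "", as.character(x))

#' Construct a dosage matrix object
#'
#' @param dosages numeric matrix, samples x variants, values in [0,2].
#' @param variants data.frame with columns id, chrom, pos (1-based), ref, alt;
#'   maf and mac are (re)computed from the dosages.
#' @param samples character vector of sample identifiers.
#' @return A `DosageMatrix`: list(samples, variants, dosages).
#' @export
dosage_matrix <- function(dosages, variants, samples = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosages)))
  stopifnot(nrow(variants) == ncol(dosages))
  if (anyDuplicated(variants$id))
    stop("duplicate variant identifiers: ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyNA(dosages)) stop("dosages must not contain NA (impute before construction)")
  if (any(dosages < 0 | dosages > 2)) stop("dosages must lie in [0, 2]")
  rownames(dosages) <- samples
  colnames(dosages) <- variants$id
  af <- colMeans(dosages) / 2
  variants$maf <- pmin(af, 1 - af)
  variants$mac <- as.integer(round(pmin(colSums(dosages), 2 * nrow(dosages) - colSums(dosages))))
  rownames(variants) <- NULL
  structure(list(samples = as.character(samples),
                 variants = as.data.frame(variants),
                 dosages = dosages),
            class = "DosageMatrix")
}

#' @export
print.DosageMatrix <- function(x, ...) {
  cat("DosageMatrix:", length(x$samples), "samples x", nrow(x$variants), "variants\n")
  invisible(x)
}

## Impute missing entries to column means and drop zero-variance columns.
.finalize_dosages <- function(dos, variants, samples, verbose = TRUE) {
  for (j in seq_len(ncol(dos))) {
    miss <- is.na(dos[, j])
    if (any(miss)) {
      if (all(miss)) dos[, j] <- 0 else dos[miss, j] <- mean(dos[!miss, j])
    }
  }
  v <- apply(dos, 2, stats::var)
  keep <- v > 0
  if (verbose && any(!keep))
    message("read_genotypes: dropped ", sum(!keep), " zero-variance variant(s)")
  dosage_matrix(dos[, keep, drop = FALSE], variants[keep, , drop = FALSE], samples)
}

#' Read genotype dosages
#'
#' Reads either a VCF (dosages from the DS FORMAT field if present, otherwise
#' GT allele counts; multi-allelic records are rejected) or a TSV dosage
#' matrix (rows = variants, columns = samples) with a sidecar variant table
#' (columns id, chrom, pos, ref, alt). Missing entries are imputed to the
#' column mean and zero-variance variants are dropped with a message.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"`, or `"tsv"`.
#' @param variant_table sidecar TSV path (required for `format = "tsv"`;
#'   default `paste0(path, ".variants")`).
#' @return a [dosage_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           variant_table = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") return(.read_genotypes_vcf(path))
  if (is.null(variant_table)) variant_table <- paste0(path, ".variants")
  if (!file.exists(variant_table))
    stop("variant sidecar table not found: ", variant_table)
  m <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  ids <- m[[1]]
  dos <- t(as.matrix(m[, -1, drop = FALSE]))
  samples <- colnames(m)[-1]
  vt <- data.table::fread(variant_table, sep = "\t", header = TRUE,
                          data.table = FALSE,
                          colClasses = list(character = c("id", "chrom", "ref", "alt")))
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(vt)))
    stop("variant sidecar must have columns: ", paste(need, collapse = ", "))
  if (!identical(as.character(ids), as.character(vt$id)))
    stop("variant ids in the dosage matrix do not align with the sidecar table")
  .finalize_dosages(dos, vt[, need], samples)
}

.read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix) # single-record VCF returns a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multi-allelic VCF records are not supported; split or filter them first")
  ids <- fix$ID
  blank <- is.na(ids) | ids == "." | ids == ""
  ids[blank] <- paste0(fix$CHROM[blank], ":", fix$POS[blank], ":",
                       fix$REF[blank], ">", fix$ALT[blank])
  has_ds <- any(grepl("(^|:)DS(:|$)", v@gt[, "FORMAT"]))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(gt)) stop("VCF has neither DS nor GT FORMAT fields")
    ds <- apply(gt, c(1, 2), function(s) {
      if (is.na(s) || grepl("\\.", s)) return(NA_real_)
      sum(strsplit(gsub("|", "/", s, fixed = TRUE), "/")[[1]] == "1")
    })
  }
  dos <- t(ds)
  samples <- rownames(dos)
  variants <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  .finalize_dosages(dos, variants, samples)
}

#' Variant quality-control filter
#'
#' Retains variants by minor-allele frequency and minor-allele count. The
#' default rule keeps a variant when it meets either criterion
#' (MAF >= maf_min OR MAC >= mac_min); `rule = "both"` requires both.
#'
#' @param geno a `DosageMatrix`.
#' @param maf_min minimum MAF (default 0.01).
#' @param mac_min minimum MAC (default 5).
#' @param rule `"either"` (default) or `"both"`.
#' @return filtered `DosageMatrix`.
#' @export
qc_variants <- function(geno, maf_min = 0.01, mac_min = 5L,
                        rule = c("either", "both")) {
  rule <- match.arg(rule)
  ok_maf <- geno$variants$maf >= maf_min
  ok_mac <- geno$variants$mac >= mac_min
  keep <- if (rule == "either") ok_maf | ok_mac else ok_maf & ok_mac
  dosage_matrix(geno$dosages[, keep, drop = FALSE],
                geno$variants[keep, , drop = FALSE], geno$samples)
}

#' Phenotype table (BED-style gene x sample expression)
#'
#' Gene coordinates follow the BED convention: 0-based half-open intervals.
#'
#' @param genes data.frame with gene_id, chrom, start, end.
#' @param values numeric matrix, genes x samples.
#' @param samples sample identifiers.
#' @return a `PhenotypeTable`.
#' @export
phenotype_table <- function(genes, values, samples = colnames(values)) {
  values <- as.matrix(values)
  stopifnot(nrow(genes) == nrow(values))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene identifiers: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (any(genes$end <= genes$start)) stop("gene intervals must satisfy start < end")
  rownames(values) <- genes$gene_id
  colnames(values) <- samples
  structure(list(genes = as.data.frame(genes), values = values,
                 samples = as.character(samples)),
            class = "PhenotypeTable")
}

#' Read a BED-style phenotype table
#'
#' Expected columns: `#chr`, `start`, `end`, `gene_id`, then one column per
#' sample. Coordinates are 0-based half-open.
#'
#' @param path TSV path.
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  names(d)[1] <- sub("^#", "", names(d)[1])
  need <- c("chr", "start", "end", "gene_id")
  if (!all(need %in% names(d)[1:4]))
    stop("phenotype BED must start with columns #chr, start, end, gene_id")
  genes <- data.frame(gene_id = as.character(d$gene_id), chrom = as.character(d$chr),
                      start = as.integer(d$start), end = as.integer(d$end))
  phenotype_table(genes, as.matrix(d[, -(1:4), drop = FALSE]),
                  samples = names(d)[-(1:4)])
}

#' Covariate matrix
#'
#' @param values numeric matrix, samples x covariates.
#' @param samples sample ids.
#' @return a `CovariateMatrix`; errors if [1, C] is rank deficient.
#' @export
covariate_matrix <- function(values, samples = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) colnames(values) <- paste0("c", seq_len(ncol(values)))
  X <- cbind(1, values)
  if (qr(X)$rank < ncol(X))
    stop("covariate matrix is rank deficient after adding an intercept")
  structure(list(names = colnames(values), values = values,
                 samples = as.character(samples)),
            class = "CovariateMatrix")
}

#' Read covariates (TSV, rows = covariates, columns = samples)
#' @param path TSV path; first column holds covariate names.
#' @return a [covariate_matrix()].
#' @export
read_covariates <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  cn <- as.character(d[[1]])
  if (anyDuplicated(cn))
    stop("duplicate covariate names: ", paste(unique(cn[duplicated(cn)]), collapse = ", "))
  m <- t(as.matrix(d[, -1, drop = FALSE]))
  colnames(m) <- cn
  covariate_matrix(m, samples = names(d)[-1])
}

#' Read GWAS summary statistics
#'
#' Expected TSV columns: id, chrom, pos, a1 (effect allele), a2, z.
#'
#' @param path TSV path.
#' @return a `GwasSummary` data.frame.
#' @export
read_gwas <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                         colClasses = list(character = c("id", "chrom", "a1", "a2")))
  need <- c("id", "chrom", "pos", "a1", "a2", "z")
  if (!all(need %in% names(d))) stop("GWAS TSV must have columns: ", paste(need, collapse = ", "))
  d <- d[, need]
  bad <- which(toupper(d$a1) == toupper(d$a2))
  if (length(bad))
    stop("GWAS rows with identical alleles (a1 == a2) at row(s): ",
         paste(bad, collapse = ", "))
  if (any(!is.finite(d$z))) stop("GWAS z-scores must be finite")
  if (anyDuplicated(d$id))
    stop("duplicate GWAS variant ids: ",
         paste(unique(d$id[duplicated(d$id)]), collapse = ", "))
  class(d) <- c("GwasSummary", "data.frame")
  d
}

#' LD matrix
#'
#' @param sigma symmetric correlation matrix with unit diagonal.
#' @param ids variant identifiers (ordered as in sigma).
#' @return an `LdMatrix`.
#' @export
ld_matrix <- function(sigma, ids = colnames(sigma)) {
  sigma <- as.matrix(sigma)
  if (is.null(ids)) stop("LD matrix requires variant ids")
  stopifnot(nrow(sigma) == ncol(sigma), length(ids) == ncol(sigma))
  if (max(abs(sigma - t(sigma))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(sigma) - 1)) > 1e-8) stop("LD matrix must have unit diagonal")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("LD matrix must be positive semi-definite")
  dimnames(sigma) <- list(ids, ids)
  structure(list(ids = as.character(ids), sigma = sigma), class = "LdMatrix")
}

#' Read an LD matrix, or compute one from a genotype panel
#'
#' @param path square TSV with a header of variant ids and an id first column.
#' @param panel alternatively, a `DosageMatrix`; Pearson correlation of
#'   dosage columns is used.
#' @return an [ld_matrix()].
#' @export
read_ld <- function(path = NULL, panel = NULL) {
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "DosageMatrix"))
    return(ld_matrix(stats::cor(panel$dosages), ids = panel$variants$id))
  }
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  ids <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!identical(ids, colnames(m)))
    stop("LD TSV row ids must match its column header")
  ## symmetrize away round-trip noise below the invariant tolerance
  m <- (m + t(m)) / 2
  ld_matrix(m, ids)
}

#' Read BED intervals (0-based half-open)
#' @param path BED path (at least chrom/start/end; optional name column).
#' @return data.frame(chrom, start, end[, name]).
#' @export
read_bed <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  if (ncol(d) >= 4) names(d)[4] <- "name"
  d$chrom <- as.character(d$chrom)
  d[, seq_len(min(4, ncol(d))), drop = FALSE]
}

#' Read gene sets in GMT format
#' @param path GMT path (name, description, then member genes, tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  out
}

## ---- writers (fixed dialects; round-trip tested) ----

#' Writers for the package's TSV dialects
#'
#' Each writer emits the exact dialect the matching reader expects, so that
#' write -> read round-trips reproduce values to numerical precision and
#' metadata exactly.
#'
#' @param x object to write.
#' @param path output path.
#' @name writers
NULL

#' @rdname writers
#' @export
write_genotypes_tsv <- function(x, path) {
  stopifnot(inherits(x, "DosageMatrix"))
  d <- data.frame(id = x$variants$id, t(x$dosages), check.names = FALSE)
  data.table::fwrite(d, path, sep = "\t")
  data.table::fwrite(x$variants[, c("id", "chrom", "pos", "ref", "alt")],
                     paste0(path, ".variants"), sep = "\t")
  invisible(path)
}

#' @rdname writers
#' @export
write_genotypes_vcf <- function(x, path) {
  stopifnot(inherits(x, "DosageMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", x$samples), collapse = "\t")), con)
  v <- x$variants
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS", ".",
            "DS", format(x$dosages[, j], trim = TRUE, digits = 15)),
          collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' @rdname writers
#' @export
write_phenotypes <- function(x, path) {
  stopifnot(inherits(x, "PhenotypeTable"))
  d <- data.frame(`#chr` = x$genes$chrom, start = x$genes$start, end = x$genes$end,
                  gene_id = x$genes$gene_id, x$values,
                  check.names = FALSE)
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' @rdname writers
#' @export
write_covariates <- function(x, path) {
  stopifnot(inherits(x, "CovariateMatrix"))
  d <- data.frame(covariate = x$names, t(x$values), check.names = FALSE)
  colnames(d)[-1] <- x$samples
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' @rdname writers
#' @export
write_gwas <- function(x, path) {
  data.table::fwrite(as.data.frame(unclass(x))[, c("id", "chrom", "pos", "a1", "a2", "z")],
                     path, sep = "\t")
  invisible(path)
}

#' @rdname writers
#' @export
write_ld <- function(x, path) {
  stopifnot(inherits(x, "LdMatrix"))
  d <- data.frame(id = x$ids, x$sigma, check.names = FALSE)
  colnames(d)[-1] <- x$ids
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' @rdname writers
#' @export
write_bed <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Align samples across genotype, phenotype, and covariate objects
#'
#' Restricts all objects to the samples common to all of them, ordered as in
#' the genotype object, so that the i-th row refers to the same individual
#' everywhere.
#'
#' @param geno `DosageMatrix`.
#' @param pheno `PhenotypeTable`.
#' @param covar `CovariateMatrix` or NULL.
#' @return list(geno, pheno, covar) with identical sample order.
#' @export
align_samples <- function(geno, pheno, covar = NULL) {
  common <- intersect(geno$samples, pheno$samples)
  if (!is.null(covar)) common <- intersect(common, covar$samples)
  if (length(common) == 0L) stop("no samples shared across inputs")
  common <- geno$samples[geno$samples %in% common]
  g <- dosage_matrix(geno$dosages[match(common, geno$samples), , drop = FALSE],
                     geno$variants, common)
  p <- phenotype_table(pheno$genes,
                       pheno$values[, match(common, pheno$samples), drop = FALSE],
                       common)
  cv <- NULL
  if (!is.null(covar))
    cv <- covariate_matrix(covar$values[match(common, covar$samples), , drop = FALSE],
                           common)
  list(geno = g, pheno = p, covar = cv)
}

#' Harmonize GWAS summary statistics to a variant table
#'
#' Matches on (chrom, pos). When the GWAS alleles are swapped relative to the
#' reference (a1 == ref, a2 == alt), the z-score sign is flipped.
#' Strand-ambiguous A/T and C/G pairs are dropped by default; mismatched
#' allele pairs are always dropped.
#'
#' @param gwas `GwasSummary`.
#' @param variants data.frame with id, chrom, pos, ref, alt (alt = effect allele).
#' @param drop_ambiguous drop A/T and C/G pairs (default TRUE).
#' @return data.frame(id, z) aligned to `variants` rows that matched.
#' @export
harmonize_gwas <- function(gwas, variants, drop_ambiguous = TRUE) {
  key_v <- paste(.strip_chr(variants$chrom), variants$pos)
  key_g <- paste(.strip_chr(gwas$chrom), gwas$pos)
  idx <- match(key_v, key_g)
  out <- data.frame(id = variants$id, z = NA_real_)
  hit <- which(!is.na(idx))
  for (i in hit) {
    j <- idx[i]
    a1 <- toupper(gwas$a1[j]); a2 <- toupper(gwas$a2[j])
    ref <- toupper(variants$ref[i]); alt <- toupper(variants$alt[i])
    ambiguous <- paste0(a1, a2) %in% c("AT", "TA", "CG", "GC")
    if (drop_ambiguous && ambiguous) next
    if (a1 == alt && a2 == ref) out$z[i] <- gwas$z[j]
    else if (a1 == ref && a2 == alt) out$z[i] <- -gwas$z[j]
    ## otherwise: allele mismatch, left NA
  }
  out[!is.na(out$z), , drop = FALSE]
}
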