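## Excess-of-overlap (EOO) enrichment of variant-gene link sets, LOCO
## jackknife errors, difference z-tests, and hypergeometric gene-set ORA.

#' Flag variants overlapping BED annotation intervals
#'
#' A variant with 1-based position `pos` overlaps a 0-based half-open
#' interval [start, end) iff pos - 1 lies in it. Chromosome names are
#' normalized ("chr1" and "1" match).
#'
#' @param variants data.frame with chrom and pos (1-based).
#' @param annotation data.frame(chrom, start, end) of BED intervals.
#' @return logical vector, one flag per variant row.
#' @export
overlap_annotation <- function(variants, annotation) {
  n <- nrow(variants)
  if (n == 0L || nrow(annotation) == 0L) return(logical(n))
  ## point query at pos - 1 against closed intervals [start, end - 1],
  ## equivalent to the half-open convention [start, end)
  q <- data.table::data.table(chrom = .strip_chr(variants$chrom),
                              start = variants$pos - 1L,
                              end = variants$pos - 1L,
                              row = seq_len(n))
  a <- data.table::data.table(chrom = .strip_chr(annotation$chrom),
                              start = as.integer(annotation$start),
                              end = as.integer(annotation$end) - 1L)
  a <- a[a$end >= a$start, ]
  if (nrow(a) == 0L) return(logical(n))
  data.table::setkey(a, chrom, start, end)
  hits <- data.table::foverlaps(q, a, type = "within", nomatch = NULL)
  out <- logical(n)
  out[unique(hits$row)] <- TRUE
  out
}

#' Excess of overlap between two variant-gene link sets
#'
#' EOO = (|VG1 and VG2| / T12) / ((VG1/T1) (VG2/T2)), where T1, T2 are the
#' sizes of the tested universes of each method and T12 the size of the
#' jointly tested universe. Values above 1 indicate more overlap than
#' expected under independence. Here the three flag vectors are defined over
#' a common pair universe, so T1 = T2 = T12 = number of tested pairs.
#'
#' @param vg1,vg2 logical significance flags over the common pair universe.
#' @param tested logical flags of the jointly tested pairs (default all).
#' @return list(eoo, counts = c(VG1, VG2, overlap, T1, T2, T12)); `eoo` is NA
#'   with a reason attribute when a denominator count is zero.
#' @export
eoo <- function(vg1, vg2, tested = NULL) {
  if (is.null(tested)) tested <- rep(TRUE, length(vg1))
  stopifnot(length(vg1) == length(vg2), length(vg1) == length(tested))
  cnt <- .eoo_counts(vg1, vg2, tested)
  list(eoo = .eoo_value(cnt), counts = cnt)
}

.eoo_counts <- function(vg1, vg2, tested) {
  c(VG1 = sum(vg1 & tested), VG2 = sum(vg2 & tested),
    overlap = sum(vg1 & vg2 & tested),
    T1 = sum(tested), T2 = sum(tested), T12 = sum(tested))
}

.eoo_value <- function(cnt) {
  if (cnt[["T1"]] == 0 || cnt[["T2"]] == 0 || cnt[["T12"]] == 0 ||
      cnt[["VG1"]] == 0 || cnt[["VG2"]] == 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero denominator count"
    return(out)
  }
  (cnt[["overlap"]] / cnt[["T12"]]) /
    ((cnt[["VG1"]] / cnt[["T1"]]) * (cnt[["VG2"]] / cnt[["T2"]]))
}

#' Leave-one-chromosome-out jackknife for the EOO statistic
#'
#' Recomputes EOO with each chromosome's pairs removed in turn; the delete-one
#' jackknife variance is se^2 = (K-1)/K sum_c (theta_(-c) - mean)^2.
#'
#' @param vg1,vg2,tested flags as in [eoo()].
#' @param chrom chromosome of each pair.
#' @return list(eoo, se, loco = per-chromosome leave-out estimates).
#' @export
eoo_loco_se <- function(vg1, vg2, chrom, tested = NULL) {
  if (is.null(tested)) tested <- rep(TRUE, length(vg1))
  chrom <- .strip_chr(chrom)
  chroms <- unique(chrom[tested])
  if (length(chroms) < 2L) stop("LOCO jackknife needs >= 2 chromosomes with tested pairs")
  theta <- vapply(chroms, function(cc) {
    keep <- chrom != cc
    .eoo_value(.eoo_counts(vg1[keep], vg2[keep], tested[keep]))
  }, numeric(1))
  if (anyNA(theta)) stop("EOO undefined in a leave-one-chromosome-out fold")
  K <- length(theta)
  se <- sqrt((K - 1) / K * sum((theta - mean(theta))^2))
  list(eoo = .eoo_value(.eoo_counts(vg1, vg2, tested)), se = se,
       loco = stats::setNames(theta, chroms))
}

#' z-test for a difference of enrichment estimates
#'
#' z = (e1 - e2) / sqrt(se1^2 + se2^2), two-sided p, with Benjamini-Hochberg
#' q-values across annotations when vectors are supplied. Zero pooled
#' standard error with unequal estimates yields an infinite-z sentinel
#' (p = 0).
#'
#' @param e1,se1,e2,se2 enrichment estimates and standard errors (vectors
#'   are treated as one test per annotation).
#' @return data.frame(z, p, q).
#' @export
eoo_diff_test <- function(e1, se1, e2, se2) {
  pooled <- sqrt(se1^2 + se2^2)
  z <- ifelse(pooled == 0, ifelse(e1 == e2, 0, Inf * sign(e1 - e2)),
              (e1 - e2) / pooled)
  p <- ifelse(is.infinite(z), 0, 2 * stats::pnorm(-abs(z)))
  p[which(z == 0 & pooled == 0)] <- 1
  data.frame(z = z, p = p, q = stats::p.adjust(p, method = "BH"))
}

#' Hypergeometric over-representation analysis
#'
#' For a gene set G and a term set T within a universe U, forms the 2x2 table
#' a = |G and T|, b = |G \ T|, c = |T \ G|, d = |U \ (G or T)| and reports
#' enrichment = (a d) / (b c) with the upper-tail hypergeometric p-value.
#' A zero margin makes the enrichment undefined (NA sentinel, p = 1).
#'
#' @param gene_set character vector (subset of universe).
#' @param term_set character vector (subset of universe).
#' @param universe character vector of background genes.
#' @return list(counts = c(a,b,c,d), enrichment, p).
#' @export
ora <- function(gene_set, term_set, universe) {
  universe <- unique(universe)
  gene_set <- unique(intersect(gene_set, universe))
  term_set <- unique(intersect(term_set, universe))
  a <- length(intersect(gene_set, term_set))
  b <- length(setdiff(gene_set, term_set))
  c_ <- length(setdiff(term_set, gene_set))
  d <- length(universe) - a - b - c_
  enr <- if (b == 0 || c_ == 0) {
    if (a == 0) 0 else NA_real_
  } else (a * d) / (b * c_)
  p <- if (length(gene_set) == 0L || length(term_set) == 0L) 1 else
    stats::phyper(a - 1, length(term_set), length(universe) - length(term_set),
                  length(gene_set), lower.tail = FALSE)
  list(counts = c(a = a, b = b, c = c_, d = d), enrichment = enr, p = p)
}

#' ORA over a list of gene sets
#'
#' @param gene_set genes of interest.
#' @param term_sets named list of term gene vectors (e.g. from [read_gmt()]).
#' @param universe background genes.
#' @return data.frame(term, a, b, c, d, enrichment, p, q) with BH q-values.
#' @export
ora_table <- function(gene_set, term_sets, universe) {
  rows <- lapply(names(term_sets), function(nm) {
    r <- ora(gene_set, term_sets[[nm]], universe)
    data.frame(term = nm, a = r$counts["a"], b = r$counts["b"],
               c = r$counts["c"], d = r$counts["d"],
               enrichment = r$enrichment, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
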