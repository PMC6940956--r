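#' Normalize an expression matrix
#'
#' Microarray mode (log2 intensities): per-chip percentile-shift
#' normalization to the 75th percentile (each sample's 75th percentile is
#' subtracted, shifting it to zero), followed by a baseline transformation
#' on the median of all samples (each gene is centred on its cross-sample
#' median). RNA-seq mode (counts): median-of-ratios size factors — each
#' gene's geometric mean across samples is the reference, a sample's size
#' factor is the median of its count-to-reference ratios over genes with
#' nonzero geometric mean, and counts are divided by the factor.
#'
#' @param em An [expression_matrix()].
#' @return The normalized `ExpressionMatrix`; in RNA-seq mode the size
#'   factors are attached as attribute `size_factors`.
#' @examples
#' sim <- simulate_expression_matrix(n_genes = 100, seed = 1)
#' norm <- normalize_matrix(sim$matrix)
#' attr(norm, "size_factors")
#' @export
normalize_matrix <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  x <- em$values
  if (any(colSums(abs(x)) == 0))
    .stopf("all-zero sample(s): %s",
           paste(colnames(x)[colSums(abs(x)) == 0], collapse = ", "))
  if (em$mode == "microarray") {
    shifted <- sweep(x, 2, apply(x, 2, quantile, probs = 0.75, names = FALSE))
    centred <- sweep(shifted, 1, apply(shifted, 1, median))
    em$values <- centred
    em
  } else {
    if (any(x < 0) || any(x != round(x)))
      .stopf("rnaseq mode requires non-negative integer counts")
    log_geo <- rowMeans(log(x))            # -Inf for genes with any zero
    usable <- is.finite(log_geo)
    if (!any(usable))
      .stopf("no gene has all-positive counts; size factors inestimable")
    sf <- apply(x, 2, function(col) {
      median(exp(log(col[usable]) - log_geo[usable]))
    })
    em$values <- sweep(x, 2, sf, `/`)
    attr(em, "size_factors") <- sf
    em
  }
}

#' Negative-binomial Wald test for differential expression
#'
#' Transparent per-gene two-group test on a normalized count matrix.
#' For each gene the log2 fold change is
#' `log2((meanB + c)/(meanA + c))` with pseudo-count `c = 0.5` on normalized
#' counts. The Wald statistic divides the log2 fold change by its
#' delta-method standard error under the negative-binomial variance
#' `mu + alpha mu^2`. The gene-wise dispersion `alpha` is estimated by the
#' method of moments from within-group means and variances, floored below at
#' the dataset-wide median of the gene-wise estimates (a conservative floor
#' that protects the small-replicate Wald test from understated variances).
#' Two-sided normal p-values are returned together with BH-adjusted values.
#'
#' @param em A normalized [expression_matrix()] (see [normalize_matrix()]).
#' @param contrast Character vector `c(groupA, groupB)`; the fold change is
#'   B over A.
#' @param pseudo_count Pseudo-count added to group means in the fold change.
#' @return A data frame of class `DegTable`: gene, base_mean, log2FC, se,
#'   stat, p, fdr.
#' @export
de_test <- function(em, contrast, pseudo_count = 0.5) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (length(contrast) != 2) .stopf("contrast must name two groups")
  missing <- setdiff(contrast, unique(em$design))
  if (length(missing))
    .stopf("contrast group(s) absent from design: %s",
           paste(missing, collapse = ", "))
  a <- em$values[, em$design == contrast[1], drop = FALSE]
  b <- em$values[, em$design == contrast[2], drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2)
    .stopf("each contrasted group needs >= 2 replicates")
  nA <- ncol(a); nB <- ncol(b)
  mA <- rowMeans(a); mB <- rowMeans(b)
  vA <- apply(a, 1, var); vB <- apply(b, 1, var)
  pooled_mean <- (mA + mB) / 2
  pooled_var <- (vA + vB) / 2
  alpha_gene <- pmax(0, (pooled_var - pooled_mean) / pooled_mean^2)
  alpha_gene[!is.finite(alpha_gene)] <- 0
  expressed <- pooled_mean > 5
  alpha_floor <- if (any(expressed)) median(alpha_gene[expressed]) else 0
  alpha <- pmax(alpha_gene, alpha_floor)
  log2fc <- log2((mB + pseudo_count) / (mA + pseudo_count))
  var_mA <- (mA + alpha * mA^2) / nA
  var_mB <- (mB + alpha * mB^2) / nB
  se <- sqrt(var_mA / (mA + pseudo_count)^2 +
             var_mB / (mB + pseudo_count)^2) / log(2)
  stat <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pnorm(-abs(stat))
  out <- data.frame(gene = rownames(em$values), base_mean = pooled_mean,
                    log2FC = log2fc, se = se, stat = stat, p = p,
                    fdr = adjust_pvalues(p, "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("DegTable", "data.frame")
  attr(out, "contrast") <- contrast
  attr(out, "dispersion_floor") <- alpha_floor
  out
}

#' Adjust p-values for multiple testing (BH / BY step-up)
#'
#' Benjamini-Hochberg controls the false discovery rate under independence
#' or positive dependence; Benjamini-Yekutieli multiplies by the harmonic
#' sum H(m) and controls it under arbitrary dependence.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` or `"BY"`.
#' @return Adjusted p-values, clipped to `[0, 1]`, monotone in rank.
#' @export
adjust_pvalues <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    .stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' Call differentially expressed genes
#'
#' A gene is up-regulated when `log2FC >= lfc_threshold` and
#' `fdr <= fdr_threshold`, down-regulated when `log2FC <= -lfc_threshold`
#' and `fdr <= fdr_threshold` (thresholds inclusive). The sets are disjoint
#' by construction.
#'
#' @param records A `DegTable` (or data frame with `gene`, `log2FC`, `fdr`).
#' @param lfc_threshold Minimum absolute log2 fold change (default 2).
#' @param fdr_threshold Maximum adjusted p-value (default 0.01).
#' @return A list with character vectors `up` and `down`, and `records` with
#'   an added `direction` column (`"up"`, `"down"`, `"ns"`).
#' @export
call_degs <- function(records, lfc_threshold = 2, fdr_threshold = 0.01) {
  if (!all(c("gene", "log2FC", "fdr") %in% names(records)))
    .stopf("records must carry gene, log2FC and fdr columns")
  up <- records$log2FC >= lfc_threshold & records$fdr <= fdr_threshold
  down <- records$log2FC <= -lfc_threshold & records$fdr <= fdr_threshold
  records$direction <- ifelse(up, "up", ifelse(down, "down", "ns"))
  list(up = records$gene[up], down = records$gene[down], records = records)
}

#' Cluster the most variable genes
#'
#' Ranks genes by cross-sample standard deviation (ties broken by gene id),
#' keeps the top `n_top` with nonzero SD, z-scores each gene's row, and
#' clusters either by k-means (fixed seed, `n_init` restarts, Euclidean) or
#' hierarchically (average linkage on 1 - Pearson correlation distance, cut
#' at `k`).
#'
#' @param em An [expression_matrix()].
#' @param n_top Number of top-variance genes to keep (default 1000).
#' @param k Number of clusters (default 2).
#' @param method `"kmeans"` or `"hierarchical"`.
#' @param seed Seed for the k-means restarts.
#' @param n_init Number of k-means restarts.
#' @return Named integer vector of cluster assignments (1..k) over the
#'   selected genes, with the ranking attached as attribute `ranked_genes`.
#' @export
cluster_top_genes <- function(em, n_top = 1000, k = 2,
                              method = c("kmeans", "hierarchical"),
                              seed = 1L, n_init = 10) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  method <- match.arg(method)
  x <- em$values
  if (n_top > nrow(x)) .stopf("n_top (%d) exceeds gene count (%d)", n_top, nrow(x))
  sds <- apply(x, 1, sd)
  keep <- sds > 0
  ord <- order(-sds[keep], rownames(x)[keep])
  ranked <- rownames(x)[keep][ord]
  top <- head(ranked, n_top)
  z <- t(scale(t(x[top, , drop = FALSE])))
  cl <- if (k == 1) {
    setNames(rep(1L, length(top)), top)
  } else if (method == "kmeans") {
    fit <- .with_seed(seed, function()
      kmeans(z, centers = k, nstart = n_init, iter.max = 100))
    setNames(as.integer(fit$cluster), top)
  } else {
    d <- as.dist(1 - cor(t(z)))
    setNames(as.integer(cutree(hclust(d, method = "average"), k = k)), top)
  }
  attr(cl, "ranked_genes") <- ranked
  cl
}

#' GO term enrichment by the exact hypergeometric (one-sided Fisher) test
#'
#' For each term with at least `min_mapping` genes mapped in the background,
#' tests over-representation of the term in the query set with the upper
#' hypergeometric tail, then adjusts across terms (Benjamini-Yekutieli by
#' default, matching FDR control under the dependence between nested GO
#' terms).
#'
#' @param query Character vector of genes of interest (must be a subset of
#'   `background`).
#' @param background Character vector of all assayed genes.
#' @param annotation Data frame with columns `gene` and `term`.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param min_mapping Minimum background genes per term (default 5); smaller
#'   terms are dropped before testing.
#' @param adjust `"BY"` (default) or `"BH"`.
#' @return A data frame of class `EnrichmentResult`: term, term_size,
#'   query_size, overlap, expected, p, adjusted_p, enriched; sorted by p.
#' @export
go_enrichment <- function(query, background, annotation, alpha = 0.05,
                          min_mapping = 5, adjust = "BY") {
  outside <- setdiff(query, background)
  if (length(outside))
    .stopf("query gene(s) outside the background: %s",
           paste(head(outside, 5), collapse = ", "))
  if (!all(c("gene", "term") %in% names(annotation)))
    .stopf("annotation must have 'gene' and 'term' columns")
  ann <- annotation[annotation$gene %in% background, , drop = FALSE]
  ann <- unique(ann[c("gene", "term")])
  term_genes <- split(ann$gene, ann$term)
  term_genes <- term_genes[lengths(term_genes) >= min_mapping]
  N <- length(unique(background))
  n <- length(unique(query))
  rows <- lapply(names(term_genes), function(tm) {
    K <- length(term_genes[[tm]])
    k <- length(intersect(query, term_genes[[tm]]))
    # upper tail P(X >= k), X ~ Hypergeom(N, K, n)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, term_size = K, query_size = n, overlap = k,
               expected = n * K / N, p = p, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(), term_size = integer(),
               query_size = integer(), overlap = integer(),
               expected = numeric(), p = numeric())
  out$adjusted_p <- if (nrow(out)) adjust_pvalues(out$p, adjust) else numeric(0)
  out$enriched <- out$adjusted_p <= alpha
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}
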