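#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fits a one-way ANOVA on replicate values grouped by label, follows it
#' with Tukey's honestly-significant-difference test (studentized-range
#' distribution), and assigns compact letters so that two groups share a
#' letter exactly when their Tukey-adjusted p exceeds `alpha` (the
#' annotation style used on bar plots of fluorescence parameters). Letters
#' are assigned by insert-and-absorb over the significant-difference graph
#' with groups ordered by mean descending.
#'
#' @param values Numeric replicate measurements.
#' @param groups Group label per value (>= 2 groups, >= 2 replicates each).
#' @param alpha Significance level for both the ANOVA gate and the letters.
#' @return A list with `F`, `p`, `df`, `tukey` (data frame: comparison,
#'   diff, lwr, upr, p_adj) and `letters` (named character vector).
#' @examples
#' anova_tukey(c(1, 2, 3, 5, 6, 7), rep(c("ctrl", "drought"), each = 3))
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  if (length(values) != length(groups))
    .stopf("values and groups must have equal length")
  tab <- table(groups)
  if (length(tab) < 2) .stopf("need >= 2 groups")
  if (any(tab < 2)) .stopf("need >= 2 replicates per group")
  wvar <- tapply(values, groups, var)
  if (all(wvar == 0))
    .stopf("zero within-group variance: ANOVA undefined")
  g <- factor(groups)
  fit <- aov(values ~ g)
  an <- summary(fit)[[1]]
  f_stat <- an[["F value"]][1]
  p_val <- an[["Pr(>F)"]][1]
  if (!is.finite(f_stat)) { f_stat <- 0; p_val <- 1 }
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  # significant-difference matrix
  lev <- levels(g)
  sig <- matrix(FALSE, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_len(nrow(tukey))) {
    pr <- strsplit(tukey$comparison[i], "-", fixed = TRUE)[[1]]
    s <- is.finite(tukey$p_adj[i]) && tukey$p_adj[i] <= alpha
    sig[pr[1], pr[2]] <- sig[pr[2], pr[1]] <- s
  }
  ord <- names(sort(tapply(values, groups, mean), decreasing = TRUE))
  letters_out <- .compact_letters(sig[ord, ord, drop = FALSE])
  list(F = f_stat, p = p_val, df = an[["Df"]], tukey = tukey,
       letters = letters_out[lev])
}

# Compact letter display over the significant-difference graph. `sig` is a
# symmetric logical matrix (TRUE = significantly different), rows/cols in
# display order (mean descending). One letter per maximal clique of the
# NON-difference graph: groups share a letter iff they are not
# significantly different. Bron-Kerbosch is cheap at the handful of groups
# a comparison ever has.
.compact_letters <- function(sig) {
  gn <- rownames(sig)
  n <- length(gn)
  adj <- !sig & !diag(TRUE, n)        # compatibility (non-difference) graph
  cliques <- list()
  bk <- function(r, p, x) {
    if (!length(p) && !length(x)) {
      cliques[[length(cliques) + 1]] <<- r
      return()
    }
    for (v in p) {
      nb <- which(adj[v, ])
      bk(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  # order letters by each clique's best-ranked (largest-mean) member
  cliques <- cliques[order(vapply(cliques, min, numeric(1)))]
  out <- setNames(rep("", n), gn)
  for (ci in seq_along(cliques)) {
    for (v in sort(cliques[[ci]])) out[v] <- paste0(out[v], letters[ci])
  }
  out
}

#' Signed squared Pearson correlation
#'
#' Returns `sign(r) * r^2`, the convention under which a tight negative
#' association prints as a negative R-squared.
#'
#' @param x,y Equal-length numeric vectors (n >= 3) with nonzero variance.
#' @return Scalar in `[-1, 1]` whose absolute value is r-squared.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    .stopf("x and y must be equal-length vectors with n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    .stopf("constant series: correlation undefined")
  r <- cor(x, y)
  sign(r) * r^2
}

#' qPCR fold change from Ct values
#'
#' `FC = E^-(Ct_treated - Ct_control)` where E is the gene's mean
#' amplification efficiency (in (1, 2]; 2 = perfect doubling per cycle).
#' Optionally, Ct values are first normalized to a reference gene
#' (delta-delta-Ct style pre-subtraction).
#'
#' @param ct_table Data frame with columns `gene`, `condition`, `mean_ct`,
#'   `efficiency`.
#' @param treated,control Condition labels to compare (fold change of
#'   treated relative to control).
#' @param reference_gene Optional reference gene id whose Ct is subtracted
#'   from each gene's Ct within the same condition before the formula is
#'   applied (default: no pre-subtraction, matching the bare formula).
#' @return Data frame: gene, efficiency, delta_ct, fc, signed_fc (the
#'   display convention where down-regulation FC < 1 is shown as the
#'   negative reciprocal, e.g. 0.25 -> -4).
#' @export
qpcr_fold_change <- function(ct_table, treated, control,
                             reference_gene = NULL) {
  need <- c("gene", "condition", "mean_ct", "efficiency")
  if (!all(need %in% names(ct_table)))
    .stopf("ct_table must have columns %s", paste(need, collapse = ", "))
  for (cond in c(treated, control)) {
    if (!cond %in% ct_table$condition)
      .stopf("condition '%s' missing from ct_table", cond)
  }
  tab <- ct_table
  if (!is.null(reference_gene)) {
    if (!reference_gene %in% tab$gene)
      .stopf("reference gene '%s' missing from ct_table", reference_gene)
    for (cond in unique(tab$condition)) {
      ref_ct <- tab$mean_ct[tab$gene == reference_gene &
                            tab$condition == cond]
      sel <- tab$condition == cond
      tab$mean_ct[sel] <- tab$mean_ct[sel] - ref_ct
    }
    tab <- tab[tab$gene != reference_gene, , drop = FALSE]
  }
  genes <- unique(tab$gene)
  rows <- lapply(genes, function(gid) {
    ct_t <- tab$mean_ct[tab$gene == gid & tab$condition == treated]
    ct_c <- tab$mean_ct[tab$gene == gid & tab$condition == control]
    if (!length(ct_t) || !length(ct_c))
      .stopf("gene '%s' lacks Ct for one of the conditions", gid)
    e <- tab$efficiency[tab$gene == gid][1]
    if (e <= 1 || e > 2) .stopf("gene '%s': efficiency %g not in (1, 2]", gid, e)
    dct <- mean(ct_t) - mean(ct_c)
    fc <- e^(-dct)
    data.frame(gene = gid, efficiency = e, delta_ct = dct, fc = fc,
               signed_fc = ifelse(fc >= 1, fc, -1 / fc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Water loss of a dehydrated leaf
#'
#' `WL = Dw * 100 / Fw` (percent of fresh weight remaining after
#' dehydration). The rapid-dehydration protocol stops at 30% weight loss,
#' i.e. when WL first reaches 70% or less; `reached_target` flags that.
#'
#' @param fresh_weight Fresh weight (Fw), > 0.
#' @param dehydrated_weight Dehydrated weight (Dw), in `(0, Fw]`.
#' @param target_percent Stop threshold as remaining-weight percent
#'   (default 70).
#' @return List with `wl_percent` and `reached_target`.
#' @export
water_loss <- function(fresh_weight, dehydrated_weight,
                       target_percent = 70) {
  if (fresh_weight <= 0) .stopf("fresh weight must be > 0")
  if (dehydrated_weight <= 0) .stopf("dehydrated weight must be > 0")
  if (dehydrated_weight > fresh_weight)
    .stopf("dehydrated weight (%g) exceeds fresh weight (%g)",
           dehydrated_weight, fresh_weight)
  wl <- dehydrated_weight * 100 / fresh_weight
  list(wl_percent = wl, reached_target = wl <= target_percent)
}

#' Express group means as percent of a control group
#'
#' @param means Named numeric vector of group means.
#' @param control_label Name of the control entry (must be nonzero).
#' @return Named numeric vector of `100 * mean / control`; the control maps
#'   to 100.
#' @export
percent_of_control <- function(means, control_label) {
  if (!control_label %in% names(means))
    .stopf("control label '%s' absent", control_label)
  ctrl <- means[[control_label]]
  if (ctrl == 0) .stopf("control mean is zero; percentages undefined")
  100 * means / ctrl
}
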