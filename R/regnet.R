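#' Construct a position weight matrix
#'
#' @param id Motif identifier.
#' @param matrix Numeric L x 4 matrix of per-position base probabilities,
#'   columns A, C, G, T; each row must sum to 1 within 1e-3 before the
#'   pseudocount is applied.
#' @param family Optional TF family label.
#' @param pseudocount Additive pseudocount applied to every cell, after
#'   which rows are renormalized (keeps log-likelihood ratios finite on
#'   degenerate columns).
#' @return An object of class `Pwm`.
#' @export
pwm <- function(id, matrix, family = NA_character_, pseudocount = 1e-4) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4) .stopf("motif '%s': matrix must have 4 columns (A C G T)", id)
  if (nrow(matrix) < 1) .stopf("motif '%s': length must be >= 1", id)
  if (any(matrix < 0)) .stopf("motif '%s': negative probabilities", id)
  bad <- which(abs(rowSums(matrix) - 1) > 1e-3)
  if (length(bad))
    .stopf("motif '%s': row(s) %s do not sum to 1 within 1e-3", id,
           paste(bad, collapse = ", "))
  matrix <- matrix + pseudocount
  matrix <- matrix / rowSums(matrix)
  colnames(matrix) <- .DNA_BASES
  structure(list(id = id, family = family, matrix = matrix,
                 pseudocount = pseudocount), class = "Pwm")
}

#' @export
print.Pwm <- function(x, ...) {
  cat(sprintf("Pwm '%s' (%s), length %d, consensus %s\n", x$id,
              ifelse(is.na(x$family), "family NA", x$family),
              nrow(x$matrix), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a motif (highest-probability base per position)
#' @param pwm A [pwm()] object.
#' @return Character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(.DNA_BASES[apply(pwm$matrix, 1, which.max)], collapse = "")
}

#' Read motifs in MEME minimal format
#'
#' Parses the minimal motif exchange format: a `MEME version` line, an
#' `ALPHABET= ACGT` line, optional strand/background lines, then one
#' `MOTIF <id> [alt]` block per motif with its `letter-probability matrix`
#' header and probability rows. Probabilities get the additive pseudocount
#' of [pwm()].
#'
#' @param path File path.
#' @param pseudocount Passed to [pwm()].
#' @return A list of `Pwm` objects in file order.
#' @export
read_meme_motifs <- function(path, pseudocount = 1e-4) {
  lines <- readLines(path, warn = FALSE)
  strip <- trimws(lines)
  if (!any(grepl("^MEME version", strip)))
    .stopf("%s: missing 'MEME version' header line", path)
  alpha_i <- grep("^ALPHABET\\s*=", strip)
  if (length(alpha_i)) {
    alpha <- gsub("\\s", "", sub("^ALPHABET\\s*=", "", strip[alpha_i[1]]))
    if (toupper(alpha) != "ACGT")
      .stopf("%s line %d: alphabet '%s' is not DNA (ACGT)",
             path, alpha_i[1], alpha)
  }
  motif_i <- grep("^MOTIF\\b", strip)
  if (!length(motif_i)) return(list())
  bounds <- c(motif_i, length(strip) + 1L)
  motifs <- vector("list", length(motif_i))
  for (m in seq_along(motif_i)) {
    block <- strip[motif_i[m]:(bounds[m + 1] - 1L)]
    toks <- strsplit(block[1], "\\s+")[[1]]
    if (length(toks) < 2)
      .stopf("%s line %d: MOTIF line lacks an identifier", path, motif_i[m])
    id <- toks[2]
    alt <- if (length(toks) >= 3) toks[3] else NA_character_
    hdr <- grep("^letter-probability matrix", block)
    if (!length(hdr))
      .stopf("%s: motif '%s' lacks a letter-probability matrix header", path, id)
    w <- suppressWarnings(
      as.integer(sub(".*w\\s*=\\s*(\\d+).*", "\\1", block[hdr[1]])))
    rows <- list(); i <- hdr[1] + 1L
    while (i <= length(block) && grepl("^[-0-9.eE+ \t]+$", block[i]) &&
           nzchar(block[i])) {
      vals <- suppressWarnings(as.numeric(strsplit(block[i], "\\s+")[[1]]))
      if (length(vals) != 4 || any(is.na(vals)))
        .stopf("%s line %d: expected 4 probabilities", path, motif_i[m] + i - 1L)
      if (abs(sum(vals) - 1) > 1e-3)
        .stopf("%s line %d: probabilities sum to %.4f, not 1",
               path, motif_i[m] + i - 1L, sum(vals))
      rows[[length(rows) + 1L]] <- vals
      i <- i + 1L
    }
    if (!length(rows))
      .stopf("%s: motif '%s' has an empty probability matrix", path, id)
    if (!is.na(w) && w != length(rows))
      .stopf("%s: motif '%s' declares w=%d but has %d rows",
             path, id, w, length(rows))
    motifs[[m]] <- pwm(id, do.call(rbind, rows), family = alt,
                       pseudocount = pseudocount)
  }
  motifs
}

#' Write motifs in MEME minimal format
#' @param motifs List of [pwm()] objects.
#' @param path Output file.
#' @param background Background frequencies recorded in the header.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(motifs, path,
                              background = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25)) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       background[["A"]], background[["C"]],
                       background[["G"]], background[["T"]]), ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s%s", m$id,
                       ifelse(is.na(m$family), "", paste0(" ", m$family))), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(m$matrix)), con)
    writeLines(apply(m$matrix, 1, function(r)
      paste(sprintf("%.6f", r), collapse = "  ")), con)
    writeLines("", con)
  }
  invisible(path)
}

# Integer per-position score table in grid units (1/`grid` bit):
# score(i, b) = log2(pwm[i, b] / bg[b]), rounded to the grid.
.pwm_grid_scores <- function(pwm, background, grid = 1e-3) {
  if (any(background <= 0)) .stopf("background frequencies must be > 0")
  background <- background / sum(background)
  bits <- log2(sweep(pwm$matrix, 2, background[.DNA_BASES], `/`))
  round(bits / grid)
}

# Exact null distribution of the grid score under the background model,
# by dynamic-programming convolution of the per-position distributions.
# Returns list(support = integer offsets, tail = P(S >= support)).
.pwm_score_distribution <- function(grid_scores, background) {
  background <- background / sum(background)
  cur_lo <- 0L
  # Before position i the distribution lives on offsets [cur_lo, ...].
  dist <- 1
  for (i in seq_len(nrow(grid_scores))) {
    row <- grid_scores[i, ]
    new_lo <- cur_lo + min(row)
    new_hi <- cur_lo + length(dist) - 1L + max(row)
    new <- rep(0, new_hi - new_lo + 1L)
    for (b in seq_len(4)) {
      off <- cur_lo + row[b] - new_lo
      idx <- seq_along(dist) + off
      new[idx] <- new[idx] + dist * background[[b]]
    }
    dist <- new
    cur_lo <- new_lo
  }
  support <- seq.int(cur_lo, cur_lo + length(dist) - 1L)
  tail <- rev(cumsum(rev(dist)))
  tail <- pmin(tail, 1)
  list(support = support, tail = tail)
}

#' Exact p-value of a PWM score under the background model
#'
#' P(score >= s) for the log-likelihood-ratio score of a random word drawn
#' from the background, computed exactly by dynamic-programming convolution
#' of the per-position score distributions on a 1/1000-bit grid.
#'
#' @param pwm A [pwm()] object.
#' @param score Score(s) in bits.
#' @param background Base frequencies (A, C, G, T).
#' @param grid Score discretization in bits (default 1e-3).
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
pwm_score_pvalue <- function(pwm, score,
                             background = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                             grid = 1e-3) {
  gs <- .pwm_grid_scores(pwm, background, grid)
  d <- .pwm_score_distribution(gs, background)
  g <- round(score / grid)
  vapply(g, function(s) {
    if (s <= d$support[1]) return(1)
    if (s > d$support[length(d$support)]) return(0)
    d$tail[s - d$support[1] + 1]
  }, numeric(1))
}

.score_words <- function(grid_scores, seq_chars) {
  # grid score of each window of length L over the integer-coded sequence
  L <- nrow(grid_scores)
  n <- length(seq_chars) - L + 1L
  if (n < 1) return(integer(0))
  code <- match(seq_chars, .DNA_BASES)      # NA for N and friends
  out <- integer(n)
  ok <- logical(n)
  for (start in seq_len(n)) {
    idx <- code[start:(start + L - 1L)]
    if (anyNA(idx)) { ok[start] <- FALSE; next }
    out[start] <- sum(grid_scores[cbind(seq_len(L), idx)])
    ok[start] <- TRUE
  }
  list(score = out, ok = ok)
}

#' Scan a DNA sequence with a position weight matrix
#'
#' Scores every window on both strands with the log-likelihood ratio
#' `sum_i log2(pwm[i, w_i]/bg[w_i])` (in bits), converts scores to exact
#' p-values with the dynamic-programming null distribution of
#' [pwm_score_pvalue()], and reports windows with `p <= p_threshold`.
#' Windows containing non-ACGT characters are skipped. Per motif and
#' sequence, BH q-values are computed over all scored windows (both
#' strands). Overlapping hits of the same motif keep only the best-p hit.
#'
#' @param pwm A [pwm()] object.
#' @param seq A character scalar or [Biostrings::DNAString] over ACGTN.
#' @param background Base frequencies (A, C, G, T), strictly positive.
#' @param p_threshold Report hits with p-value at or below this (default 1e-4).
#' @param seq_id Sequence identifier recorded in the hits.
#' @param collapse_overlaps Keep only the best-p hit among overlapping hits
#'   of this motif (default TRUE).
#' @param grid Score discretization in bits.
#' @return Data frame: motif, seq, offset (0-based), strand, score_bits, p,
#'   q; sorted by p.
#' @export
scan_sequence <- function(pwm, seq,
                          background = c(A = 0.25, C = 0.25,
                                         G = 0.25, T = 0.25),
                          p_threshold = 1e-4, seq_id = "seq",
                          collapse_overlaps = TRUE, grid = 1e-3) {
  if (any(background <= 0)) .stopf("background frequencies must be > 0")
  seq <- toupper(as.character(seq))
  L <- nrow(pwm$matrix)
  empty <- data.frame(motif = character(), seq = character(),
                      offset = integer(), strand = character(),
                      score_bits = numeric(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE)
  if (nchar(seq) < L) return(empty)
  gs <- .pwm_grid_scores(pwm, background, grid)
  d <- .pwm_score_distribution(gs, background)
  pval_of <- function(g) {
    idx <- pmin(length(d$tail), pmax(1, g - d$support[1] + 1))
    ifelse(g <= d$support[1], 1,
           ifelse(g > d$support[length(d$support)], 0, d$tail[idx]))
  }
  chars <- strsplit(seq, "")[[1]]
  fwd <- .score_words(gs, chars)
  rc_chars <- strsplit(.revcomp(seq), "")[[1]]
  rev_ <- .score_words(gs, rc_chars)
  n_win <- nchar(seq) - L + 1L
  # minus-strand window starting at rc position j covers plus-strand offset
  # n_win - j (0-based)
  rows <- data.frame(
    offset = c(seq_len(n_win) - 1L, n_win - seq_len(n_win)),
    strand = rep(c("+", "-"), each = n_win),
    gscore = c(fwd$score, rev_$score),
    ok = c(fwd$ok, rev_$ok), stringsAsFactors = FALSE)
  rows <- rows[rows$ok, , drop = FALSE]
  if (!nrow(rows)) return(empty)
  rows$p <- pval_of(rows$gscore)
  rows$q <- adjust_pvalues(rows$p, "BH")
  hits <- rows[rows$p <= p_threshold, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  hits <- hits[order(hits$p, hits$offset, hits$strand), , drop = FALSE]
  if (collapse_overlaps && nrow(hits) > 1) {
    keep <- logical(nrow(hits))
    taken <- logical(n_win + L)      # occupied plus-strand positions
    for (i in seq_len(nrow(hits))) {
      span <- (hits$offset[i] + 1L):(hits$offset[i] + L)
      if (!any(taken[span])) {
        keep[i] <- TRUE
        taken[span] <- TRUE
      }
    }
    hits <- hits[keep, , drop = FALSE]
  }
  out <- data.frame(motif = pwm$id, seq = seq_id, offset = hits$offset,
                    strand = hits$strand, score_bits = hits$gscore * grid,
                    p = hits$p, q = hits$q, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Scan a promoter set with a motif collection
#'
#' @param motifs List of [pwm()] objects.
#' @param sequences Named character vector or [Biostrings::DNAStringSet];
#'   names are target gene ids.
#' @param ... Passed to [scan_sequence()].
#' @return Row-bound hits data frame across motifs and sequences.
#' @export
scan_promoters <- function(motifs, sequences, ...) {
  seq_chr <- as.character(sequences)
  if (is.null(names(seq_chr))) .stopf("sequences must be named by gene id")
  res <- list()
  for (m in motifs) {
    for (s in names(seq_chr)) {
      res[[length(res) + 1L]] <- scan_sequence(m, seq_chr[[s]],
                                               seq_id = s, ...)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Designate TF-to-target regulatory pairs
#'
#' Cross-references motif hits in photosynthesis-gene promoters with the
#' transcription factors found among the differentially expressed genes:
#' one pair per (TF gene, target gene) supported by at least one hit from a
#' motif assigned to that TF. The output carries both genes' fold changes
#' and FDRs and is sorted by TF fold change ascending.
#'
#' @param tf_degs Data frame of DE records restricted to TF-encoding genes:
#'   columns `gene`, `fc` (signed fold change) or `log2FC`, `fdr`, and
#'   optionally `family`, `description`.
#' @param hits Motif hits on promoters as from [scan_promoters()] (`seq` is
#'   the target gene id).
#' @param motif2tf Data frame with columns `motif` and `tf_gene`.
#' @param target_degs Data frame of DE records for the photosynthesis genes:
#'   columns `gene`, `fc` or `log2FC`, `fdr`, optionally `description`.
#' @return A data frame of class `RegulatoryPairs`: tf_gene, tf_fc, tf_fdr,
#'   tf_family, tf_description, target_gene, target_description, target_fc,
#'   target_fdr, n_hits.
#' @export
designate_pairs <- function(tf_degs, hits, motif2tf, target_degs) {
  fc_col <- function(df) {
    if ("fc" %in% names(df)) df$fc
    else if ("log2FC" %in% names(df)) sign(df$log2FC) * 2^abs(df$log2FC)
    else .stopf("DE records need an 'fc' or 'log2FC' column")
  }
  tf_tab <- data.frame(gene = tf_degs$gene, fc = fc_col(tf_degs),
                       fdr = tf_degs$fdr,
                       family = tf_degs$family %||% NA_character_,
                       description = tf_degs$description %||% NA_character_,
                       stringsAsFactors = FALSE)
  tg_tab <- data.frame(gene = target_degs$gene, fc = fc_col(target_degs),
                       fdr = target_degs$fdr,
                       description = target_degs$description %||% NA_character_,
                       stringsAsFactors = FALSE)
  unassigned <- setdiff(unique(hits$motif), motif2tf$motif)
  if (length(unassigned)) {
    warning(sprintf("ignoring hits of motif(s) without a TF assignment: %s",
                    paste(unassigned, collapse = ", ")), call. = FALSE)
    hits <- hits[hits$motif %in% motif2tf$motif, , drop = FALSE]
  }
  joined <- merge(hits, motif2tf, by = "motif")
  joined <- joined[joined$tf_gene %in% tf_tab$gene &
                   joined$seq %in% tg_tab$gene, , drop = FALSE]
  empty <- data.frame(tf_gene = character(), tf_fc = numeric(),
                      tf_fdr = numeric(), tf_family = character(),
                      tf_description = character(), target_gene = character(),
                      target_description = character(), target_fc = numeric(),
                      target_fdr = numeric(), n_hits = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(joined)) {
    class(empty) <- c("RegulatoryPairs", "data.frame")
    return(empty)
  }
  key <- paste(joined$tf_gene, joined$seq, sep = "\r")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
  out <- data.frame(tf_gene = parts[, 1], target_gene = parts[, 2],
                    n_hits = as.integer(agg$Freq), stringsAsFactors = FALSE)
  ti <- match(out$tf_gene, tf_tab$gene)
  gi <- match(out$target_gene, tg_tab$gene)
  out <- data.frame(
    tf_gene = out$tf_gene, tf_fc = tf_tab$fc[ti], tf_fdr = tf_tab$fdr[ti],
    tf_family = tf_tab$family[ti], tf_description = tf_tab$description[ti],
    target_gene = out$target_gene,
    target_description = tg_tab$description[gi],
    target_fc = tg_tab$fc[gi], target_fdr = tg_tab$fdr[gi],
    n_hits = out$n_hits, stringsAsFactors = FALSE)
  out <- out[order(out$tf_fc, out$tf_gene, out$target_gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("RegulatoryPairs", "data.frame")
  out
}

#' Summarize regulatory pairs
#'
#' Totals plus counts by TF family and by TF regulation direction (up when
#' the TF fold change is positive, down when negative). The family and
#' direction counts each sum to the total.
#'
#' @param pairs A `RegulatoryPairs` data frame (see [designate_pairs()] or
#'   [read_pairs_table()]).
#' @return A list with `total`, `by_family` (named integer vector) and
#'   `by_direction` (named integer vector `up`, `down`).
#' @export
summarize_pairs <- function(pairs) {
  if (!nrow(pairs)) {
    return(list(total = 0L, by_family = integer(0),
                by_direction = c(up = 0L, down = 0L)))
  }
  fam <- table(pairs$tf_family, useNA = "ifany")
  dir <- c(up = sum(pairs$tf_fc > 0), down = sum(pairs$tf_fc < 0))
  list(total = nrow(pairs),
       by_family = setNames(as.integer(fam), names(fam)),
       by_direction = dir)
}

#' Read a packaged regulatory-pair table
#'
#' Reads a TSV with the columns of [designate_pairs()] output (tf_gene,
#' tf_fc, tf_fdr, tf_family, tf_description, target_gene,
#' target_description, target_fc, target_fdr). The package ships one such
#' table of 17 TF-to-photosynthesis-gene pairs at
#' `system.file("extdata", "table1_regulatory_pairs.tsv",
#' package = "droughtlight")`.
#'
#' @param path TSV path; defaults to the packaged table.
#' @return A `RegulatoryPairs` data frame.
#' @export
read_pairs_table <- function(path = system.file("extdata",
                                                "table1_regulatory_pairs.tsv",
                                                package = "droughtlight")) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("tf_gene", "tf_fc", "tf_fdr", "tf_family", "tf_description",
            "target_gene", "target_description", "target_fc", "target_fdr")
  if (!all(need %in% names(out)))
    .stopf("%s: missing column(s) %s", path,
           paste(setdiff(need, names(out)), collapse = ", "))
  class(out) <- c("RegulatoryPairs", "data.frame")
  out
}

#' Percent of DEGs that encode transcription factors
#'
#' `round(100 * n_tf / (n_up + n_down))`, the headline share of
#' TF-encoding genes among all differentially expressed genes.
#'
#' @param n_tf Number of TF-encoding DEGs.
#' @param n_up,n_down Numbers of up- and down-regulated DEGs.
#' @return Integer percent.
#' @export
tf_deg_percent <- function(n_tf, n_up, n_down) {
  total <- n_up + n_down
  if (total <= 0) .stopf("total DEG count must be positive")
  if (n_tf < 0 || n_tf > total)
    .stopf("n_tf must lie in [0, n_up + n_down]")
  as.integer(round(100 * n_tf / total))
}
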