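#' Specification of a synthetic OJIP fluorescence transient
#'
#' Parametric description of a fast chlorophyll-a fluorescence rise used by
#' [simulate_ojip_transient()]. The noise-free model is a sum of three
#' saturating exponentials, one per kinetic phase of the rise (O-J, J-I, I-P),
#' scaled between the minimal fluorescence `f0` and the maximal fluorescence
#' `fm`, plus an optional Gaussian (in log-time) bump centred at 300 us that
#' emulates the K-band deviation seen when the oxygen-evolving complex is
#' impaired:
#'
#' \deqn{F(t) = F_0 + (F_M - F_0)\sum_k a_k (1 - e^{-t/\tau_k})
#'       + k_{band} (F_M - F_0) e^{-(\ln t - \ln 3\cdot10^{-4})^2 / 2\sigma_K^2}}
#'
#' @param f0 Minimal fluorescence, arbitrary units, > 0.
#' @param fm Maximal fluorescence, arbitrary units, > `f0`.
#' @param amp_oj,amp_ji,amp_ip Non-negative phase amplitudes; must sum to 1.
#' @param tau_oj,tau_ji,tau_ip Phase time constants in seconds, strictly
#'   increasing.
#' @param k_band_amp Amplitude of the K-band bump relative to `fm - f0`
#'   (>= 0; 0 disables it).
#' @param k_band_sigma Width of the K-band bump in ln-time units. The default
#'   0.35 keeps the bump local to roughly 0.15-0.6 ms.
#' @param noise_sd Relative standard deviation of multiplicative Gaussian
#'   noise (0 for a noise-free trace).
#' @param n_points Number of samples on the log-spaced time grid.
#' @param t_min,t_max Grid limits in seconds; must bracket all landmark times.
#' @param seed Integer seed for the trace's private RNG stream.
#' @param label Free-text trace identifier.
#'
#' @return An object of class `TransientSpec`.
#' @seealso [simulate_ojip_transient()], [stress_preset()]
#' @export
transient_spec <- function(f0 = 500, fm = 2500,
                           amp_oj = 0.5, amp_ji = 0.3, amp_ip = 0.2,
                           tau_oj = 4e-4, tau_ji = 8e-3, tau_ip = 8e-2,
                           k_band_amp = 0, k_band_sigma = 0.35,
                           noise_sd = 0, n_points = 120,
                           t_min = 1e-5, t_max = 1, seed = 1L,
                           label = "trace") {
  spec <- structure(
    list(f0 = f0, fm = fm,
         amp = c(oj = amp_oj, ji = amp_ji, ip = amp_ip),
         tau = c(oj = tau_oj, ji = tau_ji, ip = tau_ip),
         k_band_amp = k_band_amp, k_band_sigma = k_band_sigma,
         noise_sd = noise_sd, n_points = as.integer(n_points),
         t_min = t_min, t_max = t_max, seed = as.integer(seed),
         label = label),
    class = "TransientSpec")
  validate_transient_spec(spec)
  spec
}

validate_transient_spec <- function(spec) {
  if (spec$f0 <= 0) .stopf("f0 must be > 0, got %g", spec$f0)
  if (spec$fm <= spec$f0) .stopf("fm (%g) must exceed f0 (%g)", spec$fm, spec$f0)
  if (any(spec$amp < 0)) .stopf("phase amplitudes must be non-negative")
  if (abs(sum(spec$amp) - 1) > 1e-9)
    .stopf("phase amplitudes must sum to 1 (got %.6f)", sum(spec$amp))
  if (any(diff(spec$tau) <= 0))
    .stopf("time constants must be strictly increasing (tau_oj < tau_ji < tau_ip)")
  if (spec$k_band_amp < 0) .stopf("k_band_amp must be >= 0")
  if (spec$noise_sd < 0) .stopf("noise_sd must be >= 0")
  if (spec$n_points < max(8L, 5L)) .stopf("n_points too small")
  if (!(spec$t_min < .T_K && .T_K < spec$t_max))
    .stopf("grid [%g, %g] must bracket the K-band time %g s",
           spec$t_min, spec$t_max, .T_K)
  if (spec$t_min >= spec$t_max) .stopf("t_min must be < t_max")
  invisible(spec)
}

#' Apply a stress preset to a transient specification
#'
#' The `"prolonged_drought"` preset emulates the qualitative stress signature
#' of a prolonged water deficit: depressed maximal fluorescence (`fm` scaled
#' by 0.8), a weakened I-P phase (`amp_ip` scaled by 0.6, amplitudes
#' renormalized to sum to 1) and a positive K-band (`k_band_amp = 0.05`).
#' These are tuning constants chosen to reproduce the direction of the
#' observed changes, not measured values.
#'
#' @param spec A [transient_spec()].
#' @param preset Preset name; currently `"prolonged_drought"`.
#' @return A modified `TransientSpec`.
#' @export
stress_preset <- function(spec, preset = "prolonged_drought") {
  preset <- match.arg(preset, "prolonged_drought")
  spec$fm <- spec$fm * 0.8
  spec$amp["ip"] <- spec$amp["ip"] * 0.6
  spec$amp <- spec$amp / sum(spec$amp)
  spec$k_band_amp <- 0.05
  spec$label <- paste0(spec$label, "_", preset)
  validate_transient_spec(spec)
  spec
}

# Noise-free model evaluated at arbitrary times.
.ojip_model <- function(spec, t) {
  phases <- vapply(seq_along(spec$tau),
                   function(k) spec$amp[[k]] * (1 - exp(-t / spec$tau[[k]])),
                   numeric(length(t)))
  v <- if (is.matrix(phases)) rowSums(phases) else sum(phases)
  kb <- spec$k_band_amp *
    exp(-(log(t) - log(.T_K))^2 / (2 * spec$k_band_sigma^2))
  spec$f0 + (spec$fm - spec$f0) * (v + kb)
}

# Log-spaced grid of n points on [t_min, t_max] with the nearest grid points
# snapped to the exact landmark times, so landmark extraction on synthetic
# traces needs no interpolation.
.ojip_grid <- function(spec) {
  t <- exp(seq(log(spec$t_min), log(spec$t_max), length.out = spec$n_points))
  for (tk in c(.T_O, .T_K, .T_J, .T_I)) {
    if (tk > spec$t_min && tk < spec$t_max) {
      t[which.min(abs(log(t) - log(tk)))] <- tk
    }
  }
  sort(t)
}

#' Simulate an OJIP chlorophyll-a fluorescence transient
#'
#' Draws one fluorescence rise from the phenomenological model described in
#' [transient_spec()], sampled on a log-spaced grid containing the exact O/K/J/I
#' landmark times, with multiplicative Gaussian noise. The paired `truth`
#' element records the analytic (noise-free) landmark values and the implied
#' maximum quantum yield of primary photochemistry, for recovery tests.
#'
#' @param spec A [transient_spec()].
#' @return A list with elements `transient` (class `FluorescenceTransient`:
#'   `time`, `fluorescence`, `label`) and `truth` (class `SimTruth`).
#' @examples
#' sim <- simulate_ojip_transient(transient_spec(noise_sd = 0))
#' range(sim$transient$fluorescence)
#' @export
simulate_ojip_transient <- function(spec) {
  validate_transient_spec(spec)
  t <- .ojip_grid(spec)
  f_clean <- .ojip_model(spec, t)
  f <- if (spec$noise_sd > 0) {
    f_clean * (1 + .with_seed(spec$seed,
                              function() rnorm(length(t), 0, spec$noise_sd)))
  } else f_clean
  transient <- new_transient(t, f, label = spec$label)
  landmark_t <- c(F0 = .T_O, F300 = .T_K, FJ = .T_J, FI = .T_I)
  analytic <- .ojip_model(spec, landmark_t)
  names(analytic) <- names(landmark_t)
  fm_true <- max(f_clean)
  truth <- sim_truth(
    generator = "simulate_ojip_transient",
    params = c(as.list(analytic),
               list(FM = fm_true,
                    phiP0 = 1 - analytic[["F0"]] / fm_true,
                    f0 = spec$f0, fm = spec$fm,
                    k_band_amp = spec$k_band_amp)),
    seed = spec$seed)
  list(transient = transient, truth = truth)
}

#' Construct a fluorescence transient object
#'
#' @param time Strictly increasing times in seconds (>= 2 points).
#' @param fluorescence Positive finite fluorescence values, arbitrary units.
#' @param label Trace identifier.
#' @return An object of class `FluorescenceTransient`.
#' @export
new_transient <- function(time, fluorescence, label = "trace") {
  if (length(time) < 2 || length(time) != length(fluorescence))
    .stopf("time and fluorescence must be equal-length vectors of >= 2 points")
  if (any(diff(time) <= 0)) .stopf("times must be strictly increasing")
  if (any(!is.finite(fluorescence)) || any(fluorescence <= 0))
    .stopf("fluorescence values must be finite and positive")
  structure(list(time = as.numeric(time),
                 fluorescence = as.numeric(fluorescence),
                 label = label),
            class = "FluorescenceTransient")
}

#' @export
print.FluorescenceTransient <- function(x, ...) {
  cat(sprintf("FluorescenceTransient '%s': %d points, %.3g-%.3g s, F %.4g-%.4g a.u.\n",
              x$label, length(x$time), min(x$time), max(x$time),
              min(x$fluorescence), max(x$fluorescence)))
  invisible(x)
}

#' Ground-truth record attached to every simulator output
#'
#' @param generator Name of the generating function.
#' @param params Named list of true parameter values / labels.
#' @param seed Seed used by the generator.
#' @return An object of class `SimTruth`.
#' @export
sim_truth <- function(generator, params, seed) {
  structure(list(generator = generator, params = params,
                 seed = as.integer(seed)),
            class = "SimTruth")
}

# Run `fn` under a private RNG stream seeded with `seed`, restoring the
# caller's global RNG state afterwards. No hidden global state leaks out.
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Simulate a gene-by-sample count matrix with planted differential expression
#'
#' Negative-binomial counts with gamma-distributed baseline means. A fraction
#' `deg_fraction` of genes is planted as differentially expressed between the
#' first and second group with signed log2 fold change `+/-effect_log2fc`
#' (alternating up/down). Per-sample library-size factors scale all means.
#'
#' @param n_genes Number of genes.
#' @param groups Named integer vector of replicate counts per group, e.g.
#'   `c(control = 3, drought = 3)`. Exactly two groups; >= 2 replicates each.
#' @param deg_fraction Fraction of genes planted as DE, in `[0, 1]`.
#' @param effect_log2fc Magnitude of the planted log2 fold change (>= 0).
#' @param dispersion Negative-binomial dispersion alpha (variance
#'   `mu + alpha mu^2`); 0 gives Poisson counts.
#' @param lib_sizes Optional per-sample relative library sizes (recycled /
#'   named by sample); default all 1.
#' @param baseline_mean Mean of the gamma-distributed baseline expression.
#' @param seed Integer seed.
#' @return List with `matrix` (class `ExpressionMatrix`) and `truth`
#'   (class `SimTruth`; `params$deg` is a data frame of planted gene ids and
#'   signed log2 fold changes).
#' @export
simulate_expression_matrix <- function(n_genes = 2000,
                                       groups = c(control = 3, drought = 3),
                                       deg_fraction = 0.05,
                                       effect_log2fc = 2,
                                       dispersion = 0.05,
                                       lib_sizes = NULL,
                                       baseline_mean = 200,
                                       seed = 1L) {
  if (length(groups) != 2 || is.null(names(groups)))
    .stopf("groups must be a named vector of two replicate counts")
  if (any(groups < 2))
    .stopf("each group needs >= 2 replicates (dispersion unidentifiable otherwise)")
  if (deg_fraction < 0 || deg_fraction > 1)
    .stopf("deg_fraction must be in [0, 1]")
  if (dispersion < 0) .stopf("dispersion must be >= 0")
  n_samples <- sum(groups)
  if (is.null(lib_sizes)) lib_sizes <- rep(1, n_samples)
  if (length(lib_sizes) != n_samples)
    .stopf("lib_sizes must have one entry per sample (%d)", n_samples)

  out <- .with_seed(seed, function() {
    base_mu <- rgamma(n_genes, shape = 2, rate = 2 / baseline_mean)
    n_deg <- round(deg_fraction * n_genes)
    deg_idx <- if (n_deg > 0) sample.int(n_genes, n_deg) else integer(0)
    sgn <- rep(c(1, -1), length.out = n_deg)
    design <- rep(names(groups), times = groups)
    mu <- matrix(base_mu, n_genes, n_samples)
    if (n_deg > 0) {
      treated <- design == names(groups)[2]
      mu[deg_idx, treated] <- mu[deg_idx, treated] * 2^(sgn * effect_log2fc)
    }
    mu <- sweep(mu, 2, lib_sizes, `*`)
    counts <- if (dispersion > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             n_genes, n_samples)
    } else {
      matrix(stats::rpois(length(mu), lambda = mu), n_genes, n_samples)
    }
    list(counts = counts, design = design, deg_idx = deg_idx, sgn = sgn)
  })
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  sample_ids <- paste0(out$design, ".", stats::ave(seq_len(n_samples),
                                                   out$design, FUN = seq_along))
  dimnames(out$counts) <- list(gene_ids, sample_ids)
  em <- expression_matrix(out$counts, setNames(out$design, sample_ids),
                          mode = "rnaseq")
  truth <- sim_truth(
    generator = "simulate_expression_matrix",
    params = list(
      deg = data.frame(gene = gene_ids[out$deg_idx],
                       log2fc = out$sgn * effect_log2fc,
                       stringsAsFactors = FALSE),
      deg_fraction = deg_fraction, effect_log2fc = effect_log2fc,
      dispersion = dispersion),
    seed = seed)
  list(matrix = em, truth = truth)
}

#' Construct an expression matrix with its sample design
#'
#' @param values Numeric gene-by-sample matrix with row and column names.
#'   Non-negative counts in `rnaseq` mode, log2 intensities in `microarray`
#'   mode.
#' @param design Named character vector mapping each sample (column) to a
#'   group label.
#' @param mode `"rnaseq"` or `"microarray"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, design, mode = c("rnaseq", "microarray")) {
  mode <- match.arg(mode)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    .stopf("values must carry unique gene-id row names")
  if (is.null(colnames(values))) .stopf("values must carry sample-id column names")
  if (!all(colnames(values) %in% names(design)))
    .stopf("every sample must be assigned exactly one group in design")
  design <- design[colnames(values)]
  structure(list(values = values, design = design, mode = mode),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix (%s): %d genes x %d samples; groups: %s\n",
              x$mode, nrow(x$values), ncol(x$values),
              paste(sprintf("%s(%d)", names(table(x$design)), table(x$design)),
                    collapse = ", ")))
  invisible(x)
}

#' Simulate a promoter sequence set with planted motif sites
#'
#' Background sequences are drawn i.i.d. from `background`; planted sites are
#' drawn column-wise from the motif's probability matrix (so degenerate
#' columns yield the consensus deterministically) and written at the stated
#' offset, reverse-complemented on the minus strand.
#'
#' @param n_seqs Number of promoter sequences.
#' @param length Sequence length in bp.
#' @param background Base frequencies over A, C, G, T (summing to 1).
#' @param planted Optional data frame with columns `motif` (a [Pwm] object,
#'   stored in a list column or passed via `motifs` + id), `seq` (1-based
#'   sequence index), `offset` (0-based start) and `strand` (`"+"`/`"-"`).
#'   Use [planted_site()] to build rows.
#' @param seed Integer seed.
#' @return List with `sequences` (a [Biostrings::DNAStringSet]) and `truth`
#'   (class `SimTruth`; `params$planted` records motif id, sequence, offset,
#'   strand and the realized site).
#' @export
simulate_promoter_set <- function(n_seqs = 10, length = 1500,
                                  background = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25),
                                  planted = list(), seed = 1L) {
  if (abs(sum(background) - 1) > 1e-6 || any(background <= 0))
    .stopf("background must be strictly positive frequencies summing to 1")
  background <- background[.DNA_BASES]
  res <- .with_seed(seed, function() {
    seqs <- vapply(seq_len(n_seqs), function(i) {
      paste(sample(.DNA_BASES, length, replace = TRUE, prob = background),
            collapse = "")
    }, character(1))
    planted_log <- list()
    for (site in planted) {
      pwm <- site$motif
      L <- nrow(pwm$matrix)
      if (site$seq < 1 || site$seq > n_seqs)
        .stopf("planted site sequence index %d out of range", site$seq)
      if (site$offset < 0 || site$offset + L > length)
        .stopf("planted site at offset %d (length %d) falls outside the %d bp sequence",
               site$offset, L, length)
      draw <- vapply(seq_len(L), function(i) {
        sample(.DNA_BASES, 1, prob = pwm$matrix[i, ])
      }, character(1))
      word <- paste(draw, collapse = "")
      inserted <- if (site$strand == "-") .revcomp(word) else word
      s <- seqs[[site$seq]]
      substr(s, site$offset + 1, site$offset + L) <- inserted
      seqs[[site$seq]] <- s
      planted_log[[length(planted_log) + 1]] <-
        data.frame(motif = pwm$id, seq = site$seq, offset = site$offset,
                   strand = site$strand, site = word, stringsAsFactors = FALSE)
    }
    list(seqs = seqs, planted = planted_log)
  })
  names(res$seqs) <- sprintf("promoter%03d", seq_len(n_seqs))
  sequences <- Biostrings::DNAStringSet(res$seqs)
  truth <- sim_truth(
    generator = "simulate_promoter_set",
    params = list(planted = if (length(res$planted))
      do.call(rbind, res$planted) else
        data.frame(motif = character(), seq = integer(), offset = integer(),
                   strand = character(), site = character()),
      background = background),
    seed = seed)
  list(sequences = sequences, truth = truth)
}

#' Describe one motif site to plant in a synthetic promoter
#'
#' @param motif A [Pwm] object.
#' @param seq 1-based index of the target sequence.
#' @param offset 0-based start position of the site.
#' @param strand `"+"` or `"-"` (minus-strand sites are inserted as the
#'   reverse complement of the motif draw).
#' @return A list consumed by [simulate_promoter_set()].
#' @export
planted_site <- function(motif, seq, offset, strand = "+") {
  if (!strand %in% c("+", "-")) .stopf("strand must be '+' or '-'")
  list(motif = motif, seq = as.integer(seq), offset = as.integer(offset),
       strand = strand)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Inverse of the fold-change formula `FC = E^-(Ct_treated - Ct_control)`:
#' treated Ct values are placed at `Ct_control - log(FC)/log(E)` plus optional
#' cycle noise, so a noise-free round trip through [qpcr_fold_change()]
#' recovers `true_fc` exactly.
#'
#' @param genes Character vector of gene ids.
#' @param conditions Length-2 character vector, `c(control, treated)`.
#' @param true_fc Named numeric vector of true fold changes per gene (> 0).
#' @param efficiency Named (or recycled) per-gene amplification efficiency E
#'   in (1, 2].
#' @param ct_control Baseline control Ct in cycles (recycled per gene).
#' @param ct_noise_sd Gaussian noise SD on each Ct, in cycles.
#' @param seed Integer seed.
#' @return List with `ct_table` (data frame: gene, condition, mean_ct,
#'   efficiency) and `truth` (class `SimTruth`).
#' @export
simulate_qpcr_plate <- function(genes, conditions = c("control", "dehydrated"),
                                true_fc, efficiency = 2,
                                ct_control = 25, ct_noise_sd = 0, seed = 1L) {
  if (length(conditions) != 2) .stopf("conditions must be c(control, treated)")
  true_fc <- rep_len(true_fc, length(genes))
  efficiency <- rep_len(efficiency, length(genes))
  ct_control <- rep_len(ct_control, length(genes))
  if (any(true_fc <= 0)) .stopf("fold changes must be > 0")
  if (any(efficiency <= 1 | efficiency > 2))
    .stopf("amplification efficiency must lie in (1, 2]")
  noise <- if (ct_noise_sd > 0) {
    .with_seed(seed, function() rnorm(2 * length(genes), 0, ct_noise_sd))
  } else rep(0, 2 * length(genes))
  ct_treated <- ct_control - log(true_fc) / log(efficiency)
  ct_table <- data.frame(
    gene = rep(genes, 2),
    condition = rep(conditions, each = length(genes)),
    mean_ct = c(ct_control + noise[seq_along(genes)],
                ct_treated + noise[length(genes) + seq_along(genes)]),
    efficiency = rep(efficiency, 2),
    stringsAsFactors = FALSE)
  if (any(ct_table$mean_ct <= 0))
    .stopf("simulated Ct values must be positive; raise ct_control")
  truth <- sim_truth("simulate_qpcr_plate",
                     params = list(true_fc = setNames(true_fc, genes),
                                   efficiency = setNames(efficiency, genes)),
                     seed = seed)
  list(ct_table = ct_table, truth = truth)
}
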