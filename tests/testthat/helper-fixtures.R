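# Shared builders and independent oracles used across test files.

# Worked landmark set used throughout: F(50us)=500, F(300us)=900,
# F(2ms)=1500, F(30ms)=2100, FM=2500 -> VJ=0.5, VI=0.8, M0=0.8.
worked_landmarks <- function() {
  jip_landmarks(F0 = 500, F300 = 900, FJ = 1500, FI = 2100, FM = 2500)
}

# Random valid landmark sets: F0 < F300 < FJ < FI < FM with margins that
# keep VJ, VI strictly inside (0, 1) and M0 > 0.
random_landmarks <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    f0 <- runif(1, 100, 1000)
    fm <- f0 * runif(1, 2, 6)
    mids <- sort(runif(3, f0 + 1e-3 * (fm - f0), fm - 1e-3 * (fm - f0)))
    jip_landmarks(f0, mids[1], mids[2], mids[3], fm)
  })
}

# Exact upper hypergeometric tail by direct combinatorial enumeration,
# independent of stats::phyper.
hyper_tail_oracle <- function(N, K, n, k) {
  js <- k:min(K, n)
  js <- js[n - js <= N - K]
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Exhaustive PWM null distribution: enumerate all 4^L words, score each by
# summing per-position log-likelihood ratios rounded to the 1/1000-bit grid
# (recomputed here, independent of the package's scorer), and return the
# grid score of every word. Uniform background unless given.
enumerate_word_scores <- function(prob_matrix, background = rep(0.25, 4),
                                  grid = 1e-3) {
  L <- nrow(prob_matrix)
  bits <- log2(sweep(prob_matrix, 2, background, `/`))
  gs <- round(bits / grid)
  idx <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- integer(nrow(idx))
  for (pos in seq_len(L)) scores <- scores + gs[pos, idx[, pos]]
  # word probability under the background
  wp <- exp(rowSums(matrix(log(background)[idx], ncol = L)))
  list(scores = scores, probs = wp)
}

# P(grid score >= s) from the enumeration above.
enum_tail <- function(enum, s) sum(enum$probs[enum$scores >= s])

# Studentized-range CDF by direct double quadrature (chi times normal
# range), independent of stats::ptukey. Balanced one-way layout.
ptukey_oracle <- function(q, k, df) {
  inner <- function(s) {
    vapply(s, function(si) {
      f <- function(z) k * dnorm(z) * (pnorm(z) - pnorm(z - q * si))^(k - 1)
      integrate(f, -8, 8, rel.tol = 1e-9)$value
    }, numeric(1))
  }
  dchi_scaled <- function(s) {
    # density of sqrt(chisq_df / df)
    exp((df / 2) * log(df) - lgamma(df / 2) - (df / 2 - 1) * log(2) +
          (df - 1) * log(s) - df * s^2 / 2)
  }
  integrate(function(s) dchi_scaled(s) * inner(s), 0, 8,
            rel.tol = 1e-8)$value
}

# Rand index between two partitions (vectors of labels).
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, `==`)
  same_b <- outer(b, b, `==`)
  agree <- (same_a == same_b)
  (sum(agree[upper.tri(agree)])) / choose(n, 2)
}

# A degenerate (consensus) probability matrix from a DNA string.
consensus_matrix <- function(word) {
  chars <- strsplit(word, "")[[1]]
  m <- matrix(0, length(chars), 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(chars), match(chars, c("A", "C", "G", "T")))] <- 1
  m
}

packaged_motifs <- function() {
  read_meme_motifs(system.file("extdata", "motifs.meme",
                               package = "droughtlight"))
}
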