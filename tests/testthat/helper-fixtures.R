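# Fixture builders shared across test files. All fixtures are generated in
# code under fixed seeds.

FWHM_FACTOR <- 2 * sqrt(2 * log(2))

# nucleus table carrying one DV stripe of given full width at half maximum
fixture_stripe_nuclei <- function(width, seed, center = 0.5, noise_sd = 5,
                                  spacing = 0.02, amplitude = 100,
                                  baseline = 2) {
  spec <- pattern_spec(dv_band(center, width / FWHM_FACTOR, amplitude),
                       baseline = baseline)
  simulate_nucleus_table(spec, spacing = spacing, noise_sd = noise_sd,
                         seed = seed)
}

# rigid rotation of normalized nucleus coordinates about (0.5, 0.5),
# clipped back to the unit square
rotate_nuclei <- function(nuc, degrees) {
  th <- degrees * pi / 180
  ap <- 0.5 + cos(th) * (nuc$ap - 0.5) - sin(th) * (nuc$dv - 0.5)
  dv <- 0.5 + sin(th) * (nuc$ap - 0.5) + cos(th) * (nuc$dv - 0.5)
  out <- nuc
  out$ap <- ap; out$dv <- dv
  out[ap >= 0 & ap <= 1 & dv >= 0 & dv <= 1, ]
}

# random PWM with one dominant base per column (well-separated consensus)
fixture_peaked_pwm <- function(L, seed, dominance = 60,
                               background = rep(0.25, 4)) {
  withr::with_seed(seed, {
    cm <- matrix(1, 4, L)
    for (i in seq_len(L)) cm[sample(1:4, 1), i] <- dominance
    load_pwm(cm, pseudocount = 0.01, background = background,
             name = sprintf("peaked%d_%d", L, seed))
  })
}

pwm_consensus <- function(pwm) {
  paste(rownames(pwm$prob)[apply(pwm$prob, 2, which.max)], collapse = "")
}

# exhaustive enumeration oracle: lattice-score tail probabilities for all
# 4^L words, computed independently of the DP
enumerate_tail <- function(pwm, K) {
  L <- ncol(K)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  kw <- rowSums(matrix(K[cbind(as.vector(words),
                               rep(seq_len(L), each = nrow(words)))],
                       nrow(words), L))
  pw <- apply(matrix(pwm$background[words], nrow(words), L), 1, prod)
  list(k = kw, prob = pw,
       tail_at = function(k) vapply(k, function(kk) sum(pw[kw >= kk]),
                                    numeric(1)))
}

# independent window-scoring oracle (naive loop, real scores)
naive_window_scores <- function(s, pwm) {
  S <- log2(pwm$prob / pwm$background)
  chars <- strsplit(s, "")[[1]]
  L <- ncol(S)
  n <- length(chars)
  if (n < L) return(numeric(0))
  vapply(seq_len(n - L + 1L), function(i) {
    sum(vapply(seq_len(L), function(j) S[chars[i + j - 1L], j], numeric(1)))
  }, numeric(1))
}

# one Dirichlet(1,1,1,1)-ish draw for random backgrounds (bounded away
# from zero)
rdirichlet_one <- function() {
  x <- rgamma(4, 1) + 0.05
  x / sum(x)
}

# variant-library records with prescribed mutation counts (for summary
# arithmetic tests)
fixture_library_with_counts <- function(counts) {
  lapply(seq_along(counts), function(i) {
    k <- counts[i]
    list(line_id = sprintf("line_%03d", i),
         sequence = strrep("A", 10),
         mutations = data.frame(position = seq_len(k) - 1L,
                                ref_base = rep("A", k),
                                alt_base = rep("C", k))[seq_len(k), ,
                                                        drop = FALSE])
  })
}
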