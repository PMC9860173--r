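# PWM handling, information content, exact p-values, scanning, hit stats.

test_that("PWM construction applies pseudocounts and validates input", {
  p <- load_pwm(matrix(c(4, 0, 0, 0), 4, 1), pseudocount = 0.01)
  expect_equal(unname(p$prob[, 1]), c(4.01, 0.01, 0.01, 0.01) / 4.04)
  expect_equal(colSums(p$prob), 1, tolerance = 1e-12)

  probs <- matrix(c(0.7, 0.1, 0.1, 0.1, 0.25, 0.25, 0.25, 0.25), 4, 2)
  p2 <- load_pwm(probs, pseudocount = 0)
  expect_equal(unname(p2$prob), probs)

  # L x 4 orientation is auto-detected
  p3 <- load_pwm(t(probs), pseudocount = 0)
  expect_equal(p3$L, 2)
  expect_equal(unname(p3$prob), probs)

  expect_error(load_pwm(matrix(0, 4, 2), pseudocount = 0),
               class = "ee_input_error")
  expect_error(load_pwm(matrix(-1, 4, 2)), class = "ee_input_error")
  expect_error(load_pwm(probs, background = c(0, 0.5, 0.25, 0.25)),
               class = "ee_input_error")
})

test_that("information content follows the Kullback-Leibler identities", {
  bg_equal <- load_pwm(matrix(0.25, 4, 5), pseudocount = 0)
  expect_equal(information_content(bg_equal), 0)
  expect_equal(expected_hit_frequency(bg_equal), 1)

  onehot <- load_pwm(matrix(c(1e9, 0, 0, 0), 4, 6), pseudocount = 1e-9)
  expect_equal(information_content(onehot), 12, tolerance = 1e-5)

  halfhalf <- load_pwm(matrix(c(0.5 - 1e-12, 0.5 - 1e-12, 1e-12, 1e-12),
                              4, 2), pseudocount = 0)
  expect_equal(information_content(halfhalf), 2, tolerance = 1e-6)
  expect_equal(expected_hit_frequency(halfhalf), 0.25, tolerance = 1e-6)

  # additivity over columns and strict monotonicity of 2^-I
  p1 <- fixture_peaked_pwm(3, seed = 1)
  p2 <- fixture_peaked_pwm(4, seed = 2)
  p12 <- load_pwm(cbind(p1$prob, p2$prob), pseudocount = 0)
  expect_equal(information_content(p12),
               information_content(p1) + information_content(p2),
               tolerance = 1e-9)
  expect_gt(information_content(p12), information_content(p1))
  expect_lt(expected_hit_frequency(p12), expected_hit_frequency(p1))
})

test_that("the IC ECDF is a step function ending at 1", {
  pwms <- lapply(1:3, function(i) fixture_peaked_pwm(3 + i, seed = i))
  ec <- ic_ecdf(pwms)
  expect_equal(ec$cdf, c(1, 2, 3) / 3)
  expect_true(all(diff(ec$expected_frequency) <= 0 |
                  diff(ec$cdf) > 0))
  # duplicated PWM: vertical step of height 2/N at its frequency
  ec2 <- ic_ecdf(c(pwms, pwms[1]))
  dup_freq <- expected_hit_frequency(pwms[[1]])
  expect_equal(sum(abs(ec2$expected_frequency - dup_freq) < 1e-12), 2)
  expect_equal(max(ec2$cdf), 1)
  expect_error(ic_ecdf(list()), class = "ee_input_error")
})

test_that("DP p-values agree with exhaustive enumeration up to L = 8", {
  withr::with_seed(33, {
    for (L in c(3, 5, 8)) {
      cm <- matrix(rgamma(4 * L, 1.5), 4, L)
      bg <- as.numeric(rdirichlet_one())
      pwm <- load_pwm(cm, pseudocount = 0.01, background = bg)
      pv <- score_pvalue_table(pwm, granularity = 1000)
      oracle <- enumerate_tail(pwm, pv$K)
      ks <- sort(unique(oracle$k))
      expect_equal(embryoexpress:::lookup_pvalue(pv, ks),
                   oracle$tail_at(ks), tolerance = 1e-12)
    }
  })
  # boundary p-values
  pwm <- fixture_peaked_pwm(6, seed = 5, background = c(0.3, 0.2, 0.2, 0.3))
  pv <- score_pvalue_table(pwm)
  expect_equal(max(pv$table$p), 1)
  cons <- pwm_consensus(pwm)
  bgp <- prod(pwm$background[strsplit(cons, "")[[1]]])
  expect_equal(min(pv$table$p), bgp, tolerance = 1e-12)
  expect_error(score_pvalue_table(pwm, granularity = 50),
               class = "ee_input_error")
})

test_that("scanning reports planted sites with strand symmetry", {
  pwm <- fixture_peaked_pwm(8, seed = 6)
  cons <- pwm_consensus(pwm)
  withr::with_seed(7, {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
  })
  s <- paste0(substr(s, 1, 10), cons, substr(s, 19, 60))
  hits <- scan_sequences(c(sq = s), pwm, p_threshold = 0.001)
  plus <- hits[hits$strand == "+", ]
  expect_true(any(plus$start == 10 & plus$end == 18))

  # reverse complement mirrors intervals and swaps strands, same count
  rc <- embryoexpress:::revcomp(s)
  h2 <- scan_sequences(c(sq = rc), pwm, p_threshold = 0.001)
  expect_equal(nrow(h2), nrow(hits))
  n <- nchar(s)
  mirrored <- data.frame(start = n - h2$end, end = n - h2$start,
                         strand = ifelse(h2$strand == "+", "-", "+"))
  key <- function(d) sort(paste(d$start, d$end, d$strand))
  expect_equal(key(mirrored), key(hits[, c("start", "end", "strand")]))

  # scores and p-values match the naive per-window oracle
  sc <- naive_window_scores(s, pwm)
  for (i in which(hits$strand == "+")) {
    expect_equal(hits$score[i], sc[hits$start[i] + 1], tolerance = 1e-9)
  }

  # too-short sequences yield no hits; ambiguity letters void windows
  expect_equal(nrow(scan_sequences(c(a = "ACGTAC"), pwm)), 0)
  sN <- paste0(substr(s, 1, 12), "N", substr(s, 14, n))
  hN <- scan_sequences(c(sq = sN), pwm, p_threshold = 0.001)
  expect_false(any(hN$start <= 12 & hN$end > 12 & hN$strand == "+"))
})

test_that("hit rate on background sequence matches the p-value threshold", {
  withr::with_seed(9, {
    cm <- matrix(rgamma(40, 2), 4, 10)
    pwm <- load_pwm(cm, pseudocount = 0.01, name = "cal")
    bgseq <- paste(sample(c("A", "C", "G", "T"), 2e5, replace = TRUE),
                   collapse = "")
  })
  pv <- score_pvalue_table(pwm)
  achieved <- max(pv$tail[pv$tail <= 0.001])   # exact size at the cut
  hits <- scan_sequences(c(bg = bgseq), pwm, p_threshold = 0.001,
                         strands = "+")
  nw <- 2e5 - 10 + 1
  se <- sqrt(achieved * (1 - achieved) / nw)
  expect_lt(abs(nrow(hits) / nw - achieved), 3 * se)
  expect_lt(abs(achieved - 0.001) / 0.001, 0.1)
})

test_that("hit statistics aggregate counts, densities, and the top fraction", {
  seqs <- c(s1 = strrep("A", 100), s2 = strrep("C", 50))
  hits <- structure(data.frame(
    seq_id = c("s1", "s1", "s1", "s2"),
    start = c(0, 5, 9, 0), end = c(3, 8, 12, 3),
    strand = "+", score = c(3, 1, 2, 5), p = 0.001, motif = "m1"),
    class = c("motif_hits", "data.frame"))
  hs <- hit_statistics(hits, seqs, motif_sets = list(only = "m1"),
                       top_fraction = 0.30)
  ps <- hs$per_sequence
  expect_equal(ps$n_hits[ps$seq_id == "s1"], 3)
  expect_equal(ps$n_hits[ps$seq_id == "s2"], 1)
  expect_equal(ps$hits_per_bp[ps$seq_id == "s2"], 1 / 50)
  expect_equal(unname(hs$set_averages["only"]), 2.0)
  # ceiling(0.3 * 4) = 2 best-scoring hits retained
  expect_equal(nrow(hs$top_hits), 2)
  expect_equal(sort(hs$top_hits$score), c(3, 5))
  bad <- hits; bad$seq_id[1] <- "nope"
  expect_error(hit_statistics(bad, seqs), class = "ee_input_error")
})

test_that("MEME and TSV readers reproduce the stored matrices", {
  pwms <- read_meme(system.file("extdata", "example_motifs.meme",
                                package = "embryoexpress"))
  expect_gte(length(pwms), 3)
  expect_true(all(vapply(pwms, function(p)
    all(abs(colSums(p$prob) - 1) < 1e-6), logical(1))))
  expect_equal(unname(pwms[[1]]$background),
               c(0.29, 0.21, 0.21, 0.29))

  tsv <- read_pwm_tsv(system.file("extdata", "gata_counts.tsv",
                                  package = "embryoexpress"))
  expect_equal(tsv$L, 6)
  expect_equal(colSums(tsv$prob), rep(1, 6), tolerance = 1e-12)

  # scanning a planted GATA site with the fixture motif finds it
  gata <- pwms[["gata_like"]]
  s <- generate_random_sequences(1, 60, motif = "GATAAG",
                                 offset_policy = 30, seed = 2)
  hits <- scan_sequences(s, gata, p_threshold = 0.001)
  expect_true(any(hits$start == 30 & hits$strand == "+"))
})
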