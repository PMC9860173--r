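# PWM handling, Kullback-Leibler information content, expected chance-hit
# frequency, log-odds scanning with exact dynamic-programming p-values,
# and library-level hit statistics.

#' Build a PWM from counts or probabilities
#'
#' Count matrices are converted to column-stochastic probabilities with an
#' additive pseudocount per cell: `p = (c + pc) / (colsum + 4 pc)`.
#' Probability matrices (columns already summing to 1) pass through the
#' same formula; with `pseudocount = 0` they are returned unchanged.
#'
#' @param x numeric matrix, 4 x L (rows A, C, G, T) or L x 4; non-negative.
#' @param pseudocount additive pseudocount per cell (counts).
#' @param background nucleotide background frequencies (length 4, A/C/G/T,
#'   positive; normalized to sum to 1).
#' @param name motif name.
#' @return Object of class `pwm`: list with `name`, `L`, `prob` (4 x L,
#'   rownames ACGT), `background` (named), `pseudocount`.
#' @export
load_pwm <- function(x, pseudocount = 0.01,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                     name = "motif") {
  x <- as.matrix(x)
  if (nrow(x) != 4L && ncol(x) == 4L) x <- t(x)
  if (nrow(x) != 4L) ee_input_error("PWM must have 4 rows (A, C, G, T)")
  if (any(x < 0) || anyNA(x)) ee_input_error("PWM entries must be non-negative")
  if (pseudocount < 0) ee_input_error("`pseudocount` must be >= 0")
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0)) {
    ee_input_error("background must be 4 positive frequencies")
  }
  background <- background / sum(background)
  cs <- colSums(x)
  if (any(cs + 4 * pseudocount <= 0)) {
    ee_input_error("zero-sum PWM column with zero pseudocount")
  }
  prob <- sweep(x + pseudocount, 2, cs + 4 * pseudocount, "/")
  if (any(prob <= 0)) {
    ee_input_error("zero probability cell; use a positive pseudocount")
  }
  dimnames(prob) <- list(DNA_BASES, NULL)
  structure(list(name = name, L = ncol(prob), prob = prob,
                 background = stats::setNames(background, DNA_BASES),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': %d columns, IC %.2f bits\n", x$name, x$L,
              information_content(x)))
  invisible(x)
}

#' Motif information content (Kullback-Leibler divergence from background)
#'
#' `I = sum_i sum_n p[i,n] log2(p[i,n] / b[n])`, in bits; non-negative,
#' additive over columns, and zero iff every column equals the background.
#'
#' @param pwm a [load_pwm()] object.
#' @return Information content in bits.
#' @export
information_content <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  sum(pwm$prob * log2(pwm$prob / pwm$background))
}

#' Expected chance-hit frequency of a motif
#'
#' `2^(-I)` approximates the per-position probability of a chance motif
#' hit in background sequence; it decreases as the motif becomes more
#' informative.
#'
#' @param pwm a [load_pwm()] object.
#' @return Probability `2^(-information_content(pwm))`.
#' @export
expected_hit_frequency <- function(pwm) {
  2^(-information_content(pwm))
}

#' Empirical CDF of expected motif hit frequencies
#'
#' For a collection of PWMs, sorts their expected chance-hit frequencies
#' (`2^-I`) and returns the step-function points: the k-th sorted
#' frequency has height k/N.
#'
#' @param pwms list of `pwm` objects (>= 1).
#' @return data.frame of class `ic_ecdf` with columns `name`,
#'   `information_content`, `expected_frequency`, `cdf` (sorted by
#'   frequency, ending at 1).
#' @export
ic_ecdf <- function(pwms) {
  if (length(pwms) == 0L) ee_input_error("empty PWM list")
  ic <- vapply(pwms, information_content, numeric(1))
  freq <- 2^(-ic)
  ord <- order(freq)
  structure(data.frame(
    name = vapply(pwms, `[[`, character(1), "name")[ord],
    information_content = ic[ord],
    expected_frequency = freq[ord],
    cdf = seq_along(freq) / length(freq)),
    class = c("ic_ecdf", "data.frame"))
}

# Discretized per-column integer scores shared by the p-value DP and the
# scanner: S = log2(p/b), K = round(S / delta).
pwm_int_scores <- function(pwm, granularity) {
  S <- log2(pwm$prob / pwm$background)
  smin <- sum(apply(S, 2, min))
  smax <- sum(apply(S, 2, max))
  delta <- (smax - smin) / granularity
  if (delta <= 0) delta <- 1   # degenerate: all scores equal
  K <- matrix(int_round(S / delta), 4, pwm$L, dimnames = dimnames(S))
  list(S = S, K = K, delta = delta)
}

#' Exact score-to-p-value table for a PWM
#'
#' Computes the exact tail distribution of the log2-odds score of a random
#' background-distributed word: per-column scores are discretized to a
#' lattice of `granularity` bins over the attainable score range, and the
#' lattice distributions are convolved column by column (the standard
#' dynamic program used by exact motif scanners). The p-value of a score
#' is the background probability of an equal-or-better score; the minimum
#' attainable score has p = 1.
#'
#' @param pwm a [load_pwm()] object.
#' @param granularity number of discretization bins (>= 100).
#' @return Object of class `pwm_pvalues`: list with `delta` (bin width in
#'   bits), `k_offset`, `tail` (P(score >= k) indexed by lattice score),
#'   `table` (data.frame `score`, `p`), `K` (per-column integer scores),
#'   `S` (real log-odds), `background`.
#' @export
score_pvalue_table <- function(pwm, granularity = 1000L) {
  stopifnot(inherits(pwm, "pwm"))
  granularity <- as.integer(granularity)
  if (granularity < 100L) ee_input_error("`granularity` must be >= 100")
  iz <- pwm_int_scores(pwm, granularity)
  K <- iz$K
  kmin_cols <- apply(K, 2, min)
  kmax_cols <- apply(K, 2, max)
  kmin <- sum(kmin_cols); kmax <- sum(kmax_cols)
  width <- kmax - kmin + 1L
  pmf <- numeric(width)   # index = k - kmin + 1
  pmf[1] <- 1
  off <- 0L               # accumulated minimum so far
  bg <- pwm$background
  cur_width <- 1L
  for (i in seq_len(pwm$L)) {
    new_width <- cur_width + (kmax_cols[i] - kmin_cols[i])
    nxt <- numeric(width)
    for (n in 1:4) {
      sh <- K[n, i] - kmin_cols[i]
      nxt[(1 + sh):(cur_width + sh)] <-
        nxt[(1 + sh):(cur_width + sh)] + bg[n] * pmf[1:cur_width]
    }
    pmf <- nxt
    cur_width <- new_width
    off <- off + kmin_cols[i]
  }
  tail_p <- rev(cumsum(rev(pmf)))
  tail_p <- pmin(tail_p, 1)
  ks <- seq.int(kmin, kmax)
  structure(list(delta = iz$delta, k_offset = kmin, tail = tail_p,
                 table = data.frame(score = ks * iz$delta, p = tail_p),
                 K = K, S = iz$S, background = bg),
            class = "pwm_pvalues")
}

# p-value lookup for lattice scores (vectorized); scores outside the
# attainable range clamp to the nearest end.
lookup_pvalue <- function(pv, k) {
  idx <- pmin(pmax(k - pv$k_offset + 1L, 1L), length(pv$tail))
  pv$tail[idx]
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

# integer-encode a sequence: A=1 C=2 G=3 T=4, NA for ambiguity codes
encode_seq <- function(s) {
  match(strsplit(toupper(s), "")[[1]], DNA_BASES)
}

# score all windows of an encoded sequence with per-column score matrix
# (4 x L); windows containing NA letters give NA.
score_windows <- function(enc, M) {
  L <- ncol(M)
  n <- length(enc)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  sc <- numeric(nw)
  nas <- logical(nw)
  for (i in seq_len(L)) {
    lx <- enc[i:(i + nw - 1L)]
    bad <- is.na(lx)
    nas <- nas | bad
    lx[bad] <- 1L
    sc <- sc + M[cbind(lx, i)]
  }
  sc[nas] <- NA
  sc
}

#' Scan sequences with a PWM at an exact p-value threshold
#'
#' Scores every window of length L on the requested strands with the
#' log2-odds score and reports windows whose exact background p-value is
#' at or below the threshold. Coordinates are 0-based half-open on the
#' forward strand regardless of the hit's strand. Windows containing
#' ambiguity letters are skipped; sequences shorter than the motif yield
#' no hits.
#'
#' @param seqs a `sequence_set`, named character vector, or
#'   `DNAStringSet`.
#' @param pwm a [load_pwm()] object.
#' @param p_threshold report hits with `p <= p_threshold`.
#' @param strands `"both"`, `"+"`, or `"-"`.
#' @param granularity p-value lattice bins (see [score_pvalue_table()]).
#' @param pvalues optional precomputed `pwm_pvalues` for this PWM.
#' @return data.frame of class `motif_hits` with columns `seq_id`,
#'   `start`, `end`, `strand`, `score` (log2-odds bits), `p`, `motif`.
#' @export
scan_sequences <- function(seqs, pwm, p_threshold = 0.001,
                           strands = c("both", "+", "-"),
                           granularity = 1000L, pvalues = NULL) {
  strands <- match.arg(strands)
  sv <- as_sequence_vector(seqs)
  pv <- pvalues %||% score_pvalue_table(pwm, granularity)
  do_strand <- c("+", "-")[c(strands %in% c("both", "+"),
                             strands %in% c("both", "-"))]
  out <- list()
  for (sid in names(sv)) {
    s <- sv[[sid]]
    n <- nchar(s)
    for (st in do_strand) {
      enc <- encode_seq(if (st == "+") s else revcomp(s))
      ki <- score_windows(enc, pv$K)
      if (length(ki) == 0L) next
      valid <- which(!is.na(ki))
      if (length(valid) == 0L) next
      pvals <- lookup_pvalue(pv, as.integer(ki[valid]))
      hit <- valid[pvals <= p_threshold]
      if (length(hit) == 0L) next
      sc <- score_windows(enc, pv$S)[hit]
      start0 <- hit - 1L
      if (st == "-") start0 <- n - (start0 + pwm$L)   # mirror to + strand
      out[[length(out) + 1L]] <- data.frame(
        seq_id = sid, start = start0, end = start0 + pwm$L,
        strand = st, score = sc, p = lookup_pvalue(pv, as.integer(ki[hit])),
        motif = pwm$name, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(seq_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), score = numeric(0), p = numeric(0),
               motif = character(0), stringsAsFactors = FALSE)
  res <- res[order(res$seq_id, res$start, res$strand), ]
  rownames(res) <- NULL
  structure(res, class = c("motif_hits", "data.frame"))
}

#' Library-level motif hit statistics
#'
#' Per-sequence hit counts (zeros included), counts normalized per
#' sequence length (hits/bp), per-motif-set averages (mean over member
#' motifs of the mean per-sequence hit count), and a top-fraction filter
#' keeping the `ceiling(top_fraction * n)` best-scoring hits per motif
#' across all sequences.
#'
#' @param hits a `motif_hits` table (possibly concatenating several PWMs).
#' @param seqs the scanned sequences (for lengths and ids).
#' @param motif_sets optional named list mapping set name -> character
#'   vector of motif names.
#' @param top_fraction fraction of best-scoring hits retained per motif.
#' @return Object of class `hit_stats`: list with `per_sequence`
#'   (data.frame `seq_id`, `motif`, `n_hits`, `length`, `hits_per_bp`),
#'   `set_averages` (named numeric), `top_hits` (filtered `motif_hits`),
#'   `top_fraction`.
#' @export
hit_statistics <- function(hits, seqs, motif_sets = NULL,
                           top_fraction = 0.30) {
  sv <- as_sequence_vector(seqs)
  if (nrow(hits) && !all(hits$seq_id %in% names(sv))) {
    ee_input_error("hits reference unknown sequence ids")
  }
  motifs <- unique(if (nrow(hits)) hits$motif else character(0))
  if (length(motifs) == 0L) motifs <- NA_character_
  grid <- expand.grid(seq_id = names(sv), motif = motifs,
                      stringsAsFactors = FALSE)
  grid$n_hits <- mapply(function(sid, mo) {
    if (is.na(mo)) 0L else sum(hits$seq_id == sid & hits$motif == mo)
  }, grid$seq_id, grid$motif)
  grid$length <- nchar(sv[grid$seq_id])
  grid$hits_per_bp <- grid$n_hits / grid$length
  set_avg <- NULL
  if (!is.null(motif_sets)) {
    set_avg <- vapply(motif_sets, function(members) {
      per_motif <- vapply(members, function(mo) {
        mean(grid$n_hits[grid$motif == mo])
      }, numeric(1))
      mean(per_motif)
    }, numeric(1))
  }
  top <- hits[0, ]
  if (nrow(hits)) {
    parts <- split(seq_len(nrow(hits)), hits$motif)
    keep <- unlist(lapply(parts, function(ix) {
      k <- ceiling(top_fraction * length(ix))
      ix[order(hits$score[ix], decreasing = TRUE)[seq_len(k)]]
    }), use.names = FALSE)
    top <- hits[sort(keep), ]
  }
  structure(list(per_sequence = grid, set_averages = set_avg,
                 top_hits = top, top_fraction = top_fraction),
            class = "hit_stats")
}

# ---- PWM I/O ---------------------------------------------------------------

#' Read PWMs from MEME minimal format
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections and an
#' optional `Background letter frequencies` line.
#'
#' @param path MEME minimal-format file.
#' @param pseudocount passed to [load_pwm()] (applied to the probability
#'   columns; 0 keeps them verbatim).
#' @return Named list of `pwm` objects.
#' @export
read_meme <- function(path, pseudocount = 0) {
  if (!file.exists(path)) ee_io_error(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    if (length(toks) >= 8L) {
      vals <- as.numeric(toks[seq(2, 8, by = 2)])
      names(vals) <- toks[seq(1, 7, by = 2)]
      bg <- vals[DNA_BASES]
    }
  }
  motif_at <- grep("^MOTIF\\b", lines)
  out <- list()
  for (ma in motif_at) {
    name <- strsplit(trimws(lines[ma]), "\\s+")[[1]][2]
    hdr <- ma + grep("letter-probability matrix",
                     lines[(ma + 1):length(lines)])[1]
    w <- sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr])
    w <- as.integer(w)
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]), numeric(4)))
    out[[name]] <- load_pwm(t(mat), pseudocount = pseudocount,
                            background = bg, name = name)
  }
  out
}

#' Read a PWM from a 4-column count TSV
#'
#' Plain text, one row per motif position, columns A, C, G, T (header
#' optional).
#'
#' @param path TSV path.
#' @param ... passed to [load_pwm()].
#' @return A `pwm` object.
#' @export
read_pwm_tsv <- function(path, ...) {
  if (!file.exists(path)) ee_io_error(sprintf("no such file: %s", path))
  first <- readLines(path, n = 1L)
  header <- grepl("[A-Za-z]", gsub("[ \t]", "", first))
  tab <- utils::read.table(path, header = header, sep = "\t")
  load_pwm(t(as.matrix(tab[, 1:4])),
           name = sub("\\.[^.]*$", "", basename(path)), ...)
}

#' Write motif hits as TSV
#'
#' Columns `seq_id`, `start`, `end`, `strand`, `score`, `p`, `motif`
#' (BED6-convertible: seq, start, end, motif, score, strand).
#'
#' @param hits a `motif_hits` table.
#' @param path TSV path.
#' @return Invisibly, `path`.
#' @export
write_hits_tsv <- function(hits, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(hits), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
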