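# Sequence-library simulators: random reporter-test sequences with optional
# embedded motifs, and error-prone-PCR style mutant libraries with ground
# truth mutation lists.

DNA_BASES <- c("A", "C", "G", "T")

#' Generate a library of random DNA sequences with an optional embedded motif
#'
#' Emulates oligo-pool synthesis of random candidate regulatory sequences:
#' `n` unique sequences of fixed length over ACGT, optionally carrying a
#' fixed motif (e.g. a UAS, Grh or Zld site) at a controlled offset. The
#' classic design places the motif approximately at the center of each
#' sequence; this generator uses the deterministic offset
#' `floor((length - nchar(motif)) / 2)` under the `"center"` policy.
#'
#' @param n number of sequences (>= 1).
#' @param length sequence length in bp; must be >= the motif length.
#' @param motif optional DNA string over ACGT embedded verbatim in every
#'   sequence.
#' @param offset_policy one of `"center"` (deterministic central offset),
#'   `"uniform"` (offset drawn uniformly per sequence), or a single
#'   non-negative integer giving a fixed 0-based offset.
#' @param seed integer RNG seed; identical arguments and seed give
#'   byte-identical output.
#' @param prefix id prefix for the generated records.
#' @return An object of class `sequence_set`: a list with element
#'   `records` (data.frame with columns `id`, `sequence`, `motif`,
#'   `motif_offset` (0-based, NA when no motif)) and the generation
#'   parameters. Ids are unique; uniqueness of sequences is enforced by
#'   rejection-resampling on collision.
#' @export
generate_random_sequences <- function(n, length, motif = NULL,
                                      offset_policy = "center",
                                      seed = 1L, prefix = "rand") {
  if (!is.numeric(n) || n < 1) ee_input_error("`n` must be >= 1")
  n <- as.integer(n)
  len <- as.integer(length)
  if (len < 1) ee_input_error("`length` must be >= 1")
  m <- 0L
  if (!is.null(motif)) {
    motif <- toupper(motif)
    if (!grepl("^[ACGT]+$", motif)) {
      ee_input_error("`motif` must be a DNA string over ACGT")
    }
    m <- nchar(motif)
    if (m > len) {
      ee_design_error(sprintf(
        "motif length (%d) exceeds sequence length (%d)", m, len))
    }
  }
  fixed_offset <- NULL
  if (is.numeric(offset_policy)) {
    fixed_offset <- as.integer(offset_policy)
    if (is.null(motif)) ee_input_error("offset policy given without a motif")
    if (fixed_offset < 0 || fixed_offset + m > len) {
      ee_design_error("fixed motif offset places the motif outside the sequence")
    }
  } else if (!offset_policy %in% c("center", "uniform")) {
    ee_input_error("`offset_policy` must be 'center', 'uniform' or an integer")
  }

  with_seed_ee(seed, {
    seqs <- character(n)
    offs <- rep(NA_integer_, n)
    seen <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        s <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
        off <- NA_integer_
        if (!is.null(motif)) {
          off <- if (!is.null(fixed_offset)) fixed_offset
                 else if (identical(offset_policy, "center")) (len - m) %/% 2L
                 else sample.int(len - m + 1L, 1L) - 1L
          substr(s, off + 1L, off + m) <- motif
        }
        if (is.null(seen[[s]])) {
          seen[[s]] <- TRUE
          seqs[i] <- s
          offs[i] <- off
          ok <- TRUE
          break
        }
      }
      if (!ok) ee_generation_error("could not generate unique sequences (design space exhausted)")
    }
    structure(list(
      records = data.frame(
        id = sprintf("%s_%03d", prefix, seq_len(n)),
        sequence = seqs,
        motif = if (is.null(motif)) NA_character_ else motif,
        motif_offset = offs,
        stringsAsFactors = FALSE),
      length = len, motif = motif, offset_policy = offset_policy,
      seed = as.integer(seed)),
      class = "sequence_set")
  })
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("sequence_set: %d sequences of %d bp%s\n",
              nrow(x$records), x$length,
              if (!is.null(x$motif))
                sprintf(", embedded motif %s (%s policy)", x$motif,
                        paste(x$offset_policy, collapse = ","))
              else ""))
  invisible(x)
}

# Coerce the things scanning/statistics accept into a named character vector.
as_sequence_vector <- function(seqs) {
  if (inherits(seqs, "sequence_set")) {
    stats::setNames(seqs$records$sequence, seqs$records$id)
  } else if (inherits(seqs, "DNAStringSet")) {
    stats::setNames(as.character(seqs), names(seqs))
  } else if (is.character(seqs)) {
    if (is.null(names(seqs))) names(seqs) <- sprintf("seq_%03d", seq_along(seqs))
    seqs
  } else ee_input_error("unsupported sequence container")
}

#' Simulate an error-prone-PCR mutant library
#'
#' Each line is an independent copy of `reference` in which every position
#' mutates independently with probability `per_base_rate`; a mutated
#' position is substituted by one of the three other bases uniformly at
#' random. The per-line mutation count is therefore
#' Binomial(nchar(reference), rate), matching the ~0.5%/base error-prone
#' PCR regime that yields roughly 1-5 substitutions on a 300-500 bp
#' enhancer. Indels are not simulated.
#'
#' @param reference reference DNA string over ACGT.
#' @param per_base_rate per-base substitution probability in \[0, 1\].
#' @param n_lines number of variant lines.
#' @param seed integer RNG seed.
#' @param prefix id prefix for line names.
#' @return An object of class `variant_library`: list of records, each a
#'   list with `line_id`, `sequence`, and `mutations` (data.frame with
#'   0-based `position`, `ref_base`, `alt_base`, positions strictly
#'   increasing). The reference is attached as attribute `reference`.
#' @export
simulate_mutant_library <- function(reference, per_base_rate, n_lines,
                                    seed = 1L, prefix = "line") {
  reference <- toupper(reference)
  if (!nzchar(reference)) ee_input_error("`reference` must be non-empty")
  if (!grepl("^[ACGT]+$", reference)) {
    ee_input_error("`reference` must be a DNA string over ACGT")
  }
  if (!is.numeric(per_base_rate) || per_base_rate < 0 || per_base_rate > 1) {
    ee_input_error("`per_base_rate` must be in [0, 1]")
  }
  n_lines <- as.integer(n_lines)
  if (n_lines < 1) ee_input_error("`n_lines` must be >= 1")
  L <- nchar(reference)
  ref_chars <- strsplit(reference, "")[[1]]

  recs <- with_seed_ee(seed, {
    lapply(seq_len(n_lines), function(i) {
      hit <- which(stats::runif(L) < per_base_rate)
      chars <- ref_chars
      alt <- character(length(hit))
      for (j in seq_along(hit)) {
        alt[j] <- sample(setdiff(DNA_BASES, ref_chars[hit[j]]), 1L)
        chars[hit[j]] <- alt[j]
      }
      list(line_id = sprintf("%s_%04d", prefix, i),
           sequence = paste(chars, collapse = ""),
           mutations = data.frame(position = hit - 1L,
                                  ref_base = ref_chars[hit],
                                  alt_base = alt,
                                  stringsAsFactors = FALSE))
    })
  })
  structure(recs, class = "variant_library",
            reference = reference, per_base_rate = per_base_rate,
            seed = as.integer(seed))
}

#' Apply a mutation list to a reference sequence
#'
#' @param reference DNA string.
#' @param mutations data.frame with 0-based `position`, `ref_base`,
#'   `alt_base` as in [simulate_mutant_library()] records.
#' @return The mutated sequence. Errors if a `ref_base` does not match the
#'   reference at its position.
#' @export
apply_mutations <- function(reference, mutations) {
  chars <- strsplit(toupper(reference), "")[[1]]
  if (nrow(mutations)) {
    pos <- mutations$position + 1L
    if (any(pos < 1L | pos > length(chars))) {
      ee_input_error("mutation position outside the reference")
    }
    if (any(chars[pos] != mutations$ref_base)) {
      ee_input_error("ref_base does not match the reference sequence")
    }
    chars[pos] <- mutations$alt_base
  }
  paste(chars, collapse = "")
}

#' Summarize a mutant library
#'
#' Aggregates per-line mutation counts into the library-level summary used
#' to describe mutagenesis panels: total mutations, mean mutations per line
#' (total / n), and the histogram of lines per mutation count.
#'
#' @param variants a `variant_library` or a list of variant records.
#' @return An object of class `library_summary`: list with `n_lines`,
#'   `total_mutations`, `mean_mutations_per_line`, and `histogram` (named
#'   integer vector, names = mutation count).
#' @export
summarize_library <- function(variants) {
  if (length(variants) == 0L) ee_input_error("empty variant list")
  counts <- vapply(variants, function(r) nrow(r$mutations), integer(1))
  histo <- table(counts)
  out <- list(n_lines = length(counts),
              total_mutations = sum(counts),
              mean_mutations_per_line = sum(counts) / length(counts),
              histogram = stats::setNames(as.integer(histo), names(histo)))
  class(out) <- "library_summary"
  out
}

#' @export
print.library_summary <- function(x, ...) {
  cat(sprintf("library_summary: %d lines, %d mutations, mean %.1f mutations/line\n",
              x$n_lines, x$total_mutations, x$mean_mutations_per_line))
  invisible(x)
}

#' Write a sequence set or variant library to FASTA plus sidecar metadata
#'
#' FASTA is wrapped at 60 columns. Metadata go to `<stem>.csv` and
#' `<stem>.json` next to the FASTA: for sequence sets, id / motif /
#' 0-based offset; for variant libraries, line id, mutation count and
#' semicolon-separated 0-based positions.
#'
#' @param x a `sequence_set` or `variant_library`.
#' @param path output FASTA path; sidecars replace the extension.
#' @return Invisibly, the paths written.
#' @export
write_library <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  stem <- sub("\\.[^.]*$", "", path)
  if (inherits(x, "sequence_set")) {
    dna <- Biostrings::DNAStringSet(stats::setNames(x$records$sequence,
                                                    x$records$id))
    meta <- x$records[, c("id", "motif", "motif_offset")]
  } else if (inherits(x, "variant_library")) {
    dna <- Biostrings::DNAStringSet(stats::setNames(
      vapply(x, `[[`, character(1), "sequence"),
      vapply(x, `[[`, character(1), "line_id")))
    meta <- data.frame(
      line_id = vapply(x, `[[`, character(1), "line_id"),
      n_mutations = vapply(x, function(r) nrow(r$mutations), integer(1)),
      positions = vapply(x, function(r)
        paste(r$mutations$position, collapse = ";"), character(1)),
      stringsAsFactors = FALSE)
  } else ee_input_error("`x` must be a sequence_set or variant_library")
  Biostrings::writeXStringSet(dna, path, width = 60L)
  utils::write.csv(meta, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(meta, paste0(stem, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(path, paste0(stem, ".csv"), paste0(stem, ".json")))
}
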