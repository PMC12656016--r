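# Independent brute-force oracles and small fixture builders. These are
# deliberately naive (character-by-character loops, no regex, no prefix
# sums) so they share no code path with the package implementation.

rand_dna <- function(n, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(background), n, replace = TRUE, prob = background),
        collapse = "")
}

# Naive reverse complement via explicit lookup.
oracle_revcomp <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(seq, "")[[1L]]])), collapse = "")
}

# Brute-force double-strand core scan: slide a 6-window, compare
# literally against the two cores and their reverse complements.
# Returns data.frame(offset, strand), 0-based offsets.
oracle_scan <- function(seq) {
  fwd <- c("TTGACC", "TTGACT")
  rev <- c("GGTCAA", "AGTCAA")
  chars <- strsplit(seq, "")[[1L]]
  L <- length(chars)
  out <- list()
  if (L >= 6L) {
    for (i in 1:(L - 5L)) {
      w <- paste(chars[i:(i + 5L)], collapse = "")
      if (w %in% fwd) out[[length(out) + 1L]] <- data.frame(offset = i - 1L, strand = "+")
      if (w %in% rev) out[[length(out) + 1L]] <- data.frame(offset = i - 1L, strand = "-")
    }
  }
  if (length(out) == 0L) {
    return(data.frame(offset = integer(0), strand = character(0)))
  }
  do.call(rbind, out)
}

# Exhaustive enumerator over trims, placements and strands for one motif
# against one promoter. Mirrors the matcher contract: total terminal trim
# 0 or 2..6 (span within [min_span, max_span]), promoter N is a mismatch,
# E-value = n_positions * binomial tail, duplicates collapsed to lowest
# mismatch count. Returns data.frame(start, end, strand, mismatches).
oracle_match <- function(motif, promoter, params, n_positions = NULL) {
  m <- nchar(motif)
  L <- nchar(promoter)
  spans <- params$min_span:min(params$max_span, m)
  spans <- spans[(m - spans) == 0L | (m - spans) >= 2L]
  if (is.null(n_positions)) {
    n_positions <- sapply(spans, function(s) 2 * max(0L, L - s + 1L) * (m - s + 1L))
    names(n_positions) <- spans
  }
  p_match <- sum(params$background^2)
  qc <- strsplit(motif, "")[[1L]]
  best <- list()
  for (strand in c("+", "-")) {
    work <- if (strand == "+") promoter else oracle_revcomp(promoter)
    wc <- strsplit(work, "")[[1L]]
    for (s in spans) {
      if (L < s) next
      for (l in 0:(m - s)) {
        sub <- qc[(l + 1L):(l + s)]
        for (p in 1:(L - s + 1L)) {
          mm <- sum(sub != wc[p:(p + s - 1L)])
          if (mm > params$max_mismatch) next
          ev <- n_positions[[as.character(s)]] *
            stats::pbinom(mm, s, 1 - p_match)
          if (ev > params$evalue_max) next
          if (strand == "+") {
            st <- p - 1L
          } else {
            st <- L - p + 1L - s
          }
          key <- paste(st, st + s, strand)
          if (is.null(best[[key]]) || best[[key]]$mismatches > mm) {
            best[[key]] <- data.frame(start = st, end = st + s,
                                      strand = strand, mismatches = mm)
          }
        }
      }
    }
  }
  if (length(best) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  out <- do.call(rbind, best)
  rownames(out) <- NULL
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# Canonical sortable key for hit-set comparison.
hit_key <- function(df) {
  sort(paste(df$start, df$end, df$strand, df$mismatches))
}

# Random 17-nt motif over ACGT.
rand_motif <- function(m = 17L) rand_dna(m)

# Plant `txt` into `seq` at 0-based offset.
plant_at <- function(seq, offset, txt) {
  paste0(substr(seq, 1L, offset), txt,
         substr(seq, offset + nchar(txt) + 1L, nchar(seq)))
}

# Substitute bases of `motif` at the given 1-based positions.
mutate_at <- function(motif, positions) {
  chars <- strsplit(motif, "")[[1L]]
  for (p in positions) {
    chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1L]
  }
  paste(chars, collapse = "")
}
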