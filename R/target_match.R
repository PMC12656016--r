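# Approximate matching of ranked 17-nt W-box motifs against promoter sets.
#
# A hit is an ungapped placement of a contiguous motif substring onto a
# promoter (either strand). Substrings arise by trimming terminal bases
# from the motif: either no trimming, or 2-6 bases in total split freely
# between the two ends (a total trim of exactly 1 is not allowed).
# Trimmed bases are not mismatches; within the aligned span at most
# `max_mismatch` substitutions are tolerated (promoter `N` counts as a
# mismatch). Each surviving hit carries a binomial expectation value
# (E-value) and is kept only if it does not exceed `evalue_max`.
#
# Mismatch counting is done with a prefix-sum trick: a single
# motif-vs-promoter mismatch indicator matrix per strand serves every
# (trim, placement) combination in O(1) each.

#' Matching parameters
#'
#' @param max_mismatch Maximum internal mismatches per hit (default 2).
#' @param min_span Shortest allowed hit span in nt (default 11, i.e. a
#'   17-nt motif trimmed by the maximal 6 nt).
#' @param max_span Longest allowed hit span (default 17, the full motif).
#' @param evalue_max E-value cutoff for reported hits (default 2).
#' @param background Base-composition vector over A, C, G, T summing to 1;
#'   used by the E-value model. Default uniform.
#' @return A list of class `wbox_match_params`.
#' @export
match_params <- function(max_mismatch = 2L, min_span = 11L, max_span = 17L,
                         evalue_max = 2.0,
                         background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  max_mismatch <- as.integer(max_mismatch)
  min_span <- as.integer(min_span)
  max_span <- as.integer(max_span)
  if (max_mismatch < 0L) stop("`max_mismatch` must be >= 0")
  if (min_span <= 0L || min_span > max_span) stop("need 0 < min_span <= max_span")
  if (evalue_max <= 0) stop("`evalue_max` must be > 0")
  background <- .check_background(background)
  structure(list(max_mismatch = max_mismatch, min_span = min_span,
                 max_span = max_span, evalue_max = evalue_max,
                 background = background),
            class = "wbox_match_params")
}

.check_background <- function(background) {
  if (length(background) != 4L) stop("`background` must have 4 entries (A,C,G,T)")
  if (is.null(names(background))) names(background) <- c("A", "C", "G", "T")
  background <- background[c("A", "C", "G", "T")]
  if (any(is.na(background)) || any(background < 0)) {
    stop("`background` entries must be nonnegative and named A/C/G/T")
  }
  if (abs(sum(background) - 1) > 1e-9) stop("`background` must sum to 1")
  background
}

#' Binomial E-value for an approximate short-query hit
#'
#' Expected number of chance hits of the given quality in a search of
#' `n_positions` independent trials against an i.i.d. background: the
#' per-position probability that a background base matches a query base
#' (itself drawn from the same composition) is `p = sum(background^2)`,
#' and the probability that a random window of `span_len` bases matches
#' with at most `mismatches` substitutions is the binomial tail
#' `P = sum_{j<=mismatches} C(span_len, j) (1-p)^j p^(span_len-j)`.
#' Returns `n_positions * P`. Monotone non-decreasing in `mismatches`
#' and in `n_positions`.
#'
#' @param span_len Aligned span length (nt).
#' @param mismatches Mismatch count of the hit.
#' @param n_positions Number of search trials (placements, both strands,
#'   times the number of distinct query substrings of that span; see
#'   [collect_targets()]).
#' @param background Base composition over A, C, G, T.
#' @return The E-value, a nonnegative number.
#' @export
evalue <- function(span_len, mismatches, n_positions,
                   background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (any(span_len < 1L)) stop("`span_len` must be >= 1")
  if (any(n_positions < 0)) stop("`n_positions` must be >= 0")
  background <- .check_background(background)
  p_match <- sum(background^2)
  n_positions * stats::pbinom(pmin(mismatches, span_len), span_len, 1 - p_match)
}

# Span lengths allowed under the trimming rule: full length, or a total
# trim between 2 and (m - min_span) nt.
.allowed_spans <- function(m, params) {
  s <- seq(params$min_span, min(params$max_span, m))
  s[(m - s) == 0L | (m - s) >= 2L]
}

# Search-trial counts per span for a set of promoter lengths: placements
# on both strands times the number of distinct query substrings.
.n_positions <- function(prom_lens, m, params) {
  spans <- .allowed_spans(m, params)
  np <- vapply(spans, function(s) {
    2 * sum(pmax(0L, prom_lens - s + 1L)) * (m - s + 1L)
  }, numeric(1))
  names(np) <- spans
  np
}

#' Match one motif against one promoter
#'
#' Enumerates every ungapped placement of every allowed motif substring
#' on the promoter and its reverse complement, keeps placements within
#' the mismatch budget and the E-value cutoff, and collapses duplicate
#' spans (the same promoter interval and strand reachable through
#' different trims) to their lowest-mismatch representation.
#'
#' @param motif Query sequence over A/C/G/T (typically 17 nt).
#' @param promoter A single promoter sequence.
#' @param params [match_params()] object.
#' @param gene_id Gene id recorded in the output (default `""`).
#' @param n_positions Optional named vector of search-trial counts per
#'   span, for E-values computed over a whole promoter set; defaults to
#'   counts for this single promoter.
#' @return `data.frame` with columns `motif`, `gene_id`, `start`, `end`
#'   (0-based half-open on the promoter as written), `strand`,
#'   `span_len`, `mismatches`, `evalue`.
#' @export
match_motif <- function(motif, promoter, params = match_params(),
                        gene_id = "", n_positions = NULL) {
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) {
    stop("motif contains a non-ACGT character: ", motif)
  }
  promoter <- .check_dna(promoter, "promoter")
  m <- nchar(motif)
  spans <- .allowed_spans(m, params)
  if (length(spans) == 0L) return(.empty_hits())
  L <- nchar(promoter)
  if (L < min(spans)) return(.empty_hits())
  if (is.null(n_positions)) n_positions <- .n_positions(L, m, params)

  # E-value lookup by span and mismatch count
  ev <- lapply(spans, function(s) {
    evalue(s, 0:params$max_mismatch, n_positions[[as.character(s)]],
           params$background)
  })
  names(ev) <- spans

  qv <- strsplit(motif, "")[[1L]]
  hits <- list()
  for (strand in c("+", "-")) {
    work <- if (strand == "+") promoter else reverse_complement(promoter)
    wv <- c(rep("?", m), strsplit(work, "")[[1L]], rep("?", m))
    # full-motif alignment starts considered (1-based on work, may be <= 0)
    a_vals <- (1L - (m - min(spans))):(L - min(spans) + 1L)
    nA <- length(a_vals)
    mm_mat <- matrix(FALSE, nrow = m, ncol = nA)
    for (i in seq_len(m)) {
      mm_mat[i, ] <- wv[m + a_vals + i - 1L] != qv[i]
    }
    cum <- apply(mm_mat, 2L, cumsum)          # m x nA
    for (s in spans) {
      p <- seq_len(L - s + 1L)                 # placement starts on work
      for (l in 0:(m - s)) {
        a <- p - l
        j <- a - a_vals[1L] + 1L
        mm <- cum[l + s, j] - if (l > 0L) cum[l, j] else 0
        keep <- mm <= params$max_mismatch
        if (!any(keep)) next
        pk <- p[keep]; mmk <- mm[keep]
        e <- ev[[as.character(s)]][mmk + 1L]
        ok <- e <= params$evalue_max
        if (!any(ok)) next
        pk <- pk[ok]; mmk <- mmk[ok]; e <- e[ok]
        if (strand == "+") {
          start0 <- pk - 1L
        } else {
          start0 <- L - pk + 1L - s
        }
        hits[[length(hits) + 1L]] <- data.frame(
          motif = motif, gene_id = gene_id,
          start = start0, end = start0 + s, strand = strand,
          span_len = s, mismatches = as.integer(mmk), evalue = e,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(hits) == 0L) return(.empty_hits())
  out <- do.call(rbind, hits)
  # collapse duplicate spans from different trims: keep lowest mismatches
  key <- paste(out$start, out$end, out$strand)
  out <- out[order(key, out$mismatches), , drop = FALSE]
  out <- out[!duplicated(paste(out$start, out$end, out$strand)), , drop = FALSE]
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_hits <- function() {
  data.frame(motif = character(0), gene_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             span_len = integer(0), mismatches = integer(0),
             evalue = numeric(0), stringsAsFactors = FALSE)
}

#' Collect the best hit per target gene
#'
#' Matches every motif against every promoter (E-values computed over the
#' whole set: search trials are pooled across promoters, strands and
#' query substrings per span class) and reports, per gene, the single
#' best hit: lowest E-value, then fewest mismatches, then longest span,
#' then leftmost start. Genes with no surviving hit are omitted.
#'
#' @param motifs Character vector of query motifs, or a ranked-motif
#'   `data.frame` with a `window` column (see [rank_motifs()]).
#' @param promoters Promoter `data.frame` or named character vector.
#' @param params [match_params()] object.
#' @return `data.frame` of best hits, one row per reported gene, with the
#'   columns of [match_motif()].
#' @export
collect_targets <- function(motifs, promoters, params = match_params()) {
  if (is.data.frame(motifs)) motifs <- motifs$window
  if (length(motifs) == 0L) stop("`motifs` must be non-empty")
  promoters <- .as_promoter_df(promoters)
  if (nrow(promoters) == 0L) {
    warning("empty promoter set; no targets to report")
    return(.empty_hits())
  }
  m <- unique(nchar(motifs))
  if (length(m) != 1L) stop("all motifs must have equal length")
  np <- .n_positions(nchar(promoters$sequence), m, params)

  all_hits <- list()
  for (mo in motifs) {
    for (i in seq_len(nrow(promoters))) {
      h <- match_motif(mo, promoters$sequence[i], params,
                       gene_id = promoters$gene_id[i], n_positions = np)
      if (nrow(h) > 0L) all_hits[[length(all_hits) + 1L]] <- h
    }
  }
  if (length(all_hits) == 0L) return(.empty_hits())
  hits <- do.call(rbind, all_hits)
  ord <- order(hits$gene_id, hits$evalue, hits$mismatches, -hits$span_len,
               hits$start, hits$strand, hits$motif)
  hits <- hits[ord, , drop = FALSE]
  best <- hits[!duplicated(hits$gene_id), , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Write match hits as BED6
#'
#' Promoter-relative 0-based half-open spans; the name column carries the
#' motif and the score column the mismatch count.
#'
#' @param hits Hit `data.frame` from [match_motif()] or [collect_targets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$gene_id, start = hits$start, end = hits$end,
                    name = hits$motif, score = hits$mismatches,
                    strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data frame as TSV
#'
#' Plain tab-separated output with a header, used for hit tables, ranked
#' motifs and reports.
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
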