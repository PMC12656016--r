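# W-box core scanning, 17-bp window extension, and frequency ranking.
#
# The W-box core recognised by WRKY transcription factors is TTGAC
# followed by C or T. Promoters are scanned as written (the gene's own
# strand, 5'->3'); with `both_strands = TRUE` occurrences of the reverse
# complement ([AG]GTCAA) are reported as strand "-". All occurrence
# coordinates are 0-based starts on the promoter as written.

# Parse a core pattern like "TTGAC[CT]" into a list of per-position
# allowed-base sets.
.parse_core <- function(core) {
  chars <- strsplit(core, "")[[1L]]
  pos <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      set <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        set <- c(set, chars[j])
        j <- j + 1L
      }
      if (j > length(chars)) stop("unbalanced '[' in core pattern: ", core)
      pos[[length(pos) + 1L]] <- toupper(set)
      i <- j + 1L
    } else {
      pos[[length(pos) + 1L]] <- toupper(ch)
      i <- i + 1L
    }
  }
  if (any(!unlist(pos) %in% c("A", "C", "G", "T"))) {
    stop("core pattern may only contain A/C/G/T and [] classes: ", core)
  }
  pos
}

.core_regex <- function(pos_sets) {
  paste0(vapply(pos_sets, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

.core_revcomp_sets <- function(pos_sets) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev(lapply(pos_sets, function(s) unname(comp[s])))
}

# All 0-based start positions of a regex in `seq`, overlapping matches
# included (lookahead trick).
.find_all <- function(seq, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Scan promoters for W-box core occurrences
#'
#' Reports every occurrence of the core pattern (default `TTGAC[CT]`) on
#' each promoter, on both strands by default. Overlapping occurrences are
#' all reported and `N` never matches. For strand `-` sites the `core`
#' and `window` columns are given in motif orientation (reverse
#' complement of the written sequence) so the core always reads
#' `TTGAC[C/T]`; the `offset` column is always the 0-based start of the
#' matched bases on the promoter as written.
#'
#' @param promoters Promoter `data.frame` (columns `gene_id`, `sequence`)
#'   or a named character vector of sequences.
#' @param core Core pattern; single bases and `[..]` classes only.
#' @param both_strands Scan the reverse complement orientation too?
#' @param upstream_flank,window_len,pad Passed to [extend_site()].
#' @return `data.frame` with columns `gene_id`, `offset`, `strand`,
#'   `core`, `window`.
#' @export
scan_wbox <- function(promoters, core = "TTGAC[CT]", both_strands = TRUE,
                      upstream_flank = 4L, window_len = 17L, pad = "N") {
  promoters <- .as_promoter_df(promoters)
  pos_sets <- .parse_core(core)
  fwd_re <- .core_regex(pos_sets)
  rev_re <- .core_regex(.core_revcomp_sets(pos_sets))
  core_len <- length(pos_sets)

  res <- vector("list", nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    seq <- .check_dna(promoters$sequence[i],
                      paste0("promoter ", promoters$gene_id[i]))
    offs <- .find_all(seq, fwd_re)
    strands <- rep("+", length(offs))
    if (both_strands) {
      offs_m <- .find_all(seq, rev_re)
      offs <- c(offs, offs_m)
      strands <- c(strands, rep("-", length(offs_m)))
    }
    if (length(offs) == 0L) next
    ord <- order(offs, strands)
    offs <- offs[ord]; strands <- strands[ord]
    cores <- substr(rep(seq, length(offs)), offs + 1L, offs + core_len)
    cores[strands == "-"] <- reverse_complement(cores[strands == "-"])
    res[[i]] <- data.frame(
      gene_id = promoters$gene_id[i],
      offset = offs,
      strand = strands,
      core = cores,
      stringsAsFactors = FALSE
    )
  }
  sites <- do.call(rbind, res)
  if (is.null(sites)) {
    sites <- data.frame(gene_id = character(0), offset = integer(0),
                        strand = character(0), core = character(0),
                        stringsAsFactors = FALSE)
  }
  sites$window <- extend_site(sites, promoters, upstream_flank = upstream_flank,
                              window_len = window_len, pad = pad,
                              core_len = core_len)
  sites
}

#' Build the extended window around a core occurrence
#'
#' The window spans `window_len` bases starting `upstream_flank` bases
#' upstream of the core, in motif orientation: for strand `-` sites the
#' window is taken on the reverse complement of the promoter so the core
#' reads `TTGAC[C/T]` inside it. Positions falling outside the promoter
#' are filled with `pad`. With the defaults (4 upstream, 17 total, 6-nt
#' core) the downstream flank is 7 nt.
#'
#' @param sites Site `data.frame` (columns `gene_id`, `offset`, `strand`),
#'   e.g. from [scan_wbox()].
#' @param promoters Promoter `data.frame` or named character vector.
#' @param upstream_flank Bases upstream of the core start (default 4).
#' @param window_len Total window length (default 17).
#' @param pad Padding character for positions outside the promoter.
#' @param core_len Length of the matched core (default 6).
#' @return Character vector of windows, one per site.
#' @export
extend_site <- function(sites, promoters, upstream_flank = 4L,
                        window_len = 17L, pad = "N", core_len = 6L) {
  if (window_len < core_len + upstream_flank) {
    stop("`window_len` must be at least core length + `upstream_flank`")
  }
  promoters <- .as_promoter_df(promoters)
  pseq <- promoters$sequence
  names(pseq) <- promoters$gene_id
  n <- nrow(sites)
  out <- character(n)
  for (i in seq_len(n)) {
    seq <- pseq[[sites$gene_id[i]]]
    L <- nchar(seq)
    if (sites$strand[i] == "+") {
      s0 <- sites$offset[i]            # core start, 0-based on written
      work <- seq
    } else {
      s0 <- L - sites$offset[i] - core_len  # core start on the revcomp
      work <- reverse_complement(seq)
    }
    from <- s0 - upstream_flank        # 0-based window start
    idx <- from + seq_len(window_len) - 1L
    chars <- rep(pad, window_len)
    inside <- idx >= 0L & idx < L
    if (any(inside)) {
      chars[inside] <- strsplit(substr(work, min(idx[inside]) + 1L,
                                       max(idx[inside]) + 1L), "")[[1L]]
    }
    out[i] <- paste(chars, collapse = "")
  }
  out
}

#' Rank extended windows by occurrence frequency
#'
#' Windows are grouped by exact text identity, counted over the whole
#' site set, and sorted by count (decreasing) with lexicographic
#' tie-breaking. A window and its reverse complement are distinct keys.
#' Windows containing the padding character `N` are edge artefacts and
#' only enter the top `k` if no `N`-free window remains.
#'
#' @param sites Site `data.frame` with a `window` column.
#' @param k Number of motifs to keep (default 20).
#' @return `data.frame` with columns `rank`, `window`, `count`.
#' @export
rank_motifs <- function(sites, k = 20L) {
  k <- as.integer(k)
  if (is.na(k) || k <= 0L) stop("`k` must be a positive integer")
  tab <- table(sites$window)
  df <- data.frame(window = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  has_n <- grepl("N", df$window, fixed = TRUE)
  ord <- order(has_n, -df$count, df$window)   # N-free first
  df <- df[ord, , drop = FALSE]
  if (nrow(df) < k) {
    warning(sprintf("only %d distinct windows available (k = %d)", nrow(df), k))
  }
  df <- utils::head(df, k)
  if (nrow(df) > 0L) df$rank <- seq_len(nrow(df))
  else df$rank <- integer(0)
  rownames(df) <- NULL
  df[, c("rank", "window", "count")]
}

# Accept either a promoter data.frame or a named character vector.
.as_promoter_df <- function(promoters) {
  if (is.data.frame(promoters)) {
    if (!all(c("gene_id", "sequence") %in% names(promoters))) {
      stop("promoter data.frame needs columns `gene_id` and `sequence`")
    }
    return(promoters)
  }
  if (is.character(promoters)) {
    if (is.null(names(promoters)) || any(!nzchar(names(promoters)))) {
      stop("promoter character vector must be named by gene id")
    }
    return(data.frame(gene_id = names(promoters),
                      sequence = unname(promoters),
                      stringsAsFactors = FALSE))
  }
  stop("`promoters` must be a data.frame or a named character vector")
}

#' Write motif sites as BED6
#'
#' Promoter-relative coordinates (0-based half-open); the score column
#' carries 0 and the name column the matched core.
#'
#' @param sites Site `data.frame` from [scan_wbox()].
#' @param path Output path.
#' @param core_len Core length used for the interval end (default 6).
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path, core_len = 6L) {
  bed <- data.frame(
    chrom = sites$gene_id,
    start = sites$offset,
    end = sites$offset + core_len,
    name = sites$core,
    score = 0L,
    strand = sites$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
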