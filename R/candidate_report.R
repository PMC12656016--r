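# Candidate selection, ipTM ingestion/filtering, and the final
# target-gene report (gene id, 17-nt site, reverse complement, ipTM).

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards (no hidden global state).
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Reconstruct the 17-nt site sequence for a best hit
#'
#' The reported site is the promoter window that the full-length motif
#' would cover at the hit's placement: the aligned span extended by the
#' trimmed amounts at each end, read in the hit's strand orientation,
#' with `N` padding where the window runs off the promoter.
#'
#' @param hits Best-hit `data.frame` from [collect_targets()].
#' @param promoters Promoter `data.frame` or named character vector.
#' @return Character vector of site sequences (length = motif length).
#' @export
hit_site_sequence <- function(hits, promoters) {
  promoters <- .as_promoter_df(promoters)
  pseq <- promoters$sequence
  names(pseq) <- promoters$gene_id
  n <- nrow(hits)
  out <- character(n)
  for (i in seq_len(n)) {
    seq <- pseq[[hits$gene_id[i]]]
    L <- nchar(seq)
    m <- nchar(hits$motif[i])
    s <- hits$span_len[i]
    if (hits$strand[i] == "+") {
      work <- seq
      span_start <- hits$start[i]                  # 0-based on work
    } else {
      work <- reverse_complement(seq)
      span_start <- L - hits$end[i]
    }
    # left trim: which motif substring sat at this span is unknown after
    # collapsing; centre the full window on the span, biased upstream.
    l <- (m - s) %/% 2L
    from <- span_start - l
    idx <- from + seq_len(m) - 1L
    chars <- rep("N", m)
    inside <- idx >= 0L & idx < L
    if (any(inside)) {
      chars[inside] <- strsplit(substr(work, min(idx[inside]) + 1L,
                                       max(idx[inside]) + 1L), "")[[1L]]
    }
    out[i] <- paste(chars, collapse = "")
  }
  out
}

#' Randomly select candidate targets for structure prediction
#'
#' Samples `n` distinct rows uniformly without replacement, with an
#' explicit seed so the selection is reproducible. If fewer than `n`
#' rows are available, all are returned with a warning.
#'
#' @param targets A `data.frame` of target rows (any columns).
#' @param n Number of candidates (default 30).
#' @param seed Integer seed; required.
#' @return The selected rows, in sampling order.
#' @export
select_candidates <- function(targets, n = 30L, seed) {
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("`n` must be a positive integer")
  if (missing(seed)) stop("`seed` must be given explicitly")
  pool <- nrow(targets)
  if (pool <= n) {
    if (pool < n) {
      warning(sprintf("only %d targets available (n = %d); returning all",
                      pool, n))
    }
    if (pool == n) {
      idx <- .with_seed(seed, sample.int(pool, n))
      return(targets[idx, , drop = FALSE])
    }
    return(targets)
  }
  idx <- .with_seed(seed, sample.int(pool, n))
  targets[idx, , drop = FALSE]
}

#' Read an ipTM score table
#'
#' Two-column TSV with a header (`gene_id`, `iptm`). ipTM (interface
#' predicted TM-score) is the [0,1] confidence that an external structure
#' predictor assigns to a modelled protein--DNA interface.
#'
#' @param tsv_path Path to the TSV file.
#' @return Named numeric vector mapping gene id to ipTM.
#' @export
ingest_iptm <- function(tsv_path) {
  df <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("ipTM table must have two columns (gene_id, iptm)")
  ids <- as.character(df[[1L]])
  vals <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyDuplicated(ids)) {
    stop("duplicate gene id in ipTM table: ", ids[duplicated(ids)][1L])
  }
  bad <- which(is.na(vals) | vals < 0 | vals > 1)
  if (length(bad) > 0L) {
    stop(sprintf("ipTM value out of [0,1] at row %d (gene %s): %s",
                 bad[1L], ids[bad[1L]], df[[2L]][bad[1L]]))
  }
  stats::setNames(vals, ids)
}

#' Filter candidates by ipTM and build the target report
#'
#' Retains rows whose ipTM meets the threshold (inclusive), sorts by ipTM
#' descending then gene id, and recomputes the reverse-complement column
#' from the site sequence. The four report columns are `gene_id`,
#' `sequence`, `reverse_complement`, `iptm`.
#'
#' @param rows `data.frame` with columns `gene_id` and `sequence`
#'   (17-nt site text); an existing `reverse_complement` column is
#'   recomputed and checked.
#' @param iptm_map Named numeric vector from [ingest_iptm()], or `NULL`
#'   with `allow_missing = TRUE` to skip the filter entirely.
#' @param threshold Minimum ipTM retained (default 0.8, inclusive).
#' @param allow_missing Keep rows absent from `iptm_map` (with `NA`
#'   ipTM)? Default `FALSE` (absence is an error).
#' @return Report `data.frame` with columns `gene_id`, `sequence`,
#'   `reverse_complement`, `iptm`.
#' @export
filter_and_report <- function(rows, iptm_map, threshold = 0.8,
                              allow_missing = FALSE) {
  if (!all(c("gene_id", "sequence") %in% names(rows))) {
    stop("`rows` must have columns `gene_id` and `sequence`")
  }
  rc <- reverse_complement(rows$sequence)
  if (!is.null(rows$reverse_complement) &&
      any(rows$reverse_complement != rc)) {
    stop("inconsistent reverse_complement column in `rows`")
  }
  iptm <- unname(iptm_map[rows$gene_id])
  missing_ids <- rows$gene_id[!rows$gene_id %in% names(iptm_map)]
  if (length(missing_ids) > 0L && !allow_missing) {
    stop("gene missing from ipTM table: ", missing_ids[1L],
         " (use allow_missing = TRUE to keep it)")
  }
  out <- data.frame(gene_id = rows$gene_id, sequence = rows$sequence,
                    reverse_complement = rc, iptm = iptm,
                    stringsAsFactors = FALSE)
  keep <- !is.na(out$iptm) & out$iptm >= threshold
  if (allow_missing) keep <- keep | is.na(out$iptm)
  out <- out[keep, , drop = FALSE]
  out <- out[order(-ifelse(is.na(out$iptm), -Inf, out$iptm), out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Published TrWRKY41 target-site table
#'
#' The 29 predicted TrWRKY41 binding sites in Arabidopsis target-gene
#' promoters shipped with the package: gene id, 17-nt site sequence, its
#' reverse complement, and the AlphaFold2 interface confidence (ipTM) of
#' the corresponding protein--DNA model. All ipTM values lie in
#' [0.80, 0.86].
#'
#' @return `data.frame` with columns `gene_id`, `sequence`,
#'   `reverse_complement`, `iptm`.
#' @export
trwrky41_sites <- function() {
  path <- system.file("extdata", "trwrky41_sites.tsv", package = "wboxscan",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Join functional annotation onto a report
#'
#' Optional left join of a user-supplied two-column annotation TSV
#' (`gene_id`, `annotation`) onto a report; no remote lookup is
#' performed.
#'
#' @param report Report `data.frame` from [filter_and_report()].
#' @param annotation_tsv Path to the annotation TSV.
#' @return The report with an extra `annotation` column.
#' @export
annotate_report <- function(report, annotation_tsv) {
  ann <- utils::read.table(annotation_tsv, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  idx <- match(report$gene_id, ann[[1L]])
  report$annotation <- ifelse(is.na(idx), NA_character_,
                              as.character(ann[[2L]])[idx])
  report
}
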