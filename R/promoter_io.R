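# Promoter extraction and sequence I/O.
#
# Coordinates follow the GFF3 convention (1-based, inclusive) at the
# interface; internal arithmetic is 0-based half-open. The promoter of a
# gene is the `length` bp immediately upstream of its transcription start,
# written 5'->3' on the gene's own strand, so the TSS-proximal base is
# always the last character.

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of a DNA sequence
#'
#' Standard Watson-Crick complement, reversed. `N` maps to `N`. Input may
#' be lowercase; output is always uppercase. Vectorised over `seq`.
#'
#' @param seq Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse-complemented sequences.
#' @examples
#' reverse_complement("ACGAACTTGACTCGCTC")
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq)) stop("`seq` must be a character vector")
  up <- toupper(seq)
  bad <- regexpr("[^ACGTN]", up)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid nucleotide '%s' at position %d of sequence %d",
                 substr(up[i], bad[i], bad[i]), bad[i], i))
  }
  comp <- chartr("ACGTN", "TGCAN", up)
  vapply(comp, function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Internal: validate a DNA string, returning it uppercased.
.check_dna <- function(seq, what = "sequence") {
  up <- toupper(seq)
  bad <- regexpr("[^ACGTN]", up)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("%s contains invalid character '%s' at position %d",
                 what, substr(up[i], bad[i], bad[i]), bad[i]))
  }
  up
}

#' Load a genome from a FASTA file
#'
#' Reads a (multi-)FASTA file into a named character vector of uppercase
#' contig sequences. Record ids are taken as the first whitespace-delimited
#' token of each header.
#'
#' @param fasta_path Path to a FASTA file.
#' @return Named character vector mapping contig id to uppercase sequence.
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("file not found: ", fasta_path)
  lines <- readLines(fasta_path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", fasta_path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("malformed FASTA: line %d of %s does not start a record ('%s')",
                 first, fasta_path, lines[first]))
  }
  dss <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(ids)) {
    stop("duplicate contig id in FASTA: ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(dss))
  names(seqs) <- ids
  seqs
}

#' Load gene models from a GFF3 annotation
#'
#' Keeps features of type `gene` and derives each gene's transcription
#' start from the feature's 5' end: `start` for `+` genes and `end` for
#' `-` genes (GFF3 coordinates, 1-based inclusive).
#'
#' @param gff3_path Path to a GFF3 file with `gene` features carrying an
#'   `ID` attribute.
#' @return `data.frame` with columns `gene_id`, `contig`, `strand`, `tss`,
#'   `start`, `end`.
#' @export
load_annotation <- function(gff3_path) {
  if (!file.exists(gff3_path)) stop("file not found: ", gff3_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  if (length(gr) == 0L) stop("no gene features in ", gff3_path)
  ids <- as.character(S4Vectors::mcols(gr)$ID)
  if (is.null(S4Vectors::mcols(gr)$ID) || any(is.na(ids)) || any(!nzchar(ids))) {
    stop("gene feature without an ID attribute in ", gff3_path)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene ID in annotation: ", ids[duplicated(ids)][1L])
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("gene feature with unknown strand symbol '",
         strand[!strand %in% c("+", "-")][1L], "'")
  }
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  data.frame(
    gene_id = ids,
    contig  = as.character(GenomicRanges::seqnames(gr)),
    strand  = strand,
    tss     = ifelse(strand == "+", st, en),
    start   = st,
    end     = en,
    stringsAsFactors = FALSE
  )
}

#' Extract strand-aware upstream promoter regions
#'
#' For a `+` gene the promoter is `contig[tss - length .. tss - 1]`; for a
#' `-` gene it is the reverse complement of `contig[tss + 1 .. tss + length]`.
#' Either way the result reads 5'->3' on the gene's own strand with the
#' TSS-proximal end last. Genes closer than `length` to the contig edge
#' yield a shorter promoter flagged `truncated`; they are never padded.
#'
#' @param genome Named character vector of contig sequences
#'   (see [load_genome()]).
#' @param genes `data.frame` of gene models (see [load_annotation()]);
#'   columns `gene_id`, `contig`, `strand`, `tss` are required.
#' @param length Promoter length in bp upstream of the TSS (default 2000).
#' @return `data.frame` with columns `gene_id`, `sequence`, `length`,
#'   `truncated`.
#' @export
extract_promoters <- function(genome, genes, length = 2000L) {
  length <- as.integer(length)
  if (length <= 0L) stop("`length` must be positive")
  need <- c("gene_id", "contig", "strand", "tss")
  if (!all(need %in% names(genes))) {
    stop("`genes` must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!genes$strand %in% c("+", "-"))) stop("unknown strand symbol in `genes`")
  if (any(genes$tss < 1L)) stop("tss must be >= 1")
  miss <- setdiff(unique(genes$contig), names(genome))
  if (length(miss) > 0L) stop("contig missing from genome: ", miss[1L])

  seqs <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ctg <- genome[[genes$contig[i]]]
    L <- nchar(ctg)
    tss <- genes$tss[i]
    if (genes$strand[i] == "+") {
      from <- max(1L, tss - length)
      to <- tss - 1L
      seqs[i] <- if (to < from) "" else substr(ctg, from, to)
    } else {
      from <- tss + 1L
      to <- min(L, tss + length)
      seqs[i] <- if (to < from) "" else reverse_complement(substr(ctg, from, to))
    }
  }
  lens <- nchar(seqs)
  data.frame(
    gene_id = genes$gene_id,
    sequence = seqs,
    length = lens,
    truncated = lens < length,
    stringsAsFactors = FALSE
  )
}

#' Write promoters to FASTA
#'
#' One record per gene; the header is the gene id, with `truncated` noted
#' in the description field for promoters shorter than the requested
#' length.
#'
#' @param promoters Promoter `data.frame` from [extract_promoters()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  hdr <- ifelse(promoters$truncated,
                paste0(promoters$gene_id, " truncated length=", promoters$length),
                promoters$gene_id)
  out <- character(2L * nrow(promoters))
  out[c(TRUE, FALSE)] <- paste0(">", hdr)
  out[c(FALSE, TRUE)] <- promoters$sequence
  writeLines(out, path)
  invisible(path)
}

#' Read a promoter set from FASTA
#'
#' Convenience reader for pre-extracted promoter files (one record per
#' gene, header = gene id).
#'
#' @param fasta_path Path to a promoter FASTA file.
#' @return Promoter `data.frame` with columns `gene_id`, `sequence`,
#'   `length`, `truncated` (truncation inferred from the description
#'   field when present, otherwise `FALSE`).
#' @export
read_promoters_fasta <- function(fasta_path) {
  seqs <- load_genome(fasta_path)
  dss <- Biostrings::readDNAStringSet(fasta_path)
  trunc <- grepl("\\btruncated\\b", names(dss))
  data.frame(
    gene_id = names(seqs),
    sequence = unname(seqs),
    length = nchar(unname(seqs)),
    truncated = trunc,
    stringsAsFactors = FALSE
  )
}
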