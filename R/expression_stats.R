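# Relative qPCR expression by the 2^-ddCt (Livak) method.

#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are averaged on the Ct scale per (sample, gene);
#' then `delta_ct = mean_ct(gene) - mean_ct(reference)` within each
#' sample, `ddct = delta_ct(sample) - delta_ct(calibrator)`, and
#' `fold_change = 2^(-ddct)`. The calibrator sample's fold change is 1
#' for every gene by construction. No amplification-efficiency
#' correction is applied (plain Livak form).
#'
#' @param ct_table `data.frame` with columns `sample`, `gene`,
#'   `replicate`, `ct` (one row per well).
#' @param reference_gene Internal reference gene (e.g. `"GAPDH"`); must
#'   be measured in every sample.
#' @param calibrator_sample Sample against which fold changes are
#'   expressed (e.g. the untreated wild type).
#' @return `data.frame` with one row per (sample, gene) excluding the
#'   reference gene: `sample`, `gene`, `n_reps`, `mean_ct`, `delta_ct`,
#'   `ddct`, `fold_change`, and `ct_sd` (replicate spread on the Ct
#'   scale, `NA` for a single replicate).
#' @examples
#' ct <- data.frame(
#'   sample = rep(c("treated", "control"), each = 2),
#'   gene = rep(c("COR47", "GAPDH"), 2),
#'   replicate = 1L,
#'   ct = c(20, 18, 24, 18)
#' )
#' ddct(ct, reference_gene = "GAPDH", calibrator_sample = "control")
#' @export
ddct <- function(ct_table, reference_gene, calibrator_sample) {
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(ct_table))) {
    stop("`ct_table` must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(ct_table) == 0L) stop("`ct_table` is empty")
  if (any(!is.finite(ct_table$ct))) stop("non-finite Ct value in table")
  dup <- duplicated(ct_table[, c("sample", "gene", "replicate")])
  if (any(dup)) stop("duplicate (sample, gene, replicate) row in `ct_table`")
  if (!calibrator_sample %in% ct_table$sample) {
    stop("calibrator sample not present: ", calibrator_sample)
  }

  agg <- stats::aggregate(ct ~ sample + gene, data = ct_table, FUN = mean)
  names(agg)[names(agg) == "ct"] <- "mean_ct"
  nrep <- stats::aggregate(ct ~ sample + gene, data = ct_table, FUN = length)
  sds <- stats::aggregate(ct ~ sample + gene, data = ct_table,
                          FUN = function(x) if (length(x) > 1L) stats::sd(x) else NA_real_)
  agg$n_reps <- nrep$ct[match(paste(agg$sample, agg$gene),
                              paste(nrep$sample, nrep$gene))]
  agg$ct_sd <- sds$ct[match(paste(agg$sample, agg$gene),
                            paste(sds$sample, sds$gene))]

  ref <- agg[agg$gene == reference_gene, c("sample", "mean_ct")]
  samples <- unique(agg$sample)
  missing_ref <- setdiff(samples, ref$sample)
  if (length(missing_ref) > 0L) {
    stop("reference gene '", reference_gene, "' missing in sample: ",
         missing_ref[1L])
  }
  out <- agg[agg$gene != reference_gene, , drop = FALSE]
  out$delta_ct <- out$mean_ct - ref$mean_ct[match(out$sample, ref$sample)]

  cal <- out[out$sample == calibrator_sample, c("gene", "delta_ct")]
  cal_dct <- cal$delta_ct[match(out$gene, cal$gene)]
  if (any(is.na(cal_dct))) {
    stop("gene absent from calibrator sample: ",
         out$gene[is.na(cal_dct)][1L])
  }
  out$ddct <- out$delta_ct - cal_dct
  out$fold_change <- 2^(-out$ddct)
  out <- out[order(out$sample, out$gene),
             c("sample", "gene", "n_reps", "mean_ct", "ct_sd",
               "delta_ct", "ddct", "fold_change")]
  rownames(out) <- NULL
  out
}

#' Read a Ct table from TSV
#'
#' @param tsv_path Path to a TSV with columns `sample`, `gene`,
#'   `replicate`, `ct`.
#' @return The Ct `data.frame`.
#' @export
read_ct_table <- function(tsv_path) {
  utils::read.table(tsv_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
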