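# Synthetic genomes, annotations, planted W-box sites, ipTM tables and
# qPCR Ct tables, with machine-readable ground truth.
#
# Promoter background is i.i.d. over a configurable base composition
# (default Arabidopsis-like AT-rich). Planted motif copies are written
# into promoters at recorded offsets with exactly the requested number
# of internal substitutions; mutations are confined to the central zone
# of the motif that no allowed terminal trim can remove, so a copy
# planted with k mismatches is seen with exactly k mismatches at every
# admissible span. Accidental W-box cores -- in the background, at
# splice junctions, or created by a mutation -- are removed by bounded
# rejection/repair, so the emitted ground truth is exhaustive.

.BASES <- c("A", "C", "G", "T")

# sample() guarding against the scalar-x surprise
.sample_from <- function(x, k = 1L) x[sample.int(length(x), k)]

.rand_dna <- function(n, background) {
  if (n <= 0L) return("")
  paste(sample(.BASES, n, replace = TRUE, prob = background), collapse = "")
}

# 0-based start positions of core occurrences on both strands.
.core_positions <- function(seq, core = "TTGAC[CT]") {
  pos_sets <- .parse_core(core)
  fwd <- .find_all(seq, .core_regex(pos_sets))
  rev <- .find_all(seq, .core_regex(.core_revcomp_sets(pos_sets)))
  sort(unique(c(fwd, rev)))
}

#' Simulation configuration
#'
#' @param seed Integer seed; required, all randomness flows from it.
#' @param n_contigs Number of contigs (default 2).
#' @param n_genes Number of genes, distributed round-robin over contigs
#'   and alternating strands (default 12).
#' @param promoter_len Promoter length in bp (default 2000).
#' @param gene_len Gene-body length in bp (default 600).
#' @param spacer Intergenic spacer in bp (default 200).
#' @param background Base composition over A, C, G, T; default the
#'   AT-rich composition typical of Arabidopsis intergenic sequence
#'   (A = T = 0.32, C = G = 0.18).
#' @param plant_spec `data.frame` describing motif plantings: columns
#'   `motif` (text), `copies` (per entry), `mismatches` (internal
#'   substitutions per copy), `strand` (`"+"`, `"-"` or `"random"`), and
#'   optionally `gene` (1-based gene index; otherwise copies are dealt
#'   round-robin over genes). `NULL` for no plantings.
#' @param forbid_background_cores Scrub unplanned W-box cores from
#'   promoter background (default `TRUE`, so planted ground truth is
#'   exhaustive)?
#' @param core Core pattern the scrubbing and mutation-rejection checks
#'   use (default `"TTGAC[CT]"`).
#' @param trim_margin Bases at each motif end that mutations must avoid
#'   (default 6, the maximal one-sided trim of the matcher).
#' @return A list of class `wbox_sim_config`.
#' @export
sim_config <- function(seed, n_contigs = 2L, n_genes = 12L,
                       promoter_len = 2000L, gene_len = 600L, spacer = 200L,
                       background = c(A = 0.32, C = 0.18, G = 0.18, T = 0.32),
                       plant_spec = NULL, forbid_background_cores = TRUE,
                       core = "TTGAC[CT]", trim_margin = 6L) {
  if (missing(seed)) stop("`seed` must be given explicitly")
  background <- .check_background(background)
  if (!is.null(plant_spec)) {
    need <- c("motif", "copies", "mismatches", "strand")
    if (!all(need %in% names(plant_spec))) {
      stop("`plant_spec` needs columns: ", paste(need, collapse = ", "))
    }
    if (any(plant_spec$copies < 0L)) stop("`copies` must be >= 0")
    if (any(plant_spec$mismatches < 0L) ||
        any(plant_spec$mismatches >= nchar(plant_spec$motif))) {
      stop("`mismatches` must be in [0, motif length)")
    }
  }
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 n_genes = as.integer(n_genes),
                 promoter_len = as.integer(promoter_len),
                 gene_len = as.integer(gene_len), spacer = as.integer(spacer),
                 background = background, plant_spec = plant_spec,
                 forbid_background_cores = forbid_background_cores,
                 core = core, trim_margin = as.integer(trim_margin)),
            class = "wbox_sim_config")
}

# Mutate `motif` at exactly k positions inside the trim-proof interior,
# rejecting mutations that create core occurrences absent from the
# original motif (either strand).
.mutate_motif <- function(motif, k, core, trim_margin, max_tries = 200L) {
  m <- nchar(motif)
  if (k == 0L) {
    return(list(text = motif, positions = integer(0)))
  }
  lo <- trim_margin + 1L
  hi <- m - trim_margin
  if (hi - lo + 1L < k) {
    stop(sprintf("cannot place %d internal mutations in a %d-nt motif with trim margin %d",
                 k, m, trim_margin))
  }
  orig_cores <- .core_positions(motif, core)
  chars <- strsplit(motif, "")[[1L]]
  for (try in seq_len(max_tries)) {
    pos <- sort(.sample_from(lo:hi, k))
    mut <- chars
    for (p in pos) {
      mut[p] <- .sample_from(setdiff(.BASES, chars[p]))
    }
    text <- paste(mut, collapse = "")
    new_cores <- .core_positions(text, core)
    if (all(new_cores %in% orig_cores)) {
      return(list(text = text, positions = pos))
    }
  }
  stop("failed to place mutations without creating new cores after ",
       max_tries, " tries")
}

# Replace characters of `seq` at 0-based interval [at, at + nchar(txt)).
.splice <- function(seq, at, txt) {
  paste0(substr(seq, 1L, at), txt, substr(seq, at + nchar(txt) + 1L, nchar(seq)))
}

# Build one promoter: background + plantings; scrub unplanned cores.
.build_promoter <- function(len, plants, cfg, max_rounds = 200L) {
  seq <- .rand_dna(len, cfg$background)
  planted_iv <- matrix(numeric(0), ncol = 2)   # 0-based [start, end)
  expected <- integer(0)                        # 0-based allowed core starts
  if (nrow(plants) > 0L) {
    # choose non-overlapping offsets with clearance from the edges
    margin <- 20L
    offsets <- integer(nrow(plants))
    taken <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nrow(plants))) {
      w <- nchar(plants$text[i])
      for (try in 1:500) {
        o <- .sample_from(margin:(len - w - margin))
        if (nrow(taken) == 0L ||
            all(o + w <= taken[, 1] | o >= taken[, 2])) break
        if (try == 500L) stop("could not place plantings without overlap")
      }
      offsets[i] <- o
      taken <- rbind(taken, c(o, o + w))
    }
    for (i in seq_len(nrow(plants))) {
      txt <- plants$text[i]
      if (plants$strand[i] == "-") txt <- reverse_complement(txt)
      seq <- .splice(seq, offsets[i], txt)
      expected <- c(expected, offsets[i] + .core_positions(txt, cfg$core))
    }
    plants$offset <- offsets
    planted_iv <- taken
  }
  if (cfg$forbid_background_cores) {
    for (round in seq_len(max_rounds)) {
      bad <- setdiff(.core_positions(seq, cfg$core), expected)
      if (length(bad) == 0L) break
      if (round == max_rounds) stop("failed to scrub background cores")
      core_len <- length(.parse_core(cfg$core))
      for (b in bad) {
        cand <- b:(b + core_len - 1L)
        free <- cand[vapply(cand, function(p) {
          nrow(planted_iv) == 0L ||
            all(p < planted_iv[, 1] | p >= planted_iv[, 2])
        }, logical(1))]
        if (length(free) == 0L) {
          stop("unplanned core inside a planted interval; mutation check failed")
        }
        p <- .sample_from(free)
        old <- substr(seq, p + 1L, p + 1L)
        seq <- .splice(seq, p, .sample_from(setdiff(.BASES, old)))
      }
    }
  }
  list(sequence = seq, plants = plants)
}

#' Simulate a genome with annotated genes and planted promoter motifs
#'
#' Emits multi-contig genome sequence, a gene annotation, the as-built
#' promoters, and a ground-truth table of every planted motif copy.
#' Genes alternate strands and are placed so that each has its full
#' promoter clear of contig edges; extracting promoters from the emitted
#' genome + annotation with [extract_promoters()] reproduces the built
#' promoters exactly. Deterministic given the config seed.
#'
#' @param config A [sim_config()] object.
#' @return List with elements `genome` (named character vector),
#'   `genes` (annotation `data.frame`: `gene_id`, `contig`, `strand`,
#'   `tss`, `start`, `end`), `promoters` (promoter `data.frame`), and
#'   `truth` (`data.frame`: `gene_id`, `offset`, `strand`, `motif`,
#'   `planted_text`, `n_mutations`, `mutated_positions`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "wbox_sim_config"))
  .with_seed(config$seed, {
    n <- config$n_genes
    gene_ids <- sprintf("g%03d", seq_len(n))
    strands <- rep(c("+", "-"), length.out = n)
    contigs <- rep(sprintf("ctg%02d", seq_len(config$n_contigs)),
                   length.out = n)

    # expand plant spec to per-copy records and deal them to genes
    plant_rows <- list()
    if (!is.null(config$plant_spec) && nrow(config$plant_spec) > 0L) {
      rr <- 0L
      for (i in seq_len(nrow(config$plant_spec))) {
        e <- config$plant_spec[i, ]
        for (cp in seq_len(e$copies)) {
          if (!is.null(config$plant_spec$gene) && !is.na(e$gene)) {
            g <- as.integer(e$gene)
          } else {
            rr <- rr + 1L
            g <- ((rr - 1L) %% n) + 1L
          }
          strand <- as.character(e$strand)
          if (strand == "random") strand <- .sample_from(c("+", "-"))
          mut <- .mutate_motif(toupper(e$motif), as.integer(e$mismatches),
                               config$core, config$trim_margin)
          plant_rows[[length(plant_rows) + 1L]] <- data.frame(
            gene = g, motif = toupper(e$motif), text = mut$text,
            strand = strand, n_mutations = as.integer(e$mismatches),
            mutated_positions = paste(mut$positions, collapse = ","),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    plants_all <- if (length(plant_rows) > 0L) do.call(rbind, plant_rows)
                  else data.frame(gene = integer(0), motif = character(0),
                                  text = character(0), strand = character(0),
                                  n_mutations = integer(0),
                                  mutated_positions = character(0),
                                  stringsAsFactors = FALSE)

    prom_seqs <- character(n)
    truth <- list()
    for (g in seq_len(n)) {
      pl <- plants_all[plants_all$gene == g, , drop = FALSE]
      built <- .build_promoter(config$promoter_len, pl, config)
      prom_seqs[g] <- built$sequence
      if (nrow(built$plants) > 0L) {
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = gene_ids[g], offset = built$plants$offset,
          strand = built$plants$strand, motif = built$plants$motif,
          planted_text = built$plants$text,
          n_mutations = built$plants$n_mutations,
          mutated_positions = built$plants$mutated_positions,
          stringsAsFactors = FALSE
        )
      }
    }
    truth <- if (length(truth) > 0L) do.call(rbind, truth)
             else data.frame(gene_id = character(0), offset = integer(0),
                             strand = character(0), motif = character(0),
                             planted_text = character(0),
                             n_mutations = integer(0),
                             mutated_positions = character(0),
                             stringsAsFactors = FALSE)

    # assemble contigs: [spacer] promoter/body per gene [spacer]
    genome <- stats::setNames(rep("", config$n_contigs),
                              sprintf("ctg%02d", seq_len(config$n_contigs)))
    ann <- data.frame(gene_id = gene_ids, contig = contigs, strand = strands,
                      tss = NA_integer_, start = NA_integer_,
                      end = NA_integer_, stringsAsFactors = FALSE)
    for (g in seq_len(n)) {
      ctg <- contigs[g]
      cur <- genome[[ctg]]
      cur <- paste0(cur, .rand_dna(config$spacer, config$background))
      body <- .rand_dna(config$gene_len, config$background)
      if (strands[g] == "+") {
        cur <- paste0(cur, prom_seqs[g])
        tss <- nchar(cur) + 1L
        cur <- paste0(cur, body)
        ann$start[g] <- tss
        ann$end[g] <- tss + config$gene_len - 1L
      } else {
        cur <- paste0(cur, body)
        tss <- nchar(cur)
        cur <- paste0(cur, reverse_complement(prom_seqs[g]))
        ann$start[g] <- tss - config$gene_len + 1L
        ann$end[g] <- tss
      }
      ann$tss[g] <- tss
      genome[[ctg]] <- cur
    }

    promoters <- data.frame(gene_id = gene_ids, sequence = prom_seqs,
                            length = nchar(prom_seqs),
                            truncated = nchar(prom_seqs) < config$promoter_len,
                            stringsAsFactors = FALSE)
    list(genome = genome, genes = ann, promoters = promoters, truth = truth)
  })
}

#' Write a simulated genome as FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @param width Line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(genome)) {
    writeLines(paste0(">", id), con)
    s <- genome[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a gene annotation as GFF3
#'
#' @param genes Annotation `data.frame` from [simulate_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\twboxscan_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$contig, genes$start, genes$end, genes$strand,
                     genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate an ipTM score table
#'
#' Draws one uniform ipTM value per gene from `[lo, hi]`; `lo`/`hi` are
#' recycled over genes, so mixed specs (some genes guaranteed above a
#' threshold, some below) are a single call.
#'
#' @param gene_ids Character vector of gene ids.
#' @param lo,hi Lower/upper bounds in [0,1], recycled over `gene_ids`.
#' @param seed Integer seed; required.
#' @return `data.frame` with columns `gene_id`, `iptm`.
#' @export
simulate_iptm <- function(gene_ids, lo = 0.8, hi = 0.9, seed) {
  if (missing(seed)) stop("`seed` must be given explicitly")
  lo <- rep_len(lo, length(gene_ids))
  hi <- rep_len(hi, length(gene_ids))
  if (any(lo < 0) || any(hi > 1) || any(lo > hi)) {
    stop("ipTM bounds must satisfy 0 <= lo <= hi <= 1")
  }
  vals <- .with_seed(seed, stats::runif(length(gene_ids), lo, hi))
  data.frame(gene_id = gene_ids, iptm = vals, stringsAsFactors = FALSE)
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Target-gene Ct values follow `ct = baseline - log2(fold) + noise`,
#' so [ddct()] recovers the configured fold changes exactly at zero
#' noise. The reference gene is constant across samples up to noise.
#'
#' @param true_folds `data.frame` with columns `sample`, `gene`, `fold`
#'   (fold changes relative to the calibrator; calibrator rows should be
#'   1).
#' @param reference_gene Reference gene name (default `"GAPDH"`).
#' @param n_reps Replicates per (sample, gene) (default 3).
#' @param baseline_ct Baseline target Ct (default 24).
#' @param ref_ct Reference-gene Ct (default 18).
#' @param noise_sd Gaussian Ct noise sd (default 0.2).
#' @param seed Integer seed; required.
#' @return List with `ct` (Ct `data.frame`: `sample`, `gene`,
#'   `replicate`, `ct`) and `truth` (the `true_folds` input).
#' @export
simulate_ct <- function(true_folds, reference_gene = "GAPDH", n_reps = 3L,
                        baseline_ct = 24, ref_ct = 18, noise_sd = 0.2, seed) {
  if (missing(seed)) stop("`seed` must be given explicitly")
  need <- c("sample", "gene", "fold")
  if (!all(need %in% names(true_folds))) {
    stop("`true_folds` needs columns: ", paste(need, collapse = ", "))
  }
  if (any(true_folds$fold <= 0)) stop("fold changes must be positive")
  .with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(true_folds))) {
      mu <- baseline_ct - log2(true_folds$fold[i])
      rows[[length(rows) + 1L]] <- data.frame(
        sample = true_folds$sample[i], gene = true_folds$gene[i],
        replicate = seq_len(n_reps),
        ct = mu + stats::rnorm(n_reps, 0, noise_sd),
        stringsAsFactors = FALSE
      )
    }
    for (s in unique(true_folds$sample)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, gene = reference_gene, replicate = seq_len(n_reps),
        ct = ref_ct + stats::rnorm(n_reps, 0, noise_sd),
        stringsAsFactors = FALSE
      )
    }
    list(ct = do.call(rbind, rows), truth = true_folds)
  })
}
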