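# Synthetic-data generator: determinism and ground-truth fidelity.

test_that("the generator is byte-deterministic given the seed", {
  ps <- data.frame(motif = "TTGACC", copies = 4L, mismatches = 0L,
                   strand = "random")
  cfg <- sim_config(seed = 77, n_genes = 6L, promoter_len = 400L,
                    plant_spec = ps)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a, b)

  fa1 <- withr::local_tempfile(fileext = ".fa")
  fa2 <- withr::local_tempfile(fileext = ".fa")
  gf1 <- withr::local_tempfile(fileext = ".gff3")
  gf2 <- withr::local_tempfile(fileext = ".gff3")
  write_genome_fasta(a$genome, fa1); write_genome_fasta(b$genome, fa2)
  write_gff3(a$genes, gf1); write_gff3(b$genes, gf2)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_identical(readLines(gf1), readLines(gf2))

  c2 <- simulate_genome(sim_config(seed = 78, n_genes = 6L,
                                   promoter_len = 400L, plant_spec = ps))
  expect_false(identical(a$genome, c2$genome))
})

test_that("every ground-truth record matches the emitted promoter text", {
  ps <- data.frame(motif = c("TTGACC", rand_motif()),
                   copies = c(5L, 5L), mismatches = c(0L, 2L),
                   strand = c("random", "random"))
  set.seed(1)  # rand_motif above
  sim <- simulate_genome(sim_config(seed = 17, n_genes = 8L,
                                    promoter_len = 600L, plant_spec = ps))
  expect_equal(nrow(sim$truth), 10L)
  pseq <- setNames(sim$promoters$sequence, sim$promoters$gene_id)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    w <- nchar(tr$planted_text)
    emitted <- substr(pseq[[tr$gene_id]], tr$offset + 1L, tr$offset + w)
    want <- if (tr$strand == "+") tr$planted_text
            else oracle_revcomp(tr$planted_text)
    expect_identical(emitted, want)
    # mutated positions really differ from the source motif, others do not
    mut <- if (nzchar(tr$mutated_positions)) {
      as.integer(strsplit(tr$mutated_positions, ",")[[1]])
    } else integer(0)
    diffs <- which(strsplit(tr$planted_text, "")[[1]] !=
                   strsplit(tr$motif, "")[[1]])
    expect_identical(diffs, mut)
    expect_equal(length(mut), tr$n_mutations)
  }
})

test_that("promoters extracted from the emitted files equal the built ones", {
  ps <- data.frame(motif = "TTGACT", copies = 6L, mismatches = 0L,
                   strand = "+")
  sim <- simulate_genome(sim_config(seed = 23, n_genes = 6L,
                                    promoter_len = 500L, plant_spec = ps))
  fa <- withr::local_tempfile(fileext = ".fa")
  gf <- withr::local_tempfile(fileext = ".gff3")
  write_genome_fasta(sim$genome, fa)
  write_gff3(sim$genes, gf)
  genome <- load_genome(fa)
  genes <- load_annotation(gf)
  prom <- extract_promoters(genome, genes, length = 500L)
  prom <- prom[match(sim$promoters$gene_id, prom$gene_id), ]
  expect_identical(prom$sequence, sim$promoters$sequence)
  expect_false(any(prom$truncated))
})

test_that("scanning recovers exactly the planted cores when background is scrubbed", {
  ps <- data.frame(motif = "TTGACC", copies = 10L, mismatches = 0L,
                   strand = "+")
  sim <- simulate_genome(sim_config(seed = 42, n_genes = 10L,
                                    plant_spec = ps))
  sites <- scan_wbox(sim$promoters)
  expect_equal(nrow(sites), 10L)
  got <- sort(paste(sites$gene_id, sites$offset, sites$strand))
  want <- sort(paste(sim$truth$gene_id, sim$truth$offset, sim$truth$strand))
  expect_identical(got, want)
})

test_that("mismatch-graded plantings split at the matcher's budget", {
  motif <- "ACGTTTGACCGTATGCA"
  ps <- data.frame(motif = motif, copies = 1L, mismatches = 0:4,
                   strand = "+", gene = 1:5)
  sim <- simulate_genome(sim_config(seed = 99, n_genes = 5L,
                                    promoter_len = 800L, plant_spec = ps))
  params <- match_params(evalue_max = 1e9,
                         background = c(A = 0.32, C = 0.18, G = 0.18, T = 0.32))
  tg <- collect_targets(motif, sim$promoters, params)
  planted_ok <- sim$truth$gene_id[sim$truth$n_mutations <= 2L]
  # with a permissive E-value, exactly the <=2-mismatch genes survive the
  # mismatch budget at spans covering the mutation zone; >2-mismatch genes
  # must not be reported at any span covering their planted copy
  expect_true(all(planted_ok %in% tg$gene_id))
  over <- sim$truth[sim$truth$n_mutations > 2L, ]
  for (i in seq_len(nrow(over))) {
    g <- tg[tg$gene_id == over$gene_id[i], ]
    if (nrow(g) == 0L) next
    # any surviving hit must be a chance background hit, not the planting
    expect_false(g$start <= over$offset[i] + 6L &&
                 g$end >= over$offset[i] + 11L)
  }
})

test_that("simulated ipTM tables honour their bounds", {
  ids <- sprintf("g%02d", 1:20)
  hi_tab <- simulate_iptm(ids, lo = 0.8, hi = 0.9, seed = 3)
  expect_true(all(hi_tab$iptm >= 0.8 & hi_tab$iptm <= 0.9))
  lo_tab <- simulate_iptm(ids, lo = 0.0, hi = 0.5, seed = 3)
  expect_true(all(lo_tab$iptm < 0.8))

  # mixed spec: pass count equals the ground-truth count
  lo <- rep(c(0.85, 0.1), each = 10)
  hi <- rep(c(0.95, 0.5), each = 10)
  mixed <- simulate_iptm(ids, lo = lo, hi = hi, seed = 4)
  expect_equal(sum(mixed$iptm >= 0.8), 10L)

  expect_error(simulate_iptm(ids, lo = -0.1, hi = 0.5, seed = 1), "bounds")
  expect_error(simulate_iptm(ids, lo = 0.2, hi = 1.2, seed = 1), "bounds")
})

test_that("mutated plantings never create new W-box cores", {
  set.seed(7)
  for (rep in 1:20) {
    motif <- rand_motif()
    mut <- wboxscan:::.mutate_motif(motif, 3L, "TTGAC[CT]", 6L)
    orig <- wboxscan:::.core_positions(motif)
    new <- wboxscan:::.core_positions(mut$text)
    expect_true(all(new %in% orig))
    expect_true(all(mut$positions >= 7L & mut$positions <= 11L))
  }
})
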