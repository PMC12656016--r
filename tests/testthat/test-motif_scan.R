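# W-box core scanning, window extension and frequency ranking.

test_that("scan_wbox finds forced occurrences with correct coordinates", {
  p <- c(g1 = "AAATTGACCAAA")
  s <- scan_wbox(p)
  expect_equal(nrow(s), 1L)
  expect_equal(s$offset, 3L)
  expect_identical(s$strand, "+")
  expect_identical(s$core, "TTGACC")

  p <- c(g1 = "AAGGTCAAAA")
  s <- scan_wbox(p)
  expect_equal(nrow(s), 1L)
  expect_equal(s$offset, 2L)
  expect_identical(s$strand, "-")
  expect_identical(s$core, "TTGACC")  # motif orientation

  expect_equal(nrow(scan_wbox(c(g1 = "AAAAAAAAAA"))), 0L)
  # N never matches
  expect_equal(nrow(scan_wbox(c(g1 = "AATTGACNAA"))), 0L)
  # overlapping occurrences all reported
  s <- scan_wbox(c(g1 = "TTGACTTGACC"))
  expect_true(all(c(0L, 5L) %in% s$offset))
})

test_that("scan matches the brute-force double-strand oracle", {
  set.seed(101)
  bg <- c(A = 0.32, C = 0.18, G = 0.18, T = 0.32)
  for (rep in 1:20) {
    seq <- rand_dna(sample(100:400, 1), bg)
    got <- scan_wbox(c(g = seq))
    want <- oracle_scan(seq)
    expect_identical(sort(paste(got$offset, got$strand)),
                     sort(paste(want$offset, want$strand)))
  }
})

test_that("scanning the reverse complement mirrors sites and swaps strands", {
  set.seed(111)
  for (rep in 1:10) {
    seq <- rand_dna(sample(100:300, 1))
    L <- nchar(seq)
    a <- scan_wbox(c(g = seq))
    b <- scan_wbox(c(g = reverse_complement(seq)))
    # a "+" site at offset o maps to a "-" site at L - o - 6 and vice versa
    mapped <- paste(L - b$offset - 6L, ifelse(b$strand == "+", "-", "+"))
    expect_identical(sort(paste(a$offset, a$strand)), sort(mapped))
  }
})

test_that("extended windows have the designed geometry and padding", {
  set.seed(121)
  p <- rand_dna(100)
  p <- plant_at(p, 10L, "TTGACC")
  sites <- data.frame(gene_id = "g", offset = 10L, strand = "+")
  w <- extend_site(sites, c(g = p))
  expect_identical(w, substr(p, 7, 23))   # 4 bases upstream, 17 total
  expect_equal(nchar(w), 17L)
  expect_identical(substr(w, 5, 10), "TTGACC")

  # core at offset 0: left-padded with 4 N's
  p0 <- plant_at(rand_dna(60), 0L, "TTGACT")
  w0 <- extend_site(data.frame(gene_id = "g", offset = 0L, strand = "+"),
                    c(g = p0))
  expect_identical(substr(w0, 1, 4), "NNNN")
  expect_identical(substr(w0, 5, 10), "TTGACT")

  # core at the right edge: right-padded
  pe <- plant_at(rand_dna(30), 24L, "TTGACC")
  we <- extend_site(data.frame(gene_id = "g", offset = 24L, strand = "+"),
                    c(g = pe))
  expect_equal(nchar(we), 17L)
  expect_identical(substr(we, 11, 17), "NNNNNNN")

  expect_error(extend_site(sites, c(g = p), window_len = 8L),
               "window_len")
})

test_that("minus-strand windows read the core in motif orientation", {
  set.seed(131)
  p <- rand_dna(80)
  p <- plant_at(p, 40L, "GGTCAA")   # revcomp of TTGACC on the written strand
  s <- scan_wbox(c(g = p))
  s <- s[s$offset == 40L & s$strand == "-", ]
  expect_equal(nrow(s), 1L)
  expect_identical(substr(s$window, 5, 10), "TTGACC")
  # the window is a subsequence of the reverse-complemented promoter
  expect_true(grepl(s$window, reverse_complement(p), fixed = TRUE))
})

test_that("rank_motifs sorts by count with lexicographic ties and caps at k", {
  sites <- data.frame(window = c(rep("CCC", 5), rep("TTT", 3), rep("AAA", 3)))
  r <- rank_motifs(sites, k = 2)
  expect_identical(r$window, c("CCC", "AAA"))
  expect_identical(r$count, c(5L, 3L))
  expect_identical(r$rank, 1:2)

  # 25 distinct windows -> exactly 20 back
  sites <- data.frame(window = sprintf("W%02d", 1:25))
  expect_equal(nrow(rank_motifs(sites, k = 20)), 20L)

  # degenerate: fewer distinct windows than k
  sites <- data.frame(window = sprintf("W%d", 1:7))
  expect_warning(r <- rank_motifs(sites, k = 20), "7 distinct")
  expect_equal(nrow(r), 7L)

  expect_error(rank_motifs(sites, k = 0), "positive")
})

test_that("N-containing windows only fill ranks after N-free ones", {
  sites <- data.frame(window = c(rep("NNACG", 10), "TGCAT", "GGGGG"))
  r <- rank_motifs(sites, k = 2)
  expect_identical(r$window, c("GGGGG", "TGCAT"))
  r3 <- rank_motifs(sites, k = 3)
  expect_identical(r3$window[3], "NNACG")
})

test_that("top-k ranking is stable under removal of lower-ranked windows", {
  set.seed(141)
  counts <- c(9L, 7L, 7L, 5L, 4L, 2L, 1L)
  wins <- sprintf("M%d", 1:7)
  sites <- data.frame(window = rep(wins, counts))
  k <- 4L
  top <- rank_motifs(sites, k)
  dropped <- rank_motifs(sites, k + 1L)$window[k + 1L]
  again <- rank_motifs(sites[sites$window != dropped, , drop = FALSE], k)
  expect_identical(top, again)
  expect_true(sum(top$count) <= nrow(sites))
})

test_that("sites round-trip to BED6 with promoter-relative spans", {
  p <- c(g1 = "AAATTGACCAAAGGTCAAAA")
  s <- scan_wbox(p)
  f <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(s, f)
  bed <- read.table(f, sep = "\t")
  expect_equal(nrow(bed), nrow(s))
  expect_equal(bed$V3 - bed$V2, rep(6L, nrow(bed)))
  expect_identical(bed$V6, s$strand)
})
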