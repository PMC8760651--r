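test_that("SAM parsing converts coordinates, decodes flags and anchors", {
  hdr <- sam_sq(chr1 = 10000L)
  expect_equal(nrow(read_sam(hdr)), 0L)
  expect_error(read_sam("no header"), "header")

  aln <- read_sam(c(hdr,
                    sam_line("r1", 4L, "*", 0L, "*"),
                    sam_line("r2", 16L, "chr1", 101L, "50M",
                             tags = "SA:Z:chr1,101,+,50S150M,60,0;")))
  expect_true(aln$unmapped[1])
  expect_false(aln$unmapped[2])
  expect_true(aln$reverse[2])
  expect_equal(aln$pos[2], 100L)
  anch <- parse_sa_anchors(aln$sa_tag)
  expect_equal(nrow(anch), 1L)
  expect_equal(anch$chrom, "chr1")
  expect_equal(anch$pos, 100L)
  expect_identical(anch$cigar, "50S150M")

  expect_error(read_sam(c(hdr, "r3\t0\tchr1")), "malformed.*line 1")
})

test_that("split-junction calling implements the wrap-around rule with support threshold", {
  hdr <- sam_sq(chr1 = 10000L)
  mk <- function(n, ...) {
    unlist(lapply(seq_len(n), function(i)
      split_read_lines(paste0("q", i, "_", paste(c(...), collapse = "")),
                       "chr1", 300L, 7000L, ...)))
  }
  # five wrap-around reads at identical breakpoints -> one junction
  aln5 <- read_sam(c(hdr, mk(5)))
  j <- call_split_junctions(aln5, min_split = 5)
  expect_equal(nrow(j), 1L)
  expect_equal(j$start, 300L)
  expect_equal(j$end, 7000L)
  expect_equal(j$support, 5L)
  # four reads are below "at least five"
  expect_equal(nrow(call_split_junctions(read_sam(c(hdr, mk(4))),
                                         min_split = 5)), 0L)
  # colinear (deletion-signature) splits never count
  expect_equal(nrow(call_split_junctions(
    read_sam(c(hdr, mk(8, colinear = TRUE))), min_split = 1)), 0L)
  # minus-strand junction reads carry the same signature
  jm <- call_split_junctions(read_sam(c(hdr, mk(5, strand = "-"))), min_split = 5)
  expect_equal(nrow(jm), 1L)
  expect_equal(c(jm$start, jm$end), c(300L, 7000L))
  # mixed-strand segment pairs are not circular evidence
  mixed <- split_read_lines("qx", "chr1", 300L, 7000L)
  mixed[1] <- sub("SA:Z:chr1,301,\\+", "SA:Z:chr1,301,-", mixed[1])
  expect_equal(nrow(call_split_junctions(read_sam(c(hdr, rep(mixed, 5))),
                                         min_split = 1)), 0L)
})

test_that("split junctions pool nearby breakpoints and ignore record order", {
  hdr <- sam_sq(chr1 = 10000L)
  lines <- unlist(lapply(1:6, function(i)
    split_read_lines(paste0("p", i), "chr1", 300L + (i %% 3L), 7000L - (i %% 2L),
                     frac = 0.3 + 0.05 * i)))
  aln <- read_sam(c(hdr, lines))
  j1 <- call_split_junctions(aln, min_split = 5, breakpoint_tolerance = 5)
  expect_equal(nrow(j1), 1L)
  expect_equal(j1$support, 6L)
  expect_true(abs(j1$start - 301L) <= 5 && abs(j1$end - 6999L) <= 5)
  # permutation invariance
  perm <- aln[sample.int(nrow(aln)), ]
  data.table::setattr(perm, "seqlengths", attr(aln, "seqlengths"))
  j2 <- call_split_junctions(perm, min_split = 5, breakpoint_tolerance = 5)
  expect_equal(j1, j2)
  # far-apart breakpoints do not pool
  far <- c(lines, unlist(lapply(1:5, function(i)
    split_read_lines(paste0("f", i), "chr1", 1000L, 5000L))))
  jf <- call_split_junctions(read_sam(c(hdr, far)), min_split = 5)
  expect_equal(nrow(jf), 2L)
})

test_that("discordant pairs are detected from flags, distance and orientation", {
  hdr <- sam_sq(chr1 = 100000L, chr2 = 50000L)
  # proper-pair flag unset, mates 50 kb apart -> one region spanning both
  d <- call_discordant_regions(read_sam(c(hdr,
    pair_lines("d1", "chr1", 1000L, 51000L, proper = FALSE))), max_insert = 1000)
  expect_equal(nrow(d), 1L)
  expect_equal(c(d$start, d$end, d$pair_count), c(1000L, 51100L, 1L))

  # all-proper input -> empty
  ok <- c(pair_lines("p1", "chr1", 1000L, 1400L),
          pair_lines("p2", "chr1", 2000L, 2350L))
  expect_equal(nrow(call_discordant_regions(read_sam(c(hdr, ok)),
                                            max_insert = 1000)), 0L)

  # outward-facing orientation is discordant even with the proper bit set
  out <- pair_lines("o1", "chr1", 5000L, 5400L, rev1 = TRUE, rev2 = FALSE)
  expect_equal(nrow(call_discordant_regions(read_sam(c(hdr, out)),
                                            max_insert = 1000)), 1L)

  # cross-chromosome pairs count as discordant but add no interval
  xc <- pair_lines("x1", "chr1", 100L, 200L, chrom2 = "chr2", proper = FALSE)
  expect_equal(nrow(call_discordant_regions(read_sam(c(hdr, xc)),
                                            max_insert = 1000)), 0L)
})

test_that("overlapping discordant spans merge like a brute-force interval union", {
  hdr <- sam_sq(chr1 = 100000L)
  two <- c(pair_lines("m1", "chr1", 1000L, 3000L, proper = FALSE),
           pair_lines("m2", "chr1", 2500L, 4500L, proper = FALSE))
  d <- call_discordant_regions(read_sam(c(hdr, two)), max_insert = 10000)
  expect_equal(nrow(d), 1L)
  expect_equal(d$pair_count, 2L)
  expect_equal(c(d$start, d$end), c(1000L, 4600L))

  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    s <- sort(sample(0:5000, n))
    e <- s + sample(200:2500, n, replace = TRUE)
    lines <- unlist(lapply(seq_len(n), function(i)
      pair_lines(paste0("r", i), "chr1", s[i], e[i] - 100L, proper = FALSE)))
    d <- call_discordant_regions(read_sam(c(hdr, lines)), max_insert = 1e6)
    want <- oracle_interval_union(s, e, 100000L)
    expect_equal(d$start, want$start)
    expect_equal(d$end, want$end)
  }
})

test_that("coverage counts reference-consuming bases of primary and supplementary records", {
  hdr <- sam_sq(chr1 = 1000L)
  cov <- compute_coverage(read_sam(c(hdr, sam_line("c1", 0L, "chr1", 11L, "100M"))))
  # 0-based [10, 110) -> R indices 11..110
  expect_equal(cov$depth$chr1[10:111], c(0, rep(1, 100), 0))
  expect_equal(sum(cov$depth$chr1), 100)
  expect_equal(cov$total_aligned_bases, 100)

  empty <- compute_coverage(read_sam(sam_sq(chr1 = 1000L)))
  expect_true(all(empty$depth$chr1 == 0))
  expect_equal(empty$total_aligned_bases, 0)

  # soft clips consume no reference; supplementary counted, secondary not
  mix <- read_sam(c(hdr,
                    sam_line("s1", 0L, "chr1", 1L, "40S60M"),
                    sam_line("s1", 2048L, "chr1", 101L, "60S40M"),
                    sam_line("s2", 256L, "chr1", 501L, "100M")))
  cov2 <- compute_coverage(mix)
  expect_equal(sum(cov2$depth$chr1), 100)
  expect_equal(cov2$depth$chr1[501], 0)

  expect_error(compute_coverage(read_sam(c(hdr,
    sam_line("over", 0L, "chr1", 950L, "100M")))), "beyond chromosome end")

  # brute-force per-base recount on random alignment sets
  set.seed(17)
  for (rep in 1:15) {
    n <- sample(1:30, 1)
    st <- sample(0:800, n, replace = TRUE)
    ln <- sample(20:150, n, replace = TRUE)
    lines <- vapply(seq_len(n), function(i)
      sam_line(paste0("r", i), 0L, "chr1", st[i] + 1L,
               sprintf("%dM", ln[i])), character(1))
    cov <- compute_coverage(read_sam(c(sam_sq(chr1 = 1000L), lines)))
    expect_equal(cov$depth$chr1, oracle_coverage(st, st + ln, 1000L))
  }
})

test_that("BPM normalization conserves one million and is depth-scale invariant", {
  hdr <- sam_sq(chr1 = 1000L)
  one <- read_sam(c(hdr, sam_line("a", 0L, "chr1", 101L, "80M")))
  bpm <- normalize_bpm(compute_coverage(one))
  expect_equal(sum(bpm$depth$chr1), 1e6, tolerance = 1e-9)
  expect_equal(unique(bpm$depth$chr1[101:180]), 1e6 / 80)

  dbl <- read_sam(c(hdr, sam_line("a", 0L, "chr1", 101L, "80M"),
                    sam_line("b", 0L, "chr1", 101L, "80M")))
  bpm2 <- normalize_bpm(compute_coverage(dbl))
  expect_equal(bpm$depth$chr1, bpm2$depth$chr1, tolerance = 1e-12)

  expect_error(normalize_bpm(compute_coverage(read_sam(hdr))), "no aligned bases")
})

test_that("BPM makes different read lengths comparable on the same template", {
  # same template, same base throughput, read lengths 100 vs 200
  tpl_cfg1 <- tiny_sim_config(seed = 61, n_chromosomes = 1L,
                              total_ref_length = 30000L,
                              element_length = 2000L, read_length = 100L,
                              n_pairs_circ = 4000L, n_pairs_control = 10L,
                              error_rate = 0, enrichment_fraction = 0)
  tpl_cfg2 <- tiny_sim_config(seed = 61, n_chromosomes = 1L,
                              total_ref_length = 30000L,
                              element_length = 2000L, read_length = 200L,
                              n_pairs_circ = 2000L, n_pairs_control = 10L,
                              error_rate = 0, enrichment_fraction = 0)
  bpm_of <- function(cfg) {
    sim <- simulate_circseq(cfg)
    aln <- read_sam(write_oracle_sam(sim$genome, sim$circ_pairs, tempfile()))
    normalize_bpm(compute_coverage(aln))
  }
  b1 <- bpm_of(tpl_cfg1); b2 <- bpm_of(tpl_cfg2)
  m1 <- mean(b1$depth$chr1[5000:25000])
  m2 <- mean(b2$depth$chr1[5000:25000])
  expect_lt(abs(m1 - m2) / m2, 0.10)
})

test_that("error-free simulated splits recover the ground-truth interval exactly", {
  cfg <- tiny_sim_config(seed = 37, error_rate = 0, n_pairs_circ = 2000L,
                         n_pairs_control = 50L)
  sim <- simulate_circseq(cfg)
  aln <- read_sam(write_oracle_sam(sim$genome, sim$circ_pairs, tempfile()))
  j <- call_split_junctions(aln, min_split = 5, breakpoint_tolerance = 5)
  expect_gt(nrow(j), 0L)
  expect_true(all(abs(j$start - sim$truth$start) <= 5))
  expect_true(all(abs(j$end - sim$truth$end) <= 5))
})

test_that("peak detection matches the stated examples", {
  mk_track <- function(x) structure(list(depth = list(chr1 = x),
                                         total_aligned_bases = sum(x),
                                         normalized = TRUE),
                                    class = "ecc_coverage")
  expect_equal(nrow(find_peaks(mk_track(rep(2, 500)))), 0L)

  x <- rep(0.5, 400); x[101:200] <- 5
  p <- find_peaks(mk_track(x))
  expect_equal(nrow(p), 1L)
  expect_equal(p$prominence, 4.5)
  expect_equal(c(p$start, p$end), c(100L, 200L))

  y <- rep(1, 300); y[150:160] <- 1.5
  expect_equal(nrow(find_peaks(mk_track(y), min_prominence = 1)), 0L)
  expect_equal(nrow(find_peaks(mk_track(y), min_prominence = 0.5)), 1L)
})

test_that("peak detection agrees with the brute-force prominence oracle", {
  set.seed(23)
  for (rep in 1:40) {
    n <- sample(50:800, 1)
    x <- round(cumsum(rnorm(n)), 1)
    x[x < 0] <- 0
    got <- eccscout:::cpp_find_peaks(x, 1.0)
    want <- oracle_peaks(x, 1.0)
    expect_equal(got$apex, want$apex)
    expect_equal(got$prominence, want$prominence)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})
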