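write_pair_fastq <- function(dir, stem, n, len = 100L, seqs = NULL) {
  if (is.null(seqs)) seqs <- vapply(seq_len(n), function(i) rand_dna(len),
                                    character(1))
  r1 <- file.path(dir, paste0(stem, "_1.fastq"))
  r2 <- file.path(dir, paste0(stem, "_2.fastq"))
  nm <- sprintf("%s%04d", stem, seq_len(n))
  eccscout:::write_fastq(paste0(nm, "/1"), seqs, r1)
  eccscout:::write_fastq(paste0(nm, "/2"), revcomp_chr(seqs), r2)
  c(r1, r2)
}

test_that("read preparation subsamples, prefixes, equalizes and interlaces", {
  d <- tempfile("prep_"); dir.create(d)
  set.seed(41)
  circ <- write_pair_fastq(d, "c", 10L, len = 101L)
  ctrl <- write_pair_fastq(d, "k", 10L, len = 96L)
  prep <- prepare_reads(circ, ctrl, sample_pairs = 5L, seed = 3L)
  expect_equal(nrow(prep), 20L)
  expect_equal(sum(prep$dataset == "circ"), 10L)
  expect_equal(attr(prep, "equalized_length"), 96L)
  expect_true(all(nchar(prep$seq) == 96L))
  expect_true(all(grepl("^(CIRC|CTRL)_", prep$name)))
  expect_true(all(grepl("/[12]$", prep$name)))
  # interlaced: circ pair block then ctrl pair block
  expect_identical(prep$dataset[1:4], c("circ", "circ", "ctrl", "ctrl"))
  # mate partners resolve
  expect_true(all(prep$mate_partner %in% prep$name))

  w <- capture_warnings(prepare_reads(circ, ctrl, sample_pairs = 50L, seed = 1L))
  expect_match(w, "only", all = TRUE)
  expect_length(w, 2L)
  empty <- file.path(d, "empty.fastq"); writeLines(character(0), empty)
  expect_error(prepare_reads(c(empty, empty), ctrl, 5L), "empty input")
})

test_that("clustering groups reads by shared k-mers into connected components", {
  set.seed(51)
  fam1 <- rand_dna(100)
  fam2 <- rand_dna(100)
  mkprep <- function(seqs, datasets) {
    structure(data.frame(name = sprintf("r%03d/1", seq_along(seqs)),
                         seq = seqs, dataset = datasets,
                         mate_partner = sprintf("r%03d/1", seq_along(seqs)),
                         stringsAsFactors = FALSE),
              equalized_length = unique(nchar(seqs))[1],
              class = c("ecc_prepared", "data.frame"))
  }
  # 100 identical reads form a single cluster of 100
  p1 <- mkprep(rep(fam1, 100), rep(c("circ", "ctrl"), 50))
  c1 <- cluster_reads(p1, k = 15, min_shared = 3, min_cluster = 5)
  expect_equal(nrow(c1$clusters), 1L)
  expect_equal(c1$clusters$n_reads, 100L)
  expect_equal(c1$clusters$proportion_circ, 0.5)

  # two unrelated families stay apart
  p2 <- mkprep(c(rep(fam1, 10), rep(fam2, 10)), rep("circ", 20))
  c2 <- cluster_reads(p2, k = 15, min_shared = 3, min_cluster = 5)
  expect_equal(nrow(c2$clusters), 2L)
  expect_equal(sort(c2$clusters$n_reads), c(10L, 10L))

  # similarity chain a-b, b-c joins a and c transitively
  a <- paste0(rand_dna(60), substr(fam1, 1, 40))
  b <- fam1
  cc <- paste0(substr(fam1, 61, 100), rand_dna(60))
  p3 <- mkprep(c(rep(a, 3), rep(b, 3), rep(cc, 3)), rep("circ", 9))
  c3 <- cluster_reads(p3, k = 15, min_shared = 3, min_cluster = 5)
  expect_equal(nrow(c3$clusters), 1L)
  expect_equal(c3$clusters$n_reads, 9L)

  # reverse-complement reads share canonical k-mers
  p4 <- mkprep(c(rep(fam1, 5), rep(revcomp_chr(fam1), 5)), rep("circ", 10))
  c4 <- cluster_reads(p4, k = 15, min_shared = 3, min_cluster = 5)
  expect_equal(nrow(c4$clusters), 1L)

  expect_error(cluster_reads(p1, k = 200), "equalized")
})

test_that("cluster components match a brute-force all-pairs oracle", {
  set.seed(53)
  for (rep in 1:8) {
    base <- replicate(3, rand_dna(80))
    n <- 18L
    seqs <- vapply(seq_len(n), function(i) {
      b <- base[[sample.int(3, 1)]]
      s <- mutate_seq(b, 0.02)
      if (runif(1) < 0.3) revcomp_chr(s) else s
    }, character(1))
    prep <- structure(data.frame(name = sprintf("r%02d/1", 1:n), seq = seqs,
                                 dataset = "circ",
                                 mate_partner = sprintf("r%02d/1", 1:n),
                                 stringsAsFactors = FALSE),
                      equalized_length = 80L,
                      class = c("ecc_prepared", "data.frame"))
    got <- cluster_reads(prep, k = 13, min_shared = 4, min_cluster = 1)
    want <- oracle_components(seqs, k = 13, min_shared = 4)
    # same partition: compare co-membership matrices
    got_member <- rep(NA_character_, n)
    for (id in names(got$members)) got_member[got$members[[id]]] <- id
    co_got <- outer(got_member, got_member, "==")
    co_want <- outer(want, want, "==")
    expect_identical(co_got, co_want)
  }
})

test_that("candidate cluster selection is strictly greater than the proportion cutoff", {
  cl <- list(clusters = data.frame(
    id = c("CL001", "CL002", "CL003"),
    n_reads = c(100L, 100L, 50L),
    count_circ = c(90L, 80L, 0L),
    count_ctrl = c(10L, 20L, 50L),
    proportion_circ = c(0.9, 0.8, 0)))
  class(cl) <- "ecc_clusters"
  expect_identical(select_candidate_clusters(cl, 0.8), "CL001")
  expect_identical(select_candidate_clusters(cl, 0.79), c("CL001", "CL002"))
})

test_that("proportion depends only on dataset tags, not read names", {
  set.seed(59)
  fam <- rand_dna(90)
  mk <- function(names) structure(
    data.frame(name = names, seq = rep(fam, 20),
               dataset = rep(c("circ", "ctrl"), c(15, 5)),
               mate_partner = names, stringsAsFactors = FALSE),
    equalized_length = 90L, class = c("ecc_prepared", "data.frame"))
  a <- cluster_reads(mk(sprintf("x%02d", 1:20)), min_shared = 3, min_cluster = 2)
  b <- cluster_reads(mk(sprintf("zz_%02d", 20:1)), min_shared = 3, min_cluster = 2)
  expect_equal(a$clusters$proportion_circ, b$clusters$proportion_circ)
  expect_equal(a$clusters$proportion_circ, 0.75)
})

test_that("superclusters join clusters bridged by enough mate pairs", {
  # two read families; mates bridge family A and family B for 5 pairs
  set.seed(61)
  famA <- rand_dna(90); famB <- rand_dna(90)
  n <- 10L
  name1 <- sprintf("P%02d/1", 1:n); name2 <- sprintf("P%02d/2", 1:n)
  prep <- structure(
    data.frame(name = c(name1, name2),
               seq = c(rep(famA, n), rep(famB, n)),
               dataset = "circ",
               mate_partner = c(name2, name1), stringsAsFactors = FALSE),
    equalized_length = 90L, class = c("ecc_prepared", "data.frame"))
  cl <- cluster_reads(prep, min_shared = 3, min_cluster = 2)
  expect_equal(nrow(cl$clusters), 2L)
  sc <- link_superclusters(cl, min_mate_links = 2L)
  expect_equal(length(unique(sc$supercluster)), 1L)
  expect_equal(attr(sc, "links")$mate_links, 10L)

  # requiring more links than exist keeps them separate
  sc2 <- link_superclusters(cl, min_mate_links = 11L)
  expect_equal(length(unique(sc2$supercluster)), 2L)

  # chain A-B, B-C collapses into one supercluster
  famC <- rand_dna(90)
  nameB2 <- sprintf("Q%02d/1", 1:n); nameC <- sprintf("Q%02d/2", 1:n)
  prep3 <- structure(
    data.frame(name = c(name1, name2, nameB2, nameC),
               seq = c(rep(famA, n), rep(famB, n), rep(famB, n), rep(famC, n)),
               dataset = "circ",
               mate_partner = c(name2, name1, nameC, nameB2),
               stringsAsFactors = FALSE),
    equalized_length = 90L, class = c("ecc_prepared", "data.frame"))
  cl3 <- cluster_reads(prep3, min_shared = 3, min_cluster = 2)
  expect_equal(nrow(cl3$clusters), 3L)
  sc3 <- link_superclusters(cl3, min_mate_links = 2L)
  expect_equal(length(unique(sc3$supercluster)), 1L)
})

test_that("greedy contig assembly merges overlapping reads in both orientations", {
  set.seed(67)
  # identical reads collapse to one contig equal to the read
  r <- rand_dna(120)
  expect_identical(build_contigs(rep(r, 8)), r)

  # two non-overlapping reads stay separate
  r2 <- rand_dna(120)
  expect_length(build_contigs(c(r, r2)), 2L)

  # error-free tiling at 50% overlap reassembles the template
  tpl <- rand_dna(1000)
  starts <- seq(1L, 901L, by = 50L)
  reads <- substring(tpl, starts, starts + 99L)
  ctg <- build_contigs(sample(reads), min_overlap = 31L)
  expect_equal(length(ctg), 1L)
  expect_true(grepl(ctg[1], tpl, fixed = TRUE) || identical(ctg[1], tpl))
  expect_gte(nchar(ctg[1]), 0.95 * 1000)

  # orientation-aware: half of the reads reverse-complemented
  flip <- seq(2, length(reads), by = 2)
  reads_rc <- reads
  reads_rc[flip] <- revcomp_chr(reads[flip])
  ctg2 <- build_contigs(sample(reads_rc), min_overlap = 31L)
  expect_equal(length(ctg2), 1L)
  expect_true(grepl(ctg2[1], tpl, fixed = TRUE) ||
                grepl(revcomp_chr(ctg2[1]), tpl, fixed = TRUE))
})

test_that("coverage-based sample sizing matches the stated formula", {
  expect_equal(pairs_for_coverage(4, 600000, 200), 6000L)
  expect_equal(pairs_for_coverage(1, 100000, 100), 500L)
})
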