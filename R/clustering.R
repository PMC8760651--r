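read_fastx <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  setNames(as.character(x), sub(" .*", "", names(x)))
}

#' Number of read pairs for a target genome coverage
#'
#' Converts a desired sequencing depth into a clustering subsample size:
#' `coverage * genome_size / (2 * read_length)` pairs.
#'
#' @param coverage Desired fold coverage (e.g. 4).
#' @param genome_size Genome length in bases.
#' @param read_length Read length in bases.
#' @return Integer pair count.
#' @export
pairs_for_coverage <- function(coverage, genome_size, read_length) {
  as.integer(round(coverage * genome_size / (2 * read_length)))
}

#' Prepare circSeq and control reads for comparative clustering
#'
#' Sub-samples the same number of pairs from each dataset (uniformly, without
#' replacement, seeded), prefixes read names with `CIRC_` / `CTRL_` and mate
#' suffixes `/1` / `/2`, truncates every read to the minimum read length in
#' the sample (length equalization, so k-mer statistics are comparable), and
#' interlaces the two datasets pair by pair.
#'
#' @param circ_fastq,ctrl_fastq Character vector of one (interleaved-free
#'   single file per mate) or two FASTQ/FASTA paths (`R1`, `R2`), optionally
#'   gzipped.
#' @param sample_pairs Pairs to draw from each dataset; datasets with fewer
#'   pairs are used in full with a warning.
#' @param seed Integer seed for the subsampling.
#' @return A data.frame of class `ecc_prepared` with columns `name`, `seq`,
#'   `dataset` (`"circ"`/`"ctrl"`), `mate_partner`; attribute
#'   `equalized_length`.
#' @export
prepare_reads <- function(circ_fastq, ctrl_fastq, sample_pairs, seed = 1L) {
  load_pairs <- function(paths, label) {
    reads <- lapply(paths, read_fastx)
    if (any(lengths(reads) == 0L))
      stop("prepare_reads: empty input file for ", label, " dataset")
    if (length(reads) == 2L) {
      if (length(reads[[1L]]) != length(reads[[2L]]))
        stop("prepare_reads: mate files of ", label, " differ in read count")
      list(r1 = reads[[1L]], r2 = reads[[2L]])
    } else {
      # single file: consecutive records are mates
      x <- reads[[1L]]
      if (length(x) %% 2L != 0L)
        stop("prepare_reads: odd read count in interleaved ", label, " file")
      list(r1 = x[seq(1L, length(x), 2L)], r2 = x[seq(2L, length(x), 2L)])
    }
  }
  circ <- load_pairs(circ_fastq, "circSeq")
  ctrl <- load_pairs(ctrl_fastq, "control")

  set.seed(seed)
  take <- function(ps, label) {
    n <- length(ps$r1)
    k <- min(sample_pairs, n)
    if (k < sample_pairs)
      warning("prepare_reads: ", label, " has only ", n, " pairs; using all")
    idx <- sort(sample.int(n, k))
    list(r1 = ps$r1[idx], r2 = ps$r2[idx])
  }
  circ <- take(circ, "circSeq")
  ctrl <- take(ctrl, "control")

  eq <- min(nchar(c(circ$r1, circ$r2, ctrl$r1, ctrl$r2)))
  mk <- function(ps, prefix) {
    base <- paste0(prefix, names(ps$r1))
    data.frame(name = c(rbind(paste0(base, "/1"), paste0(base, "/2"))),
               seq = c(rbind(substr(ps$r1, 1L, eq), substr(ps$r2, 1L, eq))),
               dataset = if (prefix == "CIRC_") "circ" else "ctrl",
               mate_partner = c(rbind(paste0(base, "/2"), paste0(base, "/1"))),
               stringsAsFactors = FALSE)
  }
  a <- mk(circ, "CIRC_")
  b <- mk(ctrl, "CTRL_")
  # interlace circ/ctrl pair blocks
  na <- nrow(a) / 2L; nb <- nrow(b) / 2L
  ord <- order(c(rep(seq_len(na), each = 2L), rep(seq_len(nb), each = 2L) + 0.5))
  out <- rbind(a, b)[ord, , drop = FALSE]
  if (anyDuplicated(out$name))
    stop("prepare_reads: read names are not unique after prefixing")
  rownames(out) <- NULL
  structure(out, equalized_length = eq,
            class = c("ecc_prepared", "data.frame"))
}

#' Comparative read clustering on the shared-k-mer graph
#'
#' Builds an undirected graph over all prepared reads with an edge between
#' two reads iff they share at least `min_shared` distinct canonical
#' (strand-collapsed) k-mers; clusters are the connected components with at
#' least `min_cluster` members. Per-dataset read counts and the circSeq
#' proportion are recorded per cluster.
#'
#' The defaults are scale-aware: `min_shared` of ~0.3x the equalized read
#' length demands roughly half-read overlap between neighbours at a 1%
#' error rate, mirroring the majority-overlap similarity rule of comparative
#' clustering engines (a fixed small value would chain the genomic background
#' into one component at typical 4x clustering coverage), and `min_cluster`
#' of 0.25% of the clustered reads keeps only clusters at the size such
#' engines treat as top clusters.
#'
#' @param prepared An `ecc_prepared` data.frame.
#' @param k K-mer length (default 15, must be < equalized length).
#' @param min_shared Minimum shared canonical k-mers per edge; default
#'   `max(3, round(0.3 * equalized_length))`.
#' @param min_cluster Minimum component size; default
#'   `max(10, round(0.0025 * n_reads))`.
#' @return An `ecc_clusters` object: list with `clusters` (data.frame: `id`,
#'   `n_reads`, `count_circ`, `count_ctrl`, `proportion_circ`), `members`
#'   (list of integer row indices into `reads`), `reads` (the prepared
#'   data.frame), and `contigs` (filled by [build_contigs()]).
#' @export
cluster_reads <- function(prepared, k = 15L, min_shared = NULL, min_cluster = NULL) {
  eq <- attr(prepared, "equalized_length")
  if (k > eq)
    stop("cluster_reads: k exceeds the equalized read length")
  n <- nrow(prepared)
  if (is.null(min_shared)) min_shared <- max(3L, as.integer(round(0.3 * eq)))
  if (is.null(min_cluster)) min_cluster <- max(10L, as.integer(round(0.0025 * n)))

  edges <- cpp_kmer_edges(prepared$seq, as.integer(k), as.integer(min_shared))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  keep <- which(comp$csize >= min_cluster)
  members <- lapply(keep, function(ci) which(comp$membership == ci))
  ord <- order(-lengths(members))
  members <- members[ord]

  cl <- data.frame(
    id = sprintf("CL%03d", seq_along(members)),
    n_reads = lengths(members),
    count_circ = vapply(members, function(ix)
      sum(prepared$dataset[ix] == "circ"), integer(1)),
    count_ctrl = vapply(members, function(ix)
      sum(prepared$dataset[ix] == "ctrl"), integer(1)),
    stringsAsFactors = FALSE)
  cl$proportion_circ <- ifelse(cl$n_reads > 0,
                               cl$count_circ / (cl$count_circ + cl$count_ctrl), 0)
  names(members) <- cl$id
  structure(list(clusters = cl, members = members, reads = prepared,
                 contigs = setNames(vector("list", nrow(cl)), cl$id)),
            class = "ecc_clusters")
}

#' Select candidate clusters by circSeq read proportion
#'
#' Keeps clusters whose circSeq read count proportion is strictly greater
#' than `threshold` (default 0.8, i.e. "more than 80%"): sequences present as
#' circles are over-represented in the enriched circSeq data relative to the
#' control.
#'
#' @param clusters An `ecc_clusters` object.
#' @param threshold Proportion cutoff (default 0.8, strict).
#' @return Character vector of selected cluster ids.
#' @export
select_candidate_clusters <- function(clusters, threshold = 0.8) {
  cl <- clusters$clusters
  cl$id[cl$proportion_circ > threshold]
}

#' Link clusters into superclusters via mate pairs
#'
#' Two clusters are linked when at least `min_mate_links` read pairs have one
#' mate in each; superclusters are the connected components of the resulting
#' cluster graph (a circular element split over several clusters typically
#' re-joins into one supercluster). Unlinked clusters form singletons.
#'
#' @param clusters An `ecc_clusters` object.
#' @param min_mate_links Minimum cross-cluster mate pairs per link (default 2).
#' @return data.frame with `id`, `supercluster`, plus a `links` attribute
#'   (data.frame `cluster1`, `cluster2`, `mate_links`).
#' @export
link_superclusters <- function(clusters, min_mate_links = 2L) {
  cl <- clusters$clusters
  read_cluster <- rep(NA_character_, nrow(clusters$reads))
  for (id in names(clusters$members))
    read_cluster[clusters$members[[id]]] <- id
  partner_idx <- match(clusters$reads$mate_partner, clusters$reads$name)
  a <- read_cluster
  b <- read_cluster[partner_idx]
  # 'a < b' keeps exactly one of the two rows a mate pair contributes
  ok <- !is.na(a) & !is.na(b) & a < b
  links <- data.frame(cluster1 = a[ok], cluster2 = b[ok],
                      stringsAsFactors = FALSE)
  if (nrow(links) > 0L) {
    agg <- as.data.frame(table(links$cluster1, links$cluster2),
                         stringsAsFactors = FALSE)
    names(agg) <- c("cluster1", "cluster2", "mate_links")
    agg <- agg[agg$mate_links >= min_mate_links, , drop = FALSE]
  } else {
    agg <- data.frame(cluster1 = character(0), cluster2 = character(0),
                      mate_links = integer(0))
  }
  g <- igraph::graph_from_data_frame(agg[, 1:2], directed = FALSE,
                                     vertices = cl$id)
  comp <- igraph::components(g)
  sc <- data.frame(id = cl$id,
                   supercluster = sprintf("SC%03d", comp$membership),
                   stringsAsFactors = FALSE)
  attr(sc, "links") <- agg
  sc
}

#' Assemble cluster contigs by greedy overlap layout
#'
#' Repeatedly merges the pair of sequences with the longest exact
#' suffix-prefix overlap of at least `min_overlap` bases, trying both
#' orientations; remaining sequences are emitted as their own contigs,
#' longest first. Clusters larger than `max_reads` are subsampled (seeded)
#' before assembly to bound the quadratic overlap search; at the default
#' coverage this retains far more than enough depth to tile the element.
#'
#' @param clusters An `ecc_clusters` object (or a character vector of
#'   sequences, in which case contigs are returned directly).
#' @param ids Cluster ids to assemble (default: all).
#' @param min_overlap Minimum exact overlap in bases (default 31).
#' @param max_reads Subsample cap per cluster (default 300).
#' @param seed Seed for the subsample.
#' @return The `ecc_clusters` object with `contigs[[id]]` filled (or a
#'   character vector of contigs for raw sequence input).
#' @export
build_contigs <- function(clusters, ids = NULL, min_overlap = 31L,
                          max_reads = 300L, seed = 1L) {
  if (is.character(clusters))
    return(as.character(cpp_greedy_assemble(clusters, as.integer(min_overlap))))
  stopifnot(inherits(clusters, "ecc_clusters"))
  if (is.null(ids)) ids <- clusters$clusters$id
  set.seed(seed)
  for (id in ids) {
    ix <- clusters$members[[id]]
    if (length(ix) > max_reads) ix <- sort(sample(ix, max_reads))
    clusters$contigs[[id]] <-
      as.character(cpp_greedy_assemble(clusters$reads$seq[ix],
                                       as.integer(min_overlap)))
  }
  clusters
}
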