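#' Rotated junction sequence of a candidate region
#'
#' Concatenates the end half of a region sequence with its start half. A
#' contig assembled from reads of a circular template may run across the
#' circular breakpoint; on the linear region sequence such a contig has no
#' contiguous match, but on the rotated sequence it matches across the seam.
#'
#' @param seq Region DNA string.
#' @return List with `seq` (rotated string) and `seam` (0-based position of
#'   the original start coordinate within the rotated sequence).
#' @export
rotate_region_sequence <- function(seq) {
  n <- nchar(seq)
  half <- n %/% 2L
  list(seq = paste0(substr(seq, half + 1L, n), substr(seq, 1L, half)),
       seam = n - half)
}

#' Link candidate clusters to candidate regions
#'
#' Each contig of each candidate cluster is searched (ungapped seed-and-
#' extend, both strands) against every eligible region's sequence and its
#' rotated junction sequence. A match with identity of at least
#' `min_identity` over at least `min_length` bases links the cluster to the
#' region; a rotated-sequence match crossing the seam marks the cluster as
#' junction-spanning. Only high-confidence regions are eligible unless none
#' exist, in which case low-confidence regions are used as fallback.
#'
#' @param clusters An `ecc_clusters` object with contigs built for
#'   `cluster_ids`.
#' @param cluster_ids Candidate cluster ids (from
#'   [select_candidate_clusters()]).
#' @param regions Candidate regions data.frame from [intersect_evidence()].
#' @param genome Named character vector of reference sequences (or an
#'   `ecc_genome`).
#' @param min_identity Minimum match identity (default 0.8).
#' @param min_length Minimum aligned length in bases (default 50).
#' @return List with `links` (data.frame: `region_name`, `cluster_id`,
#'   `contig`, `identity`, `aligned_length`, `spans_junction`) and
#'   `linked_candidates` (data.frame: one row per eligible region with
#'   `linked_clusters`, `junction_spanning_clusters`,
#'   `combined_confidence`).
#' @export
link_clusters_to_regions <- function(clusters, cluster_ids, regions, genome,
                                     min_identity = 0.8, min_length = 50L) {
  if (inherits(genome, "ecc_genome")) genome <- genome$seqs
  elig <- regions[regions$use_in_linking, , drop = FALSE]
  links <- list()
  for (ri in seq_len(nrow(elig))) {
    ch <- elig$chrom[ri]
    if (is.null(genome[[ch]]))
      stop("link_clusters_to_regions: no reference sequence for ", ch)
    rseq <- substr(genome[[ch]], elig$start[ri] + 1L, elig$end[ri])
    rot <- rotate_region_sequence(rseq)
    for (cid in cluster_ids) {
      contigs <- clusters$contigs[[cid]]
      if (is.null(contigs)) next
      for (ti in seq_along(contigs)) {
        lin <- seed_extend_align(contigs[[ti]], rseq,
                                 min_identity = min_identity,
                                 min_length = min_length)
        rotated <- seed_extend_align(contigs[[ti]], rot$seq,
                                     min_identity = min_identity,
                                     min_length = min_length)
        spans <- nrow(rotated) > 0L &&
          any(rotated$subject_start < rot$seam & rotated$subject_end > rot$seam)
        if (nrow(lin) == 0L && nrow(rotated) == 0L) next
        best <- rbind(lin, rotated)
        best <- best[order(-best$score), , drop = FALSE][1L, ]
        links[[length(links) + 1L]] <- data.frame(
          region_name = elig$name[ri], cluster_id = cid, contig = ti,
          identity = best$identity, aligned_length = best$aligned_length,
          spans_junction = spans, stringsAsFactors = FALSE)
      }
    }
  }
  links <- if (length(links) > 0L) do.call(rbind, links) else
    data.frame(region_name = character(0), cluster_id = character(0),
               contig = integer(0), identity = numeric(0),
               aligned_length = integer(0), spans_junction = logical(0))
  # duplicate region-cluster links (several contigs) collapse to one
  link_pairs <- unique(links[, c("region_name", "cluster_id", "spans_junction")])
  lc <- do.call(rbind, lapply(seq_len(nrow(elig)), function(ri) {
    nm <- elig$name[ri]
    lk <- unique(link_pairs$cluster_id[link_pairs$region_name == nm])
    js <- unique(link_pairs$cluster_id[link_pairs$region_name == nm &
                                         link_pairs$spans_junction])
    data.frame(region_name = nm,
               n_linked_clusters = length(lk),
               linked_clusters = paste(sort(lk), collapse = ","),
               junction_spanning_clusters = paste(sort(js), collapse = ","),
               combined_confidence = if (length(lk) > 0L) "very_high"
                                     else "mapping_only",
               stringsAsFactors = FALSE)
  }))
  if (is.null(lc))
    lc <- data.frame(region_name = character(0), n_linked_clusters = integer(0),
                     linked_clusters = character(0),
                     junction_spanning_clusters = character(0),
                     combined_confidence = character(0))
  list(links = links, linked_candidates = lc)
}

#' Conclusive summary of a combined mapping + clustering run
#'
#' @param regions Ranked candidate regions (with enrichment scores).
#' @param linked Result of [link_clusters_to_regions()].
#' @param cluster_ids Selected candidate cluster ids.
#' @return List of three deterministic tables: `candidates` (regions joined
#'   with link information, very-high-confidence first), `mapping_only`
#'   (regions without cluster support), `clustering_only` (selected clusters
#'   not linked to any region).
#' @export
summarize_run <- function(regions, linked, cluster_ids) {
  lc <- linked$linked_candidates
  tab <- merge(regions, lc, by.x = "name", by.y = "region_name",
               all.x = TRUE, sort = FALSE)
  tab$n_linked_clusters[is.na(tab$n_linked_clusters)] <- 0L
  tab$combined_confidence[is.na(tab$combined_confidence)] <- "mapping_only"
  tab <- tab[order(match(tab$combined_confidence, c("very_high", "mapping_only")),
                   match(tab$confidence, c("high", "low")),
                   -tab$enrichment_score, tab$chrom, tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  linked_ids <- unique(linked$links$cluster_id)
  list(candidates = tab,
       mapping_only = tab[tab$n_linked_clusters == 0L, , drop = FALSE],
       clustering_only = sort(setdiff(cluster_ids, linked_ids)))
}
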