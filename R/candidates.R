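overlaps_any <- function(chrom, start, end, other) {
  # >= 1 bp overlap against data.frame `other` (chrom/start/end, half-open)
  vapply(seq_along(chrom), function(i) {
    sel <- other$chrom == chrom[i]
    any(other$start[sel] < end[i] & other$end[sel] > start[i])
  }, logical(1))
}

#' Intersect split, discordant and peak evidence into candidate regions
#'
#' Every split junction seeds a candidate whose boundaries are the junction
#' itself (split boundaries are the most precise of the three signatures);
#' overlap with discordant regions and coverage peaks (>= 1 bp, the usual
#' interval-intersection convention) sets the remaining evidence flags.
#' Discordant/peak double overlaps not touched by any split junction are
#' added with boundaries equal to the intersection of the two intervals.
#' Candidates supported by all three signatures are high confidence; two of
#' three gives low confidence. When at least one high-confidence candidate
#' exists, low-confidence candidates are retained for reporting but flagged
#' `use_in_linking = FALSE` so downstream linking ignores them.
#'
#' @param splits data.frame from [call_split_junctions()].
#' @param discordants data.frame from [call_discordant_regions()].
#' @param peaks data.frame from [find_peaks()].
#' @return data.frame with `chrom`, `start`, `end`, `name`,
#'   `evidence_split`, `evidence_discordant`, `evidence_peak`, `confidence`,
#'   `split_reads`, `discordant_pairs`, `peak_prominence`, `use_in_linking`.
#' @export
intersect_evidence <- function(splits, discordants, peaks) {
  cands <- list()
  if (nrow(splits) > 0L) {
    for (i in seq_len(nrow(splits))) {
      ch <- splits$chrom[i]; s <- splits$start[i]; e <- splits$end[i]
      dsel <- discordants$chrom == ch & discordants$start < e & discordants$end > s
      psel <- peaks$chrom == ch & peaks$start < e & peaks$end > s
      cands[[length(cands) + 1L]] <- data.frame(
        chrom = ch, start = s, end = e,
        evidence_split = TRUE,
        evidence_discordant = any(dsel),
        evidence_peak = any(psel),
        split_reads = splits$support[i],
        discordant_pairs = if (any(dsel)) sum(discordants$pair_count[dsel]) else 0L,
        peak_prominence = if (any(psel)) max(peaks$prominence[psel]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  # discordant-peak overlaps with no split junction: intersection boundaries
  if (nrow(discordants) > 0L && nrow(peaks) > 0L) {
    for (i in seq_len(nrow(discordants))) {
      ch <- discordants$chrom[i]
      psel <- which(peaks$chrom == ch & peaks$start < discordants$end[i] &
                      peaks$end > discordants$start[i])
      for (j in psel) {
        s <- max(discordants$start[i], peaks$start[j])
        e <- min(discordants$end[i], peaks$end[j])
        if (nrow(splits) > 0L && overlaps_any(ch, s, e, splits)) next
        cands[[length(cands) + 1L]] <- data.frame(
          chrom = ch, start = s, end = e,
          evidence_split = FALSE, evidence_discordant = TRUE,
          evidence_peak = TRUE,
          split_reads = 0L,
          discordant_pairs = discordants$pair_count[i],
          peak_prominence = peaks$prominence[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cands) == 0L)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      name = character(0), evidence_split = logical(0),
                      evidence_discordant = logical(0), evidence_peak = logical(0),
                      confidence = character(0), split_reads = integer(0),
                      discordant_pairs = integer(0), peak_prominence = numeric(0),
                      use_in_linking = logical(0)))
  res <- do.call(rbind, cands)
  res <- res[!duplicated(res[, c("chrom", "start", "end")]), , drop = FALSE]
  n_evid <- res$evidence_split + res$evidence_discordant + res$evidence_peak
  res <- res[n_evid >= 2L, , drop = FALSE]
  res$confidence <- ifelse(res$evidence_split & res$evidence_discordant &
                             res$evidence_peak, "high", "low")
  res$use_in_linking <- if (any(res$confidence == "high"))
    res$confidence == "high" else rep(TRUE, nrow(res))
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  res$name <- sprintf("ecc_candidate_%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("chrom", "start", "end", "name", "evidence_split",
          "evidence_discordant", "evidence_peak", "confidence", "split_reads",
          "discordant_pairs", "peak_prominence", "use_in_linking")]
}

region_mean_depth <- function(track, chrom, start, end) {
  d <- track$depth[[chrom]]
  if (is.null(d) || start < 0L || end > length(d) || start >= end)
    stop("score_enrichment: region outside coverage track")
  mean(d[(start + 1L):end])
}

#' Enrichment score of candidate regions
#'
#' Ratio of the region's mean BPM coverage in the circSeq data to the same
#' region's mean BPM in the control (floored at `epsilon` to avoid division
#' by zero). Without a control the denominator is the global mean BPM of the
#' circSeq track, i.e. enrichment relative to a uniform library. The score
#' estimates the fold amplification of the candidate and is used for ranking.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param circ_bpm BPM-normalized `ecc_coverage` of the circSeq data.
#' @param ctrl_bpm Optional BPM-normalized `ecc_coverage` of the control.
#' @param epsilon Floor for the control mean, in BPM (default 0.1).
#' @return Numeric vector of scores (one per region).
#' @export
score_enrichment <- function(regions, circ_bpm, ctrl_bpm = NULL, epsilon = 0.1) {
  stopifnot(inherits(circ_bpm, "ecc_coverage"), isTRUE(circ_bpm$normalized))
  if (nrow(regions) == 0L) return(numeric(0))
  num <- mapply(region_mean_depth, regions$chrom, regions$start, regions$end,
                MoreArgs = list(track = circ_bpm))
  if (!is.null(ctrl_bpm)) {
    stopifnot(inherits(ctrl_bpm, "ecc_coverage"), isTRUE(ctrl_bpm$normalized))
    den <- mapply(region_mean_depth, regions$chrom, regions$start, regions$end,
                  MoreArgs = list(track = ctrl_bpm))
    den <- pmax(den, epsilon)
  } else {
    den <- sum(vapply(circ_bpm$depth, sum, numeric(1))) /
      sum(vapply(circ_bpm$depth, length, numeric(1)))
  }
  unname(num / den)
}

#' Annotate a candidate sequence against an annotation database
#'
#' Internal ungapped seed-and-extend similarity search (exact `seed_k`-mer
#' seeds, +1/-2 scoring, exact best segment per seeded diagonal) of the
#' region sequence against both strands of each database sequence. Hits need
#' identity of at least `min_identity` over at least `3 * seed_k` aligned
#' bases and are ordered by score, then identity, then subject id.
#'
#' @param region_sequence DNA string of the candidate region.
#' @param db Named character vector of database sequences, a
#'   `Biostrings::DNAStringSet`, a FASTA path, or `NULL` (no annotation).
#' @param min_identity Minimum hit identity (default 0.8).
#' @param seed_k Seed length in bases (default 13).
#' @return data.frame with `subject_id`, `identity`, `aligned_length`,
#'   `score`, `subject_strand`; zero rows when `db` is absent or nothing
#'   matches.
#' @export
annotate_region <- function(region_sequence, db, min_identity = 0.8, seed_k = 13L) {
  empty <- data.frame(subject_id = character(0), identity = numeric(0),
                      aligned_length = integer(0), score = numeric(0),
                      subject_strand = character(0))
  if (is.null(db) || length(db) == 0L) return(empty)
  if (is.character(db) && length(db) == 1L && file.exists(db))
    db <- Biostrings::readDNAStringSet(db)
  db <- setNames(as.character(db), names(db))
  hits <- list()
  for (id in names(db)) {
    h <- seed_extend_align(region_sequence, db[[id]], k = seed_k,
                           min_identity = min_identity,
                           min_length = 3L * seed_k)
    if (nrow(h) == 0L) next
    h <- h[1L, ]      # best segment for this subject
    hits[[length(hits) + 1L]] <- data.frame(
      subject_id = id, identity = h$identity,
      aligned_length = h$aligned_length, score = h$score,
      subject_strand = h$strand, stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) return(empty)
  res <- do.call(rbind, hits)
  res <- res[order(-res$score, -res$identity, res$subject_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Rank candidate regions
#'
#' High-confidence candidates precede low-confidence ones; within a tier,
#' candidates are ordered by decreasing enrichment score, then decreasing
#' length, then chromosome and start.
#'
#' @param candidates data.frame with `confidence`, `enrichment_score`,
#'   `chrom`, `start`, `end`.
#' @return The reordered data.frame.
#' @export
rank_candidates <- function(candidates) {
  if (nrow(candidates) == 0L) return(candidates)
  tier <- match(candidates$confidence, c("high", "low"))
  ord <- order(tier, -candidates$enrichment_score,
               -(candidates$end - candidates$start),
               candidates$chrom, candidates$start)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
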