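#' Call circular split-read junctions
#'
#' A split read supports a circular junction when its two aligned segments lie
#' on the same chromosome and strand with their order along the stored (i.e.
#' reference-forward) sequence inverted relative to the reference: the segment
#' occupying the later part of the sequence aligns upstream of the segment
#' occupying the earlier part. This wrap-around layout is what a read crossing
#' the junction of a circle produces, and it is strand-symmetric in stored-SEQ
#' coordinates; colinear splits (deletion signature) are ignored. The junction
#' interval is (start of the upstream segment, end of the downstream segment).
#'
#' Junctions whose endpoints agree within `breakpoint_tolerance` are pooled
#' (single linkage on both endpoints); pooled junctions with support of at
#' least `min_split` reads are reported with consensus (median) boundaries.
#'
#' @param records An `ecc_alignments` table from [read_sam()].
#' @param min_split Minimum pooled split-read support (default 5).
#' @param breakpoint_tolerance Endpoint pooling window in bases (default 5).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `support`.
#' @export
call_split_junctions <- function(records, min_split = 5L, breakpoint_tolerance = 5L) {
  stopifnot(min_split >= 1L)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), support = integer(0))
  r <- records[!records$unmapped & !records$secondary & !records$supplementary &
                 !is.na(records$sa_tag), ]
  if (nrow(r) == 0L) return(empty)

  anch <- parse_sa_anchors(r$sa_tag)
  anch <- anch[!duplicated(anch$record), ]            # first anchor per record
  r <- r[anch$record, ]
  same <- r$chrom == anch$chrom &
    (ifelse(r$reverse, "-", "+") == anch$strand)
  r <- r[same, ]; anch <- anch[same, ]
  if (nrow(r) == 0L) return(empty)

  rec_start <- r$pos
  rec_end <- r$pos + cigar_ref_width(r$cigar)
  a_start <- anch$pos
  a_end <- anch$pos + cigar_ref_width(anch$cigar)
  rec_off <- cigar_lead_clip(r$cigar)
  a_off <- cigar_lead_clip(anch$cigar)

  # segment with the larger stored-SEQ offset must lie upstream (wrap-around)
  lo_first <- rec_off <= a_off
  early_start <- ifelse(lo_first, rec_start, a_start)
  early_end <- ifelse(lo_first, rec_end, a_end)
  late_start <- ifelse(lo_first, a_start, rec_start)
  circular <- late_start < early_start
  s <- late_start[circular]
  e <- early_end[circular]
  chrom <- r$chrom[circular]
  if (length(s) == 0L) return(empty)

  out <- list()
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    ss <- s[sel]; ee <- e[sel]
    ord <- order(ss, ee)
    ss <- ss[ord]; ee <- ee[ord]
    # single-linkage pooling: chain while both endpoints stay within tolerance
    grp <- cumsum(c(1L, (diff(ss) > breakpoint_tolerance) |
                          (abs(diff(ee)) > breakpoint_tolerance)))
    for (g in unique(grp)) {
      m <- grp == g
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = as.integer(round(median(ss[m]))),
        end = as.integer(round(median(ee[m]))),
        support = sum(m))
    }
  }
  res <- do.call(rbind, out)
  res <- res[res$support >= min_split, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Call discordant read-pair regions
#'
#' A mapped primary pair is discordant when its proper-pair flag is unset, its
#' mates map to different chromosomes, its observed template length exceeds
#' `max_insert`, or its orientation is not forward-reverse inward. Same-
#' chromosome discordant pairs contribute the interval spanning both mates;
#' intervals closer than `merge_distance` are merged.
#'
#' @param records An `ecc_alignments` table.
#' @param max_insert Template-length cutoff; default is mean + 3 SD of the
#'   absolute template length of proper pairs (estimated from the first
#'   100,000 pairs), the usual insert-size heuristic.
#' @param merge_distance Maximum gap between merged intervals (default 0:
#'   overlapping or touching intervals merge).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `pair_count`.
#' @export
call_discordant_regions <- function(records, max_insert = NULL, merge_distance = 0L) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), pair_count = integer(0))
  r <- records[records$paired & !records$unmapped & !records$mate_unmapped &
                 !records$secondary & !records$supplementary, ]
  if (nrow(r) == 0L) return(empty)

  if (is.null(max_insert)) {
    tl <- abs(r$tlen[r$proper_pair & r$first_in_pair])
    tl <- head(tl, 100000L)
    max_insert <- if (length(tl) > 1L)
      mean(tl) + 3 * stats::sd(tl) else Inf
  }

  m1 <- r[r$first_in_pair, ]
  m2 <- r[!r$first_in_pair, ]
  m2 <- m2[match(m1$qname, m2$qname), ]
  ok <- !is.na(m2$qname)
  m1 <- m1[ok, ]; m2 <- m2[ok, ]
  if (nrow(m1) == 0L) return(empty)

  end1 <- m1$pos + cigar_ref_width(m1$cigar)
  end2 <- m2$pos + cigar_ref_width(m2$cigar)
  left_rev <- ifelse(m1$pos <= m2$pos, m1$reverse, m2$reverse)
  right_rev <- ifelse(m1$pos <= m2$pos, m2$reverse, m1$reverse)
  fr_inward <- !left_rev & right_rev
  disc <- !m1$proper_pair | (m1$chrom != m2$chrom) |
    (abs(m1$tlen) > max_insert) | !fr_inward
  same <- disc & (m1$chrom == m2$chrom)
  if (!any(same)) return(empty)

  ivl <- data.frame(chrom = m1$chrom[same],
                    start = pmin(m1$pos[same], m2$pos[same]),
                    end = pmax(end1[same], end2[same]))
  out <- list()
  for (ch in unique(ivl$chrom)) {
    v <- ivl[ivl$chrom == ch, ]
    ir <- IRanges::IRanges(start = v$start + 1L, end = v$end)
    red <- IRanges::reduce(ir, min.gapwidth = merge_distance + 1L)
    cnt <- IRanges::countOverlaps(red, ir)
    out[[length(out) + 1L]] <- data.frame(chrom = ch,
                                          start = IRanges::start(red) - 1L,
                                          end = IRanges::end(red),
                                          pair_count = cnt)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Compute a raw per-base coverage track
#'
#' Depth counts every reference-consuming aligned base (CIGAR M/=/X/D) of
#' mapped primary and supplementary alignments; secondary alignments and
#' reference skips (N) are excluded.
#'
#' @param records An `ecc_alignments` table (needs the `seqlengths`
#'   attribute from the SAM header).
#' @param seqlengths Optional named integer vector overriding the attribute.
#' @return An `ecc_coverage` object: list with `depth` (named list of numeric
#'   per-base vectors), `total_aligned_bases`, `normalized = FALSE`.
#' @export
compute_coverage <- function(records, seqlengths = attr(records, "seqlengths")) {
  if (is.null(seqlengths))
    stop("compute_coverage: chromosome lengths unknown (no @SQ header)")
  r <- records[!records$unmapped & !records$secondary & !is.na(records$chrom), ]
  depth <- lapply(seqlengths, function(L) numeric(L))
  total <- 0
  if (nrow(r) > 0L) {
    u <- unique(r$cigar)
    blocks_u <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      u, ops = c("M", "=", "X", "D"), reduce.ranges = TRUE)
    blocks <- blocks_u[match(r$cigar, u)]
    nb <- S4Vectors::elementNROWS(blocks)
    flat <- unlist(blocks)
    bstart <- r$pos[rep(seq_len(nrow(r)), nb)] + IRanges::start(flat) - 1L
    bend <- r$pos[rep(seq_len(nrow(r)), nb)] + IRanges::end(flat)   # half-open
    bchrom <- r$chrom[rep(seq_len(nrow(r)), nb)]
    for (ch in unique(bchrom)) {
      if (!ch %in% names(seqlengths))
        stop("compute_coverage: alignment on unknown chromosome ", ch)
      L <- seqlengths[[ch]]
      sel <- bchrom == ch
      if (any(bend[sel] > L) || any(bstart[sel] < 0L))
        stop("compute_coverage: alignment beyond chromosome end on ", ch)
      delta <- tabulate(bstart[sel] + 1L, nbins = L + 1L) -
        tabulate(bend[sel] + 1L, nbins = L + 1L)
      depth[[ch]] <- depth[[ch]] + head(cumsum(delta), L)
    }
    total <- sum(bend - bstart)
  }
  structure(list(depth = depth, total_aligned_bases = total,
                 normalized = FALSE), class = "ecc_coverage")
}

#' Normalize a coverage track to bases per million bases (BPM)
#'
#' Each position's depth is scaled by `1e6 / total_aligned_bases`, so the
#' track sums to one million regardless of read length or library size,
#' making datasets with different read lengths directly comparable.
#'
#' @param track An `ecc_coverage` object with raw depth.
#' @return The BPM-normalized `ecc_coverage` object.
#' @export
normalize_bpm <- function(track) {
  stopifnot(inherits(track, "ecc_coverage"))
  if (track$total_aligned_bases <= 0)
    stop("normalize_bpm: no aligned bases; cannot normalize or compute enrichment")
  track$depth <- lapply(track$depth, function(d) d * 1e6 / track$total_aligned_bases)
  track$normalized <- TRUE
  track
}

#' Detect coverage peak regions by prominence
#'
#' Local maxima (plateaus allowed, apex at the leftmost plateau position;
#' plateaus touching a chromosome boundary are not maxima) are kept when
#' their topographic prominence reaches `min_prominence`. The prominence is
#' the apex height minus the higher of the two bases, where each base is the
#' minimum depth between the apex and the nearest strictly higher position on
#' that side (or the chromosome boundary). The reported region is the maximal
#' interval around the apex with depth above apex height minus prominence.
#'
#' @param track An `ecc_coverage` object (BPM-normalized for the pipeline's
#'   default threshold of 1 BPM to be meaningful).
#' @param min_prominence Minimum prominence, in track units (default 1.0).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `apex`, `height`, `prominence`.
#' @export
find_peaks <- function(track, min_prominence = 1.0) {
  stopifnot(inherits(track, "ecc_coverage"))
  out <- lapply(names(track$depth), function(ch) {
    p <- cpp_find_peaks(track$depth[[ch]], min_prominence)
    if (nrow(p) == 0L) return(NULL)
    data.frame(chrom = ch, p, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), apex = integer(0),
                      height = numeric(0), prominence = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
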