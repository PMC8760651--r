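# Internal ungapped seed-and-extend aligner shared by the annotation search
# and the contig-to-region linker.
#
# Exact k-mer seeds between query and subject define diagonals; on each
# seeded diagonal the best-scoring ungapped segment under +1 match / -2
# mismatch is computed exactly (maximum-scoring subarray on the score
# profile, which dominates any X-drop extension from the same seeds). The
# best segment per (subject strand, diagonal) is kept and filtered on
# identity and aligned length. Coordinates are 0-based half-open; minus-
# strand subject intervals are reported in original subject orientation.

diag_best_segment <- function(v) {
  # maximum-scoring subarray via cumulative sums; ties -> leftmost, shortest
  cs <- cumsum(v)
  prev <- c(0, head(cs, -1L))
  cm <- cummin(prev)
  score <- cs - cm
  j <- which.max(score)
  i <- which(prev[seq_len(j)] == cm[j])[1L]
  c(start = i, end = j, score = score[j])   # 1-based inclusive on v
}

seed_extend_align <- function(query, subject, k = 13L, min_identity = 0.8,
                              min_length = 3L * k, both_strands = TRUE) {
  hits <- list()
  nq <- nchar(query)
  qr <- charToRaw(query)
  strands <- if (both_strands) c("+", "-") else "+"
  for (strand in strands) {
    subj <- if (strand == "+") subject else revcomp(subject)
    ns <- nchar(subj)
    if (nq < k || ns < k) next
    sr <- charToRaw(subj)
    qk <- substring(query, seq_len(nq - k + 1L), seq_len(nq - k + 1L) + k - 1L)
    sk <- substring(subj, seq_len(ns - k + 1L), seq_len(ns - k + 1L) + k - 1L)
    spos <- split(seq_along(sk), sk)
    seed_s <- spos[qk]
    seed_q <- rep(seq_along(qk), lengths(seed_s))
    seed_s <- unlist(seed_s, use.names = FALSE)
    if (length(seed_s) == 0L) next
    for (d in unique(seed_q - seed_s)) {           # diagonal: qpos - spos
      q1 <- max(1L, 1L + d)
      q2 <- min(nq, ns + d)
      if (q2 - q1 + 1L < min_length) next
      qs <- q1:q2
      match_vec <- qr[qs] == sr[qs - d]
      seg <- diag_best_segment(ifelse(match_vec, 1, -2))
      len <- seg[["end"]] - seg[["start"]] + 1L
      ident <- sum(match_vec[seg[["start"]]:seg[["end"]]]) / len
      if (len < min_length || ident < min_identity) next
      qstart <- q1 + seg[["start"]] - 2L            # 0-based
      qend <- q1 + seg[["end"]] - 1L
      sstart <- qstart - d                          # 0-based on this strand
      send <- qend - d
      if (strand == "-") { tmp <- sstart; sstart <- ns - send; send <- ns - tmp }
      hits[[length(hits) + 1L]] <- data.frame(
        strand = strand, score = seg[["score"]], identity = ident,
        aligned_length = len, query_start = qstart, query_end = qend,
        subject_start = sstart, subject_end = send,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(strand = character(0), score = numeric(0),
                      identity = numeric(0), aligned_length = integer(0),
                      query_start = integer(0), query_end = integer(0),
                      subject_start = integer(0), subject_end = integer(0)))
  res <- do.call(rbind, hits)
  # collapse near-identical segments found from adjacent diagonals
  res <- res[order(-res$score, -res$identity, res$subject_start), , drop = FALSE]
  keep <- !duplicated(res[, c("strand", "subject_start", "subject_end")])
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}
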