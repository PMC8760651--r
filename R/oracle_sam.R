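#' SAM header for a simulated genome
#' @param genome An `ecc_genome`.
#' @return Character vector of header lines.
#' @export
sam_header <- function(genome) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome$seqs), nchar(genome$seqs)),
    "@PG\tID:eccscout\tPN:eccscout")
}

#' Emit oracle alignments for simulated reads
#'
#' Converts read provenance (template, fragment offset, strand) into the exact
#' alignments a split-aware mapper would report, so the evidence engine can be
#' tested without an external mapper:
#'
#' * reads from a chromosome template, and concatemer reads lying fully inside
#'   one element copy, become single full-match primary alignments;
#' * concatemer reads spanning a copy boundary become a primary plus a
#'   supplementary alignment with soft-clipped CIGARs anchored at the
#'   ground-truth element end and start (the circular split signature), each
#'   carrying an `SA:Z:` tag pointing at its partner segment;
#' * pairs whose fragment crosses a copy boundary have the proper-pair flag
#'   unset (on the reference the mates face outward around the junction);
#' * all other pairs are plain proper pairs.
#'
#' Concatemer offsets map to reference coordinates modulo the element length.
#' Reads that cannot be placed (read longer than the element) are skipped with
#' a message. Output positions are 1-based SAM.
#'
#' @param genome An `ecc_genome`.
#' @param reads An `ecc_readpairs` data.frame; `template_id` is either a
#'   chromosome id or `"concatemer"`.
#' @param truth Ground-truth row (defaults to `genome$truth`).
#' @return Character vector of SAM alignment lines (no header).
#' @export
oracle_alignments <- function(genome, reads, truth = genome$truth) {
  stopifnot(inherits(genome, "ecc_genome"))
  if (nrow(reads) == 0L) return(character(0))
  le <- truth$end - truth$start
  rl <- nchar(reads$seq1[1L])

  is_conc <- reads$template_id == "concatemer"
  if (any(is_conc) && rl > le) {
    message("oracle_alignments: skipped ", sum(is_conc),
            " pairs (read length exceeds element length)")
    reads <- reads[!is_conc, , drop = FALSE]
    if (nrow(reads) == 0L) return(character(0))
    is_conc <- rep(FALSE, nrow(reads))
  }

  n <- nrow(reads)
  # per-mate layout: template interval and orientation
  m <- data.table(
    pair = rep(seq_len(n), 2L),
    mate = rep(1:2, each = n),
    qname = rep(reads$name, 2L),
    template_id = rep(reads$template_id, 2L),
    is_conc = rep(is_conc, 2L),
    offset = rep(reads$offset, 2L),
    isize = rep(reads$isize, 2L),
    frag_strand = rep(reads$strand, 2L),
    fq = c(reads$seq1, reads$seq2)
  )
  # mate1 sits at the fragment start for "+" fragments, fragment end for "-"
  left_start <- m$offset
  right_start <- m$offset + m$isize - rl
  is_left <- (m$mate == 1L) == (m$frag_strand == "+")
  m[, `:=`(tstart = ifelse(is_left, left_start, right_start),
           reverse = !is_left)]
  m[, seq_sam := fq]
  m[reverse == TRUE, seq_sam := revcomp(fq)]

  s0 <- truth$start
  m[, p := ifelse(is_conc, tstart %% le, tstart)]
  m[, chrom := ifelse(is_conc, truth$chrom, template_id)]
  m[, split := is_conc & (p + rl > le)]
  m[, len_a := ifelse(split, le - p, rl)]

  # primary segment: the longer of the two pieces (ties favour the upstream-in-read piece)
  m[, a_primary := !split | (len_a >= rl - len_a)]
  m[, pos_a := ifelse(is_conc, s0 + p, tstart)]
  m[, pos_b := s0]                       # only meaningful when split
  m[, cig_a := ifelse(split, paste0(len_a, "M", rl - len_a, "S"), paste0(rl, "M"))]
  m[, cig_b := paste0(len_a, "S", rl - len_a, "M")]
  m[, prim_pos := ifelse(a_primary, pos_a, pos_b)]
  m[, prim_end := ifelse(a_primary, pos_a + len_a, pos_b + (rl - len_a))]

  # pair-level geometry from the primary alignments of both mates
  prim1 <- m[mate == 1L]; prim2 <- m[mate == 2L]
  proper <- ifelse(is_conc,
                   (reads$offset %/% le) == ((reads$offset + reads$isize - 1L) %/% le),
                   TRUE)
  left_pos <- pmin(prim1$prim_pos, prim2$prim_pos)
  right_end <- pmax(prim1$prim_end, prim2$prim_end)
  span <- right_end - left_pos
  tlen1 <- ifelse(prim1$prim_pos <= prim2$prim_pos, span, -span)

  m[, proper := rep(proper, 2L)]
  m[, mate_pos := c(prim2$prim_pos, prim1$prim_pos)]
  m[, mate_rev := c(prim2$reverse, prim1$reverse)]
  m[, tlen := c(tlen1, -tlen1)]

  flag_base <- 1L + ifelse(m$proper, 2L, 0L) + ifelse(m$reverse, 16L, 0L) +
    ifelse(m$mate_rev, 32L, 0L) + ifelse(m$mate == 1L, 64L, 128L)
  strand_char <- ifelse(m$reverse, "-", "+")

  fmt <- function(flag, pos, cig, sa) {
    line <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                    m$qname, flag, m$chrom, pos + 1L, cig,
                    m$mate_pos + 1L, m$tlen, m$seq_sam, strrep("I", rl))
    ifelse(is.na(sa), line, paste0(line, "\tSA:Z:", sa))
  }
  sa_a <- ifelse(m$split, sprintf("%s,%d,%s,%s,60,0;", m$chrom, m$pos_b + 1L,
                                  strand_char, m$cig_b), NA_character_)
  sa_b <- sprintf("%s,%d,%s,%s,60,0;", m$chrom, m$pos_a + 1L, strand_char, m$cig_a)

  prim_line <- fmt(flag_base,
                   ifelse(m$a_primary, m$pos_a, m$pos_b),
                   ifelse(m$a_primary, m$cig_a, m$cig_b),
                   ifelse(m$a_primary, sa_a, sa_b))
  # supplementary record for the other piece of split mates
  supp <- m$split
  supp_line <- fmt(flag_base + 2048L,
                   ifelse(m$a_primary, m$pos_b, m$pos_a),
                   ifelse(m$a_primary, m$cig_b, m$cig_a),
                   ifelse(m$a_primary, sa_b, sa_a))[supp]

  ord <- order(c(m$pair, m$pair[supp]), c(m$mate, m$mate[supp]),
               c(rep(0L, nrow(m)), rep(1L, sum(supp))))
  c(prim_line, supp_line)[ord]
}

#' Write oracle alignments with header to a SAM file
#' @inheritParams oracle_alignments
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_oracle_sam <- function(genome, reads, path, truth = genome$truth) {
  writeLines(c(sam_header(genome), oracle_alignments(genome, reads, truth)), path)
  invisible(path)
}
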