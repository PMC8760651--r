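# Builders for hand-constructed SAM inputs.

sam_sq <- function(...) {
  lens <- c(...)
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
}

# one alignment line; pos is 1-based as in SAM text
sam_line <- function(qname, flag, chrom, pos, cigar, mate_chrom = "=",
                     mate_pos = pos, tlen = 0L, seq = "*", tags = character(0)) {
  line <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t%d\t%s\t*",
                  qname, flag, chrom, pos, cigar, mate_chrom, mate_pos, tlen, seq)
  if (length(tags)) line <- paste(c(line, tags), collapse = "\t")
  line
}

# a wrap-around split read: primary matches the element end (downstream),
# supplementary anchor matches the element start (upstream)
split_read_lines <- function(qname, chrom, s, e, rl = 100L, frac = 0.5,
                             strand = "+", colinear = FALSE) {
  la <- as.integer(rl * frac)          # first-in-SEQ piece
  lb <- rl - la
  rev_flag <- if (strand == "-") 16L else 0L
  if (!colinear) {
    # SEQ-earlier piece ends at e; SEQ-later piece starts at s
    pos_a <- e - la                    # 0-based start of downstream piece
    cig_a <- sprintf("%dM%dS", la, lb)
    pos_b <- s
    cig_b <- sprintf("%dS%dM", la, lb)
  } else {
    # colinear (deletion-like): earlier piece upstream, later piece downstream
    pos_a <- s
    cig_a <- sprintf("%dM%dS", la, lb)
    pos_b <- e - lb
    cig_b <- sprintf("%dS%dM", la, lb)
  }
  c(sam_line(qname, 0L + rev_flag, chrom, pos_a + 1L, cig_a,
             tags = sprintf("SA:Z:%s,%d,%s,%s,60,0;", chrom, pos_b + 1L,
                            strand, cig_b)),
    sam_line(qname, 2048L + rev_flag, chrom, pos_b + 1L, cig_b,
             tags = sprintf("SA:Z:%s,%d,%s,%s,60,0;", chrom, pos_a + 1L,
                            strand, cig_a)))
}

# a mapped read pair; set proper = FALSE and positions far apart for
# discordant fixtures
pair_lines <- function(qname, chrom, pos1, pos2, rl = 100L, proper = TRUE,
                       chrom2 = chrom, rev1 = FALSE, rev2 = TRUE) {
  tlen <- (max(pos1, pos2) + rl) - min(pos1, pos2)
  f1 <- 1L + (if (proper) 2L else 0L) + (if (rev1) 16L else 0L) +
    (if (rev2) 32L else 0L) + 64L
  f2 <- 1L + (if (proper) 2L else 0L) + (if (rev2) 16L else 0L) +
    (if (rev1) 32L else 0L) + 128L
  c(sam_line(qname, f1, chrom, pos1 + 1L, sprintf("%dM", rl), chrom2, pos2 + 1L,
             if (pos1 <= pos2) tlen else -tlen),
    sam_line(qname, f2, chrom2, pos2 + 1L, sprintf("%dM", rl), chrom, pos1 + 1L,
             if (pos1 <= pos2) -tlen else tlen))
}

tiny_sim_config <- function(...) {
  defaults <- list(seed = 5L, total_ref_length = 90000L, element_length = 3000L,
                   n_pairs_circ = 2500L, n_pairs_control = 2500L,
                   insert_mean = 450L, insert_sd = 40L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
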