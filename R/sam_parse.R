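#' Parse a SAM file into alignment records
#'
#' Reads plain-text SAM (decode BAM externally, e.g. `samtools view -h`).
#' Positions are converted to 0-based; SAM flags are decoded into logical
#' columns; the first `SA:Z:` supplementary-alignment anchor, if present, is
#' kept as a raw tag string (decode with [parse_sa_anchors()]).
#'
#' @param path Path to a SAM file (or a character vector of SAM lines).
#' @return A `data.table` of class `ecc_alignments` with columns `qname`,
#'   `flag`, `chrom`, `pos`, `mapq`, `cigar`, `mate_chrom`, `mate_pos`,
#'   `tlen`, decoded flag logicals (`paired`, `proper_pair`, `unmapped`,
#'   `mate_unmapped`, `reverse`, `mate_reverse`, `secondary`,
#'   `supplementary`, `first_in_pair`), and `sa_tag`. Chromosome lengths from
#'   the `@SQ` header are attached as attribute `seqlengths`.
#' @export
read_sam <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  is_hdr <- startsWith(lines, "@")
  hdr <- lines[is_hdr]
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (length(sq) == 0L)
    stop("read_sam: missing @SQ header lines")
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  seqlengths <- setNames(ln, sn)

  body <- lines[!is_hdr]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    rec <- data.table(qname = character(0), flag = integer(0),
                      chrom = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      mate_chrom = character(0), mate_pos = integer(0),
                      tlen = integer(0), sa_tag = character(0))
  } else {
    f <- tstrsplit(body, "\t", fixed = TRUE)
    if (length(f) < 11L || anyNA(f[[11L]])) {
      bad <- if (length(f) < 11L) 1L else which(is.na(f[[11L]]))[1L]
      stop("read_sam: malformed alignment line ", bad, " (fewer than 11 fields)")
    }
    sa <- regmatches(body, regexpr("SA:Z:[^\t]+", body))
    sa_tag <- rep(NA_character_, length(body))
    sa_tag[grepl("SA:Z:", body, fixed = TRUE)] <- substring(sa, 6L)
    rec <- data.table(qname = f[[1L]], flag = as.integer(f[[2L]]),
                      chrom = f[[3L]], pos = as.integer(f[[4L]]) - 1L,
                      mapq = as.integer(f[[5L]]), cigar = f[[6L]],
                      mate_chrom = f[[7L]], mate_pos = as.integer(f[[8L]]) - 1L,
                      tlen = as.integer(f[[9L]]), sa_tag = sa_tag)
  }
  rec[, `:=`(paired = bitwAnd(flag, 1L) > 0L,
             proper_pair = bitwAnd(flag, 2L) > 0L,
             unmapped = bitwAnd(flag, 4L) > 0L,
             mate_unmapped = bitwAnd(flag, 8L) > 0L,
             reverse = bitwAnd(flag, 16L) > 0L,
             mate_reverse = bitwAnd(flag, 32L) > 0L,
             first_in_pair = bitwAnd(flag, 64L) > 0L,
             secondary = bitwAnd(flag, 256L) > 0L,
             supplementary = bitwAnd(flag, 2048L) > 0L)]
  rec[mate_chrom == "=", mate_chrom := chrom]
  rec[chrom == "*", chrom := NA_character_]
  data.table::setattr(rec, "seqlengths", seqlengths)
  data.table::setattr(rec, "class", c("ecc_alignments", class(rec)))
  rec[]
}

#' Decode SA:Z supplementary-alignment anchors
#'
#' @param sa_tag Character vector of `SA:Z` tag payloads in the standard
#'   `"rname,pos,strand,CIGAR,mapq,NM;"` dialect (possibly several anchors
#'   separated by `;`); `NA` entries yield no rows.
#' @return data.table with `record` (index into `sa_tag`), `chrom`, `pos`
#'   (0-based), `strand`, `cigar`, `mapq`, `nm`.
#' @export
parse_sa_anchors <- function(sa_tag) {
  idx <- which(!is.na(sa_tag) & nzchar(sa_tag))
  if (length(idx) == 0L)
    return(data.table(record = integer(0), chrom = character(0),
                      pos = integer(0), strand = character(0),
                      cigar = character(0), mapq = integer(0), nm = integer(0)))
  parts <- strsplit(sa_tag[idx], ";", fixed = TRUE)
  rec <- rep(idx, lengths(parts))
  flat <- unlist(parts, use.names = FALSE)
  fields <- tstrsplit(flat, ",", fixed = TRUE)
  data.table(record = rec, chrom = fields[[1L]],
             pos = as.integer(fields[[2L]]) - 1L, strand = fields[[3L]],
             cigar = fields[[4L]], mapq = as.integer(fields[[5L]]),
             nm = as.integer(fields[[6L]]))
}

# reference-consumed width per CIGAR (vectorized; cached over unique strings)
cigar_ref_width <- function(cigar) {
  u <- unique(cigar)
  w <- GenomicAlignments::cigarWidthAlongReferenceSpace(u)
  w[match(cigar, u)]
}

# leading soft/hard clip length in stored-SEQ orientation
cigar_lead_clip <- function(cigar) {
  m <- regmatches(cigar, regexpr("^[0-9]+[SH]", cigar))
  out <- integer(length(cigar))
  has <- grepl("^[0-9]+[SH]", cigar)
  out[has] <- as.integer(sub("[SH]", "", m))
  out
}
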