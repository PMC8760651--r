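# Independent brute-force oracles used to freeze expected values.

# Peak prominence by direct scan, mirroring the stated definition:
# local maxima are plateaus with strictly smaller flanks (boundary plateaus
# excluded), apex leftmost; bases are minima up to the nearest strictly
# higher position or the array edge; region = maximal run above apex - prom.
oracle_peaks <- function(x, min_prominence) {
  n <- length(x)
  out <- list()
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j + 1L <= n && x[j + 1L] == x[i]) j <- j + 1L
      if (j + 1L <= n && x[j + 1L] < x[i]) {
        h <- x[i]
        left <- x[seq_len(i - 1L)]
        hi <- which(left > h)
        lmin <- min(left[seq.int(if (length(hi)) max(hi) + 1L else 1L, i - 1L)])
        right <- x[seq.int(j + 1L, n)]
        hi <- which(right > h)
        rmin <- min(right[seq_len(if (length(hi)) min(hi) - 1L else length(right))])
        prom <- h - max(lmin, rmin)
        if (prom >= min_prominence) {
          thr <- h - prom
          s <- i
          while (s - 1L >= 1L && x[s - 1L] > thr) s <- s - 1L
          e <- j
          while (e + 1L <= n && x[e + 1L] > thr) e <- e + 1L
          out[[length(out) + 1L]] <-
            data.frame(start = s - 1L, end = e, apex = i - 1L,
                       height = h, prominence = prom)
        }
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0), apex = integer(0),
                      height = numeric(0), prominence = numeric(0)))
  do.call(rbind, out)
}

# Interval union by per-base painting (merge oracle).
oracle_interval_union <- function(starts, ends, L) {
  covered <- logical(L)
  for (i in seq_along(starts)) covered[(starts[i] + 1L):ends[i]] <- TRUE
  r <- rle(covered)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  data.frame(start = lo[r$values] - 1L, end = hi[r$values])
}

# Per-base coverage recount from explicit blocks.
oracle_coverage <- function(starts, ends, L) {
  d <- numeric(L)
  for (i in seq_along(starts))
    d[(starts[i] + 1L):ends[i]] <- d[(starts[i] + 1L):ends[i]] + 1
  d
}

# All-pairs shared-canonical-k-mer graph + connected components.
oracle_components <- function(seqs, k, min_shared) {
  canon_kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    km <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
    unique(pmin(km, rc))
  }
  sets <- lapply(seqs, canon_kmers)
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (length(intersect(sets[[i]], sets[[j]])) >= min_shared) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# random DNA string helper
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# mutate a sequence at a given per-base rate (substitutions only)
mutate_seq <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
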