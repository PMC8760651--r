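#' Simulation configuration for semi-artificial circSeq experiments
#'
#' Builds the parameter set for the built-in circSeq simulator. The defaults
#' reproduce the geometry of a small plant-genome benchmark: a ~0.6 Mb
#' three-chromosome reference carrying a single 6,695 bp LTR-retrotransposon-like
#' element, whose circular excision product is amplified by rolling-circle
#' amplification into a nine-copy tandem concatemer. circSeq reads are drawn
#' as a mixture of concatemer and genomic background fragments; control reads
#' come from the reference only.
#'
#' @param seed Integer seed; all simulator randomness derives from it.
#' @param n_chromosomes Number of reference chromosomes.
#' @param total_ref_length Total reference length in bases (split evenly).
#' @param element_length Length of the planted circular element (bases).
#' @param tandem_copies Copies of the element in the rolling-circle concatemer.
#' @param n_pairs_circ,n_pairs_control Read pairs per dataset.
#' @param read_length Read length in bases (both mates).
#' @param insert_mean,insert_sd Fragment (insert) size distribution in bases;
#'   inserts are truncated to `[2 * read_length, template length]`.
#' @param error_rate Per-base substitution error probability.
#' @param enrichment_fraction Fraction of circSeq pairs drawn from the
#'   concatemer template; the remainder is genomic background. The default of
#'   0.5 makes the circle the majority species after amplification and yields
#'   a region enrichment score of the magnitude seen in practice (tens).
#'
#' @return A list of class `ecc_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, total_ref_length = 60000, element_length = 2000,
#'                   n_pairs_circ = 500, n_pairs_control = 500)
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       total_ref_length = 600000L,
                       element_length = 6695L,
                       tandem_copies = 9L,
                       n_pairs_circ = 50000L,
                       n_pairs_control = 50000L,
                       read_length = 200L,
                       insert_mean = 500L,
                       insert_sd = 50L,
                       error_rate = 0.01,
                       enrichment_fraction = 0.5) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              total_ref_length = as.integer(total_ref_length),
              element_length = as.integer(element_length),
              tandem_copies = as.integer(tandem_copies),
              n_pairs_circ = as.integer(n_pairs_circ),
              n_pairs_control = as.integer(n_pairs_control),
              read_length = as.integer(read_length),
              insert_mean = as.integer(insert_mean),
              insert_sd = as.integer(insert_sd),
              error_rate = as.numeric(error_rate),
              enrichment_fraction = as.numeric(enrichment_fraction))
  counts <- c("n_chromosomes", "total_ref_length", "element_length",
              "tandem_copies", "n_pairs_circ", "n_pairs_control",
              "read_length", "insert_mean", "insert_sd")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      stop("sim_config: '", f, "' must be a positive count")
  }
  if (cfg$error_rate < 0 || cfg$error_rate >= 1)
    stop("sim_config: error_rate must be in [0, 1)")
  if (cfg$enrichment_fraction < 0 || cfg$enrichment_fraction > 1)
    stop("sim_config: enrichment_fraction must be in [0, 1]")
  if (cfg$read_length >= cfg$insert_mean)
    stop("sim_config: read_length must be smaller than insert_mean")
  if (cfg$element_length >= cfg$total_ref_length)
    stop("sim_config: element_length must be smaller than total_ref_length")
  class(cfg) <- "ecc_sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a multi-chromosome reference with one planted circular element
#'
#' Generates `n_chromosomes` i.i.d. random DNA sequences whose lengths sum to
#' `total_ref_length` and embeds a single copy of a random element of
#' `element_length` bases into the last chromosome (replacement, so chromosome
#' lengths are unchanged). The planted locus is recorded as the ground-truth
#' circle: the simulated eccDNA is the circularized element, and its junction
#' maps the element end back onto the element start.
#'
#' Deterministic for a fixed `config$seed` (the seed is applied here).
#'
#' @param config An `ecc_sim_config`.
#' @return An object of class `ecc_genome`: list with `seqs` (named character
#'   vector of chromosome sequences), `truth` (one-row data.frame with
#'   `chrom`, `start`, `end` in 0-based half-open coordinates, `element_id`,
#'   `junction_position`), and `element` (the element sequence).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "ecc_sim_config"))
  set.seed(config$seed)
  n <- config$n_chromosomes
  base_len <- config$total_ref_length %/% n
  lens <- rep(base_len, n)
  lens[n] <- lens[n] + config$total_ref_length %% n
  if (config$element_length > lens[n])
    stop("simulate_reference: element is longer than its host chromosome")
  ids <- paste0("chr", seq_len(n))
  seqs <- vapply(lens, random_dna, character(1))
  names(seqs) <- ids

  element <- random_dna(config$element_length)
  host <- n
  # keep the element away from chromosome ends so inserts fit around it
  margin <- min(config$insert_mean * 4L, (lens[host] - config$element_length) %/% 2L)
  start <- sample.int(lens[host] - config$element_length - 2L * margin + 1L, 1L) - 1L + margin
  substr(seqs[host], start + 1L, start + config$element_length) <- element

  truth <- data.frame(chrom = ids[host],
                      start = start,
                      end = start + config$element_length,
                      element_id = "element1",
                      junction_position = start,
                      stringsAsFactors = FALSE)
  structure(list(seqs = seqs, truth = truth, element = element),
            class = "ecc_genome")
}

#' Build the rolling-circle concatemer of the planted element
#'
#' Random rolling-circle amplification of a circular template produces a
#' head-to-tail tandem repeat of the circle sequence; every copy boundary in
#' the concatemer is therefore an exact copy of the circular junction
#' (element end followed by element start).
#'
#' @param genome An `ecc_genome` from [simulate_reference()].
#' @param truth Ground-truth row (defaults to `genome$truth`).
#' @param copies Number of tandem copies (>= 1).
#' @return A single DNA string of length `copies * element_length`.
#' @export
build_concatemer <- function(genome, truth = genome$truth, copies) {
  stopifnot(inherits(genome, "ecc_genome"))
  copies <- as.integer(copies)
  if (is.na(copies) || copies < 1L) stop("build_concatemer: copies must be >= 1")
  element <- substr(genome$seqs[[truth$chrom]], truth$start + 1L, truth$end)
  strrep(element, copies)
}

# vectorized per-base substitution errors: flatten reads into one byte vector,
# mutate sampled offsets to a different base, then re-slice fixed-width reads
inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  widths <- nchar(seqs)
  big <- charToRaw(paste(seqs, collapse = ""))
  n_err <- rbinom(1L, length(big), error_rate)
  if (n_err > 0L) {
    pos <- sample.int(length(big), n_err)
    bases <- charToRaw("ACGT")
    cur <- match(big[pos], bases)
    step <- sample.int(3L, n_err, replace = TRUE)
    big[pos] <- bases[((cur - 1L + step) %% 4L) + 1L]
  }
  ends <- cumsum(widths)
  substring(rawToChar(big), ends - widths + 1L, ends)
}

#' Simulate paired-end reads from a single template
#'
#' Fragments start uniformly on the template with insert length drawn from
#' Normal(`insert_mean`, `insert_sd`) truncated (by rejection) to
#' `[2 * read_length, template length]`. Mate 1 is the fragment start, mate 2
#' the reverse complement of the fragment end; with probability 1/2 the roles
#' are swapped (fragment strand "-"). Substitution errors are applied at
#' `error_rate` per base. Qualities are constant Sanger 'I'.
#'
#' Uses the current RNG stream; seed via `set.seed()` or run under
#' [simulate_circseq()], which seeds from the config.
#'
#' @param template DNA string.
#' @param n_pairs Number of pairs.
#' @param config An `ecc_sim_config`.
#' @param template_id Provenance label stored in read names.
#' @param prefix Read-name prefix (must make names unique across calls).
#' @return A data.frame of class `ecc_readpairs` with columns `name`, `seq1`,
#'   `seq2` (as sequenced; mate 2 reverse-complemented), `template_id`,
#'   `offset` (0-based fragment start on the template), `isize`, `strand`.
#' @export
simulate_read_pairs <- function(template, n_pairs, config,
                                template_id = "template", prefix = "sim") {
  n_pairs <- as.integer(n_pairs)
  tlen_t <- nchar(template)
  rl <- config$read_length
  min_ins <- 2L * rl
  if (tlen_t < config$insert_mean + 4L * config$insert_sd)
    stop("simulate_read_pairs: template shorter than insert_mean + 4*insert_sd")
  isize <- integer(0)
  while (length(isize) < n_pairs) {
    draw <- as.integer(round(rnorm(n_pairs - length(isize),
                                   config$insert_mean, config$insert_sd)))
    isize <- c(isize, draw[draw >= min_ins & draw <= tlen_t])
  }
  offset <- vapply(tlen_t - isize + 1L,
                   function(m) sample.int(m, 1L) - 1L, integer(1))
  strand <- c("+", "-")[sample.int(2L, n_pairs, replace = TRUE)]

  left <- substring(template, offset + 1L, offset + rl)
  right <- substring(template, offset + isize - rl + 1L, offset + isize)
  # "+" fragments: mate1 = fragment start (forward), mate2 = rc(fragment end);
  # "-" fragments: roles swap (mate1 sequenced off the minus strand)
  right_rc <- revcomp(right)
  seq1 <- ifelse(strand == "+", left, right_rc)
  seq2 <- ifelse(strand == "+", right_rc, left)
  seq1 <- inject_errors(seq1, config$error_rate)
  seq2 <- inject_errors(seq2, config$error_rate)

  name <- sprintf("%s_%07d|%s|%d|%d|%s", prefix, seq_len(n_pairs),
                  template_id, offset, isize, strand)
  out <- data.frame(name = name, seq1 = seq1, seq2 = seq2,
                    template_id = template_id, offset = offset,
                    isize = isize, strand = strand, stringsAsFactors = FALSE)
  class(out) <- c("ecc_readpairs", "data.frame")
  out
}

# background pairs drawn across chromosomes proportional to length
simulate_background_pairs <- function(genome, n_pairs, config, prefix) {
  lens <- nchar(genome$seqs)
  ok <- lens >= config$insert_mean + 4L * config$insert_sd
  if (!any(ok)) stop("no chromosome long enough for background inserts")
  n_per <- as.vector(stats::rmultinom(1L, n_pairs, lens[ok] / sum(lens[ok])))
  sets <- mapply(function(id, n) {
    if (n == 0L) return(NULL)
    simulate_read_pairs(genome$seqs[[id]], n, config, template_id = id,
                        prefix = paste0(prefix, "_", id))
  }, names(genome$seqs)[ok], n_per, SIMPLIFY = FALSE)
  out <- do.call(rbind, sets[!vapply(sets, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("ecc_readpairs", "data.frame")
  out
}

#' Write the ground-truth circle as BED4
#'
#' @param truth One-row data.frame (`chrom`, `start`, `end`, `element_id`),
#'   0-based half-open.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", truth$chrom, truth$start, truth$end,
                     truth$element_id), path)
  invisible(path)
}

#' Read a BED4 ground-truth file
#' @param path BED file written by [write_ground_truth()].
#' @return data.frame with `chrom`, `start`, `end`, `element_id`.
#' @export
read_ground_truth <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(x) <- c("chrom", "start", "end", "element_id")[seq_len(ncol(x))]
  x
}

write_fastq <- function(names, seqs, path, qual_char = "I") {
  qual <- strrep(qual_char, nchar(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", names, "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

write_fasta <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = width)
  invisible(path)
}

#' Simulate a complete circSeq experiment with ground truth
#'
#' Runs the whole simulator: reference with one planted circular element,
#' rolling-circle concatemer, circSeq reads (an `enrichment_fraction` mixture
#' of concatemer and genomic background pairs), control reads from the
#' reference only, oracle alignments for both datasets, and the ground-truth
#' BED. All outputs are deterministic for a fixed `config$seed`.
#'
#' @param config An `ecc_sim_config`.
#' @param out_dir Output directory (created if missing); set `NULL` to skip
#'   writing files and return the in-memory objects only.
#' @return Invisibly, a list with `genome`, `truth`, `circ_pairs`,
#'   `ctrl_pairs`, and `files` (named paths: `reference`, `circ_r1`,
#'   `circ_r2`, `ctrl_r1`, `ctrl_r2`, `circ_sam`, `ctrl_sam`, `truth_bed`,
#'   `annotation`, `config`).
#' @export
simulate_circseq <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "ecc_sim_config"))
  genome <- simulate_reference(config)          # seeds the RNG stream
  concat <- build_concatemer(genome, copies = config$tandem_copies)

  n_conc <- as.integer(round(config$enrichment_fraction * config$n_pairs_circ))
  n_bg <- config$n_pairs_circ - n_conc
  parts <- list()
  if (n_conc > 0L)
    parts$conc <- simulate_read_pairs(concat, n_conc, config,
                                      template_id = "concatemer",
                                      prefix = "circ_conc")
  if (n_bg > 0L)
    parts$bg <- simulate_background_pairs(genome, n_bg, config, prefix = "circ_bg")
  circ <- do.call(rbind, unname(parts))
  class(circ) <- c("ecc_readpairs", "data.frame")
  ctrl <- simulate_background_pairs(genome, config$n_pairs_control, config,
                                    prefix = "ctrl")

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(out_dir, x)
    files <- c(reference = fp("reference.fasta"),
               circ_r1 = fp("circ_1.fastq"), circ_r2 = fp("circ_2.fastq"),
               ctrl_r1 = fp("ctrl_1.fastq"), ctrl_r2 = fp("ctrl_2.fastq"),
               circ_sam = fp("circ.sam"), ctrl_sam = fp("ctrl.sam"),
               truth_bed = fp("truth.bed"), annotation = fp("element.fasta"),
               config = fp("sim_config.json"))
    write_fasta(genome$seqs, files[["reference"]])
    write_fastq(paste0(circ$name, "/1"), circ$seq1, files[["circ_r1"]])
    write_fastq(paste0(circ$name, "/2"), circ$seq2, files[["circ_r2"]])
    write_fastq(paste0(ctrl$name, "/1"), ctrl$seq1, files[["ctrl_r1"]])
    write_fastq(paste0(ctrl$name, "/2"), ctrl$seq2, files[["ctrl_r2"]])
    write_oracle_sam(genome, circ, files[["circ_sam"]])
    write_oracle_sam(genome, ctrl, files[["ctrl_sam"]])
    write_ground_truth(genome$truth, files[["truth_bed"]])
    write_fasta(setNames(genome$element, genome$truth$element_id),
                files[["annotation"]])
    jsonlite::write_json(unclass(config), files[["config"]], auto_unbox = TRUE)
  }
  invisible(list(genome = genome, truth = genome$truth,
                 circ_pairs = circ, ctrl_pairs = ctrl, files = files))
}
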