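#' Pipeline configuration
#'
#' Assembles paths and thresholds for [run_pipeline()]. Three running modes
#' are supported, mirroring the available input data: `"map"` needs circSeq
#' alignments plus the reference genome and detects candidate regions from
#' read signatures; `"clu"` needs circSeq and control reads and detects
#' enriched circular sequences reference-free by comparative clustering;
#' `"all"` runs both and combines them into very-high-confidence candidates.
#' Reads are expected pre-trimmed; quality trimming is out of scope.
#'
#' @param mode One of `"all"`, `"map"`, `"clu"`.
#' @param circ_reads Character vector of 1-2 FASTQ/FASTA paths (circSeq).
#' @param control_reads Character vector of 1-2 paths (control dataset).
#' @param reference Reference genome FASTA path.
#' @param circ_alignments,control_alignments SAM paths (circSeq / control
#'   reads mapped to `reference`).
#' @param annotation Optional FASTA of known repeats/genes for annotation.
#' @param out_dir Output directory.
#' @param seed Seed for subsampling steps.
#' @param min_split Minimum split reads flanking a circular junction (5).
#' @param breakpoint_tolerance Split endpoint pooling window in bp (5).
#' @param max_insert Discordant insert cutoff (default: estimated).
#' @param merge_distance Discordant interval merge distance in bp (0).
#' @param min_prominence Minimum coverage peak prominence in BPM (1.0).
#' @param epsilon Control-coverage floor for enrichment scores, BPM (0.1).
#' @param sample_pairs Pairs per dataset for clustering (6000, ~4x coverage
#'   of a 0.6 Mb genome at 200 bp reads).
#' @param cluster_k K-mer size for read clustering (15).
#' @param min_shared,min_cluster Cluster graph thresholds (scale-aware
#'   defaults; see [cluster_reads()]).
#' @param cluster_proportion circSeq proportion cutoff, strict (0.8).
#' @param min_mate_links Mate links per supercluster edge (2).
#' @param min_overlap Contig assembly overlap in bp (31).
#' @param link_min_identity,link_min_length Contig-to-region match thresholds
#'   (0.8, 50 bp).
#' @param annotation_min_identity,annotation_seed_k Annotation search
#'   thresholds (0.8, 13).
#' @param max_low_confidence Cap on reported low-confidence candidates (10000).
#' @return A list of class `ecc_pipeline_config`.
#' @export
ecc_config <- function(mode = c("all", "map", "clu"),
                       circ_reads = NULL, control_reads = NULL,
                       reference = NULL, circ_alignments = NULL,
                       control_alignments = NULL, annotation = NULL,
                       out_dir = tempfile("eccscout_run_"), seed = 1L,
                       min_split = 5L, breakpoint_tolerance = 5L,
                       max_insert = NULL, merge_distance = 0L,
                       min_prominence = 1.0, epsilon = 0.1,
                       sample_pairs = 6000L, cluster_k = 15L,
                       min_shared = NULL, min_cluster = NULL,
                       cluster_proportion = 0.8, min_mate_links = 2L,
                       min_overlap = 31L, link_min_identity = 0.8,
                       link_min_length = 50L, annotation_min_identity = 0.8,
                       annotation_seed_k = 13L, max_low_confidence = 10000L) {
  cfg <- list(mode = match.arg(mode), circ_reads = circ_reads,
              control_reads = control_reads, reference = reference,
              circ_alignments = circ_alignments,
              control_alignments = control_alignments,
              annotation = annotation, out_dir = out_dir,
              seed = as.integer(seed), min_split = min_split,
              breakpoint_tolerance = breakpoint_tolerance,
              max_insert = max_insert, merge_distance = merge_distance,
              min_prominence = min_prominence, epsilon = epsilon,
              sample_pairs = sample_pairs, cluster_k = cluster_k,
              min_shared = min_shared, min_cluster = min_cluster,
              cluster_proportion = cluster_proportion,
              min_mate_links = min_mate_links, min_overlap = min_overlap,
              link_min_identity = link_min_identity,
              link_min_length = link_min_length,
              annotation_min_identity = annotation_min_identity,
              annotation_seed_k = annotation_seed_k,
              max_low_confidence = max_low_confidence)
  class(cfg) <- "ecc_pipeline_config"
  cfg
}

sniff_format <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  l1 <- readLines(con, n = 1L)
  if (length(l1) == 0L) return("empty")
  if (startsWith(l1, ">")) return("fasta")
  if (grepl("^@(HD|SQ|PG|RG|CO)\t", l1)) return("sam")
  if (startsWith(l1, "@")) return("fastq")
  if (length(strsplit(l1, "\t", fixed = TRUE)[[1L]]) >= 11L) return("sam")
  "unknown"
}

check_file <- function(path, what, formats) {
  if (is.null(path)) return(invisible(NULL))
  for (p in path) {
    if (!file.exists(p)) stop("validate_inputs: ", what, " file not found: ", p)
    fmt <- sniff_format(p)
    gz <- grepl("\\.gz$", p)
    if (!gz && !fmt %in% formats)
      stop("validate_inputs: ", what, " (", p, ") looks like '", fmt,
           "', expected ", paste(formats, collapse = "/"))
  }
  invisible(NULL)
}

#' Validate pipeline inputs for the chosen mode
#'
#' circSeq data are always mandatory. Mode `"map"` additionally requires a
#' reference genome and circSeq alignments; mode `"clu"` requires a control
#' read set; mode `"all"` requires everything. Files are existence- and
#' format-sniffed (FASTA `>`, FASTQ `@`, SAM header) before any compute.
#'
#' @param config An `ecc_pipeline_config`.
#' @return The config, invisibly, or an error naming the missing input.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "ecc_pipeline_config"))
  mode <- config$mode
  need_map <- mode %in% c("all", "map")
  need_clu <- mode %in% c("all", "clu")
  if (need_map) {
    if (is.null(config$circ_alignments))
      stop("validate_inputs: mode '", mode, "' requires circSeq alignments (SAM)")
    if (is.null(config$reference))
      stop("validate_inputs: mode '", mode, "' requires a reference genome FASTA")
  }
  if (need_clu) {
    if (is.null(config$circ_reads))
      stop("validate_inputs: mode '", mode, "' requires circSeq reads; ",
           "the clustering module is only executed with read data")
    if (is.null(config$control_reads))
      stop("validate_inputs: mode '", mode, "' requires a control read dataset")
  }
  if (mode == "map" && is.null(config$circ_alignments) && is.null(config$circ_reads))
    stop("validate_inputs: circSeq data are mandatory")
  check_file(config$circ_reads, "circSeq reads", c("fastq", "fasta"))
  check_file(config$control_reads, "control reads", c("fastq", "fasta"))
  check_file(config$reference, "reference", "fasta")
  check_file(config$circ_alignments, "circSeq alignments", "sam")
  check_file(config$control_alignments, "control alignments", "sam")
  check_file(config$annotation, "annotation database", "fasta")
  invisible(config)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the eccDNA detection pipeline
#'
#' Executes the stages selected by `config$mode` (see [ecc_config()]), writes
#' per-stage BED/TSV/FASTA outputs plus a JSON run manifest under
#' `config$out_dir`, and returns the results. Deterministic for fixed inputs
#' and seed.
#'
#' @param config A validated `ecc_pipeline_config`.
#' @return Invisibly, a list with (depending on mode) `candidates` (ranked
#'   candidate regions), `splits`, `discordants`, `peaks`, `clusters`,
#'   `selected_clusters`, `superclusters`, `linked`, `summary`, and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  validate_inputs(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t_all <- proc.time()[["elapsed"]]
  timings <- list()
  counts <- list()
  res <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  op <- function(x) file.path(config$out_dir, x)
  genome <- NULL

  if (config$mode %in% c("all", "map")) {
    circ_aln <- stage("parse_alignments", read_sam(config$circ_alignments))
    counts$circ_alignments <- nrow(circ_aln)
    splits <- stage("split_junctions",
                    call_split_junctions(circ_aln, config$min_split,
                                         config$breakpoint_tolerance))
    disc <- stage("discordant_regions",
                  call_discordant_regions(circ_aln, config$max_insert,
                                          config$merge_distance))
    circ_bpm <- stage("coverage", normalize_bpm(compute_coverage(circ_aln)))
    peaks <- stage("peaks", find_peaks(circ_bpm, config$min_prominence))
    counts$split_junctions <- nrow(splits)
    counts$discordant_regions <- nrow(disc)
    counts$coverage_peaks <- nrow(peaks)

    cands <- stage("intersect_evidence", intersect_evidence(splits, disc, peaks))
    ctrl_bpm <- NULL
    if (!is.null(config$control_alignments)) {
      ctrl_aln <- stage("parse_control_alignments", read_sam(config$control_alignments))
      counts$control_alignments <- nrow(ctrl_aln)
      ctrl_bpm <- stage("control_coverage",
                        normalize_bpm(compute_coverage(ctrl_aln)))
    }
    cands$enrichment_score <- stage("enrichment",
      score_enrichment(cands, circ_bpm, ctrl_bpm, config$epsilon))

    # cap reported low-confidence candidates to bound output size
    if (sum(cands$confidence == "low") > config$max_low_confidence) {
      low <- which(cands$confidence == "low")
      drop <- low[order(-cands$enrichment_score[low])][-seq_len(config$max_low_confidence)]
      cands <- cands[-drop, , drop = FALSE]
    }

    genome <- stage("load_reference", {
      g <- Biostrings::readDNAStringSet(config$reference)
      setNames(as.character(g), sub(" .*", "", names(g)))
    })
    cands$annotation <- ""
    if (!is.null(config$annotation) && nrow(cands) > 0L) {
      db <- Biostrings::readDNAStringSet(config$annotation)
      cands$annotation <- stage("annotation", vapply(seq_len(nrow(cands)), function(i) {
        rseq <- substr(genome[[cands$chrom[i]]], cands$start[i] + 1L, cands$end[i])
        h <- annotate_region(rseq, db, config$annotation_min_identity,
                             config$annotation_seed_k)
        if (nrow(h) == 0L) "unannotated" else
          sprintf("%s(%.3f/%dbp/%s)", h$subject_id[1L], h$identity[1L],
                  h$aligned_length[1L], h$subject_strand[1L])
      }, character(1)))
    }
    cands <- rank_candidates(cands)
    counts$candidate_regions <- nrow(cands)
    counts$high_confidence_regions <- sum(cands$confidence == "high")
    res$splits <- splits; res$discordants <- disc; res$peaks <- peaks
    res$candidates <- cands
    res$circ_bpm <- circ_bpm; res$ctrl_bpm <- ctrl_bpm

    stage("write_mapping_outputs", {
      writeLines(sprintf("%s\t%d\t%d\tSJ%03d\t%d", splits$chrom, splits$start,
                         splits$end, seq_len(nrow(splits)), splits$support),
                 op("split_junctions.bed"))
      writeLines(sprintf("%s\t%d\t%d\tDR%03d\t%d", disc$chrom, disc$start,
                         disc$end, seq_len(nrow(disc)), disc$pair_count),
                 op("discordant_regions.bed"))
      writeLines(sprintf("%s\t%d\t%d\tPK%03d\t%.4f\t.\t%.4f", peaks$chrom,
                         peaks$start, peaks$end, seq_len(nrow(peaks)),
                         peaks$height, peaks$prominence),
                 op("coverage_peaks.bed"))
      writeLines(sprintf("%s\t%d\t%d\t%s\t%.4f\t.\t%s\t%s\t%d\t%d\t%s\t%s",
                         cands$chrom, cands$start, cands$end, cands$name,
                         cands$enrichment_score, cands$confidence,
                         paste0(ifelse(cands$evidence_split, "S", ""),
                                ifelse(cands$evidence_discordant, "D", ""),
                                ifelse(cands$evidence_peak, "P", "")),
                         cands$split_reads, cands$discordant_pairs,
                         ifelse(is.na(cands$peak_prominence), ".",
                                sprintf("%.4f", cands$peak_prominence)),
                         cands$annotation),
                 op("candidate_regions.bed"))
      write_tsv(cands, op("candidate_regions.tsv"))
    })
  }

  if (config$mode %in% c("all", "clu")) {
    prepared <- stage("prepare_reads",
                      prepare_reads(config$circ_reads, config$control_reads,
                                    config$sample_pairs, config$seed))
    counts$clustered_reads <- nrow(prepared)
    clusters <- stage("cluster_reads",
                      cluster_reads(prepared, config$cluster_k,
                                    config$min_shared, config$min_cluster))
    selected <- stage("select_clusters",
                      select_candidate_clusters(clusters, config$cluster_proportion))
    sc <- stage("superclusters", link_superclusters(clusters, config$min_mate_links))
    clusters <- stage("contigs",
                      build_contigs(clusters, ids = selected,
                                    min_overlap = config$min_overlap,
                                    seed = config$seed))
    counts$clusters <- nrow(clusters$clusters)
    counts$selected_clusters <- length(selected)
    res$clusters <- clusters; res$selected_clusters <- selected
    res$superclusters <- sc

    stage("write_clustering_outputs", {
      tab <- merge(clusters$clusters, sc, by = "id", sort = FALSE)
      write_tsv(tab, op("clusters.tsv"))
      write_tsv(tab[tab$id %in% selected, , drop = FALSE],
                op("selected_clusters.tsv"))
      contigs <- unlist(lapply(selected, function(id) {
        ct <- clusters$contigs[[id]]
        if (length(ct) == 0L) return(character(0))
        setNames(ct, sprintf("%s_contig%03d", id, seq_along(ct)))
      }))
      if (length(contigs) > 0L) write_fasta(contigs, op("contigs.fasta"))
      else writeLines(character(0), op("contigs.fasta"))
    })
  }

  if (config$mode == "all") {
    linked <- stage("comparative_linking",
                    link_clusters_to_regions(res$clusters, res$selected_clusters,
                                             res$candidates, genome,
                                             config$link_min_identity,
                                             config$link_min_length))
    summ <- stage("summarize", summarize_run(res$candidates, linked,
                                             res$selected_clusters))
    counts$very_high_confidence <-
      sum(summ$candidates$combined_confidence == "very_high")
    res$linked <- linked; res$summary <- summ
    stage("write_summary", {
      write_tsv(summ$candidates, op("summary_candidates.tsv"))
      write_tsv(linked$links, op("cluster_region_links.tsv"))
      vh <- summ$candidates[summ$candidates$combined_confidence == "very_high", ]
      writeLines(sprintf("%s\t%d\t%d\t%s\t%.4f\t.", vh$chrom, vh$start, vh$end,
                         vh$name, vh$enrichment_score),
                 op("very_high_confidence.bed"))
      writeLines(as.character(summ$clustering_only), op("clustering_only.txt"))
    })
  }

  manifest <- list(
    tool = "eccscout", version = as.character(utils::packageVersion("eccscout")),
    config = config[!vapply(config, is.null, logical(1))],
    input_checksums = {
      ins <- unlist(config[c("circ_reads", "control_reads", "reference",
                             "circ_alignments", "control_alignments", "annotation")])
      if (length(ins) > 0L) as.list(tools::md5sum(ins)) else list()
    },
    record_counts = counts,
    seconds_per_stage = timings,
    total_seconds = round(proc.time()[["elapsed"]] - t_all, 3))
  jsonlite::write_json(manifest, op("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  res$manifest <- manifest
  invisible(res)
}
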