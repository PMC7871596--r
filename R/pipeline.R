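## End-to-end orchestration: filter -> frequencies -> infer AA -> scan per
## focal group -> select -> annotate, with every intermediate artifact
## written so each stage can be re-run independently, plus a machine-
## readable manifest (versions, parameters, input/output checksums,
## per-stage record counts). The manifest carries no timestamps: identical
## inputs and parameters must reproduce byte-identical artifacts. Timing
## and progress go to standard error.

#' Pipeline run configuration
#'
#' @param vcf multi-sample VCF path.
#' @param group_map sample-to-group TSV path.
#' @param fai FASTA index (chromosome lengths).
#' @param genes BED/GFF3 gene models; `NULL` skips the annotation stage.
#' @param outdir output directory.
#' @param thresholds a [filter_thresholds()] object.
#' @param min_called minimum called chromosomes per outgroup lineage.
#' @param window_bp scan window size in bp.
#' @param top_fraction selected upper tail of window counts per chromosome.
#' @param flank_bp annotation flank width.
#' @param focal_groups focal cattle groups to score.
#' @return a list of class `aa_run_config`.
#' @export
run_config <- function(vcf, group_map, fai, genes = NULL,
                       outdir = tempfile("aascan_run_"),
                       thresholds = filter_thresholds(),
                       min_called = 2L, window_bp = 10000L,
                       top_fraction = 0.001, flank_bp = 1000L,
                       focal_groups = aa_focal_groups()) {
  for (p in c(vcf, group_map, fai, genes))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  if (window_bp < 1L || top_fraction <= 0 || top_fraction >= 1 ||
      flank_bp < 0L || min_called < 1L)
    stop("run_config parameter out of range")
  structure(list(vcf = vcf, group_map = group_map, fai = fai, genes = genes,
                 outdir = outdir, thresholds = thresholds,
                 min_called = min_called, window_bp = as.integer(window_bp),
                 top_fraction = top_fraction, flank_bp = as.integer(flank_bp),
                 focal_groups = focal_groups),
            class = "aa_run_config")
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[aascan] stage %-12s done in %.1fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the complete ancestral-allele analysis
#'
#' Executes all stages of the scan on one cohort and writes every
#' intermediate and final artifact under `config$outdir`, together with
#' `manifest.json`.
#'
#' @param config an [run_config()] object.
#' @return the manifest, invisibly (also written as JSON): parameters,
#'   input/output md5 checksums and per-stage record counts.
#' @export
run_aa_pipeline <- function(config) {
  stopifnot(inherits(config, "aa_run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  counts <- list()

  gm <- .stage("group_map", parse_group_map(config$group_map))
  vcf <- .stage("read_vcf", read_cohort_vcf(config$vcf))
  counts$vcf_records <- nrow(vcf$sites)

  flt <- .stage("filter", filter_sites(vcf, config$thresholds))
  counts$filtered_records <- nrow(flt$records$sites)
  fwrite(flt$report, out("filter_report.tsv"), sep = "\t")

  freqs <- .stage("frequencies", site_frequencies(flt$records, gm))
  counts$frequency_rows <- nrow(freqs)
  write_freqs(freqs, out("frequencies.tsv"))

  calls <- .stage("infer_aa", call_genome(freqs, min_called = config$min_called))
  counts$aa_calls <- nrow(calls)
  write_aa_list(calls, out("aa_list.txt"))

  chrom_lengths <- read_fai(config$fai)
  theta <- .stage("scan", compute_theta(calls, freqs,
                                        focal_groups = config$focal_groups))
  fwrite(theta, out("theta.tsv"), sep = "\t")
  windows <- count_windows(theta, chrom_lengths,
                           window_bp = config$window_bp, freqs = freqs)
  fwrite(windows, out("windows.tsv"), sep = "\t")
  counts$theta_records <- nrow(theta)
  counts$retained_sites <- sum(theta$f)
  counts$windows <- nrow(windows)

  cls <- .stage("select", {
    th <- chromosome_thresholds(windows, top_fraction = config$top_fraction)
    fwrite(th, out("thresholds.tsv"), sep = "\t")
    classify_windows(windows, th)
  })
  fwrite(cls, out("window_classes.tsv"), sep = "\t")
  write_windows_bed(cls, out("window_classes.bed"),
                    labels = c("high", "null_no_aa", "null_derived"))
  counts$high_windows <- sum(cls$label == "high")
  counts$null_windows <- sum(cls$label %in% c("null_no_aa", "null_derived"))
  fwrite(null_ratio(windows), out("null_ratio.tsv"), sep = "\t")

  if (!is.null(config$genes)) {
    ann <- .stage("annotate", {
      genes <- load_genes(config$genes)
      annotate_windows(cls, genes, flank_bp = config$flank_bp)
    })
    fwrite(ann$annotated, out("annotated_windows.tsv"), sep = "\t")
    for (g in names(ann$genes_high))
      writeLines(ann$genes_high[[g]], out(sprintf("genes_high_%s.txt", g)),
                 useBytes = TRUE)
    for (g in names(ann$genes_null))
      writeLines(ann$genes_null[[g]], out(sprintf("genes_null_%s.txt", g)),
                 useBytes = TRUE)
    counts$genes_high <- lengths(ann$genes_high)
    counts$genes_null <- lengths(ann$genes_null)
  }

  artifacts <- sort(setdiff(list.files(config$outdir), "manifest.json"))
  manifest <- list(
    tool = "aascan",
    version = as.character(utils::packageVersion("aascan")),
    parameters = list(
      filter = unclass(config$thresholds),
      min_called = config$min_called,
      window_bp = config$window_bp,
      top_fraction = config$top_fraction,
      flank_bp = config$flank_bp,
      focal_groups = config$focal_groups
    ),
    inputs = as.list(tools::md5sum(unlist(
      config[c("vcf", "group_map", "fai", "genes")]))),
    counts = counts,
    outputs = as.list(tools::md5sum(file.path(config$outdir, artifacts)))
  )
  names(manifest$outputs) <- artifacts
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
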