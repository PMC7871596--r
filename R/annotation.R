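## Gene-model annotation of selected windows.
##
## Selected windows are intersected with gene bodies; windows falling in
## intergenic space or only in the upstream/downstream flanks of a gene are
## excluded from the gene lists, leaving regions that overlap functional
## genes. Genes found in high-count windows are dropped if they also occur
## in null windows. The flank defaults to 1 kb on either side of the gene
## body, the convention of common region-based annotators.

#' Load gene models from BED or GFF3
#'
#' BED input (0-based half-open) and GFF3 input (1-based inclusive) are
#' normalized to 1-based inclusive intervals and sorted. From GFF3, rows of
#' type `gene` become `feature_kind = "gene"` and rows of type `mRNA` or
#' `transcript` become `"transcript"`; other feature types are ignored.
#' Gene identifiers come from the BED name column, or from the `Name`,
#' `ID` or `gene_id` GFF3 attribute (first available).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return data.table of class `aa_genes`: chrom, start, end, strand
#'   (`+`, `-` or `.`), gene_id, feature_kind. Malformed lines (missing
#'   fields, non-numeric or inverted coordinates) raise an error naming the
#'   line number.
#' @export
load_genes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines)) &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  idx <- which(keep)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)

  fail <- function(i, why) stop("malformed ", format, " line ", idx[i], ": ", why)
  if (format == "bed") {
    rows <- lapply(seq_along(parts), function(i) {
      p <- parts[[i]]
      if (length(p) < 3L) fail(i, "fewer than 3 fields")
      start0 <- suppressWarnings(as.numeric(p[2L]))
      end0 <- suppressWarnings(as.numeric(p[3L]))
      if (is.na(start0) || is.na(end0)) fail(i, "non-numeric coordinates")
      if (start0 >= end0) fail(i, "start >= end")
      data.table(chrom = p[1L], start = as.integer(start0) + 1L,
                 end = as.integer(end0),
                 strand = if (length(p) >= 6L && p[6L] %in% c("+", "-")) p[6L] else ".",
                 gene_id = if (length(p) >= 4L && nzchar(p[4L])) p[4L]
                           else sprintf("feature_%d", idx[i]),
                 feature_kind = "gene")
    })
  } else {
    rows <- lapply(seq_along(parts), function(i) {
      p <- parts[[i]]
      if (length(p) < 9L) fail(i, "fewer than 9 fields")
      type <- p[3L]
      kind <- if (type == "gene") "gene"
        else if (type %in% c("mRNA", "transcript")) "transcript"
        else return(NULL)
      start1 <- suppressWarnings(as.numeric(p[4L]))
      end1 <- suppressWarnings(as.numeric(p[5L]))
      if (is.na(start1) || is.na(end1)) fail(i, "non-numeric coordinates")
      if (start1 > end1) fail(i, "start > end")
      attrs <- strsplit(p[9L], ";", fixed = TRUE)[[1L]]
      kv <- strsplit(trimws(attrs), "=", fixed = TRUE)
      keys <- vapply(kv, `[`, character(1L), 1L)
      vals <- vapply(kv, function(x) if (length(x) >= 2L) x[2L] else "", character(1L))
      id <- c(vals[keys == "Name"], vals[keys == "ID"], vals[keys == "gene_id"],
              sprintf("feature_%d", idx[i]))[1L]
      data.table(chrom = p[1L], start = as.integer(start1), end = as.integer(end1),
                 strand = if (p[7L] %in% c("+", "-")) p[7L] else ".",
                 gene_id = id, feature_kind = kind)
    })
  }
  genes <- rbindlist(rows[!vapply(rows, is.null, logical(1L))])
  if (nrow(genes) == 0L) stop("no gene features found in ", path)
  setorder(genes, chrom, start, end)
  setattr(genes, "class", c("aa_genes", "data.table", "data.frame"))
  genes[]
}

.genes_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = ifelse(genes$strand %in% c("+", "-"), genes$strand, "*"),
    gene_id = genes$gene_id)
}

#' Classify windows against gene models
#'
#' A window is `genic` when it overlaps at least one gene body (any
#' overlap, >= 1 bp); otherwise `upstream` / `downstream` when it lies
#' within `flank_bp` of a gene on its 5' / 3' side (strand-aware; genes on
#' `.` strand make a nearby window eligible for both, resolved to
#' `upstream`); otherwise `intergenic`. Genic windows carry the identifiers
#' of all overlapping genes.
#'
#' @param windows a table with columns chrom, start, end (1-based
#'   inclusive), e.g. an `aa_windows` / `aa_classified` table.
#' @param genes an `aa_genes` table (rows with `feature_kind == "gene"` are
#'   used).
#' @param flank_bp flank width in bp (default 1000).
#' @return `windows` with columns `region_class` and `genes` (comma-joined
#'   gene ids, `""` when non-genic) added.
#' @export
classify_window_regions <- function(windows, genes, flank_bp = 1000L) {
  windows <- copy(as.data.table(windows))
  genes <- as.data.table(genes)
  gb <- genes[feature_kind == "gene"]
  wr <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(windows$start, windows$end))
  if (nrow(gb) == 0L) {
    windows[, `:=`(region_class = "intergenic", genes = "")]
    return(windows[])
  }
  gr <- .genes_granges(gb)
  ov <- GenomicRanges::findOverlaps(wr, gr, ignore.strand = TRUE)
  hits <- data.table(w = S4Vectors::queryHits(ov),
                     gene_id = gb$gene_id[S4Vectors::subjectHits(ov)])
  gene_lists <- hits[, .(genes = paste(unique(gene_id), collapse = ",")), by = w]
  windows[, genes := ""]
  windows[gene_lists$w, genes := gene_lists$genes]
  windows[, region_class := fifelse(nzchar(genes), "genic", "intergenic")]

  ## flanks, strand-aware: upstream = 5' side of the gene
  up <- gb[, .(chrom,
               start = fifelse(strand == "-", end + 1L, pmax(1L, start - flank_bp)),
               end = fifelse(strand == "-", end + flank_bp, start - 1L),
               side = "upstream")]
  dn <- gb[, .(chrom,
               start = fifelse(strand == "-", pmax(1L, start - flank_bp), end + 1L),
               end = fifelse(strand == "-", start - 1L, end + flank_bp),
               side = "downstream")]
  ## "." strand genes: both flanks count as upstream and as downstream
  dot <- gb[strand == ".", ]
  if (nrow(dot) > 0L) {
    up <- rbind(up, dot[, .(chrom, start = end + 1L, end = end + flank_bp,
                            side = "upstream")])
    dn <- rbind(dn, dot[, .(chrom, start = pmax(1L, start - flank_bp),
                            end = start - 1L, side = "downstream")])
  }
  flanks <- rbind(up, dn)[start <= end]
  if (nrow(flanks) > 0L) {
    fr <- GenomicRanges::GRanges(flanks$chrom,
                                 IRanges::IRanges(flanks$start, flanks$end))
    fov <- GenomicRanges::findOverlaps(wr, fr, ignore.strand = TRUE)
    fh <- data.table(w = S4Vectors::queryHits(fov),
                     side = flanks$side[S4Vectors::subjectHits(fov)])
    wu <- unique(fh[side == "upstream", w])
    wd <- unique(fh[side == "downstream", w])
    windows[wd, region_class := fifelse(region_class == "intergenic",
                                        "downstream", region_class)]
    windows[wu, region_class := fifelse(region_class %in%
                                          c("intergenic", "downstream"),
                                        "upstream", region_class)]
  }
  windows[]
}

#' Annotate classified windows and derive gene lists
#'
#' Runs [classify_window_regions()] on the high and null windows of a
#' classified window table, keeps genic windows only (excluding intergenic,
#' upstream and downstream regions), and applies the cross-filter: genes in
#' high-count windows that also occur in null windows are removed.
#'
#' @param classified an `aa_classified` table (one focal group or several).
#' @param genes an `aa_genes` table.
#' @param flank_bp flank width for region classification.
#' @return list with `annotated` (the high/null windows with region classes
#'   and gene ids), `genes_high` (per group: filtered ranked gene list),
#'   `genes_null` (per group: genes in null windows).
#' @export
annotate_windows <- function(classified, genes, flank_bp = 1000L) {
  cw <- as.data.table(classified)[label != "background"]
  ann <- classify_window_regions(cw, genes, flank_bp = flank_bp)
  split_genes <- function(x) unique(unlist(strsplit(x[nzchar(x)], ",", fixed = TRUE)))
  out_high <- list(); out_null <- list()
  for (g in unique(ann$group)) {
    hi <- split_genes(ann[group == g & label == "high" &
                            region_class == "genic", genes])
    nu <- split_genes(ann[group == g & label %in% c("null_no_aa", "null_derived") &
                            region_class == "genic", genes])
    out_high[[g]] <- filter_high_genes(hi, nu)
    out_null[[g]] <- nu
  }
  list(annotated = ann[], genes_high = out_high, genes_null = out_null)
}

#' Cross-filter high-window genes against null-window genes
#'
#' Pure set difference: genes implicated by high-count windows are dropped
#' when they also occur in windows without ancestral alleles.
#'
#' @param high_genes,null_genes character vectors of gene ids.
#' @return `high_genes` minus `null_genes` (order-independent, no
#'   duplicates).
#' @export
filter_high_genes <- function(high_genes, null_genes) {
  setdiff(unique(high_genes), unique(null_genes))
}

#' GC content of the ancestral alleles
#'
#' @param calls a non-empty `aa_calls` table.
#' @return fraction of calls whose ancestral base is G or C.
#' @export
aa_gc_content <- function(calls) {
  calls <- as.data.table(calls)
  if (nrow(calls) == 0L) stop("empty AA list: GC content undefined")
  mean(calls$aa %in% c("G", "C"))
}

#' Fraction of ancestral alleles inside transcript regions
#'
#' @param calls an `aa_calls` table.
#' @param transcripts an `aa_genes` table; rows with
#'   `feature_kind == "transcript"` are used when present, otherwise all
#'   intervals (a BED of transcript spans loads as `"gene"` rows).
#' @return fraction of AA positions overlapping any transcript interval
#'   (0 when there are no transcripts).
#' @export
transcript_overlap_fraction <- function(calls, transcripts) {
  calls <- as.data.table(calls)
  if (nrow(calls) == 0L) stop("empty AA list")
  tx <- as.data.table(transcripts)
  if (any(tx$feature_kind == "transcript"))
    tx <- tx[feature_kind == "transcript"]
  if (nrow(tx) == 0L) return(0)
  pr <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$pos, calls$pos))
  tr <- GenomicRanges::GRanges(tx$chrom, IRanges::IRanges(tx$start, tx$end))
  mean(IRanges::overlapsAny(pr, tr, ignore.strand = TRUE))
}
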