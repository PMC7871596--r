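## Per-group allele frequency spectra from a multi-sample VCF, after the
## hard site filters used upstream of ancestral-allele inference:
## SNP records are removed when MQ < 40, QUAL < 30 or QD < 30 (equality
## passes; the filters remove strictly smaller values). Non-SNP,
## multiallelic and unannotated records are removed and accounted for
## separately so that the filter report partitions the input.

#' Hard filter thresholds for SNP records
#'
#' @param min_mq minimum RMS mapping quality (INFO/MQ).
#' @param min_qual minimum site QUAL.
#' @param min_qd minimum quality by depth (INFO/QD). A QD floor of 30 is
#'   unusually stringent for this annotation; it is the default here because
#'   it is the operating point of the upstream variant-calling recipe this
#'   package mirrors, and it is fully configurable.
#' @return a list of class `aa_filter_thresholds`.
#' @export
filter_thresholds <- function(min_mq = 40, min_qual = 30, min_qd = 30) {
  structure(list(min_mq = min_mq, min_qual = min_qual, min_qd = min_qd),
            class = "aa_filter_thresholds")
}

#' Read a multi-sample VCF into a site table and genotype matrix
#'
#' Thin wrapper over [vcfR::read.vcfR()]. Genotypes are reduced to ALT
#' dosage (0, 1, 2 copies; `NA` for missing calls), which is sufficient for
#' biallelic SNP spectra; records that are not biallelic SNPs are retained
#' here and removed (and counted) by [filter_sites()].
#'
#' @param path VCF file (plain or bgzipped).
#' @return list of class `aa_vcf` with `sites` (data.table: chrom, pos, ref,
#'   alt, qual, mq, qd), `dosage` (integer matrix sites x samples) and
#'   `samples`.
#' @export
read_cohort_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))  # single-record VCFs drop to a named vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  sites <- data.table(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    mq = suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ"))),
    qd = suppressWarnings(as.numeric(vcfR::extract.info(v, "QD")))
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT genotypes: ", path)
  dosage <- .gt_to_dosage(gt)
  structure(list(sites = sites, dosage = dosage, samples = colnames(gt)),
            class = "aa_vcf")
}

## GT strings -> ALT dosage via a lookup over the (few) distinct GT codes.
## Any genotype containing a "." or an allele index > 1 becomes NA; the
## latter only occur on multiallelic records, which are filtered out.
.gt_to_dosage <- function(gt) {
  codes <- unique(as.vector(gt))
  lut <- vapply(codes, function(code) {
    if (is.na(code)) return(NA_integer_)
    al <- strsplit(code, "[/|]")[[1L]]
    if (length(al) != 2L || any(al == ".")) return(NA_integer_)
    al <- suppressWarnings(as.integer(al))
    if (any(is.na(al)) || any(al > 1L)) return(NA_integer_)
    sum(al)
  }, integer(1L))
  d <- lut[match(as.vector(gt), codes)]
  matrix(d, nrow(gt), ncol(gt), dimnames = dimnames(gt))
}

#' Apply hard site filters to VCF records
#'
#' A record is kept iff it is a biallelic SNP, carries QUAL, MQ and QD
#' annotations, and none falls below its threshold (equality passes, since
#' the filters remove strictly smaller values). Each input record is counted
#' exactly once in the report, in the order non-SNP, multiallelic,
#' unannotated, then the three threshold failures.
#'
#' @param vcf an `aa_vcf` from [read_cohort_vcf()].
#' @param thresholds a [filter_thresholds()] object.
#' @return list with `records` (the filtered `aa_vcf`) and `report`
#'   (data.table: filter_class, n; classes kept/non_snp/multiallelic/
#'   unannotated/fail_mq/fail_qual/fail_qd).
#' @export
filter_sites <- function(vcf, thresholds = filter_thresholds()) {
  stopifnot(inherits(vcf, "aa_vcf"))
  s <- vcf$sites
  base <- c("A", "C", "G", "T")
  multi <- grepl(",", s$alt, fixed = TRUE)
  snp <- !multi & s$ref %in% base & s$alt %in% base
  unann <- is.na(s$qual) | is.na(s$mq) | is.na(s$qd)
  cls <- rep("kept", nrow(s))
  cls[!is.na(s$qd) & s$qd < thresholds$min_qd] <- "fail_qd"
  cls[!is.na(s$qual) & s$qual < thresholds$min_qual] <- "fail_qual"
  cls[!is.na(s$mq) & s$mq < thresholds$min_mq] <- "fail_mq"
  cls[unann] <- "unannotated"
  cls[multi] <- "multiallelic"
  cls[!snp & !multi] <- "non_snp"
  keep <- cls == "kept"
  levels <- c("kept", "non_snp", "multiallelic", "unannotated",
              "fail_mq", "fail_qual", "fail_qd")
  report <- data.table(filter_class = levels,
                       n = as.integer(table(factor(cls, levels = levels))))
  out <- structure(list(sites = s[keep],
                        dosage = vcf$dosage[keep, , drop = FALSE],
                        samples = vcf$samples),
                   class = "aa_vcf")
  list(records = out, report = report)
}

#' Per-group allele frequency spectra
#'
#' For each filtered site and each sample group, tallies REF/ALT alleles
#' over non-missing genotype calls only (denominator = 2 x called
#' genotypes). Groups with no called genotype at a site contribute no rows
#' there.
#'
#' @param vcf a filtered `aa_vcf` (biallelic SNPs).
#' @param group_map an `aa_group_map` from [parse_group_map()].
#' @return data.table of class `aa_freqs`: chrom, pos, group, allele, count
#'   (allele copies), n_called (non-missing chromosomes in the group),
#'   freq = count / n_called. Only observed alleles (count > 0) are listed;
#'   per (site, group), freqs sum to 1.
#' @export
site_frequencies <- function(vcf, group_map) {
  stopifnot(inherits(vcf, "aa_vcf"))
  missing_samples <- setdiff(vcf$samples, group_map$sample_id)
  if (length(missing_samples) > 0L)
    stop("VCF sample(s) absent from group map: ",
         paste(missing_samples, collapse = ", "))
  s <- vcf$sites
  groups <- intersect(aa_groups(), unique(group_map$group))
  pieces <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    g <- groups[k]
    cols <- which(vcf$samples %in% group_map[group == g, sample_id])
    d <- vcf$dosage[, cols, drop = FALSE]
    alt_n <- as.numeric(rowSums(d, na.rm = TRUE))
    called <- as.integer(2L * rowSums(!is.na(d)))
    ref_n <- called - alt_n
    pieces[[k]] <- rbindlist(list(
      data.table(chrom = s$chrom, pos = s$pos, group = g,
                 allele = s$ref, count = ref_n, n_called = called),
      data.table(chrom = s$chrom, pos = s$pos, group = g,
                 allele = s$alt, count = alt_n, n_called = called)
    ))
  }
  freqs <- rbindlist(pieces)[n_called > 0L & count > 0L]
  freqs[, freq := count / n_called]
  setorder(freqs, chrom, pos, group, allele)
  setattr(freqs, "class", c("aa_freqs", class(freqs)))
  freqs[]
}

#' Write / read a frequency table as TSV
#'
#' @param freqs an `aa_freqs` table.
#' @param path output/input path.
#' @return `write_freqs` returns `path`; `read_freqs` the table.
#' @export
write_freqs <- function(freqs, path) {
  fwrite(freqs, path, sep = "\t")
  path
}

#' @rdname write_freqs
#' @export
read_freqs <- function(path) {
  freqs <- fread(path, sep = "\t", colClasses = list(character = "chrom"))
  setattr(freqs, "class", c("aa_freqs", class(freqs)))
  freqs[]
}
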