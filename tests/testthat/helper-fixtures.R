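library(data.table)

## Hand-rolled VCF writer for fixtures: `sites` is a data.frame with columns
## chrom, pos, ref, alt, qual, mq, qd (NA mq/qd omits the INFO key);
## `gt` a character matrix (sites x samples) of GT strings.
write_test_vcf <- function(path, sites, gt, samples) {
  info <- mapply(function(mq, qd) {
    keys <- c(if (!is.na(mq)) sprintf("MQ=%s", mq),
              if (!is.na(qd)) sprintf("QD=%s", qd))
    if (length(keys) == 0L) "." else paste(keys, collapse = ";")
  }, sites$mq, sites$qd)
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(sites$chrom)),
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"mq\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
          ifelse(is.na(sites$qual), ".", as.character(sites$qual)), ".",
          info, "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  path
}

write_test_group_map <- function(path, samples, groups) {
  writeLines(paste(samples, groups, sep = "\t"), path)
  path
}

## Zero-row frequency table with the standard columns.
empty_freqs <- function() {
  data.table(chrom = character(), pos = integer(), group = character(),
             allele = character(), count = numeric(), n_called = integer(),
             freq = numeric())
}

## Frequency-table builder from explicit allele counts.
make_freqs <- function(chrom, pos, group, allele, count, n_called) {
  dt <- data.table(chrom = as.character(chrom), pos = as.integer(pos),
                   group = group, allele = allele,
                   count = as.numeric(count), n_called = as.integer(n_called))
  dt[, freq := count / n_called]
  dt
}

## Independent brute-force oracle: parse a VCF text file naively and tally
## per-group allele counts over non-missing calls. Used to cross-check
## site_frequencies; deliberately avoids the package's parsing path.
brute_group_spectra <- function(vcf_path, group_map) {
  lines <- readLines(vcf_path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  samples <- strsplit(hdr, "\t")[[1]][-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  out <- list()
  for (ln in body) {
    p <- strsplit(ln, "\t")[[1]]
    alleles <- c(p[4], p[5])
    for (g in unique(group_map$group)) {
      idx <- which(samples %in% group_map$sample_id[group_map$group == g])
      tally <- c(0, 0)
      for (i in idx) {
        gtal <- strsplit(strsplit(p[9 + i], ":")[[1]][1], "[/|]")[[1]]
        for (a in gtal) if (a %in% c("0", "1")) {
          k <- as.integer(a) + 1L
          tally[k] <- tally[k] + 1
        }
      }
      n <- sum(tally)
      if (n == 0) next
      for (k in 1:2) if (tally[k] > 0)
        out[[length(out) + 1L]] <- data.table(
          chrom = p[1], pos = as.integer(p[2]), group = g,
          allele = alleles[k], count = tally[k], n_called = n,
          freq = tally[k] / n)
    }
  }
  res <- rbindlist(out)
  setorder(res, chrom, pos, group, allele)
  res
}

## A small standard cohort shared by several tests (generated once per run).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(
        n_chromosomes = 2L, chrom_length_bp = 1e5,
        planted_windows = data.frame(
          chrom = c("1", "1", "2", "2"),
          window_index = c(2L, 5L, 3L, 7L),
          class = c("conserved", "mutated_derived", "mutated_no_aa",
                    "conserved")),
        seed = 42L)
      sim <- simulate_cohort(cfg)
      vcf <- read_cohort_vcf(sim$vcf)
      gm <- parse_group_map(sim$group_map)
      flt <- filter_sites(vcf)
      freqs <- site_frequencies(flt$records, gm)
      cache <<- list(cfg = cfg, sim = sim, vcf = vcf, gm = gm,
                     flt = flt, freqs = freqs)
    }
    cache
  }
})

## Expected window labels derived from the truth table alone (independent of
## the VCF -> frequency -> call path): retained-site counts per window and
## the same nearest-rank selection rule applied to them.
truth_window_labels <- function(truth, cfg, group) {
  ret_col <- paste0(group, "_retained")
  kept <- truth[low_quality == FALSE]
  n_win <- as.integer(ceiling(cfg$chrom_length_bp / cfg$window_bp))
  grid <- CJ(chrom = as.character(seq_len(cfg$n_chromosomes)),
             t_idx = seq_len(n_win))
  agg <- kept[, .(
    count = sum(!is.na(true_aa) & get(ret_col) %in% TRUE),
    n_aa = sum(!is.na(true_aa))
  ), by = .(chrom, t_idx = window_index)]
  w <- agg[grid, on = c("chrom", "t_idx")]
  w[is.na(count), count := 0L][is.na(n_aa), n_aa := 0L]
  w[, threshold := {
    s <- sort(count)
    s[max(1L, ceiling(0.999 * length(s)))]
  }, by = chrom]
  w[, label := "background"]
  w[count >= threshold & count > 0L, label := "high"]
  w[count == 0L, label := ifelse(n_aa == 0L, "null_no_aa", "null_derived")]
  w[]
}
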