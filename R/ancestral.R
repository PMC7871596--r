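## Outgroup consensus rule for ancestral alleles.
##
## An allele is called ancestral (AA) at a site when it is fixed -- frequency
## 1 over the pooled non-missing alleles -- in at least two of the three
## outgroup lineages (yak; bison = American + European bison; gagaba =
## gayal + gaur + banteng). Fixation is pooled across a lineage's
## constituent groups, because the lineages, not the individual species
## groups, are the consensus units. With three lineages at most one allele
## can be fixed in two of them, so the call is unique when it exists.

#' Fixed allele of one outgroup lineage at one site
#'
#' Pools the lineage's allele counts over its constituent groups and returns
#' the allele whose pooled frequency is 1 (within `tol`), provided at least
#' `min_called` chromosomes were called; otherwise `NA`.
#'
#' @param freqs rows of an `aa_freqs` table for one site, restricted to the
#'   groups of one lineage (columns `allele`, `count`, `n_called`, `group`).
#' @param min_called minimum pooled called chromosomes for the lineage to
#'   count as observed (default 2).
#' @param tol fixation tolerance on the pooled frequency.
#' @return the fixed allele as a single base, or `NA_character_`.
#' @export
lineage_fixed_allele <- function(freqs, min_called = 2L, tol = 1e-9) {
  if (nrow(freqs) == 0L) return(NA_character_)
  total <- sum(unique(as.data.table(freqs)[, .(group, n_called)])$n_called)
  if (total < min_called) return(NA_character_)
  pooled <- as.data.table(freqs)[, .(count = sum(count)), by = allele]
  hit <- pooled[abs(count / total - 1) <= tol, allele]
  if (length(hit) == 1L) hit else NA_character_
}

#' Consensus call at one site from per-lineage fixed alleles
#'
#' Applies the >= 2-lineage agreement rule: if two or three lineages are
#' fixed for the same base, that base is the ancestral allele and the
#' agreeing lineages are reported; a 2-vs-1 conflict resolves to the
#' majority pair; otherwise (including a 1-vs-1 conflict with the third
#' lineage unfixed) no call is made.
#'
#' @param fixed named character vector or list over
#'   `c("yak","bison","gagaba")`; each entry a base or `NA`.
#' @return `NULL`, or a list with `aa` (base) and `agreeing_lineages`.
#' @export
call_site <- function(fixed) {
  fixed <- unlist(fixed)[aa_outgroup_lineages()]
  obs <- fixed[!is.na(fixed)]
  if (length(obs) < 2L) return(NULL)
  tab <- table(obs)
  if (max(tab) < 2L) return(NULL)
  aa <- names(tab)[which.max(tab)]
  list(aa = aa, agreeing_lineages = names(obs)[obs == aa])
}

#' Genome-wide ancestral allele calls
#'
#' Applies the lineage-fixation consensus to every site of a frequency
#' table and returns one call per qualifying site, sorted by chromosome and
#' position. The computation is a deterministic function of the spectra:
#' rerunning, or permuting the input rows, yields the identical list.
#'
#' @param freqs an `aa_freqs` table (from [site_frequencies()]).
#' @param min_called minimum called chromosomes per lineage (pooled) for
#'   that lineage to participate, passed to the fixation rule.
#' @param tol fixation tolerance.
#' @return data.table of class `aa_calls` with the six reported columns:
#'   `chrom`, `pos`, `n_alleles` (distinct alleles observed across outgroup
#'   groups at the site), `aa` (the ancestral base), `aa_freq_pooled`
#'   (frequency of `aa` over all outgroup individuals; < 1 when a
#'   non-agreeing lineage segregates) and `agreeing_lineages`
#'   (comma-joined).
#' @export
call_genome <- function(freqs, min_called = 2L, tol = 1e-9) {
  og <- as.data.table(freqs)[, lineage := group_lineage(group)][
    lineage %in% aa_outgroup_lineages()]
  if (nrow(og) == 0L) {
    return(structure(
      data.table(chrom = character(), pos = integer(), n_alleles = integer(),
                 aa = character(), aa_freq_pooled = numeric(),
                 agreeing_lineages = character()),
      class = c("aa_calls", "data.table", "data.frame")))
  }
  ## pooled fixation per (site, lineage): an allele is fixed iff its copy
  ## count equals the lineage's pooled called chromosomes (integer counts,
  ## so the tolerance only matters for non-integer inputs)
  ncal <- unique(og[, .(chrom, pos, group, lineage, n_called)])[
    , .(total = sum(n_called)), by = .(chrom, pos, lineage)]
  pooled <- og[, .(count = sum(count)), by = .(chrom, pos, lineage, allele)]
  pooled <- ncal[pooled, on = .(chrom, pos, lineage)]
  fixed <- pooled[total >= min_called & abs(count / total - 1) <= tol]
  if (nrow(fixed) == 0L) {
    return(structure(
      data.table(chrom = character(), pos = integer(), n_alleles = integer(),
                 aa = character(), aa_freq_pooled = numeric(),
                 agreeing_lineages = character()),
      class = c("aa_calls", "data.table", "data.frame")))
  }
  agree <- fixed[, .(n_fixed = .N,
                     agreeing_lineages = paste(sort(lineage), collapse = ",")),
                 by = .(chrom, pos, allele)][n_fixed >= 2L]
  ## order the lineage list canonically (yak, bison, gagaba)
  agree[, agreeing_lineages := vapply(strsplit(agreeing_lineages, ","),
    function(x) paste(intersect(aa_outgroup_lineages(), x), collapse = ","),
    character(1L))]

  per_site <- og[, .(n_alleles = uniqueN(allele)), by = .(chrom, pos)]
  pool_tot <- unique(og[, .(chrom, pos, group, n_called)])[
    , .(total = sum(n_called)), by = .(chrom, pos)]
  pool_cnt <- og[, .(count = sum(count)), by = .(chrom, pos, allele)]

  calls <- agree[, .(chrom, pos, aa = allele, agreeing_lineages)]
  calls <- per_site[calls, on = .(chrom, pos)]
  calls <- pool_cnt[calls, on = c("chrom", "pos", allele = "aa")]
  setnames(calls, "allele", "aa")
  calls <- pool_tot[calls, on = .(chrom, pos)]
  calls[, aa_freq_pooled := count / total]
  calls <- calls[, .(chrom, pos, n_alleles, aa, aa_freq_pooled,
                     agreeing_lineages)]
  setorder(calls, chrom, pos)
  setattr(calls, "class", c("aa_calls", "data.table", "data.frame"))
  calls[]
}

#' Write / read the six-column ancestral allele list
#'
#' Plain text, tab separated, one header line starting with `#`; columns:
#' chromosome, position, number of alleles, defined ancestral allele,
#' frequency, agreeing lineages (comma-joined). `read_aa_list` is the exact
#' inverse of `write_aa_list`.
#'
#' @param calls an `aa_calls` table, sorted by (chrom, pos).
#' @param path file path.
#' @return `write_aa_list` returns `path` invisibly; `read_aa_list` returns
#'   the `aa_calls` table. Malformed lines on read raise an error naming
#'   the line number.
#' @export
write_aa_list <- function(calls, path) {
  header <- "#chrom\tpos\tn_alleles\taa\tfreq\tagreeing_lineages"
  lines <- paste(calls$chrom, calls$pos, calls$n_alleles, calls$aa,
                 format(calls$aa_freq_pooled, digits = 15, trim = TRUE,
                        scientific = FALSE),
                 calls$agreeing_lineages, sep = "\t")
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_aa_list
#' @export
read_aa_list <- function(path) {
  if (!file.exists(path)) stop("AA list not found: ", path)
  lines <- readLines(path)
  data_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  parts <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 6L)
  if (length(bad) > 0L)
    stop("malformed AA list line ", data_idx[bad[1L]], ": expected 6 columns, got ",
         lengths(parts)[bad[1L]])
  calls <- data.table(
    chrom = vapply(parts, `[`, character(1L), 1L),
    pos = as.integer(vapply(parts, `[`, character(1L), 2L)),
    n_alleles = as.integer(vapply(parts, `[`, character(1L), 3L)),
    aa = vapply(parts, `[`, character(1L), 4L),
    aa_freq_pooled = as.numeric(vapply(parts, `[`, character(1L), 5L)),
    agreeing_lineages = vapply(parts, `[`, character(1L), 6L)
  )
  if (any(is.na(calls$pos)))
    stop("malformed AA list line ", data_idx[which(is.na(calls$pos))[1L]],
         ": position is not an integer")
  setattr(calls, "class", c("aa_calls", "data.table", "data.frame"))
  calls[]
}
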