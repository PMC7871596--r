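## Retention scoring of ancestral alleles in focal cattle groups.
##
## Per AA-defined site and focal group, x is the focal-group frequency of
## the ancestral base and theta = x - 1 (the AA is defined at frequency 1
## in the outgroup consensus, so theta ranges over [-1, 0]). The retention
## indicator f is 1 exactly when theta = 0, i.e. the AA is FIXED in the
## focal group -- not merely the major allele; this follows literally from
## the indicator's definition. f is summed over non-overlapping windows
## (default 10 kb) tiling each chromosome; windows with no sites are kept,
## because zero-count windows are themselves an analysis endpoint.

#' Focal-group frequency of the ancestral allele at one site
#'
#' @param spectrum the focal group's rows of an `aa_freqs` table at one
#'   site (columns `allele`, `freq`, `n_called`).
#' @param aa the ancestral base.
#' @return the matched frequency x in `[0, 1]`: the group's frequency of
#'   `aa` (which may be its major or its minor allele), 0 if `aa` is absent
#'   from the spectrum, `NA` if the group has no called genotype at the
#'   site (empty spectrum).
#' @export
match_frequency <- function(spectrum, aa) {
  spectrum <- as.data.table(spectrum)
  if (nrow(spectrum) == 0L || all(spectrum$n_called == 0L)) return(NA_real_)
  hit <- spectrum[allele == aa, freq]
  if (length(hit) == 0L) 0 else hit[1L]
}

#' The per-site retention statistic theta
#'
#' `theta_score(x)` = x - 1, the difference between the matched focal-group
#' frequency of the ancestral allele and its defining outgroup frequency
#' of 1.
#'
#' @param x matched frequency in `[0, 1]` (NA allowed, propagated).
#' @return theta in `[-1, 0]`.
#' @export
theta_score <- function(x) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) stop("matched frequency outside [0,1]: ", x[which(bad)[1L]])
  x - 1
}

#' Retention indicator f
#'
#' 1 when theta equals 0 within tolerance (the ancestral allele is fixed in
#' the focal group), else 0. `NA` theta (group uncalled at the site) scores
#' 0: absence of evidence is not retention.
#'
#' @param theta theta values in `[-1, 0]` (NA allowed).
#' @param tol numeric tolerance on theta = 0.
#' @return integer vector of 0/1.
#' @export
retention_indicator <- function(theta, tol = 1e-9) {
  as.integer(!is.na(theta) & abs(theta) <= tol)
}

#' Window index of a genomic position
#'
#' Non-overlapping tiling: 1-based position p maps to window
#' `ceil(p / window_bp)`, so window t spans
#' `[window_bp (t - 1) + 1, window_bp t]` and every position belongs to
#' exactly one window.
#'
#' @param pos 1-based positions.
#' @param window_bp window size in bp (default 10 kb).
#' @return integer window indices (t >= 1).
#' @export
window_index <- function(pos, window_bp = 10000L) {
  if (any(pos < 1)) stop("position must be >= 1")
  as.integer(ceiling(pos / window_bp))
}

#' Per-site theta records for the focal groups
#'
#' Joins the ancestral allele calls with the focal-group spectra and scores
#' every (AA site, focal group) pair.
#'
#' @param calls an `aa_calls` table.
#' @param freqs an `aa_freqs` table (must include the focal groups).
#' @param focal_groups groups to score (default taurine and zebu).
#' @param tol tolerance on theta = 0.
#' @return data.table of class `aa_theta`: chrom, pos, group, x, theta, f.
#'   `x` is `NA` (and f = 0) where the group has no called genotype.
#' @export
compute_theta <- function(calls, freqs, focal_groups = aa_focal_groups(),
                          tol = 1e-9) {
  freqs <- as.data.table(freqs)
  unknown <- setdiff(focal_groups, aa_focal_groups())
  if (length(unknown) > 0L)
    stop("not a focal group: ", paste(unknown, collapse = ", "))
  base <- CJ(group = focal_groups, chrom = unique(calls$chrom), sorted = FALSE)
  base <- merge(base, as.data.table(calls)[, .(chrom, pos, aa)],
                by = "chrom", allow.cartesian = TRUE)
  ncal <- unique(freqs[group %in% focal_groups,
                       .(chrom, pos, group, n_called)])
  rec <- ncal[base, on = .(chrom, pos, group)]
  rec <- freqs[group %in% focal_groups, .(chrom, pos, group, allele, freq)][
    rec, on = c("chrom", "pos", "group", allele = "aa")]
  setnames(rec, "allele", "aa")
  rec[, x := fifelse(is.na(n_called), NA_real_, fifelse(is.na(freq), 0, freq))]
  rec[, theta := theta_score(x)]
  rec[, f := retention_indicator(theta, tol)]
  out <- rec[, .(chrom, pos, group, x, theta, f)]
  setorder(out, chrom, pos, group)
  setattr(out, "class", c("aa_theta", "data.table", "data.frame"))
  out[]
}

#' Window retention counts over a chromosome tiling
#'
#' Sums the retention indicator over non-overlapping windows. Every window
#' from t = 1 to `ceil(L / window_bp)` is emitted for every chromosome and
#' scored group, including windows containing no sites -- required so that
#' zero-count (null) windows can be detected downstream.
#'
#' @param theta an `aa_theta` table.
#' @param chrom_lengths data.table with columns `chrom`, `length_bp` (e.g.
#'   from [read_fai()]); every chromosome in `theta` must be present and no
#'   site may lie beyond its chromosome length.
#' @param window_bp window size in bp.
#' @param freqs optional `aa_freqs` table; when given, `n_poly_sites` (sites
#'   at which the focal group is polymorphic) is filled in per window.
#' @return data.table of class `aa_windows`: chrom, group, t_idx, start,
#'   end, count (= sum of f, the window's T statistic), n_aa_sites,
#'   n_uncalled_sites, n_poly_sites.
#' @export
count_windows <- function(theta, chrom_lengths, window_bp = 10000L,
                          freqs = NULL) {
  theta <- as.data.table(theta)
  cl <- as.data.table(chrom_lengths)
  missing_chr <- setdiff(unique(theta$chrom), cl$chrom)
  if (length(missing_chr) > 0L)
    stop("chromosome length unavailable for: ",
         paste(missing_chr, collapse = ", "))
  chk <- cl[theta, on = "chrom"]
  if (any(chk$pos > chk$length_bp))
    stop("site position exceeds chromosome length on chrom ",
         chk[pos > length_bp, chrom][1L])

  groups <- if (nrow(theta) > 0L) unique(theta$group) else aa_focal_groups()
  base_grid <- cl[, .(t_idx = seq_len(ceiling(length_bp / window_bp))), by = chrom]
  grid <- rbindlist(lapply(groups, function(g) copy(base_grid)[, group := g]))

  per <- theta[, .(count = sum(f),
                   n_aa_sites = .N,
                   n_uncalled_sites = sum(is.na(x))),
               by = .(chrom, group, t_idx = window_index(pos, window_bp))]
  win <- per[grid, on = .(chrom, group, t_idx)]
  for (col in c("count", "n_aa_sites", "n_uncalled_sites"))
    win[is.na(get(col)), (col) := 0L]
  win[, `:=`(start = window_bp * (t_idx - 1L) + 1L, end = window_bp * t_idx)]

  if (!is.null(freqs)) {
    freqs <- as.data.table(freqs)
    poly <- freqs[group %in% groups & freq < 1,
                  .(n_poly_sites = uniqueN(pos)),
                  by = .(chrom, group, t_idx = window_index(pos, window_bp))]
    win <- poly[win, on = .(chrom, group, t_idx)]
    win[is.na(n_poly_sites), n_poly_sites := 0L]
  } else {
    win[, n_poly_sites := NA_integer_]
  }
  out <- win[, .(chrom, group, t_idx, start, end, count, n_aa_sites,
                 n_uncalled_sites, n_poly_sites)]
  setorder(out, group, chrom, t_idx)
  setattr(out, "class", c("aa_windows", "data.table", "data.frame"))
  out[]
}
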