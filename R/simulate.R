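## Synthetic Bovinae cohort generator.
##
## Emulates, at desk scale, a genotyped cohort of three outgroup lineages
## (yak; American + European bison; gayal + gaur + banteng) plus taurine and
## zebu cattle, with known ancestral states and planted windows:
##   conserved       - every AA site retained (fixed) in both focal groups
##   mutated_derived - AA defined at sites, but never fixed in the focal group
##   mutated_no_aa   - polymorphic sites at which no allele is fixed in >= 2
##                     outgroup lineages, so no AA can be defined
##
## The generator protects the genotype calls that define each planted pattern
## from the missingness mask (one call per fixed group, one homozygote per
## allele in polymorphic groups), so the truth table is exact by construction
## rather than holding only in expectation.

.PLANTED_CLASSES <- c("conserved", "mutated_derived", "mutated_no_aa")

#' Configuration for the synthetic cohort generator
#'
#' Default sample sizes mirror a published Bovinae whole-genome cohort
#' (13 yak, 4 American bison, 5 European bison, 4 gayal, 4 gaur, 5 banteng,
#' 23 taurine, 8 zebu) on a scaled-down genome.
#'
#' @param n_chromosomes number of autosomes to simulate.
#' @param chrom_length_bp length of each chromosome in bp (>= `window_bp`).
#' @param window_bp retention-scan window size in bp.
#' @param samples_per_group named integer vector of diploid sample counts;
#'   must cover all eight cohort groups (aurochs optional) with >= 2 samples
#'   each.
#' @param snp_density SNP sites per kb (sites are placed uniformly within
#'   each window).
#' @param planted_windows `NULL` or a data.frame with columns `chrom`
#'   (character), `window_index` (1-based), `class` (one of `"conserved"`,
#'   `"mutated_derived"`, `"mutated_no_aa"`).
#' @param p_aa_background probability that a background site carries a
#'   definable ancestral allele.
#' @param retention_background probability that a background AA site is
#'   retained (AA fixed) in a focal group, independently per group.
#' @param aa_gc_fraction probability that a planted ancestral allele is G or
#'   C; the default reflects the elevated GC content observed among inferred
#'   ancestral alleles relative to the genome background.
#' @param missing_rate per-genotype-call missingness probability.
#' @param prop_low_quality fraction of background sites emitted with
#'   below-threshold QUAL/MQ/QD to exercise the hard filters.
#' @param seed integer seed; identical configs and seeds give byte-identical
#'   output files.
#' @return a validated list of class `aa_sim_config`.
#' @export
simulation_config <- function(n_chromosomes = 5L,
                              chrom_length_bp = 1e6,
                              window_bp = 10000L,
                              samples_per_group = c(
                                yak = 13L, american_bison = 4L,
                                european_bison = 5L, gayal = 4L, gaur = 4L,
                                banteng = 5L, taurine = 23L, zebu = 8L),
                              snp_density = 2,
                              planted_windows = NULL,
                              p_aa_background = 0.6,
                              retention_background = 0.35,
                              aa_gc_fraction = 0.58,
                              missing_rate = 0.05,
                              prop_low_quality = 0,
                              seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    window_bp = as.integer(window_bp),
    samples_per_group = samples_per_group,
    snp_density = as.numeric(snp_density),
    planted_windows = planted_windows,
    p_aa_background = as.numeric(p_aa_background),
    retention_background = as.numeric(retention_background),
    aa_gc_fraction = as.numeric(aa_gc_fraction),
    missing_rate = as.numeric(missing_rate),
    prop_low_quality = as.numeric(prop_low_quality),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "aa_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(...) stop("invalid simulation config: ", ..., call. = FALSE)
  if (is.na(cfg$n_chromosomes) || cfg$n_chromosomes < 1L)
    stop_cfg("n_chromosomes must be >= 1")
  if (is.na(cfg$chrom_length_bp) || cfg$chrom_length_bp < cfg$window_bp)
    stop_cfg("chrom_length_bp must be >= window_bp")
  if (cfg$window_bp < 1L) stop_cfg("window_bp must be positive")
  if (cfg$snp_density <= 0) stop_cfg("snp_density must be positive")
  for (p in c("p_aa_background", "retention_background", "aa_gc_fraction",
              "missing_rate", "prop_low_quality")) {
    v <- cfg[[p]]
    if (is.na(v) || v < 0 || v > 1) stop_cfg(p, " must be a probability in [0,1]")
  }
  spg <- cfg$samples_per_group
  required <- setdiff(aa_groups(), "aurochs")
  if (is.null(names(spg)) || !all(required %in% names(spg)))
    stop_cfg("samples_per_group must name all of: ", paste(required, collapse = ", "))
  if (!all(names(spg) %in% aa_groups()))
    stop_cfg("unknown group in samples_per_group: ",
             paste(setdiff(names(spg), aa_groups()), collapse = ", "))
  if (any(is.na(spg)) || any(spg < 2))
    stop_cfg("samples_per_group entries must be >= 2")
  pw <- cfg$planted_windows
  if (!is.null(pw)) {
    pw <- as.data.frame(pw)
    if (!all(c("chrom", "window_index", "class") %in% names(pw)))
      stop_cfg("planted_windows needs columns chrom, window_index, class")
    if (!all(pw$class %in% .PLANTED_CLASSES))
      stop_cfg("planted window class must be one of: ",
               paste(.PLANTED_CLASSES, collapse = ", "))
    n_win <- ceiling(cfg$chrom_length_bp / cfg$window_bp)
    if (any(pw$window_index < 1L | pw$window_index > n_win))
      stop_cfg("planted window_index out of range 1..", n_win)
    if (!all(pw$chrom %in% as.character(seq_len(cfg$n_chromosomes))))
      stop_cfg("planted window chrom outside simulated chromosomes")
    if (anyDuplicated(pw[, c("chrom", "window_index")]))
      stop_cfg("duplicated planted window")
  }
  invisible(cfg)
}

## Draw the per-site plan: alleles, true AA, per-lineage state and
## per-focal-group state. States: "fixed_ref", "fixed_alt", "poly",
## "all_missing". Everything downstream (genotypes, truth) derives from it.
.plan_sites <- function(cfg, sites) {
  n <- nrow(sites)
  bases <- c("A", "C", "G", "T")
  has_aa <- rep(NA, n)
  cls <- sites$window_class
  has_aa[cls == "conserved" | cls == "mutated_derived"] <- TRUE
  has_aa[cls == "mutated_no_aa"] <- FALSE
  bg <- cls == "background"
  has_aa[bg] <- runif(sum(bg)) < cfg$p_aa_background

  ## allele bases: the AA base is G/C with probability aa_gc_fraction
  gc <- runif(n) < cfg$aa_gc_fraction
  aa_base <- ifelse(gc, sample(c("G", "C"), n, replace = TRUE),
                        sample(c("A", "T"), n, replace = TRUE))
  other <- vapply(aa_base, function(b) sample(setdiff(bases, b), 1L), character(1L))
  aa_is_ref <- runif(n) < 0.5
  ref <- ifelse(aa_is_ref, aa_base, other)
  alt <- ifelse(aa_is_ref, other, aa_base)
  aa_state <- ifelse(aa_is_ref, "fixed_ref", "fixed_alt")
  derived_state <- ifelse(aa_is_ref, "fixed_alt", "fixed_ref")

  lin <- matrix(NA_character_, n, 3L,
                dimnames = list(NULL, aa_outgroup_lineages()))
  ## AA sites: >= 2 lineages fixed for the AA base; the odd lineage out is
  ## fixed for the other allele, polymorphic, or entirely uncalled.
  idx_aa <- which(has_aa)
  if (length(idx_aa) > 0L) {
    all3 <- runif(length(idx_aa)) < 0.12
    lin[idx_aa, ] <- aa_state[idx_aa]
    pair <- idx_aa[!all3]
    if (length(pair) > 0L) {
      odd <- sample.int(3L, length(pair), replace = TRUE)
      odd_state <- sample(c("fixed_other", "poly", "all_missing"), length(pair),
                          replace = TRUE, prob = c(0.4, 0.4, 0.2))
      odd_state[odd_state == "fixed_other"] <- derived_state[pair][odd_state == "fixed_other"]
      lin[cbind(pair, odd)] <- odd_state
    }
  }
  ## no-AA sites: patterns in which no allele is fixed in >= 2 lineages
  idx_no <- which(!has_aa)
  if (length(idx_no) > 0L) {
    patt <- sample.int(4L, length(idx_no), replace = TRUE)
    perm <- sample.int(3L, length(idx_no), replace = TRUE)
    for (k in seq_along(idx_no)) {
      p <- switch(patt[k],
        c("poly", "poly", "poly"),
        c("fixed_ref", "fixed_alt", "poly"),
        c("fixed_ref", "poly", "poly"),
        c("fixed_alt", "poly", "poly"))
      ## rotate so the distinguished slot varies across lineages
      lin[idx_no[k], ] <- p[((seq_len(3L) + perm[k]) %% 3L) + 1L]
    }
  }

  foc <- matrix(NA_character_, n, 2L, dimnames = list(NULL, aa_focal_groups()))
  retained <- matrix(NA, n, 2L, dimnames = list(NULL, aa_focal_groups()))
  for (j in seq_len(2L)) {
    ret <- rep(NA, n)
    ret[cls == "conserved"] <- TRUE
    ret[cls == "mutated_derived"] <- FALSE
    ret[bg & has_aa] <- runif(sum(bg & has_aa)) < cfg$retention_background
    st <- rep("poly", n)
    st[which(ret)] <- aa_state[which(ret)]
    lost <- which(!ret)
    lost_fixed <- lost[runif(length(lost)) < 0.5]
    st[lost_fixed] <- derived_state[lost_fixed]
    ## sites without a definable AA: focal state is unconstrained
    free <- which(!has_aa)
    st[free] <- ifelse(runif(length(free)) < 0.7, "poly",
                       ifelse(runif(length(free)) < 0.5, "fixed_ref", "fixed_alt"))
    retained[, j] <- ifelse(has_aa, ret, NA)
    foc[, j] <- st
  }

  list(has_aa = has_aa, ref = ref, alt = alt,
       true_aa = ifelse(has_aa, aa_base, NA_character_),
       lineage_state = lin, focal_state = foc, retained = retained)
}

## Realize genotype dosages (0/1/2 copies of ALT, NA = missing) for one group
## from its per-site state, marking pattern-defining calls as protected.
.realize_group <- function(state, n_samples) {
  n <- length(state)
  d <- matrix(NA_integer_, n, n_samples)
  prot <- matrix(FALSE, n, n_samples)
  i <- which(state == "fixed_ref")
  if (length(i)) { d[i, ] <- 0L; prot[i, 1L] <- TRUE }
  i <- which(state == "fixed_alt")
  if (length(i)) { d[i, ] <- 2L; prot[i, 1L] <- TRUE }
  i <- which(state == "poly")
  if (length(i)) {
    pf <- runif(length(i), 0.2, 0.8)
    d[i, ] <- matrix(rbinom(length(i) * n_samples, 2L, rep(pf, n_samples)),
                     length(i), n_samples)
    d[i, 1L] <- 0L
    d[i, 2L] <- 2L
    prot[i, 1:2] <- TRUE
  }
  list(dosage = d, protected = prot)
}

## Map a lineage-level state onto its constituent groups. A polymorphic
## multi-group lineage is realized by fixing its groups for opposite alleles
## (pooled polymorphism that survives missingness); a single-group lineage is
## polymorphic within the group.
.lineage_group_states <- function(lin_state, groups_in_lineage) {
  n <- length(lin_state)
  out <- matrix(lin_state, n, length(groups_in_lineage))
  colnames(out) <- groups_in_lineage
  if (length(groups_in_lineage) > 1L) {
    i <- which(lin_state == "poly")
    if (length(i)) {
      out[i, 1L] <- "fixed_ref"
      out[i, -1L] <- "fixed_alt"
    }
  }
  out
}

#' Simulate a genotyped Bovinae cohort with known ancestral states
#'
#' Writes a multi-sample VCF (v4.2, biallelic SNPs with QUAL and INFO MQ/QD
#' annotations and diploid GT calls), a sample-to-group map, and a FASTA
#' index with the chromosome lengths, and returns them together with a
#' per-site truth table.
#'
#' @param config an [simulation_config()] object.
#' @param dir output directory (created if needed).
#' @return A list of class `aa_sim_cohort` with elements `vcf`, `group_map`,
#'   `fai` (file paths), `truth` (per-site `data.table`: chrom, pos,
#'   window_index, window_class, ref, alt, true_aa, fixed allele per lineage,
#'   retention per focal group, low_quality flag) and `config`.
#' @export
simulate_cohort <- function(config, dir = tempfile("aascan_sim_")) {
  validate_sim_config(config)
  set.seed(config$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  chroms <- as.character(seq_len(config$n_chromosomes))
  L <- config$chrom_length_bp
  wbp <- config$window_bp
  n_win <- as.integer(ceiling(L / wbp))
  sites_per_win <- max(1L, as.integer(round(config$snp_density * wbp / 1000)))

  pw <- config$planted_windows
  if (!is.null(pw)) pw <- as.data.table(as.data.frame(pw))

  site_list <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    wcls <- rep("background", n_win)
    if (!is.null(pw)) {
      pwc <- pw[chrom == chroms[ci]]
      wcls[pwc$window_index] <- pwc$class
    }
    pos_l <- vector("list", n_win)
    for (t in seq_len(n_win)) {
      lo <- (t - 1L) * wbp + 1L
      hi <- as.integer(min(t * wbp, L))
      k <- min(sites_per_win, hi - lo + 1L)
      pos_l[[t]] <- sort(sample(seq.int(lo, hi), k))
    }
    site_list[[ci]] <- data.table(
      chrom = chroms[ci],
      pos = unlist(pos_l),
      window_index = rep(seq_len(n_win), lengths(pos_l)),
      window_class = rep(wcls, lengths(pos_l))
    )
  }
  sites <- rbindlist(site_list)
  n <- nrow(sites)

  plan <- .plan_sites(config, sites)

  ## genotypes, group by group, in a fixed canonical sample order
  spg <- config$samples_per_group[intersect(aa_groups(), names(config$samples_per_group))]
  sample_ids <- unlist(lapply(names(spg), function(g)
    sprintf("%s_%02d", g, seq_len(spg[[g]]))), use.names = FALSE)
  sample_group <- rep(names(spg), unlist(spg))

  group_state <- matrix(NA_character_, n, length(spg),
                        dimnames = list(NULL, names(spg)))
  for (ln in aa_outgroup_lineages()) {
    gs <- names(spg)[group_lineage(names(spg)) == ln & !is.na(group_lineage(names(spg)))]
    group_state[, gs] <- .lineage_group_states(plan$lineage_state[, ln], gs)
  }
  for (g in intersect(aa_focal_groups(), names(spg)))
    group_state[, g] <- plan$focal_state[, g]
  if ("aurochs" %in% names(spg)) group_state[, "aurochs"] <- "poly"

  dosage <- matrix(NA_integer_, n, length(sample_ids))
  protected <- matrix(FALSE, n, length(sample_ids))
  for (g in names(spg)) {
    cols <- which(sample_group == g)
    r <- .realize_group(group_state[, g], length(cols))
    dosage[, cols] <- r$dosage
    protected[, cols] <- r$protected
  }
  miss <- matrix(runif(length(dosage)) < config$missing_rate, n, length(sample_ids))
  dosage[miss & !protected] <- NA_integer_

  ## site-level quality annotations, optionally below-threshold on
  ## background sites to exercise the hard filters
  qual <- round(runif(n, 30, 2000), 2)
  mq <- round(runif(n, 40, 60), 2)
  qd <- round(runif(n, 30, 40), 2)
  low_quality <- rep(FALSE, n)
  if (config$prop_low_quality > 0) {
    cand <- which(sites$window_class == "background")
    lowq <- cand[runif(length(cand)) < config$prop_low_quality]
    if (length(lowq)) {
      low_quality[lowq] <- TRUE
      field <- sample.int(3L, length(lowq), replace = TRUE)
      qual[lowq[field == 1L]] <- round(runif(sum(field == 1L), 1, 29), 2)
      mq[lowq[field == 2L]] <- round(runif(sum(field == 2L), 10, 39), 2)
      qd[lowq[field == 3L]] <- round(runif(sum(field == 3L), 1, 29), 2)
    }
  }

  state_to_base <- function(st, ref, alt)
    ifelse(st == "fixed_ref", ref, ifelse(st == "fixed_alt", alt, NA_character_))
  truth <- data.table(
    chrom = sites$chrom, pos = sites$pos,
    window_index = sites$window_index, window_class = sites$window_class,
    ref = plan$ref, alt = plan$alt, true_aa = plan$true_aa,
    yak_fixed = state_to_base(plan$lineage_state[, "yak"], plan$ref, plan$alt),
    bison_fixed = state_to_base(plan$lineage_state[, "bison"], plan$ref, plan$alt),
    gagaba_fixed = state_to_base(plan$lineage_state[, "gagaba"], plan$ref, plan$alt),
    taurine_retained = plan$retained[, "taurine"],
    zebu_retained = plan$retained[, "zebu"],
    low_quality = low_quality
  )

  ## --- write artifacts -------------------------------------------------
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", n, length(sample_ids))
  ok <- !is.na(dosage)
  gt[ok] <- gt_codes[dosage[ok] + 1L]

  vcf_path <- file.path(dir, "cohort.vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=aascan_simulate_cohort",
    sprintf("##contig=<ID=%s,length=%d>", chroms, as.integer(L)),
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Variant quality by depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  body <- paste(
    sites$chrom, sites$pos, ".", plan$ref, plan$alt, sprintf("%.2f", qual),
    ".", sprintf("MQ=%.2f;QD=%.2f", mq, qd), "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t")
  writeLines(c(header, body), vcf_path, useBytes = TRUE)

  map_path <- file.path(dir, "groups.tsv")
  writeLines(paste(sample_ids, sample_group, sep = "\t"), map_path, useBytes = TRUE)

  fai_path <- file.path(dir, "genome.fai")
  rec_len <- nchar(chroms) + 2L + as.integer(L) + as.integer(ceiling(L / 60))
  offs <- cumsum(c(0L, head(rec_len, -1L))) + nchar(chroms) + 2L
  writeLines(sprintf("%s\t%d\t%d\t%d\t%d", chroms, as.integer(L),
                     offs, 60L, 61L),
             fai_path, useBytes = TRUE)

  structure(list(vcf = vcf_path, group_map = map_path, fai = fai_path,
                 truth = truth[], config = config),
            class = "aa_sim_cohort")
}

#' Simulate gene models consistent with planted windows
#'
#' Emits a BED file (0-based half-open) of gene intervals in which a
#' configurable fraction of the planted windows overlap a gene body and the
#' remaining planted windows are intergenic (no gene within `buffer_bp`).
#' Additional background genes are scattered over unplanted windows.
#'
#' @param config an [simulation_config()] object.
#' @param truth the truth table from [simulate_cohort()].
#' @param fraction_genic probability that a planted window receives an
#'   overlapping gene.
#' @param genes_per_chrom number of extra background genes per chromosome.
#' @param buffer_bp clearance kept around gene-free planted windows.
#' @param path output BED path.
#' @return the BED path, invisibly a character scalar.
#' @export
simulate_genes <- function(config, truth, fraction_genic = 0.7,
                           genes_per_chrom = 5L, buffer_bp = 2000L,
                           path = tempfile("aascan_genes_", fileext = ".bed")) {
  validate_sim_config(config)
  if (fraction_genic < 0 || fraction_genic > 1)
    stop("invalid simulation config: fraction_genic must be a probability in [0,1]")
  set.seed(config$seed + 7919L)
  wbp <- config$window_bp
  n_win <- as.integer(ceiling(config$chrom_length_bp / wbp))
  chroms <- as.character(seq_len(config$n_chromosomes))

  planted <- unique(truth[window_class != "background",
                          .(chrom, window_index, window_class)])
  rows <- list()
  k <- 0L
  gene_in_window <- function(chrom, t) {
    lo <- (t - 1L) * wbp + 1L
    gstart <- lo + sample.int(max(1L, wbp %/% 4L), 1L)
    gend <- min(gstart + sample.int(max(2L, wbp %/% 3L), 1L) + 200L,
                as.integer(min(t * wbp, config$chrom_length_bp)))
    k <<- k + 1L
    data.table(chrom = chrom, start = gstart, end = gend,
               gene_id = sprintf("gene_%s_%03d", chrom, k),
               strand = sample(c("+", "-"), 1L))
  }
  blocked <- planted[runif(nrow(planted)) >= fraction_genic]  # stay intergenic
  genic <- planted[!blocked, on = c("chrom", "window_index")]
  for (i in seq_len(nrow(genic)))
    rows[[length(rows) + 1L]] <- gene_in_window(genic$chrom[i], genic$window_index[i])

  ## background genes, clear of the intergenic planted windows (plus buffer)
  buffer_win <- as.integer(ceiling(buffer_bp / wbp))
  for (cc in chroms) {
    avoid <- blocked[chrom == cc, window_index]
    avoid <- unique(unlist(lapply(avoid, function(t)
      seq.int(max(1L, t - buffer_win), min(n_win, t + buffer_win)))))
    avoid <- union(avoid, planted[chrom == cc, window_index])
    free <- setdiff(seq_len(n_win), avoid)
    if (length(free) == 0L) next
    pick <- sample(free, min(genes_per_chrom, length(free)))
    for (t in pick) rows[[length(rows) + 1L]] <- gene_in_window(cc, t)
  }
  genes <- rbindlist(rows)
  setorder(genes, chrom, start)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$chrom,
                     genes$start - 1L, genes$end, genes$gene_id, genes$strand),
             path, useBytes = TRUE)
  path
}

#' Read chromosome lengths from a FASTA index
#'
#' @param path a `.fai` file (first two columns: sequence name, length).
#' @return a `data.table` with columns `chrom`, `length_bp`.
#' @export
read_fai <- function(path) {
  if (!file.exists(path)) stop("fai file not found: ", path)
  dt <- fread(path, header = FALSE, sep = "\t", select = 1:2,
              col.names = c("chrom", "length_bp"),
              colClasses = list(character = 1))
  if (any(is.na(dt$length_bp)) || any(dt$length_bp < 1))
    stop("malformed fai: non-positive length")
  dt
}
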