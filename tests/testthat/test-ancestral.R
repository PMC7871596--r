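## Build one site's frequency rows for a lineage from a state code:
## "fixed_A"/"fixed_T" (all called alleles equal), "poly" (both alleles
## segregate), "missing" (no called genotypes -> no rows).
lineage_state_freqs <- function(state, groups) {
  rows <- lapply(groups, function(g) {
    switch(state,
      fixed_A = make_freqs("1", 500, g, "A", 8, 8),
      fixed_T = make_freqs("1", 500, g, "T", 8, 8),
      poly = make_freqs("1", c(500, 500), g, c("A", "T"), c(5, 3), 8),
      missing = NULL)
  })
  rbindlist(c(list(empty_freqs()), rows[!vapply(rows, is.null, logical(1))]))
}

lineage_groups <- list(yak = "yak",
                       bison = c("american_bison", "european_bison"),
                       gagaba = c("gayal", "gaur", "banteng"))

test_that("lineage fixation pools alleles across the lineage's groups", {
  ## all called yak alleles equal A
  expect_identical(lineage_fixed_allele(make_freqs("1", 1, "yak", "A", 26, 26)),
                   "A")
  ## american bison fixed A, european bison carries one T: pooled freq < 1
  bison <- rbindlist(list(
    make_freqs("1", 1, "american_bison", "A", 8, 8),
    make_freqs("1", c(1, 1), "european_bison", c("A", "T"), c(9, 1), 10)))
  expect_identical(lineage_fixed_allele(bison), NA_character_)
  ## lineage with no called chromosomes
  expect_identical(lineage_fixed_allele(bison[0]), NA_character_)
  ## min_called: a single called chromosome does not qualify by default
  one <- make_freqs("1", 1, "yak", "A", 1, 1)
  expect_identical(lineage_fixed_allele(one), NA_character_)
  expect_identical(lineage_fixed_allele(one, min_called = 1L), "A")
})

test_that("consensus call follows the two-of-three agreement rule", {
  expect_identical(call_site(c(yak = "A", bison = "A", gagaba = NA)),
                   list(aa = "A", agreeing_lineages = c("yak", "bison")))
  ## 2-vs-1 conflict resolves to the majority pair
  expect_identical(call_site(c(yak = "A", bison = "T", gagaba = "T")),
                   list(aa = "T", agreeing_lineages = c("bison", "gagaba")))
  ## 1-vs-1 with the third lineage unfixed: no call
  expect_null(call_site(c(yak = "A", bison = "T", gagaba = NA)))
  ## all three agree
  expect_identical(call_site(c(yak = "A", bison = "A", gagaba = "A")),
                   list(aa = "A",
                        agreeing_lineages = c("yak", "bison", "gagaba")))
  expect_null(call_site(c(yak = NA, bison = NA, gagaba = NA)))
})

test_that("exhaustive fixation-pattern enumeration matches the consensus rule", {
  states <- c("fixed_A", "fixed_T", "poly", "missing")
  grid <- expand.grid(yak = states, bison = states, gagaba = states,
                      stringsAsFactors = FALSE)
  expect_identical(nrow(grid), 64L)
  for (i in seq_len(nrow(grid))) {
    st <- unlist(grid[i, ])
    ## independent oracle: literal restatement of the rule over state codes
    fixed_oracle <- ifelse(st == "fixed_A", "A",
                           ifelse(st == "fixed_T", "T", NA))
    tab <- table(fixed_oracle[!is.na(fixed_oracle)])
    expected <- if (length(tab) > 0 && max(tab) >= 2) {
      al <- names(tab)[which.max(tab)]
      list(aa = al,
           agreeing_lineages = names(fixed_oracle)[
             !is.na(fixed_oracle) & fixed_oracle == al])
    } else NULL

    ## route 1: scalar ops on per-lineage spectra
    freqs <- rbindlist(lapply(names(st), function(ln)
      lineage_state_freqs(st[[ln]], lineage_groups[[ln]])))
    fixed <- vapply(names(st), function(ln) {
      gs <- lineage_groups[[ln]]
      lineage_fixed_allele(freqs[group %in% gs])
    }, character(1))
    got <- call_site(fixed)
    expect_identical(got, expected, label = paste(st, collapse = "/"))

    ## route 2: the vectorized genome-wide caller on the same spectra
    calls <- call_genome(freqs)
    if (is.null(expected)) {
      expect_identical(nrow(calls), 0L, label = paste(st, collapse = "/"))
    } else {
      expect_identical(calls$aa, expected$aa)
      expect_identical(calls$agreeing_lineages,
                       paste(expected$agreeing_lineages, collapse = ","))
    }
  }
})

test_that("genome-wide calls recover the synthetic truth exactly", {
  co <- small_cohort()
  calls <- call_genome(co$freqs)
  truth_aa <- co$sim$truth[!is.na(true_aa) & low_quality == FALSE]
  expect_identical(nrow(calls), nrow(truth_aa))  # precision = recall = 1
  m <- merge(calls, truth_aa, by = c("chrom", "pos"))
  expect_identical(nrow(m), nrow(calls))
  expect_identical(m$aa, m$true_aa)
  ## agreeing lineages match the planted fixation patterns
  agree_truth <- vapply(seq_len(nrow(m)), function(i) {
    fx <- c(yak = m$yak_fixed[i], bison = m$bison_fixed[i],
            gagaba = m$gagaba_fixed[i])
    paste(names(fx)[!is.na(fx) & fx == m$true_aa[i]], collapse = ",")
  }, character(1))
  expect_identical(m$agreeing_lineages, agree_truth)
})

test_that("calls are order-invariant and idempotent", {
  co <- small_cohort()
  calls <- call_genome(co$freqs)
  set.seed(3L)
  shuffled <- co$freqs[sample(nrow(co$freqs))]
  expect_equal(call_genome(shuffled), calls)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_aa_list(calls, p1)
  write_aa_list(call_genome(co$freqs), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("raising min_called never adds calls", {
  co <- small_cohort()
  prev <- NULL
  for (mc in c(2L, 6L, 10L, 26L)) {
    calls <- call_genome(co$freqs, min_called = mc)
    if (!is.null(prev)) {
      m <- merge(calls[, .(chrom, pos)], prev[, .(chrom, pos)],
                 by = c("chrom", "pos"))
      expect_identical(nrow(m), nrow(calls))  # subset of the previous calls
    }
    prev <- calls
  }
})

test_that("the six-column AA list round-trips exactly", {
  set.seed(11L)
  n <- 1000L
  calls <- data.table(
    chrom = as.character(sample(1:5, n, replace = TRUE)),
    pos = sample(1e6, n),
    n_alleles = sample(1:2, n, replace = TRUE),
    aa = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    aa_freq_pooled = round(runif(n), 6),
    agreeing_lineages = sample(c("yak,bison", "yak,gagaba", "bison,gagaba",
                                 "yak,bison,gagaba"), n, replace = TRUE))
  setorder(calls, chrom, pos)
  path <- withr::local_tempfile()
  write_aa_list(calls, path)
  back <- read_aa_list(path)
  expect_equal(as.data.frame(back), as.data.frame(calls))

  bad <- withr::local_tempfile()
  writeLines(c("#h", "1\t100\t2\tA\t0.5\tyak,bison", "1\t200\t2\tA\t0.5"), bad)
  expect_error(read_aa_list(bad), "line 3")
})
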