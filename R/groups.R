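## Group and lineage vocabulary of the Bovinae cohort.
##
## Eight genotyped groups map onto three outgroup lineages used for the
## ancestral-allele consensus and two focal cattle groups that are scored
## against it. Aurochs samples, when present, belong to neither: they cluster
## with domestic cattle and are excluded from both consensus and scoring.

.AA_GROUP_LINEAGE <- c(
  yak             = "yak",
  american_bison  = "bison",
  european_bison  = "bison",
  gayal           = "gagaba",
  gaur            = "gagaba",
  banteng         = "gagaba",
  taurine         = "focal",
  zebu            = "focal",
  aurochs         = NA_character_
)

#' Sample groups and lineages
#'
#' `aa_groups()` returns the recognised group labels; `aa_outgroup_lineages()`
#' the three outgroup lineage names; `aa_focal_groups()` the focal cattle
#' groups; `group_lineage()` maps group labels to their lineage (`"focal"`
#' for taurine/zebu, `NA` for aurochs).
#'
#' @param group character vector of group labels.
#' @return character vectors of labels (or lineages for `group_lineage`).
#' @export
#' @examples
#' group_lineage(c("yak", "gaur", "taurine"))
aa_groups <- function() names(.AA_GROUP_LINEAGE)

#' @rdname aa_groups
#' @export
aa_outgroup_lineages <- function() c("yak", "bison", "gagaba")

#' @rdname aa_groups
#' @export
aa_focal_groups <- function() c("taurine", "zebu")

#' @rdname aa_groups
#' @export
group_lineage <- function(group) {
  unname(.AA_GROUP_LINEAGE[group])
}

#' Read and validate a sample-to-group map
#'
#' Parses a two-column tab-separated file (`sample_id<TAB>group`, no header
#' required; a header line starting with `#` is ignored) and validates it:
#' every sample must appear exactly once and every group label must be one
#' of [aa_groups()].
#'
#' @param path path to the TSV file.
#' @return A `data.table` with columns `sample_id`, `group`, `lineage`
#'   (class `aa_group_map`). The `lineage` column is `"focal"` for taurine
#'   and zebu and `NA` for aurochs.
#' @export
parse_group_map <- function(path) {
  if (!file.exists(path)) stop("group map file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("group map is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop("group map line ", bad[1L], " does not have 2 tab-separated fields")
  }
  map <- data.table(
    sample_id = vapply(parts, `[`, character(1L), 1L),
    group     = vapply(parts, `[`, character(1L), 2L)
  )
  dup <- map$sample_id[duplicated(map$sample_id)]
  if (length(dup) > 0L) {
    stop("duplicated sample_id in group map: ", paste(unique(dup), collapse = ", "))
  }
  unknown <- setdiff(unique(map$group), aa_groups())
  if (length(unknown) > 0L) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         "; allowed groups are: ", paste(aa_groups(), collapse = ", "))
  }
  map[, lineage := group_lineage(group)]
  setattr(map, "class", c("aa_group_map", class(map)))
  map[]
}
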