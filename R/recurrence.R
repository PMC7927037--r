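#' Classify a variant's recurrence status within one stratum
#'
#' A variant is a *rare recurrent* variant of interest in a stratum when it
#' is carried by at least `min_case_occurrences` cases, its carrier frequency
#' in that stratum's controls is strictly below `max_control_frequency`, and
#' every population-database frequency present (esp6500, 1000 Genomes,
#' gnomAD) is strictly below `max_population_maf` — frequencies absent from a
#' database pass the filter. It is *zero-in-control* when additionally no
#' control carries it. Everything else is `none`.
#'
#' All arguments are vectorized over variants.
#'
#' @param case_carriers,control_carriers integer carrier counts in the
#'   stratum.
#' @param n_controls stratum control cohort size (fixed denominator for the
#'   control carrier frequency).
#' @param esp6500,kg1000,gnomad population allele frequencies (`NA` =
#'   absent).
#' @param thresholds a [filter_thresholds()].
#' @return character vector: `"none"`, `"rare_recurrent"` or
#'   `"zero_in_control"`.
#' @export
classify_recurrence <- function(case_carriers, control_carriers, n_controls,
                                esp6500 = NA_real_, kg1000 = NA_real_,
                                gnomad = NA_real_,
                                thresholds = filter_thresholds()) {
  n <- length(case_carriers)
  control_carriers <- rep_len(control_carriers, n)
  n_controls <- rep_len(n_controls, n)
  esp6500 <- rep_len(esp6500, n)
  kg1000 <- rep_len(kg1000, n)
  gnomad <- rep_len(gnomad, n)
  freq_ok <- (is.na(esp6500) | esp6500 < thresholds$max_population_maf) &
    (is.na(kg1000) | kg1000 < thresholds$max_population_maf) &
    (is.na(gnomad) | gnomad < thresholds$max_population_maf)
  recurrent <- case_carriers >= thresholds$min_case_occurrences
  ctrl_rare <- control_carriers / n_controls < thresholds$max_control_frequency
  out <- rep("none", n)
  out[recurrent & ctrl_rare & freq_ok] <- "rare_recurrent"
  out[recurrent & control_carriers == 0L & freq_ok] <- "zero_in_control"
  out
}

# a minimal annotation row used when a tallied variant has no annotation
sentinel_annotation <- function(ids) {
  data.frame(id = ids, genes = ".", region = "intergenic",
             exonic_func = "none", dbsnp = NA_character_,
             SIFT = NA_character_, Polyphen2 = NA_character_,
             LRT = NA_character_, MutationTaster = NA_character_,
             MutationAssessor = NA_character_, FATHMM = NA_character_,
             RadialSVM = NA_character_,
             esp6500 = NA_real_, kg1000 = NA_real_, gnomad = NA_real_,
             host_genes = NA_character_, stringsAsFactors = FALSE)
}

#' Select recurrent variants of interest across a cohort
#'
#' Joins carrier tallies with annotations, classifies every variant in every
#' stratum with [classify_recurrence()], and keeps those that are recurrent
#' in at least one stratum or eligible for the cross-stratum meta screen. A
#' variant is meta-eligible when every stratum contributes at least one case
#' carrier, no control anywhere carries it, the total case carriers reach the
#' recurrence threshold, and the population-frequency filter passes —
#' per-stratum recurrence is deliberately not required, so a variant seen
#' once in each of two strata still enters the meta list.
#'
#' Per-stratum two-sided association p-values (exact and continuity-corrected
#' chi-square) are attached for every selected variant. Variants lacking an
#' annotation row are retained with a sentinel annotation and reported via
#' `message()`.
#'
#' @param tally carrier tally from [read_cohort_vcf()] (or
#'   [tally_from_counts()]).
#' @param annotations annotation table from [read_annotation_table()].
#' @param thresholds a [filter_thresholds()].
#' @param cohort a [cohort_spec()]; defaults to the tally's cohort attribute.
#' @return calls data.frame: one row per selected variant with annotation
#'   columns, per-stratum `case_carriers.S` / `control_carriers.S` /
#'   `class.S` / `fisher_p.S` / `chisq_p.S`, and logical `meta_eligible`.
#' @export
select_variants <- function(tally, annotations,
                            thresholds = filter_thresholds(),
                            cohort = attr(tally, "cohort")) {
  if (is.null(cohort)) stop("no cohort_spec available", call. = FALSE)
  ann_cols <- c("genes", "region", "exonic_func", "dbsnp", PREDICTOR_TOOLS,
                "esp6500", "kg1000", "gnomad", "host_genes")
  df <- merge(tally, annotations[c("id", ann_cols)], by = "id",
              all.x = TRUE, sort = FALSE)
  unann <- is.na(df$genes)
  if (any(unann)) {
    message(sum(unann), " variant(s) lack annotation; kept with sentinel annotation")
    df[unann, ann_cols] <- sentinel_annotation(df$id[unann])[ann_cols]
  }

  case_mat <- sapply(cohort$label, function(s) df[[paste0("case_carriers.", s)]])
  ctrl_mat <- sapply(cohort$label, function(s) df[[paste0("control_carriers.", s)]])
  if (nrow(df) == 1L) { case_mat <- t(case_mat); ctrl_mat <- t(ctrl_mat) }
  if (nrow(df) == 0L) {
    case_mat <- ctrl_mat <- matrix(integer(0), 0, nrow(cohort))
  }

  freq_ok <- (is.na(df$esp6500) | df$esp6500 < thresholds$max_population_maf) &
    (is.na(df$kg1000) | df$kg1000 < thresholds$max_population_maf) &
    (is.na(df$gnomad) | df$gnomad < thresholds$max_population_maf)
  for (j in seq_len(nrow(cohort))) {
    s <- cohort$label[j]
    df[[paste0("class.", s)]] <- classify_recurrence(
      case_mat[, j], ctrl_mat[, j], cohort$n_controls[j],
      df$esp6500, df$kg1000, df$gnomad, thresholds)
  }
  any_class <- Reduce(`|`, lapply(cohort$label, function(s)
    df[[paste0("class.", s)]] != "none"), rep(FALSE, nrow(df)))
  df$meta_eligible <- rowSums(case_mat >= 1L) == nrow(cohort) &
    rowSums(ctrl_mat) == 0L &
    rowSums(case_mat) >= thresholds$min_case_occurrences &
    freq_ok

  # full accounting: every input variant lands in exactly one class per stratum
  accounting <- sapply(cohort$label, function(s)
    table(factor(df[[paste0("class.", s)]],
                 levels = c("none", "rare_recurrent", "zero_in_control"))))
  if (is.null(dim(accounting)))
    accounting <- matrix(integer(0), 3L, nrow(cohort),
                         dimnames = list(c("none", "rare_recurrent",
                                           "zero_in_control"), cohort$label))

  keep <- which(any_class | df$meta_eligible)
  df <- df[keep, , drop = FALSE]
  for (j in seq_len(nrow(cohort))) {
    s <- cohort$label[j]
    nc <- cohort$n_cases[j]; nk <- cohort$n_controls[j]
    a <- df[[paste0("case_carriers.", s)]]
    c_ <- df[[paste0("control_carriers.", s)]]
    df[[paste0("fisher_p.", s)]] <- vapply(seq_along(a), function(i)
      fisher_exact_2x2(a[i], nc - a[i], c_[i], nk - c_[i]), numeric(1))
    df[[paste0("chisq_p.", s)]] <- vapply(seq_along(a), function(i)
      chisq_yates_2x2(a[i], nc - a[i], c_[i], nk - c_[i])[["p"]], numeric(1))
  }
  rownames(df) <- NULL
  attr(df, "cohort") <- cohort
  attr(df, "thresholds") <- thresholds
  attr(df, "accounting") <- accounting
  df
}

#' Build a carrier tally directly from per-stratum carrier counts
#'
#' Bypasses the genotype level: useful for published tables that report
#' carrier counts rather than genotypes. Genotyped denominators are taken as
#' the full stratum sizes.
#'
#' @param annotations annotation table carrying `id`, `chrom`, `start`,
#'   `ref`, `alt`.
#' @param counts data.frame with `id` and per-stratum `case_carriers.S` /
#'   `control_carriers.S` columns.
#' @param cohort a [cohort_spec()].
#' @return a carrier tally as from [read_cohort_vcf()].
#' @export
tally_from_counts <- function(annotations, counts, cohort) {
  tab <- merge(annotations[c("id", "chrom", "start", "ref", "alt")], counts,
               by = "id", sort = FALSE)
  names(tab)[names(tab) == "start"] <- "pos"
  for (j in seq_len(nrow(cohort))) {
    s <- cohort$label[j]
    for (st in c("case", "control")) {
      cc <- paste0(st, "_carriers.", s)
      if (is.null(tab[[cc]])) tab[[cc]] <- 0L
      tab[[paste0(st, "_genotyped.", s)]] <-
        if (st == "case") cohort$n_cases[j] else cohort$n_controls[j]
    }
  }
  attr(tab, "cohort") <- cohort
  tab
}

#' Roll selected calls up to the gene level
#'
#' Every call contributes to each gene in its annotation, plus — for
#' ncRNA-exonic loci — the coding host genes whose introns, UTRs or 1 kb
#' flanks cover the locus, so that noncoding hits can enter pathway analysis.
#'
#' @param calls calls data.frame from [select_variants()].
#' @param stratum optional stratum label: restrict to calls classified
#'   (`!= "none"`) in that stratum.
#' @return named list mapping gene symbol to the character vector of variant
#'   ids hitting it.
#' @export
gene_rollup <- function(calls, stratum = NULL) {
  if (!is.null(stratum)) {
    cl <- calls[[paste0("class.", stratum)]]
    if (is.null(cl)) stop("no such stratum: ", stratum, call. = FALSE)
    calls <- calls[cl != "none", , drop = FALSE]
  }
  out <- list()
  for (i in seq_len(nrow(calls))) {
    g <- strsplit(calls$genes[i], ";", fixed = TRUE)[[1]]
    if (!is.na(calls$host_genes[i]) && nzchar(calls$host_genes[i]))
      g <- c(g, strsplit(calls$host_genes[i], ";", fixed = TRUE)[[1]])
    g <- setdiff(unique(g), ".")
    for (gene in g) out[[gene]] <- c(out[[gene]], calls$id[i])
  }
  out
}
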