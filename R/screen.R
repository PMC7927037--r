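#' Run the full rare-recurrent variant screen
#'
#' End-to-end orchestration: tally carriers from the cohort VCF (dropping
#' variants in the optional low-confidence mask), join the annotation table,
#' attach ncRNA host genes when a gene model is given, classify recurrence
#' per stratum, attach per-variant association tests, run the cross-stratum
#' meta screen, summarize by functional class, and optionally test gene-set
#' over-representation.
#'
#' @param vcf path to the multi-sample VCF.
#' @param manifest path to the sample manifest TSV, or a
#'   [read_sample_manifest()] result.
#' @param annotation path to the annotation TSV, or a
#'   [read_annotation_table()] result.
#' @param gene_model optional path or [read_gene_model()] data.frame.
#' @param mask optional path or [read_bed_mask()] data.frame.
#' @param thresholds a [filter_thresholds()].
#' @param gmt optional path to a GMT file or [read_gmt()] list; triggers
#'   over-representation of the genes hit by selected calls.
#' @param universe gene universe for enrichment; defaults to all genes in
#'   the annotation table.
#' @return An object of class `"recur_screen"`; see [summary.recur_screen()].
#' @export
recurrence_screen <- function(vcf, manifest, annotation, gene_model = NULL,
                              mask = NULL, thresholds = filter_thresholds(),
                              gmt = NULL, universe = NULL) {
  if (is.character(manifest)) manifest <- read_sample_manifest(manifest)
  if (is.character(annotation)) annotation <- read_annotation_table(annotation)
  if (is.character(mask)) mask <- read_bed_mask(mask)
  if (is.character(gene_model)) gene_model <- read_gene_model(gene_model)
  tally <- read_cohort_vcf(vcf, manifest, mask)
  screen_core(tally, annotation, attr(tally, "cohort"), thresholds,
              gene_model = gene_model, gmt = gmt, universe = universe)
}

#' Run the screen from published carrier counts
#'
#' Same screen as [recurrence_screen()], entered at the carrier-count level
#' (e.g. from a [table_fixtures()] fixture) instead of genotypes.
#'
#' @param annotation annotation table (data.frame or path).
#' @param counts per-stratum carrier counts (see [tally_from_counts()]).
#' @param cohort a [cohort_spec()].
#' @inheritParams recurrence_screen
#' @return a `"recur_screen"` object.
#' @export
counts_screen <- function(annotation, counts, cohort = default_cohort(),
                          thresholds = filter_thresholds(), gene_model = NULL,
                          gmt = NULL, universe = NULL) {
  if (is.character(annotation)) annotation <- read_annotation_table(annotation)
  tally <- tally_from_counts(annotation, counts, cohort)
  screen_core(tally, annotation, cohort, thresholds,
              gene_model = gene_model, gmt = gmt, universe = universe)
}

screen_core <- function(tally, annotation, cohort, thresholds,
                        gene_model = NULL, gmt = NULL, universe = NULL) {
  if (!is.null(gene_model) && nrow(gene_model) > 0L)
    annotation <- annotate_ncrna_hosts(annotation, gene_model)
  calls <- select_variants(tally, annotation, thresholds, cohort)
  calls$func_class <- functional_class(calls$region, calls$exonic_func,
                                       calls$ref, calls$alt)
  calls <- meta_screen(calls, cohort, thresholds$alpha_meta)

  class_summary <- do.call(rbind, lapply(cohort$label, function(s) {
    cl <- calls[[paste0("class.", s)]]
    do.call(rbind, lapply(c("rare_recurrent", "zero_in_control"), function(rc) {
      sub <- calls[if (rc == "rare_recurrent") cl != "none" else cl == rc, ,
                   drop = FALSE]
      data.frame(stratum = s, recurrence_class = rc,
                 func_class = FUNCTIONAL_CLASSES,
                 n = as.integer(table(factor(sub$func_class,
                                             levels = FUNCTIONAL_CLASSES))),
                 stringsAsFactors = FALSE)
    }))
  }))

  enrichment <- NULL
  if (!is.null(gmt)) {
    if (is.character(gmt)) gmt <- read_gmt(gmt)
    if (is.null(universe))
      universe <- unique(unlist(strsplit(annotation$genes, ";", fixed = TRUE)))
    query <- names(gene_rollup(calls))
    enrichment <- enrich(intersect(query, universe), gmt, universe)
  }

  structure(list(calls = calls, cohort = cohort, thresholds = thresholds,
                 class_summary = class_summary,
                 accounting = attr(calls, "accounting"),
                 n_input_variants = nrow(tally),
                 enrichment = enrichment),
            class = "recur_screen")
}

#' @export
print.recur_screen <- function(x, ...) {
  cat("Rare recurrent variant screen\n")
  cat(sprintf("  cohort: %s\n", paste(
    sprintf("%s (%d cases / %d controls)", x$cohort$label, x$cohort$n_cases,
            x$cohort$n_controls), collapse = ", ")))
  cat(sprintf("  input variants: %d; selected calls: %d\n",
              x$n_input_variants, nrow(x$calls)))
  for (s in x$cohort$label) {
    cl <- x$calls[[paste0("class.", s)]]
    cat(sprintf("  %s: %d rare recurrent (%d zero-in-control)\n", s,
                sum(cl != "none"), sum(cl == "zero_in_control")))
  }
  n_el <- sum(x$calls$meta_eligible)
  cat(sprintf("  meta screen: %d eligible, %d retained at alpha = %g\n",
              n_el, sum(x$calls$meta_retained, na.rm = TRUE),
              x$thresholds$alpha_meta))
  invisible(x)
}

#' Summarize a screen by recurrence and functional class
#'
#' @param object a `"recur_screen"` object.
#' @param ... unused.
#' @return list with `counts` (the long stratum x recurrence x functional
#'   class table), `zero_in_control` (a functional-class x stratum count
#'   matrix), `meta` (the meta-retained calls) and `accounting` (every input
#'   variant's class per stratum; columns sum to the input variant count).
#' @export
summary.recur_screen <- function(object, ...) {
  zic <- sapply(object$cohort$label, function(s) {
    sub <- object$class_summary[object$class_summary$stratum == s &
                                  object$class_summary$recurrence_class ==
                                  "zero_in_control", ]
    stats::setNames(sub$n, sub$func_class)
  })
  if (is.null(dim(zic)))
    zic <- matrix(zic, ncol = length(object$cohort$label),
                  dimnames = list(FUNCTIONAL_CLASSES, object$cohort$label))
  meta <- object$calls[!is.na(object$calls$meta_retained) &
                         object$calls$meta_retained, , drop = FALSE]
  out <- list(counts = object$class_summary, zero_in_control = zic,
              meta = meta, accounting = object$accounting,
              enrichment = object$enrichment)
  class(out) <- "summary.recur_screen"
  out
}

#' @export
print.summary.recur_screen <- function(x, ...) {
  cat("Zero-in-control recurrent variants by functional class:\n")
  print(x$zero_in_control)
  cat(sprintf("\nMeta screen retained %d variant(s)\n", nrow(x$meta)))
  if (!is.null(x$enrichment) && nrow(x$enrichment) > 0L) {
    cat("\nTop enriched gene sets:\n")
    print(utils::head(x$enrichment, 5L))
  }
  invisible(x)
}

#' @export
plot.recur_screen <- function(x, ...) {
  s <- summary(x)
  graphics::barplot(t(s$zero_in_control), beside = TRUE,
                    legend.text = colnames(s$zero_in_control),
                    ylab = "zero-in-control variants",
                    main = "Zero-in-control recurrent variants", ...)
  invisible(x)
}

#' Machine-readable class-count report
#'
#' Per-stratum counts by recurrence class and functional class, plus meta
#' screen totals, as a plain list (serializable to JSON).
#'
#' @param screen a `"recur_screen"` object.
#' @param json optional path: write the report as JSON.
#' @return the report list, invisibly when `json` is given.
#' @export
summarize_screen <- function(screen, json = NULL) {
  s <- summary(screen)
  report <- list(
    n_input_variants = screen$n_input_variants,
    n_selected = nrow(screen$calls),
    zero_in_control = apply(s$zero_in_control, 2L, as.list),
    accounting = apply(screen$accounting, 2L, as.list),
    meta = list(eligible = sum(screen$calls$meta_eligible),
                retained = sum(screen$calls$meta_retained, na.rm = TRUE),
                alpha = screen$thresholds$alpha_meta),
    thresholds = unclass(screen$thresholds))
  if (!is.null(json)) {
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA), json)
    return(invisible(report))
  }
  report
}

#' Run the screen and write a results bundle to disk
#'
#' Writes `calls.tsv` (all selected calls, one row per variant-gene pair),
#' per-stratum `zero_in_control_<S>.tsv` and `rare_recurrent_<S>.tsv`,
#' `meta_screen.tsv` (meta-retained calls), `summary.json`, `enrichment.tsv`
#' when a GMT is supplied, and `run_log.txt` recording thresholds and input
#' MD5 checksums.
#'
#' @inheritParams recurrence_screen
#' @param out_dir output directory (created if needed).
#' @param bh also report Benjamini-Hochberg adjusted meta p-values in a
#'   `meta_p_adj` column (the screen's retention itself uses raw p < alpha,
#'   as the individually rare variants do not survive multiplicity
#'   correction and are reported as candidates).
#' @return the `"recur_screen"` object, invisibly, with an `out_files`
#'   attribute listing the written paths.
#' @export
run_pipeline <- function(vcf, manifest, annotation, out_dir,
                         gene_model = NULL, mask = NULL,
                         thresholds = filter_thresholds(), gmt = NULL,
                         universe = NULL, bh = FALSE) {
  inputs <- c(vcf = vcf,
              manifest = if (is.character(manifest)) manifest,
              annotation = if (is.character(annotation)) annotation,
              gene_model = if (is.character(gene_model)) gene_model,
              mask = if (is.character(mask)) mask,
              gmt = if (is.character(gmt)) gmt)
  screen <- recurrence_screen(vcf, manifest, annotation,
                              gene_model = gene_model, mask = mask,
                              thresholds = thresholds, gmt = gmt,
                              universe = universe)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  calls <- screen$calls
  if (bh && any(calls$meta_eligible)) {
    calls$meta_p_adj <- NA_real_
    el <- which(!is.na(calls$meta_p))
    calls$meta_p_adj[el] <- bh_adjust(calls$meta_p[el])
  }
  paths <- c(calls = file.path(out_dir, "calls.tsv"))
  write_calls_tsv(calls, paths[["calls"]])
  for (s in screen$cohort$label) {
    cl <- calls[[paste0("class.", s)]]
    p1 <- file.path(out_dir, paste0("zero_in_control_", s, ".tsv"))
    write_calls_tsv(calls[cl == "zero_in_control", , drop = FALSE], p1)
    p2 <- file.path(out_dir, paste0("rare_recurrent_", s, ".tsv"))
    write_calls_tsv(calls[cl != "none", , drop = FALSE], p2)
    paths[paste0("zero_in_control_", s)] <- p1
    paths[paste0("rare_recurrent_", s)] <- p2
  }
  meta <- calls[!is.na(calls$meta_retained) & calls$meta_retained, ,
                drop = FALSE]
  paths["meta"] <- file.path(out_dir, "meta_screen.tsv")
  write_calls_tsv(meta, paths[["meta"]])
  paths["summary"] <- file.path(out_dir, "summary.json")
  summarize_screen(screen, json = paths[["summary"]])
  if (!is.null(screen$enrichment)) {
    paths["enrichment"] <- file.path(out_dir, "enrichment.tsv")
    utils::write.table(screen$enrichment, paths[["enrichment"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  paths["log"] <- file.path(out_dir, "run_log.txt")
  sums <- tools::md5sum(inputs[!is.na(inputs)])
  writeLines(c("recurscreen run log",
               sprintf("thresholds: min_case_occurrences=%d max_control_frequency=%g max_population_maf=%g alpha_meta=%g",
                       thresholds$min_case_occurrences,
                       thresholds$max_control_frequency,
                       thresholds$max_population_maf, thresholds$alpha_meta),
               sprintf("input %s: %s md5=%s", names(sums), inputs[!is.na(inputs)],
                       sums)),
             paths[["log"]])
  attr(screen, "out_files") <- paths
  invisible(screen)
}
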