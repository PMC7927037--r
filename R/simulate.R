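# Synthetic cohort generation: Hardy-Weinberg background variants on a toy
# chromosome plus spiked recurrent variants with forced carrier patterns,
# emitted in exactly the file dialects the screen ingests.

#' Specify a spiked variant for the synthetic cohort
#'
#' @param chrom,pos,ref,alt variant coordinates (VCF anchored style; alleles
#'   A/C/G/T).
#' @param case_carriers named integer vector: forced case carriers per
#'   stratum label.
#' @param control_carriers named integer vector of forced control carriers
#'   (default: zero everywhere).
#' @param class functional class to annotate: one of `"stopgain"`,
#'   `"frameshift"`, `"nonsynonymous"`, `"intronic_indel"`,
#'   `"ncrna_exonic"`.
#' @param genes gene symbol(s) for the annotation row.
#' @param esp6500,kg1000,gnomad population frequencies to emit (`NA` = `.`,
#'   mimicking a novel variant absent from the databases).
#' @param host_genes for `ncrna_exonic` spikes: coding host genes whose
#'   intron spans will cover the locus in the emitted gene model.
#' @param homozygous spike carriers as homozygous alt instead of
#'   heterozygous (carrier counts are zygosity-blind, so the screen result
#'   must not change; used to test exactly that).
#' @return list of class `"spike_spec"`.
#' @export
spike_spec <- function(chrom, pos, ref, alt, case_carriers,
                       control_carriers = NULL,
                       class = c("intronic_indel", "stopgain", "frameshift",
                                 "nonsynonymous", "ncrna_exonic"),
                       genes = "SPIKEGENE", esp6500 = NA_real_,
                       kg1000 = NA_real_, gnomad = NA_real_,
                       host_genes = NULL, homozygous = FALSE) {
  class <- match.arg(class)
  if (is.null(names(case_carriers)))
    stop("case_carriers must be named by stratum label", call. = FALSE)
  if (is.null(control_carriers))
    control_carriers <- stats::setNames(rep(0L, length(case_carriers)),
                                        names(case_carriers))
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = toupper(ref), alt = toupper(alt),
                 case_carriers = case_carriers,
                 control_carriers = control_carriers,
                 class = class, genes = genes,
                 esp6500 = esp6500, kg1000 = kg1000, gnomad = gnomad,
                 host_genes = host_genes, homozygous = homozygous),
            class = "spike_spec")
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study cohort: two ancestry strata (AA 116 cases /
#' 408 controls, EA 89 cases / 262 controls), a background of biallelic SNVs
#' in Hardy-Weinberg equilibrium at stratum-specific minor allele
#' frequencies drawn from Beta(0.5, 10) truncated to [0.001, 0.5] (a
#' rare-skewed site-frequency spectrum), and user-chosen spiked variants.
#'
#' @param strata a [cohort_spec()].
#' @param n_background_variants number of background SNVs (default 2000).
#' @param maf_shape1,maf_shape2 Beta parameters of the background MAF
#'   distribution.
#' @param maf_range truncation bounds for background MAFs.
#' @param spikes list of [spike_spec()] objects.
#' @param seed integer RNG seed (mandatory: outputs are byte-identical for
#'   identical seeds).
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(strata = default_cohort(),
                       n_background_variants = 2000L,
                       maf_shape1 = 0.5, maf_shape2 = 10,
                       maf_range = c(0.001, 0.5),
                       spikes = list(), seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed", call. = FALSE)
  n_background_variants <- as.integer(n_background_variants)
  stopifnot(n_background_variants >= 0L, maf_shape1 > 0, maf_shape2 > 0,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5)
  for (sp in spikes) {
    if (!inherits(sp, "spike_spec")) stop("spikes must be spike_spec objects")
    for (s in names(sp$case_carriers)) {
      j <- match(s, strata$label)
      if (is.na(j)) stop("spike references unknown stratum: ", s, call. = FALSE)
      if (sp$case_carriers[[s]] > strata$n_cases[j] ||
          (sp$control_carriers[[s]] %||% 0L) > strata$n_controls[j])
        stop("spike carrier count exceeds stratum size in ", s, call. = FALSE)
    }
  }
  structure(list(strata = strata,
                 n_background_variants = n_background_variants,
                 maf_shape1 = maf_shape1, maf_shape2 = maf_shape2,
                 maf_range = maf_range, spikes = spikes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

spike_region <- function(class) {
  switch(class, stopgain = "exonic", frameshift = "exonic",
         nonsynonymous = "exonic", intronic_indel = "intronic",
         ncrna_exonic = "ncRNA_exonic")
}

spike_exonic_func <- function(sp) {
  switch(sp$class,
         stopgain = "stopgain",
         frameshift = if (nchar(sp$alt) > nchar(sp$ref)) "frameshift_insertion"
                      else "frameshift_deletion",
         nonsynonymous = "nonsynonymous",
         "none")
}

#' Generate a synthetic cohort on disk
#'
#' Writes five files to `dir`: `cohort.vcf` (multi-sample VCF with GT
#' genotypes), `samples.tsv` (sample manifest), `annotation.tsv`
#' (ANNOVAR-dialect annotation; background variants carry their simulated
#' MAF in the gnomAD column so common background fails the rare-variant
#' filter by construction), `gene_model.bed` (coding-gene feature model
#' covering any ncRNA-exonic spikes) and `truth.tsv` (ground truth per
#' spiked variant).
#'
#' Background genotypes are drawn per stratum as Binomial(2, MAF) allele
#' counts (Hardy-Weinberg). Spiked variants assign exactly the requested
#' carrier counts (heterozygous unless the spike says otherwise) to
#' uniformly chosen individuals without replacement. Outputs are
#' byte-identical across runs with the same config.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list with the five file `paths`, the `truth` data.frame, the
#'   background `maf` matrix (variant x stratum) and the `config`.
#' @export
generate_cohort <- function(config, dir = tempfile("simcohort")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  strata <- config$strata
  with_seed(config$seed, {
    manifest <- do.call(rbind, lapply(seq_len(nrow(strata)), function(j) {
      s <- strata$label[j]
      data.frame(
        sample_id = c(sprintf("%s_case_%04d", s, seq_len(strata$n_cases[j])),
                      sprintf("%s_ctrl_%04d", s, seq_len(strata$n_controls[j]))),
        stratum = s,
        status = rep(c("case", "control"),
                     c(strata$n_cases[j], strata$n_controls[j])),
        stringsAsFactors = FALSE)
    }))
    n_samp <- nrow(manifest)

    nbg <- config$n_background_variants
    bases <- c("A", "C", "G", "T")
    maf <- matrix(numeric(0), 0, nrow(strata))
    geno <- matrix(0L, nbg, n_samp)
    bg_ref <- bg_alt <- character(nbg)
    if (nbg > 0L) {
      maf <- matrix(pmin(pmax(stats::rbeta(nbg * nrow(strata),
                                           config$maf_shape1, config$maf_shape2),
                              config$maf_range[1]), config$maf_range[2]),
                    nbg, nrow(strata))
      bg_ref <- sample(bases, nbg, replace = TRUE)
      bg_alt <- vapply(bg_ref, function(r) sample(setdiff(bases, r), 1L),
                       character(1), USE.NAMES = FALSE)
      for (j in seq_len(nrow(strata))) {
        cols <- which(manifest$stratum == strata$label[j])
        geno[, cols] <- stats::rbinom(nbg * length(cols), 2L,
                                      rep(maf[, j], times = length(cols)))
      }
    }
    colnames(maf) <- strata$label

    spikes <- config$spikes
    sp_geno <- matrix(0L, length(spikes), n_samp)
    for (i in seq_along(spikes)) {
      sp <- spikes[[i]]
      for (s in names(sp$case_carriers)) {
        pick <- sample(which(manifest$stratum == s & manifest$status == "case"),
                       sp$case_carriers[[s]])
        sp_geno[i, pick] <- if (sp$homozygous) 2L else 1L
      }
      for (s in names(sp$control_carriers)) {
        k <- sp$control_carriers[[s]]
        if (k > 0L) {
          pick <- sample(which(manifest$stratum == s &
                               manifest$status == "control"), k)
          sp_geno[i, pick] <- if (sp$homozygous) 2L else 1L
        }
      }
    }

    # ---- VCF ----
    chrom <- c(rep("chrS", nbg), vapply(spikes, `[[`, character(1), "chrom"))
    pos <- c(if (nbg > 0L) 1000L * seq_len(nbg) else integer(0),
             vapply(spikes, `[[`, integer(1), "pos"))
    ref <- c(bg_ref, vapply(spikes, `[[`, character(1), "ref"))
    alt <- c(bg_alt, vapply(spikes, `[[`, character(1), "alt"))
    gmat <- rbind(geno, sp_geno)
    gt_strings <- c("0/0", "0/1", "1/1")[gmat + 1L]
    dim(gt_strings) <- dim(gmat)
    body <- if (nrow(gmat) > 0L)
      paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT",
            apply(gt_strings, 1L, paste, collapse = "\t"), sep = "\t")
    else character(0)
    vcf_path <- file.path(dir, "cohort.vcf")
    writeLines(c("##fileformat=VCFv4.2",
                 paste0("##source=recurscreen_simulate seed=", config$seed),
                 "##contig=<ID=chrS>",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", manifest$sample_id), collapse = "\t"),
                 body), vcf_path)

    # ---- sample manifest ----
    manifest_path <- file.path(dir, "samples.tsv")
    utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    # ---- annotation ----
    bg_ann <- if (nbg > 0L) {
      a <- sentinel_annotation(variant_id(rep("chrS", nbg), 1000L * seq_len(nbg),
                                          bg_ref, bg_alt))
      a$chrom <- "chrS"; a$start <- 1000L * seq_len(nbg)
      a$ref <- bg_ref; a$alt <- bg_alt
      a$genes <- sprintf("BGGENE%04d", seq_len(nbg))
      a$region <- "intergenic"
      a$gnomad <- apply(maf, 1L, max)
      a
    }
    sp_ann <- if (length(spikes) > 0L) {
      a <- do.call(rbind, lapply(spikes, function(sp) {
        nv <- normalize_variant(sp$chrom, sp$pos, sp$ref, sp$alt)
        ann <- sentinel_annotation(nv$id)
        ann$chrom <- sp$chrom; ann$start <- sp$pos
        ann$ref <- sp$ref; ann$alt <- sp$alt
        ann$genes <- paste(sp$genes, collapse = ";")
        ann$region <- spike_region(sp$class)
        ann$exonic_func <- spike_exonic_func(sp)
        ann$esp6500 <- sp$esp6500; ann$kg1000 <- sp$kg1000
        ann$gnomad <- sp$gnomad
        ann
      }))
      a
    }
    ann <- rbind(bg_ann, sp_ann)
    ann_path <- file.path(dir, "annotation.tsv")
    write_annotation_tsv(ann, ann_path)

    # ---- gene model (host-gene introns over ncRNA-exonic spikes) ----
    gm_rows <- character(0)
    for (sp in spikes) {
      if (sp$class == "ncrna_exonic" && length(sp$host_genes) > 0L) {
        gm_rows <- c(gm_rows, paste(sp$chrom, max(sp$pos - 500L, 0L),
                                    sp$pos + 500L, sp$host_genes, 0, "+",
                                    "intron", sep = "\t"))
      }
    }
    gm_path <- file.path(dir, "gene_model.bed")
    writeLines(gm_rows, gm_path)

    # ---- ground truth ----
    thresholds <- filter_thresholds()
    truth <- do.call(rbind, lapply(spikes, function(sp) {
      nv <- normalize_variant(sp$chrom, sp$pos, sp$ref, sp$alt)
      freq_ok <- all(c(is.na(sp$esp6500) | sp$esp6500 < thresholds$max_population_maf,
                       is.na(sp$kg1000) | sp$kg1000 < thresholds$max_population_maf,
                       is.na(sp$gnomad) | sp$gnomad < thresholds$max_population_maf))
      row <- data.frame(id = nv$id, class = sp$class, stringsAsFactors = FALSE)
      total_cases <- 0L
      all_controls0 <- TRUE
      all_strata_hit <- TRUE
      for (j in seq_len(nrow(strata))) {
        s <- strata$label[j]
        cc <- sp$case_carriers[[s]] %||% 0L
        kk <- sp$control_carriers[[s]] %||% 0L
        total_cases <- total_cases + cc
        all_controls0 <- all_controls0 && kk == 0L
        all_strata_hit <- all_strata_hit && cc >= 1L
        cls <- if (cc >= thresholds$min_case_occurrences && freq_ok) {
          if (kk == 0L) "zero_in_control"
          else if (kk / strata$n_controls[j] < thresholds$max_control_frequency)
            "rare_recurrent" else "none"
        } else "none"
        row[[paste0("expected_class.", s)]] <- cls
      }
      row$expected_meta_eligible <- all_strata_hit && all_controls0 &&
        total_cases >= thresholds$min_case_occurrences && freq_ok
      row
    }))
    truth_path <- file.path(dir, "truth.tsv")
    if (is.null(truth)) {
      truth <- data.frame(id = character(0), class = character(0),
                          expected_meta_eligible = logical(0))
    }
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    list(paths = list(vcf = vcf_path, manifest = manifest_path,
                      annotation = ann_path, gene_model = gm_path,
                      truth = truth_path),
         truth = truth, maf = maf, config = config)
  })
}
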