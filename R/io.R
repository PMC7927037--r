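#' Read a sample manifest
#'
#' The manifest maps each sequenced individual to its ancestry stratum and
#' case/control status. Tab-separated with header columns `sample_id`,
#' `stratum`, `status` (`case` or `control`).
#'
#' @param path TSV file.
#' @return A data.frame of class `"sample_manifest"` with the three columns
#'   above and a `cohort` attribute holding the derived [cohort_spec()].
#' @export
read_sample_manifest <- function(path) {
  m <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", quote = "")
  if (nrow(m) == 0L) stop("sample manifest '", path, "' is empty", call. = FALSE)
  need <- c("sample_id", "stratum", "status")
  if (!all(need %in% names(m)))
    stop("sample manifest needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  m <- m[need]
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_id in manifest: ",
         paste(unique(m$sample_id[duplicated(m$sample_id)]), collapse = ", "),
         call. = FALSE)
  bad <- !m$status %in% c("case", "control")
  if (any(bad))
    stop("unknown status token(s): ", paste(unique(m$status[bad]), collapse = ", "),
         " (expected 'case' or 'control')", call. = FALSE)
  labs <- sort(unique(m$stratum))
  cohort <- cohort_spec(
    labs,
    vapply(labs, function(s) sum(m$stratum == s & m$status == "case"), integer(1)),
    vapply(labs, function(s) sum(m$stratum == s & m$status == "control"), integer(1)))
  structure(m, cohort = cohort, class = c("sample_manifest", "data.frame"))
}

#' Read a BED mask of low-confidence regions
#'
#' Standard BED: 0-based half-open intervals, first three columns
#' chrom / start / end. Variants whose reference span overlaps any interval
#' are dropped from the screen.
#'
#' @param path BED file.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_bed_mask <- function(path) {
  b <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                         comment.char = "#", colClasses = "character")
  if (ncol(b) < 3L) stop("BED mask needs at least 3 columns", call. = FALSE)
  out <- data.frame(chrom = b[[1L]], start = as.integer(b[[2L]]),
                    end = as.integer(b[[3L]]), stringsAsFactors = FALSE)
  if (any(is.na(out$start)) || any(is.na(out$end)) || any(out$end <= out$start))
    stop("malformed BED interval (need integer start < end)", call. = FALSE)
  out
}

# TRUE for spans [pos, pos + width - 1] (1-based) overlapping any 0-based
# half-open BED interval on the same chromosome
span_in_mask <- function(chrom, pos, width, mask) {
  hit <- logical(length(chrom))
  for (j in seq_len(nrow(mask))) {
    hit <- hit | (chrom == mask$chrom[j] &
                    pos <= mask$end[j] &
                    (pos + width - 1L) >= mask$start[j] + 1L)
  }
  hit
}

#' Tally case/control carriers per variant from a multi-sample VCF
#'
#' Reads genotypes for every manifest sample, splits multi-allelic records
#' into one variant per alternate allele, normalizes each to its minimal
#' anchored representation, and counts carriers per stratum. An individual
#' with at least one copy of the alternate allele counts once, regardless of
#' zygosity; genotypes containing `.` are excluded from the genotyped
#' denominator. Variants overlapping the optional low-confidence mask are
#' dropped.
#'
#' @param path VCF file (plain or gzip), with a `GT` field for all samples.
#' @param manifest a [read_sample_manifest()] result (or equivalent
#'   data.frame with `sample_id`, `stratum`, `status`).
#' @param mask optional [read_bed_mask()] data.frame.
#' @return A "carrier tally" data.frame: one row per normalized variant with
#'   columns `id`, `chrom`, `pos`, `ref`, `alt` and, per stratum `S`,
#'   `case_carriers.S`, `control_carriers.S`, `case_genotyped.S`,
#'   `control_genotyped.S`.
#' @export
read_cohort_vcf <- function(path, manifest, mask = NULL) {
  cohort <- attr(manifest, "cohort") %||% stop("manifest lacks cohort attribute")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  empty <- empty_tally(cohort)
  if (nrow(fix) == 0L) return(empty)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(vcf@gt)[-1L]))
  missing_samples <- setdiff(manifest$sample_id, colnames(gt))
  if (length(missing_samples) > 0L)
    stop("manifest sample(s) absent from VCF header: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  gt <- gt[, manifest$sample_id, drop = FALSE]
  gt[is.na(gt)] <- "."
  ok <- grepl("^[0-9.]+([/|][0-9.]+)*$", gt)
  if (!all(ok))
    stop("malformed GT value(s), e.g. '", gt[which(!ok)[1L]], "'", call. = FALSE)
  genotyped <- !grepl(".", gt, fixed = TRUE)
  dim(genotyped) <- dim(gt)

  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  keep_rec <- n_alt > 0L & fix[, "ALT"] != "." & fix[, "ALT"] != ""

  groups <- split(manifest$sample_id,
                  paste(manifest$stratum, manifest$status, sep = "."))
  col_of <- match(manifest$sample_id, colnames(gt))
  names(col_of) <- manifest$sample_id

  rows <- list()
  for (k in seq_len(max(n_alt, 0L))) {
    ri <- which(keep_rec & n_alt >= k)
    if (length(ri) == 0L) next
    pat <- paste0("(^|[/|])", k, "($|[/|])")
    carrier <- grepl(pat, gt[ri, , drop = FALSE])
    dim(carrier) <- c(length(ri), ncol(gt))
    nv <- normalize_variant(fix[ri, "CHROM"], as.integer(fix[ri, "POS"]),
                            fix[ri, "REF"],
                            vapply(alts[ri], `[`, character(1), k))
    tab <- nv
    for (s in cohort$label) {
      for (st in c("case", "control")) {
        ids <- groups[[paste(s, st, sep = ".")]] %||% character(0)
        cols <- col_of[ids]
        tab[[paste0(st, "_carriers.", s)]] <-
          as.integer(rowSums(carrier[, cols, drop = FALSE] &
                             genotyped[ri, cols, drop = FALSE]))
        tab[[paste0(st, "_genotyped.", s)]] <-
          as.integer(rowSums(genotyped[ri, cols, drop = FALSE]))
      }
    }
    rows[[k]] <- tab
  }
  if (length(rows) == 0L) return(empty)
  tally <- do.call(rbind, rows)

  if (!is.null(mask) && nrow(mask) > 0L) {
    tally <- tally[!span_in_mask(tally$chrom, tally$pos, nchar(tally$ref), mask), ,
                   drop = FALSE]
  }
  # merge records that normalize to the same variant
  if (anyDuplicated(tally$id)) {
    num <- setdiff(names(tally), c("id", "chrom", "pos", "ref", "alt"))
    agg <- stats::aggregate(tally[num], by = list(id = tally$id), FUN = sum)
    keyed <- tally[!duplicated(tally$id), c("id", "chrom", "pos", "ref", "alt")]
    tally <- merge(keyed, agg, by = "id", sort = FALSE)
  }
  rownames(tally) <- NULL
  attr(tally, "cohort") <- cohort
  tally
}

empty_tally <- function(cohort) {
  tab <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                    alt = character(0), id = character(0), stringsAsFactors = FALSE)
  for (s in cohort$label) {
    for (col in c("case_carriers", "control_carriers",
                  "case_genotyped", "control_genotyped"))
      tab[[paste0(col, ".", s)]] <- integer(0)
  }
  attr(tab, "cohort") <- cohort
  tab
}

# locate one column among case-insensitive alias patterns; NA if absent
find_col <- function(nms, patterns) {
  for (p in patterns) {
    hit <- grep(p, nms, ignore.case = TRUE)
    if (length(hit) > 0L) return(hit[1L])
  }
  NA_integer_
}

parse_freq <- function(x) {
  x[x %in% c(".", "", "NA")] <- NA
  suppressWarnings(as.numeric(x))
}

REGION_LEVELS <- c("exonic", "intronic", "UTR5", "UTR3", "upstream", "downstream",
                   "ncRNA_exonic", "ncRNA_intronic", "intergenic", "splicing")
EXONIC_FUNC_LEVELS <- c("stopgain", "frameshift_insertion", "frameshift_deletion",
                        "nonsynonymous", "synonymous", "nonframeshift", "none")
PREDICTOR_TOOLS <- c("SIFT", "Polyphen2", "LRT", "MutationTaster",
                     "MutationAssessor", "FATHMM", "RadialSVM")

canon_exonic_func <- function(x) {
  x <- trimws(x)
  x[x %in% c(".", "", "unknown", "NA")] <- "none"
  x <- sub("^nonsynonymous SNV$", "nonsynonymous", x)
  x <- sub("^synonymous SNV$", "synonymous", x)
  x <- gsub(" ", "_", x)
  x[grepl("^nonframeshift", x)] <- "nonframeshift"
  bad <- !x %in% EXONIC_FUNC_LEVELS
  if (any(bad))
    stop("unrecognized exonic function value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  x
}

#' Read an ANNOVAR-style variant annotation table
#'
#' Tab-separated, one row per variant, with columns `Chr`, `Start`, `Ref`,
#' `Alt` (ANNOVAR dash convention allowed for indels), a gene column, the
#' region class (`Func`), the exonic function (`ExonicFunc`), an optional
#' `avsnp147` dbSNP column, optional predictor-call columns (SIFT, Polyphen2,
#' LRT, MutationTaster, MutationAssessor, FATHMM, RadialSVM) and optional
#' population-frequency columns for esp6500 / 1000 Genomes / gnomAD, where
#' `.` means no entry in the database.
#'
#' Variant identity is converted to the same canonical ids produced by
#' [read_cohort_vcf()], so dash-coded indels and VCF anchored indels meet.
#'
#' @param path TSV file.
#' @return data.frame keyed by `id` with columns `chrom`, `start`, `ref`,
#'   `alt`, `genes` (`;`-joined), `region`, `exonic_func`, `dbsnp`, one
#'   column per predictor tool, `esp6500`, `kg1000`, `gnomad` (numeric, `NA`
#'   = absent from the database) and `host_genes` (filled by
#'   [map_ncrna_hosts()] when a gene model is supplied; `NA` otherwise).
#' @export
read_annotation_table <- function(path) {
  a <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", quote = "",
                         check.names = FALSE)
  nms <- names(a)
  ic <- function(...) find_col(nms, c(...))
  core <- c(chr = ic("^chr$", "^chrom"), start = ic("^start$", "^locus$", "^pos"),
            ref = ic("^ref"), alt = ic("^alt"))
  if (anyNA(core))
    stop("annotation table needs Chr/Start/Ref/Alt columns", call. = FALSE)
  gene_col <- ic("^gene", "gene.refgene")
  func_col <- ic("^func", "func.refgene")
  exf_col <- ic("^exonicfunc", "exonicfunc.refgene")
  if (is.na(gene_col) || is.na(func_col))
    stop("annotation table needs Gene and Func columns", call. = FALSE)

  region <- trimws(a[[func_col]])
  bad <- !region %in% REGION_LEVELS
  if (any(bad))
    stop("unrecognized region class(es): ",
         paste(unique(region[bad]), collapse = ", "), call. = FALSE)
  exf <- if (is.na(exf_col)) rep("none", nrow(a)) else canon_exonic_func(a[[exf_col]])

  out <- data.frame(
    id = annovar_id(a[[core["chr"]]], a[[core["start"]]],
                    a[[core["ref"]]], a[[core["alt"]]]),
    chrom = as.character(a[[core["chr"]]]),
    start = as.integer(a[[core["start"]]]),
    ref = toupper(a[[core["ref"]]]),
    alt = toupper(a[[core["alt"]]]),
    genes = vapply(strsplit(trimws(a[[gene_col]]), "[;,]"),
                   function(g) paste(trimws(g[nzchar(trimws(g))]), collapse = ";"),
                   character(1)),
    region = region,
    exonic_func = exf,
    stringsAsFactors = FALSE)
  if (any(!nzchar(out$genes)))
    stop("empty gene field in annotation table", call. = FALSE)

  snp_col <- ic("avsnp", "^dbsnp", "^rsid")
  out$dbsnp <- if (is.na(snp_col)) NA_character_ else {
    v <- trimws(a[[snp_col]]); v[v %in% c(".", "")] <- NA; v
  }
  for (tool in PREDICTOR_TOOLS) {
    tc <- find_col(nms, paste0("^", tool, "(_pred)?$"))
    out[[tool]] <- if (is.na(tc)) NA_character_ else {
      v <- trimws(a[[tc]]); v[v %in% c("", ".")] <- "."; v
    }
  }
  freq_cols <- c(esp6500 = ic("esp6500"), kg1000 = ic("1000g", "^kg1000", "1000Genome"),
                 gnomad = ic("gnomad"))
  for (f in names(freq_cols)) {
    out[[f]] <- if (is.na(freq_cols[[f]])) NA_real_ else parse_freq(a[[freq_cols[[f]]]])
    if (any(!is.na(out[[f]]) & (out[[f]] < 0 | out[[f]] > 1)))
      stop("population frequency outside [0,1] in column matching '", f, "'",
           call. = FALSE)
  }
  out$host_genes <- NA_character_
  if (anyDuplicated(out$id))
    out <- out[!duplicated(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gene-set GMT file
#'
#' Tab-separated: term, description, then member genes.
#'
#' @param path GMT file.
#' @return named list of character gene vectors; descriptions kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(which(short), collapse = ", "), call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[`, character(1), 2L), names(sets))
  sets
}

#' Read a coding-gene feature model (BED6 + feature class)
#'
#' Used to assign ncRNA-exonic loci to host coding genes. Tab-separated, no
#' header, columns: chrom, start, end (0-based half-open), gene, score,
#' strand, feature, where feature is one of `intron`, `UTR5`, `UTR3`,
#' `upstream`, `downstream`.
#'
#' @param path BED-like file.
#' @return data.frame with columns `chrom`, `start`, `end`, `gene`, `feature`.
#' @export
read_gene_model <- function(path) {
  g <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                         comment.char = "#", colClasses = "character")
  if (ncol(g) < 7L)
    stop("gene model needs 7 columns (BED6 + feature class)", call. = FALSE)
  out <- data.frame(chrom = g[[1L]], start = as.integer(g[[2L]]),
                    end = as.integer(g[[3L]]), gene = g[[4L]],
                    feature = g[[7L]], stringsAsFactors = FALSE)
  if (any(is.na(out$start)) || any(is.na(out$end)) || any(out$end <= out$start))
    stop("malformed gene model interval", call. = FALSE)
  bad <- !out$feature %in% c("intron", "UTR5", "UTR3", "upstream", "downstream")
  if (any(bad))
    stop("unknown gene model feature(s): ",
         paste(unique(out$feature[bad]), collapse = ", "), call. = FALSE)
  out
}

# numeric columns of the calls table, serialized at full precision
CALLS_NUM_RE <- "^(fisher_p\\.|chisq_p\\.|case_carriers\\.|control_carriers\\.|case_genotyped\\.|control_genotyped\\.|esp6500$|kg1000$|gnomad$|meta_p$|meta_X$)"

#' Write screen calls to a TSV file
#'
#' One row per (variant, gene) pair: gene lists on a call are exploded so the
#' file is directly groupable by gene. Missing values (absent frequencies,
#' absent meta p) are written as `.`; numeric fields are serialized at full
#' precision so that [read_calls_tsv()] round-trips exactly.
#'
#' @param calls a calls data.frame (see [select_variants()]).
#' @param path output file.
#' @return invisibly, the exploded data.frame that was written.
#' @export
write_calls_tsv <- function(calls, path) {
  if (nrow(calls) > 0L) {
    genes <- strsplit(calls$genes, ";", fixed = TRUE)
    idx <- rep(seq_len(nrow(calls)), lengths(genes))
    out <- calls[idx, , drop = FALSE]
    out$gene <- unlist(genes)
    out$genes <- NULL
    out <- out[c("gene", setdiff(names(out), "gene"))]
  } else {
    out <- cbind(data.frame(gene = character(0)), calls[setdiff(names(calls), "genes")])
  }
  ser <- out
  for (j in names(ser)) {
    v <- ser[[j]]
    ser[[j]] <- if (is.double(v)) ifelse(is.na(v), ".", sprintf("%.17g", v))
      else { v <- as.character(v); v[is.na(v)] <- "."; v }
  }
  utils::write.table(ser, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read back a calls TSV written by [write_calls_tsv()]
#' @param path TSV file.
#' @return data.frame with one row per (variant, gene) pair.
#' @export
read_calls_tsv <- function(path) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", quote = "", check.names = FALSE)
  for (j in names(x)) {
    v <- x[[j]]
    v[v == "."] <- NA
    if (grepl(CALLS_NUM_RE, j)) v <- as.numeric(v)
    if (j %in% c("pos", "start")) v <- as.integer(v)
    if (grepl("^(meta_eligible|meta_retained|adhd_associated)$", j)) v <- as.logical(v)
    x[[j]] <- v
  }
  x
}
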