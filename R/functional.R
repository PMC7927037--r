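#' Single-label functional class of a variant
#'
#' Collapses region and exonic-function annotation to the classes the screen
#' reports on: `stopgain`, `frameshift`, `nonsynonymous`, `ncrna_exonic`,
#' `intronic_indel`, `other`. An intronic variant is an intronic indel when
#' its allele lengths differ after normalization (a dash allele counts as
#' length 0, so both dash-coded and anchored indel representations qualify).
#' When a locus admits several readings the precedence is
#' stopgain > frameshift > nonsynonymous > ncrna_exonic > intronic_indel.
#'
#' @param region region class vector (see [read_annotation_table()]).
#' @param exonic_func exonic function vector.
#' @param ref,alt allele vectors (`-` allowed).
#' @return character vector of functional classes.
#' @export
functional_class <- function(region, exonic_func, ref, alt) {
  n <- max(length(region), length(exonic_func), length(ref), length(alt))
  region <- rep_len(region, n); exonic_func <- rep_len(exonic_func, n)
  ref <- rep_len(as.character(ref), n); alt <- rep_len(as.character(alt), n)
  alen <- function(x) ifelse(x == "-", 0L, nchar(x))
  indel <- alen(ref) != alen(alt)
  out <- rep("other", n)
  out[region == "intronic" & indel] <- "intronic_indel"
  out[region == "ncRNA_exonic"] <- "ncrna_exonic"
  out[exonic_func == "nonsynonymous"] <- "nonsynonymous"
  out[exonic_func %in% c("frameshift_insertion", "frameshift_deletion")] <- "frameshift"
  out[exonic_func == "stopgain"] <- "stopgain"
  out
}

FUNCTIONAL_CLASSES <- c("stopgain", "frameshift", "nonsynonymous",
                        "ncrna_exonic", "intronic_indel", "other")

# deleterious call letters per predictor tool (dbNSFP conventions):
# MutationTaster A = disease_causing_automatic; MutationAssessor H/M =
# high/medium impact
DELETERIOUS_CODES <- list(
  SIFT = "D", Polyphen2 = c("D", "P"), LRT = "D",
  MutationTaster = c("D", "A"), MutationAssessor = c("H", "M"),
  FATHMM = "D", RadialSVM = "D")

#' Consensus across impact-predictor calls
#'
#' Counts how many of the annotated predictor tools (SIFT, Polyphen2, LRT,
#' MutationTaster, MutationAssessor, FATHMM, RadialSVM) call the variant
#' deleterious, given their single-letter calls. `.` means no call. Tools
#' not in the code table are ignored with a warning.
#'
#' @param predictor_calls named character vector of single-letter calls, one
#'   per tool.
#' @param codes named list mapping each tool to its deleterious letters;
#'   override to add tools or change conventions.
#' @return list with `n_deleterious` and `deleterious_tools`.
#' @examples
#' predictor_consensus(c(SIFT = "D", Polyphen2 = "D", LRT = "N",
#'                       MutationTaster = "D", MutationAssessor = "L",
#'                       FATHMM = "T", RadialSVM = "T"))
#' @export
predictor_consensus <- function(predictor_calls, codes = DELETERIOUS_CODES) {
  predictor_calls <- unlist(predictor_calls)
  unknown <- setdiff(names(predictor_calls), names(codes))
  if (length(unknown) > 0L) {
    warning("ignoring unknown predictor tool(s): ",
            paste(unknown, collapse = ", "))
    predictor_calls <- predictor_calls[setdiff(names(predictor_calls), unknown)]
  }
  del <- vapply(names(predictor_calls), function(tool) {
    v <- predictor_calls[[tool]]
    !is.na(v) && v %in% codes[[tool]]
  }, logical(1))
  list(n_deleterious = sum(del),
       deleterious_tools = names(predictor_calls)[del])
}

#' Host coding genes of an ncRNA-exonic locus
#'
#' Pathway databases carry coding genes, not ncRNAs. A locus lying in the
#' exon of a noncoding RNA is therefore attributed to every coding gene whose
#' intron, UTR or up/downstream flank (1 kb by default in the supplied model)
#' covers the variant's reference span.
#'
#' @param chrom,pos,ref variant coordinates: 1-based position and reference
#'   allele (`-` for a pure insertion, whose span is the anchor base).
#' @param gene_model data.frame from [read_gene_model()] (0-based half-open
#'   intervals).
#' @return sorted character vector of host gene symbols (possibly empty).
#' @export
map_ncrna_hosts <- function(chrom, pos, ref, gene_model) {
  width <- if (identical(ref, "-")) 1L else nchar(ref)
  gm <- gene_model[gene_model$chrom == chrom, , drop = FALSE]
  hit <- pos <= gm$end & (pos + width - 1L) >= gm$start + 1L
  sort(unique(gm$gene[hit]))
}

#' Attach host genes to ncRNA-exonic calls or annotations
#'
#' Fills the `host_genes` column (`;`-joined) for rows with region
#' `ncRNA_exonic`, using [map_ncrna_hosts()].
#'
#' @param annotations annotation (or calls) data.frame with `chrom`, a
#'   position column (`start` or `pos`), `ref` and `region`.
#' @param gene_model data.frame from [read_gene_model()].
#' @return the input with `host_genes` filled.
#' @export
annotate_ncrna_hosts <- function(annotations, gene_model) {
  poscol <- if ("start" %in% names(annotations)) "start" else "pos"
  for (i in which(annotations$region == "ncRNA_exonic")) {
    hosts <- map_ncrna_hosts(annotations$chrom[i], annotations[[poscol]][i],
                             annotations$ref[i], gene_model)
    annotations$host_genes[i] <-
      if (length(hosts) > 0L) paste(hosts, collapse = ";") else NA_character_
  }
  annotations
}
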