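# Published summary tables re-encoded as screen fixtures. Each fixture pairs
# an annotation table with per-stratum carrier counts (carrier level only --
# the underlying genotypes are controlled-access), so the filtering and meta
# stages can be exercised on the exact published patterns.

.fixture_stopgain <- "
stratum\tdbsnp\tchrom\tstart\tref\talt\tocc\tgene\tesp6500\tkg1000\tgnomad
AA\trs369719214\t19\t33183093\tG\tA\t2\tNUDT19\t6.0e-4\t6.0e-4\t6.0e-4
AA\trs116059545\t3\t142537266\tG\tA\t2\tPCOLCE2\t2.0e-4\t2.0e-4\t2.0e-4
AA\trs146817618\t11\t6942649\tT\tA\t2\tOR2D3\t2.0e-4\t.\t3.0e-4
AA\trs34789740\t12\t11091287\tG\tA\t2\tTAS2R14\t1.4e-3\t4.0e-4\t8.0e-4
AA\trs375920305\t19\t36259319\tC\tT\t4\tPROSER3\t7.0e-4\t8.0e-4\t3.0e-4
AA\t.\t19\t52888074\t-\tATCATGAGGTCAGGAGATCGAGACCATCCTGGCTAACAAGGTGAAACC\t2\tZNF880\t.\t.\t1.8e-3
AA\trs150768729\t4\t2073958\tC\tT\t2\tPOLN\t2.0e-4\t.\t3.3e-5
AA\trs370330395\t19\t52887191\tC\tT\t3\tZNF880\t1.3e-3\t6.0e-4\t1.2e-3
AA\trs148053441\t14\t74361075\tG\tA\t2\tZNF410\t.\t4.0e-4\t1.0e-3
AA\trs181032032\t19\t12126454\tG\tA\t2\tZNF433\t5.0e-4\t4.0e-4\t7.0e-4
AA\trs147487823\t8\t29202959\tG\tA\t2\tDUSP4\t.\t2.0e-4\t3.2e-5
AA\trs138842904\t16\t74486025\tG\tA\t2\tGLG1\t9.0e-4\t4.0e-4\t8.0e-4
EA\trs147869298\t4\t140625183\tC\tT\t2\tMGST2\t1.5e-3\t6.0e-4\t5.0e-4
EA\t.\t9\t104239264\t-\tATTAAAAA\t2\tTMEM246\t.\t.\t7.0e-5
EA\trs145322761\t14\t96730863\tC\tT\t2\tBDKRB1\t2.8e-3\t1.4e-3\t2.0e-3
EA\trs138652787\t7\t23871861\tC\tG\t2\tSTK31\t1.8e-3\t6.0e-4\t1.6e-3
EA\t.\t2\t11925167\t-\tATA\t3\tLPIN1\t.\t.\t0
EA\trs142358325\t9\t140139138\tG\tA\t2\tFAM166A\t5.0e-4\t4.0e-4\t3.0e-4
EA\t.\t13\t32731436\tC\tT\t2\tFRY\t.\t.\t.
EA\trs370788593\t10\t82348410\tC\tT\t2\tSH2D4B\t7.7e-5\t.\t3.2e-5
EA\trs371526758\t1\t10042426\tG\tA\t2\tNMNAT1\t2.0e-4\t.\t6.5e-5
"

.fixture_neuro_indels <- "
adhd\tgene\tchrom\tstart\tref\talt\tdbsnp\tocc_aa\tocc_ea\tprinted_meta_p
Y\tMAGI2\t7\t77687294\t-\tTATA\t.\t4\t1\t0.008
N\tZMYND8\t20\t45929674\t-\tTGTGTGTA\t.\t4\t1\t0.008
N\tERBB4\t2\t212606179\t-\tACACACAC\t.\t4\t1\t0.008
N\tSOX6\t11\t16031671\t-\tACACACAC\t.\t4\t1\t0.008
N\tALCAM\t3\t105241984\t-\tAA\t.\t3\t2\t0.009
N\tBRINP3\t1\t190425195\tA\t-\t.\t1\t4\t0.015
Y\tNRXN3\t14\t78954086\tATAAATAAATAAATAA\t-\t.\t2\t3\t0.012
N\tCOL25A1\t4\t110139513\t-\tT\trs34056401\t2\t3\t0.012
N\tCBFA2T2\t20\t32229919\tTTTTTGTGTGTGTG\t-\t.\t2\t3\t0.012
Y\tDCDC2\t6\t24280004\tT\t-\trs563616388\t1\t4\t0.015
Y\tDCDC2\t6\t24256576\tTA\t-\trs556522905\t1\t4\t0.015
Y\tNRXN1\t2\t50393425\t-\tTG\t.\t1\t4\t0.015
Y\tNRXN3\t14\t78937634\t-\tAC\t.\t3\t1\t0.038
Y\tCTNNA2\t2\t80029140\tT\t-\t.\t3\t1\t0.038
N\tRORA\t15\t61494733\tT\t-\t.\t3\t1\t0.038
N\tARHGEF2\t1\t155941370\t-\tAAAAAAAAAAA\t.\t3\t1\t0.038
N\tBICDL1\t12\t120451243\t-\tGTGTGTGTGTGTGT\t.\t3\t1\t0.038
N\tPARD3\t10\t34408932\t-\tTTTTTTTTTTT\t.\t3\t1\t0.038
N\tCNTN6\t3\t1136572\tAT\t-\trs367911099\t3\t1\t0.038
N\tDAB1\t1\t58589583\tAC\t-\t.\t3\t1\t0.038
N\tCOL25A1\t4\t109743199\t-\tTTTTTTTT\t.\t3\t1\t0.038
N\tANKS1A\t6\t34891869\t-\tGTGT\t.\t3\t1\t0.038
N\tPTPRD\t9\t9632617\tA\t-\t.\t3\t1\t0.038
N\tNPTN\t15\t73897440\t-\tGG\t.\t3\t1\t0.038
N\tSLC4A7\t3\t27480018\t-\tAAAAT\trs141000029\t3\t1\t0.038
N\tLAMB1\t7\t107575792\t-\tTTTTTTTTTTTTTT\t.\t3\t1\t0.038
N\tDAB1\t1\t58222892\t-\tTTTTTTTTTTTTTTTTTTTTTTTTTG\t.\t3\t1\t0.038
N\tRORA\t15\t61494730\t-\tG\t.\t3\t1\t0.038
N\tGNAQ\t9\t80366732\tAAAA\t-\t.\t3\t1\t0.038
N\tMTOR\t1\t11178676\t-\tT\t.\t3\t1\t0.038
N\tDAB1\t1\t58616263\tAA\t-\t.\t3\t1\t0.038
N\tLRP6\t12\t12392929\t-\tA\t.\t3\t1\t0.038
N\tNCAM2\t21\t22444188\t-\tTATCTAT\t.\t3\t1\t0.038
N\tSPTBN4\t19\t41005988\t-\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAAGAAAAATCTTTGCTGAGCATGGTGGTACAC\t.\t3\t1\t0.038
N\tRAB10\t2\t26331748\t-\tTATT\t.\t3\t1\t0.038
Y\tCLASP2\t3\t33577416\tA\t-\t.\t3\t1\t0.038
Y\tLINGO2\t9\t28664998\t-\tATATATAT\t.\t2\t2\t0.046
Y\tPRKG1\t10\t52873716\t-\tGT\t.\t2\t2\t0.046
N\tTENM2\t5\t166755213\t-\tT\t.\t2\t2\t0.046
N\tDNER\t2\t230419651\tGAGAGAAAAGGGAAGGG\t-\t.\t2\t2\t0.046
N\tEXT1\t8\t119053913\tGAAG\t-\t.\t2\t2\t0.046
N\tPTPRD\t9\t8632122\tTG\t-\trs755867249\t2\t2\t0.046
N\tABL2\t1\t179169177\tT\t-\t.\t2\t2\t0.046
N\tNOTCH3\t19\t15280017\t-\tTCTCTCTC\t.\t2\t2\t0.046
Y\tNRXN1\t2\t50932188\tACAC\t-\t.\t2\t2\t0.046
N\tUST\t6\t149379481\tATGTGTGTGT\t-\t.\t2\t2\t0.046
N\tGCM1\t6\t53006798\t-\tGAAA\t.\t2\t2\t0.046
"

.fixture_mglur <- "
gene\tchrom\tstart\tref\talt\tocc_aa\tocc_ea\tprinted_meta_p\tesp6500\tkg1000\tgnomad
GRM7\t3\t7515182\t-\tGAGAGAGAGA\t2\t3\t0.012\t.\t.\t.
DLGAP1\t18\t4330027\tAT\t-\t3\t1\t0.038\t.\t.\t0.0008
GNG2\t14\t52368681\t-\tA\t3\t1\t0.038\t.\t.\t.
GRIK2\t6\t102004196\t-\tTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTT\t3\t1\t0.038\t.\t.\t.
PRKACB\t1\t84664799\t-\tATAT\t3\t1\t0.038\t.\t.\t0.0038
GNAQ\t9\t80366732\tAAAA\t-\t3\t1\t0.038\t.\t.\t0.0006
PRKCG\t19\t54406144\t-\tAAAAAAAAAAAAAAAA\t3\t1\t0.038\t.\t.\t0.0022
"

read_fixture_text <- function(txt) {
  utils::read.delim(text = txt, header = TRUE, sep = "\t",
                    colClasses = "character", quote = "")
}

fixture_annotation <- function(chrom, start, ref, alt, genes, region,
                               exonic_func, dbsnp, esp, kg, gnomad) {
  ann <- sentinel_annotation(annovar_id(chrom, start, ref, alt))
  ann$chrom <- chrom
  ann$start <- as.integer(start)
  ann$ref <- toupper(ref)
  ann$alt <- toupper(alt)
  ann$genes <- genes
  ann$region <- region
  ann$exonic_func <- exonic_func
  ann$dbsnp <- ifelse(dbsnp == ".", NA_character_, dbsnp)
  ann$esp6500 <- parse_freq(esp)
  ann$kg1000 <- parse_freq(kg)
  ann$gnomad <- parse_freq(gnomad)
  ann[c("id", "chrom", "start", "ref", "alt",
        setdiff(names(ann), c("id", "chrom", "start", "ref", "alt")))]
}

#' Bundled fixtures from the published summary tables
#'
#' Three carrier-level fixtures re-encoding the published variant lists:
#' \describe{
#'   \item{`stopgain`}{the 21 novel stop-gain recurrent variants (12 in the
#'     AA stratum, 9 in EA) with their case occurrence counts and esp6500 /
#'     1000 Genomes / gnomAD frequencies (`.` = absent).}
#'   \item{`neuro_indels`}{the 47 zero-in-control intronic indels in
#'     neurodevelopmental genes entering the two-ethnicity meta screen, with
#'     per-stratum occurrence counts and the printed meta p-values.}
#'   \item{`mglur`}{the 7 intronic indels in metabotropic glutamate receptor
#'     pathway genes.}
#' }
#' Control carriers are zero throughout (the lists are zero-in-control).
#' Each fixture carries an `annotation` table (the format of
#' [read_annotation_table()]) and a `counts` table usable with
#' [tally_from_counts()]; `neuro_indels` and `mglur` additionally keep the
#' printed meta p-value for comparison.
#'
#' @param dir optional directory: write each fixture as a pair of TSV files
#'   (`<name>_annotation.tsv` in the ANNOVAR dialect, `<name>_counts.tsv`).
#' @return named list of fixtures (invisibly when `dir` is given).
#' @export
table_fixtures <- function(dir = NULL) {
  t1 <- read_fixture_text(.fixture_stopgain)
  fixA <- list(
    annotation = fixture_annotation(t1$chrom, t1$start, t1$ref, t1$alt,
                                    t1$gene, "exonic", "stopgain", t1$dbsnp,
                                    t1$esp6500, t1$kg1000, t1$gnomad),
    counts = data.frame(
      id = annovar_id(t1$chrom, t1$start, t1$ref, t1$alt),
      case_carriers.AA = ifelse(t1$stratum == "AA", as.integer(t1$occ), 0L),
      control_carriers.AA = 0L,
      case_carriers.EA = ifelse(t1$stratum == "EA", as.integer(t1$occ), 0L),
      control_carriers.EA = 0L,
      stringsAsFactors = FALSE),
    stratum = t1$stratum)

  t4 <- read_fixture_text(.fixture_neuro_indels)
  fixB <- list(
    annotation = fixture_annotation(t4$chrom, t4$start, t4$ref, t4$alt,
                                    t4$gene, "intronic", "none", t4$dbsnp,
                                    ".", ".", "."),
    counts = data.frame(
      id = annovar_id(t4$chrom, t4$start, t4$ref, t4$alt),
      case_carriers.AA = as.integer(t4$occ_aa), control_carriers.AA = 0L,
      case_carriers.EA = as.integer(t4$occ_ea), control_carriers.EA = 0L,
      stringsAsFactors = FALSE),
    printed_meta_p = as.numeric(t4$printed_meta_p),
    adhd_associated = t4$adhd == "Y")

  t5 <- read_fixture_text(.fixture_mglur)
  fixC <- list(
    annotation = fixture_annotation(t5$chrom, t5$start, t5$ref, t5$alt,
                                    t5$gene, "intronic", "none", ".",
                                    t5$esp6500, t5$kg1000, t5$gnomad),
    counts = data.frame(
      id = annovar_id(t5$chrom, t5$start, t5$ref, t5$alt),
      case_carriers.AA = as.integer(t5$occ_aa), control_carriers.AA = 0L,
      case_carriers.EA = as.integer(t5$occ_ea), control_carriers.EA = 0L,
      stringsAsFactors = FALSE),
    printed_meta_p = as.numeric(t5$printed_meta_p))

  fixtures <- list(stopgain = fixA, neuro_indels = fixB, mglur = fixC)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(fixtures)) {
      write_annotation_tsv(fixtures[[nm]]$annotation,
                           file.path(dir, paste0(nm, "_annotation.tsv")))
      utils::write.table(fixtures[[nm]]$counts,
                         file.path(dir, paste0(nm, "_counts.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(invisible(fixtures))
  }
  fixtures
}

# serialize an annotation data.frame back to the ANNOVAR-style TSV dialect
write_annotation_tsv <- function(ann, path) {
  dot <- function(x) { x <- as.character(x); x[is.na(x)] <- "."; x }
  out <- data.frame(Chr = ann$chrom, Start = ann$start, End = ann$start,
                    Ref = ann$ref, Alt = ann$alt,
                    `Func.refGene` = ann$region, `Gene.refGene` = ann$genes,
                    `ExonicFunc.refGene` = ifelse(ann$exonic_func == "none", ".",
                                                  ann$exonic_func),
                    avsnp147 = dot(ann$dbsnp), check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (tool in PREDICTOR_TOOLS) out[[paste0(tool, "_pred")]] <- dot(ann[[tool]])
  out$esp6500siv2_all <- dot(ann$esp6500)
  out$`1000g2015aug_all` <- dot(ann$kg1000)
  out$gnomAD_genome_ALL <- dot(ann$gnomad)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
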