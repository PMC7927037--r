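small_strata <- function() cohort_spec(c("AA", "EA"), c(10L, 8L), c(30L, 20L))

test_that("identical seeds give byte-identical cohorts; seeds differ otherwise", {
  cfg <- sim_config(strata = small_strata(), n_background_variants = 50L,
                    seed = 123,
                    spikes = list(spike_spec("1", 500, "A", "AT",
                                             c(AA = 2L, EA = 1L))))
  g1 <- generate_cohort(cfg, tempfile())
  g2 <- generate_cohort(cfg, tempfile())
  for (f in names(g1$paths))
    expect_identical(readLines(g1$paths[[f]]), readLines(g2$paths[[f]]),
                     label = f)
  g3 <- generate_cohort(sim_config(strata = small_strata(),
                                   n_background_variants = 50L, seed = 124),
                        tempfile())
  expect_false(identical(readLines(g1$paths$vcf), readLines(g3$paths$vcf)))
})

test_that("spiked carrier counts are forced exactly and recovered", {
  cfg <- sim_config(strata = small_strata(), n_background_variants = 20L,
                    seed = 7, spikes = list(
    spike_spec("2", 999, "G", "GA", c(AA = 3L, EA = 2L), class = "frameshift",
               genes = "FSGENE"),
    spike_spec("3", 42, "C", "T", c(AA = 2L, EA = 0L),
               control_carriers = c(AA = 1L, EA = 0L),
               class = "nonsynonymous", genes = "NSGENE")))
  g <- generate_cohort(cfg, tempfile())
  manifest <- read_sample_manifest(g$paths$manifest)
  tal <- read_cohort_vcf(g$paths$vcf, manifest)
  sp1 <- tal[tal$id == "2:999:-:A", ]
  expect_equal(sp1$case_carriers.AA, 3L)
  expect_equal(sp1$case_carriers.EA, 2L)
  expect_equal(sp1$control_carriers.AA + sp1$control_carriers.EA, 0L)
  sp2 <- tal[tal$id == "3:42:C:T", ]
  expect_equal(sp2$case_carriers.AA, 2L)
  expect_equal(sp2$control_carriers.AA, 1L)
})

test_that("homozygous spikes leave carrier counts unchanged", {
  mk <- function(hom) {
    cfg <- sim_config(strata = small_strata(), n_background_variants = 0L,
                      seed = 5, spikes = list(
      spike_spec("2", 999, "G", "A", c(AA = 3L, EA = 2L),
                 class = "nonsynonymous", homozygous = hom)))
    g <- generate_cohort(cfg, tempfile())
    tal <- read_cohort_vcf(g$paths$vcf, read_sample_manifest(g$paths$manifest))
    tal[c("case_carriers.AA", "case_carriers.EA")]
  }
  expect_equal(mk(FALSE), mk(TRUE), ignore_attr = TRUE)
})

test_that("an empty configuration still yields a valid cohort VCF", {
  cfg <- sim_config(strata = small_strata(), n_background_variants = 0L,
                    seed = 1)
  g <- generate_cohort(cfg, tempfile())
  manifest <- read_sample_manifest(g$paths$manifest)
  expect_equal(nrow(manifest), 68L)
  tal <- read_cohort_vcf(g$paths$vcf, manifest)
  expect_equal(nrow(tal), 0L)
  expect_equal(nrow(g$truth), 0L)
})

test_that("spikes exceeding the stratum size are rejected", {
  expect_error(sim_config(strata = small_strata(), seed = 1, spikes = list(
    spike_spec("1", 10, "A", "T", c(AA = 11L)))), "exceeds stratum size")
  expect_error(sim_config(strata = small_strata(), seed = 1, spikes = list(
    spike_spec("1", 10, "A", "T", c(ZZ = 1L)))), "unknown stratum")
  expect_error(sim_config(strata = small_strata(), n_background_variants = 10),
               "seed")
})

test_that("background sites follow Hardy-Weinberg at their sampled MAFs", {
  strata <- cohort_spec(c("AA", "EA"), c(116L, 89L), c(408L, 262L))
  cfg <- sim_config(strata = strata, n_background_variants = 300L, seed = 202)
  g <- generate_cohort(cfg, tempfile())
  manifest <- read_sample_manifest(g$paths$manifest)
  vcf <- vcfR::read.vcfR(g$paths$vcf, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dosage <- matrix(match(gt, c("0/0", "0/1", "1/1")) - 1L, nrow(gt), ncol(gt))
  for (s in c("AA", "EA")) {
    cols <- which(manifest$stratum == s)
    n_chrom <- 2L * length(cols)
    emp <- rowSums(dosage[, cols]) / n_chrom
    # stratum-level MAF: mean over sites, within 3 SE of the sampled means
    se_mean <- sqrt(sum(g$maf[, s] * (1 - g$maf[, s]) / n_chrom)) /
      nrow(g$maf)
    expect_lte(abs(mean(emp) - mean(g$maf[, s])), 3 * se_mean)
    # and nearly every individual site within its own 3 SE band
    se <- sqrt(g$maf[, s] * (1 - g$maf[, s]) / n_chrom)
    expect_gte(mean(abs(emp - g$maf[, s]) <= 3 * se), 0.98)
  }
})

test_that("truth manifest matches an independent reading of the filter rules", {
  th <- filter_thresholds()
  cfg <- sim_config(strata = small_strata(), n_background_variants = 0L,
                    seed = 9, spikes = list(
    spike_spec("1", 100, "A", "T", c(AA = 2L, EA = 0L), class = "stopgain"),
    spike_spec("1", 200, "A", "T", c(AA = 1L, EA = 1L)),
    spike_spec("1", 300, "A", "T", c(AA = 3L, EA = 1L), gnomad = 0.02),
    spike_spec("1", 400, "A", "T", c(AA = 2L, EA = 2L),
               control_carriers = c(AA = 1L, EA = 0L))))
  g <- generate_cohort(cfg, tempfile())
  tr <- g$truth
  want_aa <- mapply(classify_oracle, c(2, 1, 3, 2), c(0, 0, 0, 1), 30,
                    NA, NA, c(NA, NA, 0.02, NA), MoreArgs = list(th = th))
  want_ea <- mapply(classify_oracle, c(0, 1, 1, 2), c(0, 0, 0, 0), 20,
                    NA, NA, c(NA, NA, 0.02, NA), MoreArgs = list(th = th))
  expect_equal(tr$expected_class.AA, unname(want_aa))
  expect_equal(tr$expected_class.EA, unname(want_ea))
  expect_equal(tr$expected_meta_eligible, c(FALSE, TRUE, FALSE, FALSE))
})
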