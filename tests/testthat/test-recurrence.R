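test_that("recurrence classification follows the filtering rules", {
  th <- filter_thresholds()
  # two case carriers, zero controls, all database freqs ~6e-4
  expect_equal(classify_recurrence(2, 0, 408, 6e-4, 6e-4, 6e-4, th),
               "zero_in_control")
  # a singleton is below the recurrence threshold
  expect_equal(classify_recurrence(1, 0, 408, th = th), "none")
  # 5/408 = 1.23% control carrier frequency fails the <1% rule
  expect_true(5 / 408 > 0.01)
  expect_equal(classify_recurrence(3, 5, 408, th = th), "none")
  # 4/408 = 0.98% passes, but controls > 0 so not zero-in-control
  expect_equal(classify_recurrence(3, 4, 408, th = th), "rare_recurrent")
  # a present database frequency at/above 1% disqualifies (strict <)
  expect_equal(classify_recurrence(3, 0, 408, esp6500 = 0.01, th = th), "none")
  expect_equal(classify_recurrence(3, 0, 408, esp6500 = 0.0099, th = th),
               "zero_in_control")
  # absent frequencies pass
  expect_equal(classify_recurrence(2, 0, 408, NA, NA, NA, th), "zero_in_control")
})

test_that("classification agrees with the rule-by-rule oracle on random cohorts", {
  set.seed(301)
  th <- filter_thresholds()
  for (rep in 1:300) {
    n_controls <- sample(5:20, 1)
    cc <- sample(0:5, 1)
    kk <- sample(0:n_controls, 1)
    freqs <- ifelse(runif(3) < 0.3, NA, runif(3, 0, 0.03))
    got <- classify_recurrence(cc, kk, n_controls, freqs[1], freqs[2],
                               freqs[3], th)
    want <- classify_oracle(cc, kk, n_controls, freqs[1], freqs[2], freqs[3], th)
    expect_identical(got, want)
  }
})

test_that("selection is monotone in the thresholds", {
  set.seed(77)
  fx <- table_fixtures()
  ann <- fx$stopgain$annotation
  counts <- fx$stopgain$counts
  counts$control_carriers.AA <- sample(0:3, nrow(counts), replace = TRUE)
  cohort <- default_cohort()
  sel_ids <- function(th) {
    tal <- tally_from_counts(ann, counts, cohort)
    sort(select_variants(tal, ann, th, cohort)$id)
  }
  base <- sel_ids(filter_thresholds())
  stricter_occ <- sel_ids(filter_thresholds(min_case_occurrences = 3))
  stricter_maf <- sel_ids(filter_thresholds(max_population_maf = 5e-4))
  expect_true(all(stricter_occ %in% base))
  expect_true(all(stricter_maf %in% base))
})

test_that("zero-in-control calls are a subset of rare-recurrent calls", {
  set.seed(78)
  th <- filter_thresholds()
  cc <- sample(0:6, 200, replace = TRUE)
  kk <- sample(0:8, 200, replace = TRUE)
  gn <- ifelse(runif(200) < .5, NA, runif(200, 0, 0.02))
  cls <- classify_recurrence(cc, kk, 408, gnomad = gn, thresholds = th)
  zic <- which(cls == "zero_in_control")
  # reclassify with controls forced nonzero-frequency semantics: every
  # zero-in-control variant also satisfies the rare-recurrent conditions
  rr_ok <- cc >= th$min_case_occurrences &
    kk / 408 < th$max_control_frequency &
    (is.na(gn) | gn < th$max_population_maf)
  expect_true(all(rr_ok[zic]))
})

test_that("meta eligibility needs every stratum hit and zero controls overall", {
  fx <- table_fixtures()
  ann <- fx$neuro_indels$annotation[1:4, ]
  cohort <- default_cohort()
  counts <- data.frame(id = ann$id,
                       case_carriers.AA = c(3L, 1L, 1L, 2L),
                       control_carriers.AA = c(0L, 0L, 0L, 1L),
                       case_carriers.EA = c(1L, 4L, 0L, 2L),
                       control_carriers.EA = 0L)
  tal <- tally_from_counts(ann, counts, cohort)
  calls <- select_variants(tal, ann, filter_thresholds(), cohort)
  elig <- calls$meta_eligible[match(ann$id, calls$id)]
  # (3,1) and (1,4): eligible even where one stratum is below per-stratum
  # recurrence; (1,0): EA unseen; (2,2) with a control carrier: out
  expect_equal(elig[1:2], c(TRUE, TRUE))
  expect_false(isTRUE(elig[3]))
  expect_false(isTRUE(elig[4]))
})

test_that("selected variants carry a sentinel when annotation is missing", {
  fx <- table_fixtures()
  ann <- fx$stopgain$annotation
  counts <- fx$stopgain$counts
  tal <- tally_from_counts(ann, counts, default_cohort())
  expect_message(
    calls <- select_variants(tal, ann[-1, ], filter_thresholds()),
    "lack annotation")
  row <- calls[calls$id == ann$id[1], ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$genes, ".")
})

test_that("variant accounting covers every input variant exactly once per stratum", {
  fx <- table_fixtures()
  tal <- tally_from_counts(fx$stopgain$annotation, fx$stopgain$counts,
                           default_cohort())
  calls <- select_variants(tal, fx$stopgain$annotation)
  acct <- attr(calls, "accounting")
  expect_equal(colSums(acct), c(AA = 21, EA = 21))
})

test_that("gene rollup spreads calls over all genes and ncRNA hosts", {
  fx <- table_fixtures()
  sc <- counts_screen(fx$neuro_indels$annotation, fx$neuro_indels$counts)
  roll <- gene_rollup(sc$calls)
  expect_length(roll, 39L)
  expect_length(roll$DAB1, 3L)  # three distinct loci hit DAB1
  # per-stratum restriction
  roll_ea <- gene_rollup(sc$calls, stratum = "EA")
  cl <- sc$calls$class.EA
  expect_length(roll_ea, length(unique(unlist(
    strsplit(sc$calls$genes[cl != "none"], ";")))))
  expect_error(gene_rollup(sc$calls, stratum = "XX"), "no such stratum")

  # host genes fan a single ncRNA-exonic call out to many coding genes
  calls <- sc$calls[1, , drop = FALSE]
  calls$genes <- "HGB8P"
  calls$region <- "ncRNA_exonic"
  calls$host_genes <- paste(paste0("PCDHA", 1:18), collapse = ";")
  expect_length(gene_rollup(calls), 19L)
  expect_length(gene_rollup(sc$calls[0, , drop = FALSE]), 0L)
})
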