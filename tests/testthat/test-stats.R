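test_that("exact test matches enumeration and the stats package on examples", {
  expect_equal(fisher_exact_2x2(2, 114, 0, 408), 0.048677, tolerance = 1e-4)
  expect_equal(fisher_exact_2x2(4, 201, 0, 670), 0.002946, tolerance = 1e-3)
  expect_equal(fisher_exact_2x2(0, 116, 0, 408), 1.0)
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1.0)
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
  # independent routes: binomial-coefficient enumeration and fisher.test
  set.seed(99)
  for (i in 1:60) {
    cells <- as.integer(rmultinom(1, sample(4:60, 1), rep(1 / 4, 4)))
    p_impl <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    p_enum <- fisher_enum_oracle(cells[1], cells[2], cells[3], cells[4])
    p_ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(p_impl, p_enum, tolerance = 1e-12)
    expect_equal(p_impl, p_ref, tolerance = 1e-7)
  }
})

test_that("continuity-corrected chi-square matches formula and chisq.test", {
  r <- chisq_yates_2x2(3, 113, 0, 408)
  expect_equal(r[["statistic"]], 6.5555, tolerance = 1e-4)
  expect_equal(r[["p"]], 0.010456, tolerance = 1e-4)
  r2 <- chisq_yates_2x2(2, 87, 0, 262)
  expect_equal(r2[["statistic"]], 2.6192, tolerance = 1e-4)
  expect_equal(r2[["p"]], 0.105579, tolerance = 1e-4)
  expect_equal(chisq_yates_2x2(0, 116, 0, 408), c(statistic = 0, p = 1))
  expect_error(chisq_yates_2x2(1, -1, 0, 2), "non-negative")
  set.seed(13)
  for (i in 1:40) {
    cells <- as.integer(rmultinom(1, sample(20:200, 1), runif(4, .05, 1)))
    if (any(rowSums(matrix(cells, 2, byrow = TRUE)) == 0) ||
        any(colSums(matrix(cells, 2, byrow = TRUE)) == 0)) next
    got <- chisq_yates_2x2(cells[1], cells[2], cells[3], cells[4])
    ref <- suppressWarnings(
      stats::chisq.test(matrix(cells, 2, byrow = TRUE), correct = TRUE))
    expect_equal(got[["statistic"]], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got[["p"]], ref$p.value, tolerance = 1e-10)
  }
})

test_that("Yates statistic never exceeds Pearson and is transpose-invariant", {
  set.seed(21)
  for (i in 1:500) {
    x <- sample(0:30, 4, replace = TRUE)
    m <- matrix(x, 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next  # no information
    y <- chisq_yates_2x2(x[1], x[2], x[3], x[4])[["statistic"]]
    expect_lte(y, pearson_stat(x[1], x[2], x[3], x[4]) + 1e-12)
    # swapping rows with columns (transpose) leaves both tests unchanged
    yt <- chisq_yates_2x2(x[1], x[3], x[2], x[4])[["statistic"]]
    expect_equal(y, yt)
    ft <- fisher_exact_2x2(x[1], x[3], x[2], x[4])
    expect_equal(fisher_exact_2x2(x[1], x[2], x[3], x[4]), ft,
                 tolerance = 1e-12)
  }
})

test_that("Fisher's combined probability method behaves as advertised", {
  # the two-stratum chain behind the published meta p-values
  cmb <- combine_fisher(c(0.0104562, 0.1055787))
  expect_equal(cmb$df, 4L)
  expect_equal(cmb$meta_p, 0.00862, tolerance = 1e-3)
  expect_equal(round(cmb$meta_p, 3), 0.009)
  cmb2 <- combine_fisher(c(0.5017420, 0.0040623))
  expect_equal(cmb2$meta_p, 0.014666, tolerance = 1e-4)
  expect_equal(round(cmb2$meta_p, 3), 0.015)
  expect_equal(combine_fisher(1.0)$meta_p, 1.0)
  expect_error(combine_fisher(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(combine_fisher(numeric(0)), "at least one")

  # monotone: decreasing any input p never increases the combined p
  set.seed(31)
  for (i in 1:100) {
    ps <- runif(sample(1:4, 1), 0.001, 1)
    j <- sample(length(ps), 1)
    ps2 <- ps; ps2[j] <- ps[j] * runif(1)
    expect_lte(combine_fisher(ps2)$meta_p, combine_fisher(ps)$meta_p + 1e-15)
  }
  # identical pairs against the df-4 closed form exp(-X/2) * (1 + X/2);
  # combining reinforces evidence (meta p below p) up to the fixed point of
  # p * (1 - 2 log p) = 1, at p ~ 0.2847, and dilutes it beyond
  for (p in c(0.01, 0.05, 0.1, 0.2, 0.28, 0.3, 0.37, 0.9)) {
    cmb <- combine_fisher(c(p, p))
    X <- -2 * 2 * log(p)
    expect_equal(cmb$meta_p, exp(-X / 2) * (1 + X / 2), tolerance = 1e-12)
    if (p <= 0.28) expect_lte(cmb$meta_p, p) else expect_gt(cmb$meta_p, p)
  }
})

test_that("BH adjustment is step-up, monotone and decision-equivalent", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # independent step-up oracle: reject H_(1..k) with
  # k = max { i : p_(i) <= i * alpha / n }
  bh_reject_oracle <- function(p, alpha) {
    o <- order(p); n <- length(p)
    ok <- which(p[o] <= seq_len(n) * alpha / n)
    rej <- logical(n)
    if (length(ok) > 0L) rej[o[seq_len(max(ok))]] <- TRUE
    rej
  }
  set.seed(41)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # non-decreasing in the sorted order of raw p, and the monotonicity
    # enforcement is a fixed point (re-enforcing changes nothing)
    srt <- adj[order(p)]
    expect_true(!is.unsorted(srt))
    expect_equal(pmin(rev(cummin(rev(srt))), 1), srt)
    # thresholding adjusted values reproduces the step-up decisions exactly
    for (alpha in c(0.01, 0.05, 0.2, 0.5))
      expect_equal(adj <= alpha, bh_reject_oracle(p, alpha))
  }
})

test_that("meta screen builds the per-stratum tables and combines them", {
  fx <- table_fixtures()
  sc <- counts_screen(fx$neuro_indels$annotation, fx$neuro_indels$counts)
  calls <- sc$calls
  # (3 AA, 1 EA) pattern: chain the two oracles by hand
  i <- which(calls$case_carriers.AA == 3L & calls$case_carriers.EA == 1L)[1]
  p_aa <- yates_oracle(3, 113, 0, 408)[2]
  p_ea <- yates_oracle(1, 88, 0, 262)[2]
  want <- pchisq(-2 * (log(p_aa) + log(p_ea)), 4, lower.tail = FALSE)
  expect_equal(calls$meta_p[i], want, tolerance = 1e-12)
  expect_equal(calls$meta_p[i], 0.0365, tolerance = 1e-3)
  expect_true(calls$meta_retained[i])
  # ineligible rows carry no meta p
  counts <- fx$neuro_indels$counts[1:2, ]
  counts$case_carriers.EA <- 0L
  sc2 <- counts_screen(fx$neuro_indels$annotation[1:2, ], counts)
  expect_true(all(is.na(sc2$calls$meta_p)))
})

test_that("over-representation p-values match small-count enumeration", {
  # query equals one set exactly in a universe of that set plus 100 decoys
  universe <- c(paste0("S", 1:10), paste0("D", 1:100))
  sets <- list(hitset = paste0("S", 1:10), decoyset = paste0("D", 1:10))
  res <- enrich(paste0("S", 1:10), sets, universe)
  # P[all 10 draws inside the set] = 1 / choose(110, 10)
  expect_equal(res$p[res$term == "hitset"], 1 / choose(110, 10),
               tolerance = 1e-10)
  expect_equal(res$term[1], "hitset")  # smallest p of all sets sorts first
  # k = 0 still has p = P[X >= 0] = 1
  res0 <- enrich(paste0("D", 11:20), list(s = paste0("S", 1:10)), universe)
  expect_equal(res0$p, 1)
  # two identical sets get identical p and p_adj, tie broken by name
  res2 <- enrich(paste0("S", 1:5), list(b = paste0("S", 1:10),
                                        a = paste0("S", 1:10)), universe)
  expect_equal(res2$p[1], res2$p[2])
  expect_equal(res2$p_adj[1], res2$p_adj[2])
  expect_equal(res2$term, c("a", "b"))
  # hypergeometric tail equals explicit enumeration on small counts
  k <- 3; K <- 6; n <- 8; N <- 30
  enum <- sum(vapply(k:min(K, n), function(j)
    choose(K, j) * choose(N - K, n - j), numeric(1))) / choose(N, n)
  got <- enrich(c(paste0("K", 1:3), paste0("U", 1:5)),
                list(s = paste0("K", 1:6)),
                c(paste0("K", 1:6), paste0("U", 1:24)))
  expect_equal(got$p, enum, tolerance = 1e-12)
  # sets outside the universe are skipped; empty universe errors
  resx <- enrich("S1", list(out = "ZZZ"), universe)
  expect_equal(nrow(resx), 0L)
  expect_error(enrich("S1", sets, character(0)), "empty gene universe")
  expect_warning(enrich(c("S1", "NOTINUNI"), sets, universe), "outside")
})
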