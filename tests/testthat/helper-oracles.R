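# Independent oracles used across tests. These deliberately avoid the
# package's code paths: the exact test oracle works from binomial
# coefficients, the chi-square oracle from the textbook formula, and the
# recurrence oracle is a plain if/else reading of the filtering rules.

# two-sided exact p by explicit enumeration over the fixed-margin support,
# probabilities from log binomial coefficients (not dhyper)
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  N <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (N - c1) == 0) return(1)
  supp <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, supp) + lchoose(r2, c1 - supp) - lchoose(N, c1)
  dens <- exp(logp)
  p_obs <- dens[match(a, supp)]
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}

# Yates statistic and p straight from the formula; pearson for comparison
yates_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  num <- max(abs(a * d - b * c) - N / 2, 0)
  stat <- N * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  c(stat, pchisq(stat, 1, lower.tail = FALSE))
}

pearson_stat <- function(a, b, c, d) {
  N <- a + b + c + d
  N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# plain-language re-statement of the recurrence rules, scalar only
classify_oracle <- function(case_carriers, control_carriers, n_controls,
                            esp, kg, gnom, th) {
  freqs <- c(esp, kg, gnom)
  freqs <- freqs[!is.na(freqs)]
  if (any(freqs >= th$max_population_maf)) return("none")
  if (case_carriers < th$min_case_occurrences) return("none")
  if (control_carriers == 0) return("zero_in_control")
  if (control_carriers / n_controls < th$max_control_frequency)
    return("rare_recurrent")
  "none"
}

# write a small VCF from a genotype matrix (variants x samples, entries are
# GT strings), for io tests
write_test_vcf <- function(path, chrom, pos, ref, alt, gt, samples) {
  body <- vapply(seq_along(chrom), function(i)
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t"), character(1))
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               body), path)
  path
}

write_test_manifest <- function(path, sample_id, stratum, status) {
  utils::write.table(data.frame(sample_id = sample_id, stratum = stratum,
                                status = status),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small two-stratum cohort used in several io/recurrence tests
tiny_cohort <- function() {
  samples <- c(paste0("A_case", 1:3), paste0("A_ctrl", 1:4),
               paste0("B_case", 1:2), paste0("B_ctrl", 1:3))
  list(samples = samples,
       stratum = rep(c("A", "B"), c(7, 5)),
       status = c(rep("case", 3), rep("control", 4),
                  rep("case", 2), rep("control", 3)))
}
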