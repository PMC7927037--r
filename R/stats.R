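#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table
#' \preformatted{ cases:    a carriers   b non-carriers
#'  controls: c carriers   d non-carriers }
#' computed by summing, over the hypergeometric support at fixed margins, the
#' probabilities of all tables at most as probable as the observed one
#' (within relative tolerance 1e-7, the usual convention). No asymptotic
#' approximation is involved. A table with an all-zero margin carries no
#' information and returns p = 1.
#'
#' @param a,b,c,d non-negative integer cells.
#' @return two-sided p-value.
#' @examples
#' fisher_exact_2x2(2, 114, 0, 408)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers", call. = FALSE)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  supp <- max(0, c1 - r2):min(r1, c1)
  dens <- stats::dhyper(supp, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}

#' Continuity-corrected chi-square test for a 2x2 table
#'
#' Yates-corrected statistic
#' `N * (max(|ad - bc| - N/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d))` with
#' `N = a+b+c+d`, and its two-sided p-value from the chi-square distribution
#' with 1 degree of freedom. The correction matters here because every
#' zero-in-control table has an empty cell. Degenerate tables (an all-zero
#' margin) return statistic 0, p = 1.
#'
#' @inheritParams fisher_exact_2x2
#' @return named numeric vector `c(statistic =, p =)`.
#' @examples
#' chisq_yates_2x2(3, 113, 0, 408)
#' @export
chisq_yates_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cells must be non-negative", call. = FALSE)
  N <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(c(statistic = 0, p = 1))
  num <- max(abs(a * d - b * c) - N / 2, 0)
  stat <- N * num^2 / denom
  c(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fisher's combined probability method
#'
#' Combines independent p-values (one per ancestry stratum) through
#' `X = -2 * sum(log(p_i))`, chi-square distributed with `2k` degrees of
#' freedom under the joint null.
#'
#' @param p_values numeric vector of p-values in (0, 1]; at least one.
#' @return list with `X` (statistic), `df` and `meta_p`.
#' @examples
#' combine_fisher(c(0.010456, 0.105579))
#' @export
combine_fisher <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (length(p_values) == 0L) stop("need at least one p-value", call. = FALSE)
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  X <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(X = X, df = df,
       meta_p = stats::pchisq(X, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, monotonicity enforced and capped
#' at 1, order-preserving with the input.
#'
#' @param p_values numeric vector in [0, 1].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Cross-stratum meta screen of zero-in-control recurrent variants
#'
#' For each meta-eligible call (at least one case carrier in every stratum,
#' no control carriers, total case carriers above the recurrence threshold) a
#' 2x2 table `(case_carriers, n_cases - case_carriers, control_carriers,
#' n_controls - control_carriers)` is built per stratum, its
#' continuity-corrected chi-square p computed, and the per-stratum p-values
#' are combined by Fisher's method. A call is retained when the combined p
#' falls below `alpha`.
#'
#' @param calls calls data.frame from [select_variants()] (needs the
#'   per-stratum carrier columns and `meta_eligible`).
#' @param cohort a [cohort_spec()].
#' @param alpha significance level for retention (default 0.05; the screen
#'   reports raw combined p-values, multiplicity correction is left to
#'   [bh_adjust()] downstream).
#' @return `calls` with `meta_X`, `meta_p` and logical `meta_retained`
#'   columns filled for meta-eligible rows (`NA` elsewhere).
#' @export
meta_screen <- function(calls, cohort, alpha = 0.05) {
  calls$meta_X <- rep(NA_real_, nrow(calls))
  calls$meta_p <- rep(NA_real_, nrow(calls))
  calls$meta_retained <- rep(NA, nrow(calls))
  if (nrow(calls) == 0L) return(calls)
  for (i in which(calls$meta_eligible)) {
    ps <- vapply(seq_len(nrow(cohort)), function(j) {
      s <- cohort$label[j]
      a <- calls[[paste0("case_carriers.", s)]][i]
      c_ <- calls[[paste0("control_carriers.", s)]][i]
      chisq_yates_2x2(a, cohort$n_cases[j] - a,
                      c_, cohort$n_controls[j] - c_)[["p"]]
    }, numeric(1))
    cmb <- combine_fisher(ps)
    calls$meta_X[i] <- cmb$X
    calls$meta_p[i] <- cmb$meta_p
    calls$meta_retained[i] <- cmb$meta_p < alpha
  }
  calls
}

#' Gene-set over-representation test
#'
#' One-sided hypergeometric upper-tail test per gene set: given `n` query
#' genes drawn from a universe of `N`, of which `K` belong to the set, the
#' p-value is `P[hits >= k]`. Sets with no overlap with the universe are
#' skipped. Benjamini-Hochberg adjustment is applied across all tested sets.
#'
#' @param query_genes character vector of hit genes (must be drawn from the
#'   universe; genes outside it are dropped with a warning).
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param universe character vector of all assayable genes.
#' @return data.frame with columns `term`, `k`, `K`, `n`, `N`, `p`, `p_adj`,
#'   sorted by `p` then `term`.
#' @export
enrich <- function(query_genes, gene_sets, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0L) stop("empty gene universe", call. = FALSE)
  query_genes <- unique(query_genes)
  outside <- setdiff(query_genes, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query_genes <- intersect(query_genes, universe)
  }
  n <- length(query_genes)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(unique(gene_sets[[term]]), universe)
    K <- length(set)
    if (K == 0L) return(NULL)
    k <- length(intersect(set, query_genes))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), stringsAsFactors = FALSE))
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
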