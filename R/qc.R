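#' Per-variant quality-control statistics
#'
#' Computes, for every variant, the call rate (fraction of non-missing
#' genotypes), the minor allele frequency and a Hardy-Weinberg equilibrium
#' goodness-of-fit p-value.
#'
#' @param dataset A [geno_dataset].
#' @return A data.frame with columns `variant_id`, `call_rate`, `maf`,
#'   `hwe_p`. Variants with zero non-missing calls get `NA` for `maf` and
#'   `hwe_p` (they fail the call-rate filter regardless).
#' @export
variant_stats <- function(dataset) {
  g <- dataset$genotypes
  if (nrow(g) < 1L) stop("dataset has no subjects")
  n_obs <- colSums(!is.na(g))
  call_rate <- n_obs / nrow(g)
  n0 <- colSums(g == 0L, na.rm = TRUE)
  n1 <- colSums(g == 1L, na.rm = TRUE)
  n2 <- colSums(g == 2L, na.rm = TRUE)
  alt_freq <- ifelse(n_obs > 0, (n1 + 2 * n2) / (2 * n_obs), NA_real_)
  maf <- pmin(alt_freq, 1 - alt_freq)
  hwe_p <- hwe_test(n0, n1, n2)
  hwe_p[n_obs == 0] <- NA_real_
  data.frame(variant_id = colnames(g), call_rate = call_rate, maf = maf,
             hwe_p = hwe_p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed genotype
#' counts against the Hardy-Weinberg expectation (p^2, 2pq, q^2) scaled by
#' the total, where p is the sample reference-allele frequency. Monomorphic
#' variants (p equal to 0 or 1) return p-value 1 by convention. Vectorised.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (codes 0, 1, 2).
#' @return Upper-tail chi-square p-value(s).
#' @export
hwe_test <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  p <- ifelse(n > 0, (2 * n_hom_ref + n_het) / (2 * n), NA_real_)
  q <- 1 - p
  e0 <- n * p^2
  e1 <- n * 2 * p * q
  e2 <- n * q^2
  stat <- ifelse(p > 0 & p < 1,
                 (n_hom_ref - e0)^2 / e0 + (n_het - e1)^2 / e1 +
                   (n_hom_alt - e2)^2 / e2,
                 0)
  out <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  out[!is.na(p) & (p == 0 | p == 1)] <- 1
  out[n == 0] <- NA_real_
  out
}

#' Filter variants on call rate, minor allele frequency and HWE
#'
#' A variant is removed when its call rate is below `min_call_rate`, its
#' minor allele frequency is below `min_maf`, or its Hardy-Weinberg p-value
#' is below `min_hwe_p` (any one failure suffices). Defaults follow common
#' GWAS practice: 99% call rate, 5% MAF, 1e-4 HWE.
#'
#' @param dataset A [geno_dataset].
#' @param min_call_rate,min_maf,min_hwe_p Thresholds in \[0, 1\].
#' @return A list with `dataset` (surviving variants, genotype values
#'   untouched) and `report` (a data.frame of removed variants with their
#'   statistics and the comma-joined `failed_rules`).
#' @export
filter_variants <- function(dataset, min_call_rate = 0.99, min_maf = 0.05,
                            min_hwe_p = 1e-4) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1, min_hwe_p >= 0, min_hwe_p <= 1)
  st <- variant_stats(dataset)
  fail_call <- st$call_rate < min_call_rate
  fail_maf <- !is.na(st$maf) & st$maf < min_maf
  fail_hwe <- !is.na(st$hwe_p) & st$hwe_p < min_hwe_p
  drop <- fail_call | fail_maf | fail_hwe
  rules <- vapply(seq_along(drop), function(i)
    paste(c(if (fail_call[i]) "call_rate", if (fail_maf[i]) "maf",
            if (fail_hwe[i]) "hwe"), collapse = ","), character(1))
  report <- cbind(st[drop, , drop = FALSE],
                  failed_rules = rules[drop])
  if (all(drop)) warning("all variants removed by variant QC")
  keep <- which(!drop)
  list(dataset = subset_dataset(dataset, variants = keep), report = report)
}

#' Per-sample quality-control statistics
#'
#' @param dataset A [geno_dataset].
#' @return A data.frame with `subject_id`, `missing_rate` (fraction of
#'   missing genotype calls) and `het_rate` (fraction of non-missing calls
#'   that are heterozygous, code 1).
#' @export
sample_stats <- function(dataset) {
  g <- dataset$genotypes
  n_obs <- rowSums(!is.na(g))
  missing_rate <- 1 - n_obs / ncol(g)
  het_rate <- ifelse(n_obs > 0, rowSums(g == 1L, na.rm = TRUE) / n_obs,
                     NA_real_)
  data.frame(subject_id = rownames(g), missing_rate = missing_rate,
             het_rate = het_rate, row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter samples on missingness and heterozygosity outliers
#'
#' A sample is removed when its genotype missing rate exceeds `max_missing`
#' or its heterozygosity rate lies more than `het_sd` standard deviations
#' from the cohort mean. The mean and SD are computed once on the full
#' pre-removal cohort; with zero SD no sample fails the heterozygosity rule.
#'
#' @param dataset A [geno_dataset].
#' @param max_missing Maximum tolerated missing-call fraction (default 0.05).
#' @param het_sd Heterozygosity outlier cutoff in SD units (default 3).
#' @return A list with `dataset` and a removal `report` as in
#'   [filter_variants()].
#' @export
filter_samples <- function(dataset, max_missing = 0.05, het_sd = 3.0) {
  if (nrow(dataset$genotypes) < 2L)
    stop("at least two samples required (SD undefined otherwise)")
  st <- sample_stats(dataset)
  fail_miss <- st$missing_rate > max_missing
  mu <- mean(st$het_rate, na.rm = TRUE)
  sdv <- stats::sd(st$het_rate, na.rm = TRUE)
  fail_het <- if (is.na(sdv) || sdv == 0) rep(FALSE, nrow(st)) else
    !is.na(st$het_rate) & abs(st$het_rate - mu) > het_sd * sdv
  drop <- fail_miss | fail_het
  rules <- vapply(seq_along(drop), function(i)
    paste(c(if (fail_miss[i]) "missing_rate", if (fail_het[i]) "heterozygosity"),
          collapse = ","), character(1))
  report <- cbind(st[drop, , drop = FALSE], failed_rules = rules[drop])
  keep <- which(!drop)
  list(dataset = subset_dataset(dataset, subjects = keep), report = report)
}

#' Full QC pass: variant filters, then sample filters
#'
#' Applies [filter_variants()] followed by [filter_samples()], each in a
#' single pass (no iterative re-filtering).
#'
#' @inheritParams filter_variants
#' @inheritParams filter_samples
#' @return A list with the filtered `dataset`, `variant_report` and
#'   `sample_report`.
#' @export
qc_filter <- function(dataset, min_call_rate = 0.99, min_maf = 0.05,
                      min_hwe_p = 1e-4, max_missing = 0.05, het_sd = 3.0) {
  v <- filter_variants(dataset, min_call_rate, min_maf, min_hwe_p)
  s <- filter_samples(v$dataset, max_missing, het_sd)
  list(dataset = s$dataset, variant_report = v$report,
       sample_report = s$report)
}
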