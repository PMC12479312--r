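#' Observed genotype counts at one gene
#'
#' Tabulates unordered genotype classes (allele pairs) at one gene, at field
#' resolution `k`.
#'
#' @inheritParams allele_frequencies
#' @return Data frame with columns `allele1`, `allele2` (sorted within each
#'   pair in nomenclature order) and `count`.
#' @export
genotype_counts <- function(cohort, gene, k = 3L) {
  gene <- .norm_gene(gene)
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  a1 <- truncate_resolution(cohort[[paste0(gene, "_1")]], k)
  a2 <- truncate_resolution(cohort[[paste0(gene, "_2")]], k)
  swap <- allele_order_key(a1) > allele_order_key(a2)
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  tab <- table(paste(a1, a2, sep = "/"))
  parts <- strsplit(names(tab), "/", fixed = TRUE)
  out <- data.frame(allele1 = vapply(parts, `[`, "", 1L),
                    allele2 = vapply(parts, `[`, "", 2L),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(allele_order_key(out$allele1), allele_order_key(out$allele2)), ]
  rownames(out) <- NULL
  out
}

#' Expected genotype counts under Hardy--Weinberg equilibrium
#'
#' For allele frequencies \eqn{p_i} and sample size `n`, the expected count of
#' homozygote \eqn{ii} is \eqn{n p_i^2} and of heterozygote \eqn{\{i,j\}} is
#' \eqn{2 n p_i p_j}; the expectations sum to `n`.
#'
#' @param freq an `hla_freq_table` or named numeric vector of allele
#'   frequencies (renormalized to sum to 1).
#' @param n number of individuals.
#' @return Data frame `allele1`, `allele2`, `expected` over all unordered
#'   pairs.
#' @export
hwe_expected <- function(freq, n) {
  if (length(n) != 1L || is.na(n) || n <= 0) stop("n must be positive", call. = FALSE)
  p <- .freq_vector(freq)
  alleles <- names(p)[order(allele_order_key(names(p)))]
  p <- p[alleles]
  idx <- which(upper.tri(matrix(0, length(p), length(p)), diag = TRUE), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  out <- data.frame(allele1 = alleles[i], allele2 = alleles[j],
                    expected = ifelse(i == j, n * p[i]^2, 2 * n * p[i] * p[j]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Multi-allele Hardy--Weinberg chi-square test with low-count filtering
#'
#' Allele frequencies are estimated by gene-wise call counting from the full
#' observed genotype table; expected counts follow [hwe_expected()]. Genotype
#' classes observed fewer than `min_count` times are excluded from the
#' chi-square sum (the chi-square approximation is unreliable for sparse
#' classes), but expected counts are not re-normalized after filtering and
#' the degrees of freedom keep the closed form
#' \eqn{df = n_a(n_a+1)/2 - n_a}
#' with \eqn{n_a} the number of distinct alleles observed. When classes were
#' actually filtered this df no longer matches the number of summed classes;
#' the result records this in `filtered_df_mismatch` so the approximation is
#' visible rather than silently absorbed.
#'
#' @param observed data frame `allele1`, `allele2`, `count` as from
#'   [genotype_counts()] (pairs unordered; absent classes may be omitted and
#'   are treated as observed 0).
#' @param min_count smallest observed class count retained in the chi-square
#'   sum (default 5).
#' @return Object of class `hwe_result`: list with `chi2`, `df`, `p_value`,
#'   `n_alleles`, `n` (individuals), `classes` (per-class observed/expected
#'   and retention flag), `n_retained`, `filtered_df_mismatch`.
#' @export
hwe_chi_square <- function(observed, min_count = 5L) {
  if (min_count < 0L) stop("min_count must be >= 0", call. = FALSE)
  if (!all(c("allele1", "allele2", "count") %in% names(observed))) {
    stop("observed must have columns allele1, allele2, count", call. = FALSE)
  }
  n <- sum(observed$count)
  if (n <= 0L) stop("nothing to test: no observed genotypes", call. = FALSE)
  # allele frequencies from call counting over the full table
  allele_counts <- tapply(
    c(observed$count, observed$count),
    c(observed$allele1, observed$allele2),
    sum)
  p <- allele_counts / (2 * n)
  exp_tab <- hwe_expected(p, n)
  key <- function(a1, a2) {
    swap <- allele_order_key(a1) > allele_order_key(a2)
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
    paste(a1, a2, sep = "/")
  }
  obs_map <- stats::setNames(observed$count, key(observed$allele1, observed$allele2))
  classes <- exp_tab
  classes$observed <- as.integer(obs_map[key(classes$allele1, classes$allele2)])
  classes$observed[is.na(classes$observed)] <- 0L
  classes$retained <- classes$observed >= min_count
  if (!any(classes$retained)) {
    stop("nothing to test: no genotype class reaches min_count = ", min_count,
         call. = FALSE)
  }
  ret <- classes[classes$retained, , drop = FALSE]
  chi2 <- sum((ret$observed - ret$expected)^2 / ret$expected)
  n_alleles <- length(p)
  df <- n_alleles * (n_alleles + 1) / 2 - n_alleles
  structure(list(
    chi2 = chi2,
    df = as.integer(df),
    p_value = stats::pchisq(chi2, df = df, lower.tail = FALSE),
    n_alleles = as.integer(n_alleles),
    n = as.integer(n),
    allele_frequencies = p,
    classes = classes,
    n_retained = sum(classes$retained),
    filtered_df_mismatch = any(!classes$retained)
  ), class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat("<hwe_result> chi2 =", format(x$chi2, digits = 5),
      " df =", x$df, " p =", format(x$p_value, digits = 4), "\n")
  cat("  alleles:", x$n_alleles, "  genotype classes retained:", x$n_retained,
      "of", nrow(x$classes), "\n")
  if (x$filtered_df_mismatch) {
    cat("  note: low-count classes were filtered but df keeps the closed form;\n",
        "  the chi-square reference distribution is approximate.\n")
  }
  invisible(x)
}

#' Hardy--Weinberg test for one gene of a cohort
#'
#' Convenience wrapper: tabulates genotypes with [genotype_counts()] and runs
#' [hwe_chi_square()].
#'
#' @inheritParams allele_frequencies
#' @inheritParams hwe_chi_square
#' @return An `hwe_result`.
#' @export
hwe_test <- function(cohort, gene, k = 3L, min_count = 5L) {
  hwe_chi_square(genotype_counts(cohort, gene, k), min_count = min_count)
}
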