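#' Allele frequencies at one gene
#'
#' Registry allele frequency: the count of each allele among all `2n` calls at
#' the gene, divided by `2n` (two alleles per individual). Counts are integer
#' so the frequencies sum to 1 exactly up to the final float division.
#'
#' @param cohort an [hla_cohort()]; must be nonempty.
#' @param gene `"A"`, `"B"` or `"C"`.
#' @param k field resolution at which calls are aggregated (default 3).
#' @return A data frame of class `hla_freq_table` with columns `allele`,
#'   `count`, `frequency`, sorted by descending count then nomenclature
#'   order, and attributes `gene`, `k`, `n_individuals`.
#' @export
allele_frequencies <- function(cohort, gene, k = 3L) {
  gene <- .norm_gene(gene)
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  calls <- truncate_resolution(
    c(cohort[[paste0(gene, "_1")]], cohort[[paste0(gene, "_2")]]), k)
  tab <- table(calls)
  out <- data.frame(allele = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$frequency <- out$count / (2L * nrow(cohort))
  out <- out[order(-out$count, allele_order_key(out$allele)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, gene = gene, k = k, n_individuals = nrow(cohort),
            class = c("hla_freq_table", "data.frame"))
}

#' Construct a frequency table from allele/frequency pairs
#'
#' Used for published population tables read from CSV (columns
#' `allele,frequency`). Frequencies are renormalized to sum to 1.
#'
#' @param allele character vector of allele names.
#' @param frequency numeric vector of relative frequencies (will be
#'   renormalized).
#' @param gene locus; inferred from the alleles when `NULL`.
#' @param n_individuals optional backing sample size.
#' @return An `hla_freq_table`.
#' @export
freq_table <- function(allele, frequency, gene = NULL, n_individuals = NA_integer_) {
  if (length(allele) == 0L) stop("empty frequency table", call. = FALSE)
  if (any(frequency < 0) || sum(frequency) <= 0) {
    stop("frequencies must be non-negative with positive sum", call. = FALSE)
  }
  allele <- canonical_alleles(allele, gene = gene)
  g <- unique(substr(allele, 1L, 1L))
  if (length(g) != 1L) stop("frequency table mixes loci: ", paste(g, collapse = ", "),
                            call. = FALSE)
  if (anyDuplicated(allele)) stop("duplicate allele in frequency table", call. = FALSE)
  out <- data.frame(allele = allele, count = NA_integer_,
                    frequency = frequency / sum(frequency),
                    stringsAsFactors = FALSE)
  structure(out, gene = g, k = max(lengths(strsplit(sub("[NLSQCA]$", "", allele), ":"))),
            n_individuals = n_individuals,
            class = c("hla_freq_table", "data.frame"))
}

# as .freq_vector but without renormalization
.freq_vector_raw <- function(f) {
  if (inherits(f, "hla_freq_table") || is.data.frame(f)) {
    p <- stats::setNames(f$frequency, f$allele)
  } else if (is.numeric(f) && !is.null(names(f))) {
    p <- f
  } else {
    stop("expected a frequency table or a named numeric vector", call. = FALSE)
  }
  if (length(p) == 0L) stop("empty frequency table", call. = FALSE)
  p
}

# named numeric p vector from an hla_freq_table / data.frame / named numeric
.freq_vector <- function(f) {
  if (inherits(f, "hla_freq_table") || is.data.frame(f)) {
    p <- f$frequency
    names(p) <- f$allele
  } else if (is.numeric(f) && !is.null(names(f))) {
    p <- f
  } else {
    stop("expected a frequency table or a named numeric vector", call. = FALSE)
  }
  if (length(p) == 0L) stop("empty frequency table", call. = FALSE)
  p / sum(p)
}

#' Homozygosity counts with at-least semantics
#'
#' Counts individuals homozygous at each gene, at each pair of genes, and at
#' all three genes. Counts are "at least": a triple homozygote contributes to
#' every pair and every single-gene count (the convention of proportional
#' Euler diagrams).
#'
#' @inheritParams allele_frequencies
#' @return Object of class `homozygosity_counts`: list with `per_gene`
#'   (named A/B/C), `per_pair` (named AB/AC/BC), `triple`, `n`.
#' @export
homozygosity_counts <- function(cohort, k = 3L) {
  h <- sapply(CLASS_I_GENES, function(g) is_homozygous(cohort, g, k))
  if (nrow(cohort) == 0L) h <- matrix(logical(0), 0L, 3L,
                                      dimnames = list(NULL, CLASS_I_GENES))
  if (is.null(dim(h))) h <- matrix(h, nrow = 1L, dimnames = list(NULL, CLASS_I_GENES))
  new_homozygosity_counts(
    per_gene = c(A = sum(h[, "A"]), B = sum(h[, "B"]), C = sum(h[, "C"])),
    per_pair = c(AB = sum(h[, "A"] & h[, "B"]),
                 AC = sum(h[, "A"] & h[, "C"]),
                 BC = sum(h[, "B"] & h[, "C"])),
    triple = sum(h[, "A"] & h[, "B"] & h[, "C"]),
    n = nrow(cohort))
}

#' Build homozygosity counts from known tallies
#'
#' Constructor for externally reported counts (e.g. numbers printed in a
#' study); validates the containment invariants
#' `triple <= pair <= gene <= n`.
#'
#' @param per_gene named vector `c(A=, B=, C=)` of at-least single-gene counts.
#' @param per_pair named vector `c(AB=, AC=, BC=)` of at-least pairwise counts.
#' @param triple count homozygous at all three genes.
#' @param n cohort size.
#' @return `homozygosity_counts` object.
#' @export
new_homozygosity_counts <- function(per_gene, per_pair, triple, n) {
  per_gene <- per_gene[CLASS_I_GENES]
  per_pair <- per_pair[c("AB", "AC", "BC")]
  if (any(is.na(per_gene)) || any(is.na(per_pair)) || is.na(triple) || is.na(n)) {
    stop("homozygosity counts require named per_gene (A,B,C) and per_pair (AB,AC,BC)",
         call. = FALSE)
  }
  pair_parents <- list(AB = c("A", "B"), AC = c("A", "C"), BC = c("B", "C"))
  for (p in names(pair_parents)) {
    if (per_pair[[p]] > min(per_gene[pair_parents[[p]]])) {
      stop("invariant violated: pair count ", p, " exceeds a constituent gene count",
           call. = FALSE)
    }
    if (triple > per_pair[[p]]) {
      stop("invariant violated: triple count exceeds pair count ", p, call. = FALSE)
    }
  }
  if (any(per_gene > n)) stop("invariant violated: gene count exceeds cohort size",
                              call. = FALSE)
  structure(list(per_gene = per_gene, per_pair = per_pair,
                 triple = as.integer(triple), n = as.integer(n)),
            class = "homozygosity_counts")
}

#' @export
print.homozygosity_counts <- function(x, ...) {
  cat("<homozygosity_counts> n =", x$n, "\n")
  cat("  per gene:", paste(names(x$per_gene), x$per_gene, sep = "=", collapse = "  "), "\n")
  cat("  per pair:", paste(names(x$per_pair), x$per_pair, sep = "=", collapse = "  "), "\n")
  cat("  triple:  ", x$triple, "\n")
  invisible(x)
}

#' Union and exclusive homozygote counts by inclusion--exclusion
#'
#' From at-least counts, derives the number of individuals homozygous at at
#' least one gene, at exactly two genes, and at exactly one gene:
#' \deqn{|A \cup B \cup C| = \sum_g n_g - \sum_{gh} n_{gh} + n_{ABC}}
#' `exactly_two` is \eqn{\sum n_{gh} - 3 n_{ABC}} and `exactly_one` the
#' remainder.
#'
#' @param counts a `homozygosity_counts` object.
#' @return Named list `at_least_one`, `exactly_two`, `exactly_one`, `triple`.
#' @examples
#' cts <- new_homozygosity_counts(per_gene = c(A = 542, B = 233, C = 338),
#'                                per_pair = c(AB = 58, AC = 76, BC = 172),
#'                                triple = 51, n = 3496)
#' derive_union_and_exclusive(cts)
#' @export
derive_union_and_exclusive <- function(counts) {
  # construct/revalidate: invariants must hold even for hand-built inputs
  counts <- new_homozygosity_counts(counts$per_gene, counts$per_pair,
                                    counts$triple, counts$n)
  at_least_one <- sum(counts$per_gene) - sum(counts$per_pair) + counts$triple
  exactly_two <- sum(counts$per_pair) - 3L * counts$triple
  exactly_one <- at_least_one - exactly_two - counts$triple
  list(at_least_one = as.integer(at_least_one),
       exactly_two = as.integer(exactly_two),
       exactly_one = as.integer(exactly_one),
       triple = counts$triple)
}

#' Tally the haplotypes of triple homozygotes
#'
#' Triple homozygotes are the only individuals whose three-gene haplotype is
#' unambiguous without phasing: both haplotypes are identical. Returns one row
#' per distinct (A, B, C) allele triple among individuals homozygous at all
#' three genes.
#'
#' @inheritParams allele_frequencies
#' @return Data frame with columns `A`, `B`, `C`, `count`, sorted by
#'   descending count then nomenclature order; counts sum to the number of
#'   triple homozygotes.
#' @export
triple_homozygote_haplotype_tally <- function(cohort, k = 3L) {
  if (nrow(cohort) == 0L) {
    return(data.frame(A = character(), B = character(), C = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  th <- is_homozygous(cohort, "A", k) & is_homozygous(cohort, "B", k) &
    is_homozygous(cohort, "C", k)
  sub <- cohort[th, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(data.frame(A = character(), B = character(), C = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  hap <- data.frame(A = truncate_resolution(sub$A_1, k),
                    B = truncate_resolution(sub$B_1, k),
                    C = truncate_resolution(sub$C_1, k),
                    stringsAsFactors = FALSE)
  key <- paste(hap$A, hap$B, hap$C, sep = "\t")
  tab <- table(key)
  parts <- strsplit(names(tab), "\t", fixed = TRUE)
  out <- data.frame(A = vapply(parts, `[`, "", 1L),
                    B = vapply(parts, `[`, "", 2L),
                    C = vapply(parts, `[`, "", 3L),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$count, allele_order_key(out$A), allele_order_key(out$B),
                   allele_order_key(out$C)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
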