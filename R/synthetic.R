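#' Haplotype pool for registry simulation
#'
#' A set of distinct (A, B, C) allele triples with simplex weights, standing
#' in for the (unobserved) haplotype structure of a registry population.
#'
#' @param haplotypes data frame with columns `A`, `B`, `C` (allele names).
#' @param frequencies numeric weights (renormalized to sum to 1).
#' @param label pool label.
#' @return Object of class `haplotype_pool`.
#' @export
haplotype_pool <- function(haplotypes, frequencies, label = "pool") {
  haplotypes <- as.data.frame(haplotypes, stringsAsFactors = FALSE)
  stopifnot(all(c("A", "B", "C") %in% names(haplotypes)))
  for (g in CLASS_I_GENES) {
    haplotypes[[g]] <- canonical_alleles(haplotypes[[g]], gene = g)
  }
  if (length(frequencies) != nrow(haplotypes)) {
    stop("one frequency per haplotype required", call. = FALSE)
  }
  if (any(frequencies < 0) || sum(frequencies) <= 0) {
    stop("frequencies must be non-negative with positive sum", call. = FALSE)
  }
  key <- paste(haplotypes$A, haplotypes$B, haplotypes$C)
  if (anyDuplicated(key)) stop("haplotypes must be distinct", call. = FALSE)
  structure(list(haplotypes = haplotypes[c("A", "B", "C")],
                 frequencies = frequencies / sum(frequencies),
                 label = label),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("<haplotype_pool> '", x$label, "': ", nrow(x$haplotypes),
      " haplotypes\n", sep = "")
  invisible(x)
}

#' Registry simulation model with homozygote excess
#'
#' Autozygosity is modeled at the whole-haplotype level: with probability `F`
#' an individual carries two copies of a single drawn haplotype (forcing a
#' triple homozygote), otherwise two haplotypes drawn i.i.d. from the pool.
#' `F = 0` is haplotype-level Hardy--Weinberg equilibrium; increasing `F`
#' produces exactly the signature of triple homozygotes exceeding
#' independent-locus expectation.
#'
#' @param pool a [haplotype_pool()].
#' @param n number of individuals (>= 1).
#' @param F autozygosity excess in \[0, 1\].
#' @param seed RNG seed.
#' @return Object of class `registry_model`.
#' @export
registry_model <- function(pool, n, F = 0, seed = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"))
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (F < 0 || F > 1) stop("F must lie in [0, 1]", call. = FALSE)
  structure(list(pool = pool, n = as.integer(n), F = F, seed = seed),
            class = "registry_model")
}

#' Sample a synthetic registry
#'
#' Draws genotypes from a [registry_model()]: per individual, with
#' probability `F` one haplotype is drawn and duplicated; otherwise two
#' haplotypes are drawn i.i.d. Deterministic given the model's seed.
#'
#' @param model a [registry_model()].
#' @param label cohort label.
#' @return An [hla_cohort()] of `model$n` individuals.
#' @export
sample_registry <- function(model, label = NULL) {
  stopifnot(inherits(model, "registry_model"))
  if (!is.null(model$seed)) set.seed(model$seed)
  n <- model$n
  w <- model$pool$frequencies
  h1 <- sample.int(length(w), n, replace = TRUE, prob = w)
  h2 <- sample.int(length(w), n, replace = TRUE, prob = w)
  auto <- stats::runif(n) < model$F
  h2[auto] <- h1[auto]
  hp <- model$pool$haplotypes
  df <- data.frame(id = sprintf("syn_%06d", seq_len(n)),
                   A_1 = hp$A[h1], A_2 = hp$A[h2],
                   B_1 = hp$B[h1], B_2 = hp$B[h2],
                   C_1 = hp$C[h1], C_2 = hp$C[h2],
                   stringsAsFactors = FALSE)
  hla_cohort(df, label = label %||% paste0(model$pool$label, "_registry"))
}

#' Method-of-moments estimate of the autozygosity excess F
#'
#' In the oracle setting where the pool weights are known, the expected
#' triple-homozygote fraction is \eqn{h = F + (1 - F) h_0} with
#' \eqn{h_0 = \sum_k w_k^2}, so
#' \eqn{\hat F = (h_{obs} - h_0) / (1 - h_0)}.
#'
#' @param cohort a sampled registry.
#' @param pool_frequencies the pool's simplex weights.
#' @param k field resolution for the homozygosity calls.
#' @return List with `F_hat`, `h_obs`, `h0` and the standard error of
#'   `F_hat` implied by the binomial variance of `h_obs`.
#' @export
estimate_F <- function(cohort, pool_frequencies, k = 3L) {
  w <- pool_frequencies / sum(pool_frequencies)
  h0 <- sum(w^2)
  if (1 - h0 < .Machine$double.eps) {
    stop("degenerate pool (h0 = 1): F is unidentifiable", call. = FALSE)
  }
  th <- is_homozygous(cohort, "A", k) & is_homozygous(cohort, "B", k) &
    is_homozygous(cohort, "C", k)
  h_obs <- mean(th)
  F_hat <- (h_obs - h0) / (1 - h0)
  se <- sqrt(h_obs * (1 - h_obs) / nrow(cohort)) / (1 - h0)
  list(F_hat = F_hat, h_obs = h_obs, h0 = h0, se = se)
}

#' The study's triple-homozygous haplotype table
#'
#' The 15 distinct (A, B, C) triples carried by the 51 triple-homozygous
#' registry members, with their counts.
#'
#' @return Data frame `A`, `B`, `C`, `count` (counts sum to 51).
#' @export
table1_haplotypes <- function() {
  df <- utils::read.table(header = TRUE, stringsAsFactors = FALSE, text = "
A          B          C          count
A*03:01:01 B*07:02:01 C*07:02:01 15
A*02:01:01 B*13:02:01 C*06:02:01 10
A*01:01:01 B*08:01:01 C*07:01:01 6
A*02:01:01 B*07:02:01 C*07:02:01 4
A*02:01:01 B*40:01:01 C*03:04:01 3
A*02:01:01 B*57:01:01 C*06:02:01 2
A*03:01:01 B*56:01:01 C*01:02:01 2
A*25:01:01 B*18:01:01 C*12:03:01 2
A*02:01:01 B*15:01:01 C*03:04:01 1
A*02:01:01 B*27:05:02 C*02:02:02 1
A*25:01:01 B*35:01:01 C*04:01:01 1
A*26:01:01 B*38:01:01 C*12:03:01 1
A*31:01:02 B*51:01:01 C*05:01:01 1
A*68:01:01 B*40:01:01 C*03:04:01 1
A*68:01:02 B*44:02:01 C*07:04:01 1")
  df
}

#' Cohort realizing the triple-homozygote haplotype table
#'
#' Builds a 51-individual cohort in which every individual is triple
#' homozygous and the haplotype tally reproduces [table1_haplotypes()]
#' exactly.
#'
#' @return An [hla_cohort()] of 51 triple homozygotes.
#' @export
table1_fixture <- function() {
  tab <- table1_haplotypes()
  idx <- rep(seq_len(nrow(tab)), tab$count)
  df <- data.frame(id = sprintf("T1_%03d", seq_along(idx)),
                   A_1 = tab$A[idx], A_2 = tab$A[idx],
                   B_1 = tab$B[idx], B_2 = tab$B[idx],
                   C_1 = tab$C[idx], C_2 = tab$C[idx],
                   stringsAsFactors = FALSE)
  hla_cohort(df, label = "triple_homozygotes")
}

#' Illustrative demo haplotype pool
#'
#' The 15 haplotypes of [table1_haplotypes()] plus 25 synthetic heterogeneous
#' haplotypes, with Zipf-like weights. Illustrative only: not an estimate of
#' any real population's haplotype distribution.
#'
#' @param seed seed for the synthetic haplotype composition.
#' @return A [haplotype_pool()].
#' @export
demo_pool <- function(seed = 101L) {
  base <- table1_haplotypes()[c("A", "B", "C")]
  set.seed(seed)
  a_pool <- c("A*02:01:01", "A*03:01:01", "A*24:02:01", "A*01:01:01",
              "A*11:01:01", "A*26:01:01", "A*32:01:01", "A*23:01:01")
  b_pool <- c("B*07:02:01", "B*13:02:01", "B*15:01:01", "B*44:02:01",
              "B*40:01:01", "B*08:01:01", "B*35:01:01", "B*18:01:01",
              "B*51:01:01", "B*44:03:01")
  c_pool <- c("C*07:02:01", "C*06:02:01", "C*04:01:01", "C*02:02:02",
              "C*07:01:01", "C*03:04:01", "C*12:03:01", "C*05:01:01")
  extra <- data.frame(A = character(0), B = character(0), C = character(0))
  seen <- paste(base$A, base$B, base$C)
  while (nrow(extra) < 25L) {
    cand <- data.frame(A = sample(a_pool, 1L), B = sample(b_pool, 1L),
                       C = sample(c_pool, 1L), stringsAsFactors = FALSE)
    key <- paste(cand$A, cand$B, cand$C)
    if (!key %in% seen) {
      extra <- rbind(extra, cand)
      seen <- c(seen, key)
    }
  }
  haps <- rbind(base, extra)
  w <- 1 / seq_len(nrow(haps))  # Zipf-like
  haplotype_pool(haps, w, label = "demo")
}

#' Build a toy annotated gene panel
#'
#' Generates a reference gene with class-I-like architecture (by default 8
#' exons, a ~1.1 kb CDS and the transmembrane helix encoded in exon 5) and
#' allele variants differing at randomly chosen exonic positions, with exon
#' and transmembrane annotations ready for the guide-design cascade.
#'
#' @param gene locus letter used in the synthetic allele names.
#' @param exon_lengths integer vector of exon lengths (defines `n_exons`).
#' @param intron_lengths integer vector of intron lengths
#'   (`length(exon_lengths) - 1`).
#' @param utr5_len,utr3_len untranslated lengths inside the first/last exon;
#'   the CDS is the remainder of the spliced transcript and must be divisible
#'   by 3.
#' @param tm_residues 1-based residue interval of the transmembrane helix
#'   (on the full translated CDS).
#' @param n_alleles number of alleles to emit (>= 1; the first is the
#'   reference).
#' @param n_variant_positions exonic substitutions per non-reference allele.
#' @param variant_region optional 0-based half-open genomic interval to which
#'   variant positions are restricted (must intersect exons).
#' @param seed RNG seed.
#' @return Named list of [annotated_gene()] objects.
#' @export
toy_gene_builder <- function(gene = "A",
                             exon_lengths = c(73L, 270L, 276L, 276L, 117L,
                                              33L, 48L, 130L),
                             intron_lengths = c(130L, 241L, 576L, 102L,
                                                442L, 142L, 168L),
                             utr5_len = 64L, utr3_len = 58L,
                             tm_residues = c(285L, 307L),
                             n_alleles = 1L, n_variant_positions = 5L,
                             variant_region = NULL, seed = NULL) {
  gene <- .norm_gene(gene)
  if (length(intron_lengths) != length(exon_lengths) - 1L) {
    stop("need one intron length per internal junction", call. = FALSE)
  }
  spliced_len <- sum(exon_lengths)
  cds_length <- spliced_len - utr5_len - utr3_len
  if (cds_length <= 0L || cds_length %% 3L != 0L) {
    stop("UTR lengths leave no CDS divisible by 3 (got ", cds_length, " nt)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  starts <- cumsum(c(0L, utils::head(exon_lengths, -1L) + intron_lengths))
  exons <- data.frame(start = starts, end = starts + exon_lengths)
  total_len <- exons$end[nrow(exons)]
  ref <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)
  # start codon at the CDS start, for recognisability
  cds_start_genomic <- .spliced_to_genomic(
    structure(list(exons = exons), class = "annotated_gene"), utr5_len + 0:2)
  ref[cds_start_genomic + 1L] <- c("A", "T", "G")
  exonic_positions <- unlist(mapply(seq, exons$start, exons$end - 1L,
                                    SIMPLIFY = FALSE))
  if (!is.null(variant_region)) {
    exonic_positions <- exonic_positions[
      exonic_positions >= variant_region[1L] &
        exonic_positions < variant_region[2L]]
    if (length(exonic_positions) == 0L) {
      stop("variant_region contains no exonic positions", call. = FALSE)
    }
  }
  out <- list()
  for (i in seq_len(n_alleles)) {
    s <- ref
    if (i > 1L) {
      pos <- sample(exonic_positions, min(n_variant_positions,
                                          length(exonic_positions)))
      for (p in pos) {
        s[p + 1L] <- sample(setdiff(c("A", "C", "G", "T"), s[p + 1L]), 1L)
      }
    }
    al <- sprintf("%s*%02d:01:01", gene, 89L + i)  # synthetic allele range
    out[[al]] <- annotated_gene(
      allele = al, sequence = paste(s, collapse = ""), exons = exons,
      cds_start = utr5_len, cds_length = cds_length,
      tm_span = tm_residues, tm_on_mature = FALSE)
  }
  out
}
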