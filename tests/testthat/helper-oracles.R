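# Independent brute-force oracles used to cross-check package routines.
# These deliberately use the most naive algorithm available and share no code
# with the implementation paths they verify.

# naive two-strand Cas9 site scan: for every position, test the 23-mer
# (20-nt protospacer + NGG) by direct substring comparison, on the plus
# strand and on the reverse complement; report plus-strand cut boundaries.
oracle_find_sites <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp <- function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  L <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    i <- 1L
    while (i + 22L <= L) {
      pam <- substr(s, i + 20L, i + 22L)
      if (substr(pam, 2L, 3L) == "GG" && i - 4L >= 1L && i + 25L <= L) {
        cut_boundary <- if (strand == "+") i + 16L else L - (i + 16L)
        rows[[length(rows) + 1L]] <- data.frame(
          strand = strand,
          cut_pos = cut_boundary,
          protospacer = substr(s, i, i + 19L),
          pam = pam,
          context30 = substr(s, i - 4L, i + 25L),
          stringsAsFactors = FALSE)
      }
      i <- i + 1L
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(strand = character(), cut_pos = integer(),
                      protospacer = character(), pam = character(),
                      context30 = character(), stringsAsFactors = FALSE)
  }
  out[order(out$cut_pos, out$strand), , drop = FALSE]
}

# straight-line Rule Set 1 re-evaluation: walk the coefficient rows one by
# one, compare substrings, sum, then logistic.
oracle_ruleset1 <- function(context30) {
  coef <- ruleset1_coefficients()
  score <- coef$weight[coef$feature == "Intercept"]
  proto <- substr(context30, 5, 24)
  gc <- sum(strsplit(proto, "")[[1]] %in% c("G", "C"))
  w <- if (gc < 10) coef$weight[coef$feature == "GC_low"] else
    coef$weight[coef$feature == "GC_high"]
  score <- score + abs(gc - 10) * w
  for (r in seq_len(nrow(coef))) {
    pos <- coef$position[r]
    if (is.na(pos)) next
    nts <- coef$nts[r]
    if (substr(context30, pos, pos + nchar(nts) - 1L) == nts) {
      score <- score + coef$weight[r]
    }
  }
  1 / (1 + exp(-score))
}

# closed-form OLS via the normal equations
oracle_ols <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  m <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c0 <- my - m * mx
  r2 <- 1 - sum((y - (c0 + m * x))^2) / sum((y - my)^2)
  list(slope = m, intercept = c0, r_squared = r2)
}

# textbook multi-allele HWE chi-square, recomputed from first principles
oracle_hwe_chi2 <- function(observed) {
  alleles <- sort(unique(c(observed$allele1, observed$allele2)))
  n <- sum(observed$count)
  cnt <- setNames(rep(0, length(alleles)), alleles)
  for (r in seq_len(nrow(observed))) {
    cnt[observed$allele1[r]] <- cnt[observed$allele1[r]] + observed$count[r]
    cnt[observed$allele2[r]] <- cnt[observed$allele2[r]] + observed$count[r]
  }
  p <- cnt / (2 * n)
  chi2 <- 0
  for (i in seq_along(alleles)) {
    for (j in i:length(alleles)) {
      e <- if (i == j) n * p[i]^2 else 2 * n * p[i] * p[j]
      o <- 0
      hit <- (observed$allele1 == alleles[i] & observed$allele2 == alleles[j]) |
        (observed$allele1 == alleles[j] & observed$allele2 == alleles[i])
      if (any(hit)) o <- sum(observed$count[hit])
      chi2 <- chi2 + (o - e)^2 / e
    }
  }
  unname(chi2)
}

# exhaustive pairwise donor->recipient coverage
oracle_coverage <- function(donors, recipients, cfg) {
  matched <- rep(FALSE, nrow(recipients))
  for (d in seq_len(nrow(donors))) {
    for (r in seq_len(nrow(recipients))) {
      if (!matched[r]) {
        matched[r] <- donor_matches(donors[d, , drop = FALSE],
                                    recipients[r, , drop = FALSE], cfg)
      }
    }
  }
  mean(matched)
}

# small equifrequent pool with fully distinct alleles per haplotype, so that
# haplotype identity and allele identity coincide gene by gene
test_pool <- function(n_haps = 4L) {
  haplotype_pool(
    data.frame(A = sprintf("A*%02d:01:01", seq_len(n_haps)),
               B = sprintf("B*%02d:01:01", seq_len(n_haps)),
               C = sprintf("C*%02d:01:01", seq_len(n_haps))),
    rep(1 / n_haps, n_haps), label = "test")
}

random_freqs <- function(n_alleles = 4L) {
  lapply(setNames(c("A", "B", "C"), c("A", "B", "C")), function(g) {
    w <- runif(n_alleles) + 0.05
    setNames(w / sum(w), sprintf("%s*%02d:01:01", g, seq_len(n_alleles)))
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
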