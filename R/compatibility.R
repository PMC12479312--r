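#' Donor-to-recipient matching configuration
#'
#' The matching rule is directional host-versus-graft: a donor is compatible
#' with a recipient when, at every *retained* gene, the donor's allele set
#' (at resolution `k`) is a subset of the recipient's allele set — the
#' recipient's CD8 T cells see no foreign class I allele on the graft.
#' Knocking a gene out removes it from the retained set and so relaxes the
#' rule. The reverse (graft-versus-host) direction is available as an option
#' but plays no role in solid-tissue/iPSC-derivative matching.
#'
#' @param retained genes still expressed on the donor cells; subset of
#'   `c("A","B","C")`. An empty set is the universal-donor limit.
#' @param k field resolution for allele comparison (default 3).
#' @param direction `"host_vs_graft"` (default) or `"graft_vs_host"`.
#' @return Object of class `compatibility_config`.
#' @export
compatibility_config <- function(retained = c("A", "B", "C"), k = 3L,
                                 direction = c("host_vs_graft", "graft_vs_host")) {
  direction <- match.arg(direction)
  if (length(retained) > 0L) retained <- .norm_gene(retained)
  if (k < 1L) stop("resolution k must be >= 1", call. = FALSE)
  structure(list(retained = sort(unique(retained)), k = as.integer(k),
                 direction = direction),
            class = "compatibility_config")
}

#' @export
print.compatibility_config <- function(x, ...) {
  cat("<compatibility_config> retained: {",
      paste(x$retained, collapse = ","), "}  k =", x$k,
      " direction:", x$direction, "\n")
  invisible(x)
}

#' Remove knocked-out genes from a matching configuration
#'
#' Models gene editing of the donor: knocked-out genes are no longer
#' expressed and drop out of the retained set. Knocking out HLA-A and HLA-B
#' yields the HLA-C-retained configuration.
#'
#' @param cfg a [compatibility_config()].
#' @param knockout_genes genes to knock out (subset of `c("A","B","C")`; may
#'   be empty).
#' @return A new `compatibility_config`.
#' @export
apply_knockout <- function(cfg, knockout_genes) {
  if (length(knockout_genes) > 0L) knockout_genes <- .norm_gene(knockout_genes)
  compatibility_config(retained = setdiff(cfg$retained, knockout_genes),
                       k = cfg$k, direction = cfg$direction)
}

# donor row vs all recipient rows at the retained genes; returns logical
# vector over recipients. Allele columns must already be truncated to cfg$k.
.donor_match_vec <- function(donor_row, rec, cfg) {
  ok <- rep(TRUE, nrow(rec[[1L]]))
  for (g in cfg$retained) {
    d1 <- donor_row[[g]][1L]; d2 <- donor_row[[g]][2L]
    r1 <- rec[[g]][, 1L]; r2 <- rec[[g]][, 2L]
    if (cfg$direction == "host_vs_graft") {
      ok <- ok & (d1 == r1 | d1 == r2) & (d2 == r1 | d2 == r2)
    } else {
      ok <- ok & (r1 == d1 | r1 == d2) & (r2 == d1 | r2 == d2)
    }
    if (!any(ok)) break
  }
  ok
}

.truncated_calls <- function(cohort, k) {
  out <- lapply(stats::setNames(CLASS_I_GENES, CLASS_I_GENES), function(g) {
    cbind(truncate_resolution(cohort[[paste0(g, "_1")]], k),
          truncate_resolution(cohort[[paste0(g, "_2")]], k))
  })
  out
}

#' Does a donor match a recipient?
#'
#' Applies the configured rule to a single donor--recipient pair. Matching is
#' reflexive (any genotype matches itself) but not symmetric: a homozygous
#' donor can match a heterozygous recipient that would not match back.
#'
#' @param donor,recipient single-row [hla_cohort()]s (or data frames with the
#'   cohort columns).
#' @param cfg a [compatibility_config()].
#' @return `TRUE` or `FALSE`.
#' @export
donor_matches <- function(donor, recipient, cfg = compatibility_config()) {
  donor <- hla_cohort(donor); recipient <- hla_cohort(recipient)
  stopifnot(nrow(donor) == 1L, nrow(recipient) == 1L)
  if (length(cfg$retained) == 0L) return(TRUE)
  dcalls <- .truncated_calls(donor, cfg$k)
  rcalls <- .truncated_calls(recipient, cfg$k)
  drow <- lapply(dcalls, function(mm) mm[1L, ])
  .donor_match_vec(drow, rcalls, cfg)[1L]
}

#' Population coverage of a donor panel
#'
#' Fraction of recipients matched by at least one donor under the configured
#' rule, together with a coverage curve built by accumulating donors in a
#' seeded random order (the endpoint is ordering-invariant; the stochastic
#' arrangement only shapes the displayed curve) and per-donor marginal
#' coverage.
#'
#' @param donors,recipients [hla_cohort()]s; `donors` and `recipients` must
#'   be nonempty.
#' @param cfg a [compatibility_config()].
#' @param seed RNG seed for the donor ordering of the curve.
#' @param exclude_self when `TRUE`, a donor does not count as matching the
#'   recipient with the same `id` (relevant when donors are a subset of the
#'   recipient cohort).
#' @return Object of class `coverage_result`: list with `fraction_matched`,
#'   `n_matched`, `n_recipients`, `per_donor` (data frame id + marginal
#'   coverage), `curve` (data frame `n_donors`, `fraction`), `donor_order`,
#'   `config`, `seed`.
#' @export
cohort_coverage <- function(donors, recipients, cfg = compatibility_config(),
                            seed = NULL, exclude_self = FALSE) {
  if (nrow(donors) == 0L) stop("empty donor cohort", call. = FALSE)
  if (nrow(recipients) == 0L) stop("empty recipient cohort", call. = FALSE)
  dcalls <- .truncated_calls(donors, cfg$k)
  rcalls <- .truncated_calls(recipients, cfg$k)
  nd <- nrow(donors); nr <- nrow(recipients)
  if (!is.null(seed)) set.seed(seed)
  ord <- sample.int(nd)
  matched <- rep(FALSE, nr)
  curve_fraction <- numeric(nd)
  per_donor <- numeric(nd)
  for (step in seq_len(nd)) {
    d <- ord[step]
    drow <- lapply(dcalls, function(mm) mm[d, ])
    ok <- if (length(cfg$retained) == 0L) rep(TRUE, nr) else
      .donor_match_vec(drow, rcalls, cfg)
    if (exclude_self) ok[recipients$id == donors$id[d]] <- FALSE
    per_donor[d] <- mean(ok)
    matched <- matched | ok
    curve_fraction[step] <- mean(matched)
  }
  structure(list(
    fraction_matched = mean(matched),
    n_matched = sum(matched),
    n_recipients = nr,
    per_donor = data.frame(id = donors$id, coverage = per_donor,
                           stringsAsFactors = FALSE),
    curve = data.frame(n_donors = seq_len(nd), fraction = curve_fraction),
    donor_order = donors$id[ord],
    config = cfg,
    seed = seed
  ), class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat("<coverage_result> ", x$n_matched, "/", x$n_recipients,
      " recipients matched (", sprintf("%.2f%%", 100 * x$fraction_matched),
      ") by ", nrow(x$per_donor), " donors; retained {",
      paste(x$config$retained, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Coverage of random donor subsets (stochastic baseline)
#'
#' Repeatedly draws a subset of the cohort without replacement and measures
#' its coverage of the full cohort, giving the baseline against which
#' homozygote-enriched panels are compared.
#'
#' @param cohort an [hla_cohort()] serving as both donor pool and recipient
#'   population.
#' @param subset_size donors per replicate (`<= nrow(cohort)`).
#' @param cfg a [compatibility_config()].
#' @param n_reps number of replicates (>= 1).
#' @param seed RNG seed.
#' @param exclude_self passed to the coverage computation.
#' @return List with `fractions` (per replicate), `mean`, `sd`,
#'   `subset_size`, `n_reps`, `seed`.
#' @export
random_subset_baseline <- function(cohort, subset_size, cfg = compatibility_config(),
                                   n_reps = 100L, seed = NULL,
                                   exclude_self = FALSE) {
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  if (subset_size > nrow(cohort)) {
    stop("subset_size exceeds cohort size", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  calls <- .truncated_calls(cohort, cfg$k)
  nr <- nrow(cohort)
  fractions <- vapply(seq_len(n_reps), function(rep_i) {
    idx <- sample.int(nr, subset_size)
    matched <- rep(FALSE, nr)
    for (d in idx) {
      if (all(matched)) break
      drow <- lapply(calls, function(mm) mm[d, ])
      ok <- if (length(cfg$retained) == 0L) rep(TRUE, nr) else
        .donor_match_vec(drow, calls, cfg)
      if (exclude_self) ok[d] <- FALSE
      matched <- matched | ok
    }
    mean(matched)
  }, 0)
  list(fractions = fractions, mean = mean(fractions), sd = stats::sd(fractions),
       subset_size = as.integer(subset_size), n_reps = as.integer(n_reps),
       seed = seed)
}

#' Expected number of triple homozygotes under linkage equilibrium
#'
#' Simulates registries of `n` individuals by independent-locus
#' Hardy--Weinberg sampling from the measured per-gene allele frequencies and
#' counts triple homozygotes per replicate. Under this null the closed-form
#' expectation is \eqn{n \prod_g \sum_i p_{g,i}^2}; an observed excess over
#' the simulated distribution indicates population structure (autozygosity).
#'
#' @param freqs named list `A`, `B`, `C` of frequency tables or named numeric
#'   vectors.
#' @param n individuals per simulated registry.
#' @param n_reps replicates (default 1000).
#' @param seed RNG seed.
#' @return List with `mean`, `sd`, `closed_form`, `replicates`.
#' @export
expected_triple_homozygotes <- function(freqs, n, n_reps = 1000L, seed = NULL) {
  if (n < 1L || n_reps < 1L) stop("n and n_reps must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p_list <- lapply(stats::setNames(CLASS_I_GENES, CLASS_I_GENES),
                   function(g) .freq_vector(freqs[[g]]))
  hom_all <- rep(TRUE, n * n_reps)
  for (g in CLASS_I_GENES) {
    p <- p_list[[g]]
    a1 <- sample.int(length(p), n * n_reps, replace = TRUE, prob = p)
    a2 <- sample.int(length(p), n * n_reps, replace = TRUE, prob = p)
    hom_all <- hom_all & (a1 == a2)
  }
  counts <- colSums(matrix(hom_all, nrow = n, ncol = n_reps))
  closed_form <- n * prod(vapply(p_list, function(p) sum(p^2), 0))
  list(mean = mean(counts), sd = stats::sd(counts),
       closed_form = closed_form, replicates = counts)
}
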