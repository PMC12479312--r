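#' Read a published allele-frequency table
#'
#' CSV with columns `allele,frequency` (one file per gene per population).
#'
#' @param path file path.
#' @param gene optional locus check.
#' @return An `hla_freq_table` (frequencies renormalized to sum to 1).
#' @export
read_freq_table <- function(path, gene = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("allele", "frequency") %in% names(df))) {
    stop(path, ": expected columns allele, frequency", call. = FALSE)
  }
  freq_table(df$allele, as.numeric(df$frequency), gene = gene)
}

#' Write a frequency table to CSV
#'
#' Columns `allele,count,frequency` (count may be NA for published tables).
#'
#' @param freq an `hla_freq_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(freq, path) {
  utils::write.csv(as.data.frame(freq)[c("allele", "count", "frequency")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Ordinary least-squares regression of one frequency table on another
#'
#' Fits `f2 ~ m * f1 + c` over the union of alleles of the two tables;
#' alleles absent from one table enter with frequency 0. Used to compare a
#' registry's allele composition against a published population.
#'
#' @param f1,f2 frequency tables (`hla_freq_table`, data frame with
#'   `allele`/`frequency`, or named numeric) for the same gene.
#' @return List with `slope`, `intercept`, `r_squared`, `n_alleles`, and the
#'   paired `data` used for the fit.
#' @export
regress_frequencies <- function(f1, f2) {
  g1 <- attr(f1, "gene"); g2 <- attr(f2, "gene")
  if (!is.null(g1) && !is.null(g2) && !identical(g1, g2)) {
    stop("frequency tables are for different genes: HLA-", g1, " vs HLA-", g2,
         call. = FALSE)
  }
  # raw values as given: a table that does not sum to 1 (e.g. a rescaled or
  # partial published list) is regressed as-is, not renormalized
  p1 <- .freq_vector_raw(f1); p2 <- .freq_vector_raw(f2)
  alleles <- sort_alleles(union(names(p1), names(p2)))
  x <- ifelse(alleles %in% names(p1), p1[alleles], 0)
  y <- ifelse(alleles %in% names(p2), p2[alleles], 0)
  if (length(alleles) < 2L || stats::var(x) == 0) {
    stop("need at least 2 support points with varying frequency", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       n_alleles = length(alleles),
       data = data.frame(allele = alleles, f1 = x, f2 = y,
                         stringsAsFactors = FALSE))
}

#' Simulate a population cohort from per-gene allele frequencies
#'
#' Monte Carlo reconstruction of genotypes from published allele-frequency
#' tables: for each individual and each gene independently, two allele calls
#' are drawn i.i.d. from the gene's frequency distribution. Between-gene
#' linkage is therefore ignored, exactly as in frequency-only reconstruction;
#' to simulate linked genes draw from a haplotype pool instead
#' ([sample_registry()]).
#'
#' @param freqs named list with elements `A`, `B`, `C`, each a frequency
#'   table or named numeric vector (renormalized to sum to 1).
#' @param n number of individuals (> 0).
#' @param seed RNG seed for reproducibility (optional).
#' @param label cohort label.
#' @return An [hla_cohort()] of `n` simulated individuals.
#' @export
monte_carlo_population <- function(freqs, n, seed = NULL, label = "simulated") {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (!all(CLASS_I_GENES %in% names(freqs))) {
    stop("freqs must be a list with elements A, B, C", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cols <- list(id = sprintf("%s_%06d", label, seq_len(n)))
  for (gene in CLASS_I_GENES) {
    p <- .freq_vector(freqs[[gene]])
    names(p) <- canonical_alleles(names(p), gene = gene)
    draws <- sample(names(p), 2L * n, replace = TRUE, prob = p)
    cols[[paste0(gene, "_1")]] <- draws[seq_len(n)]
    cols[[paste0(gene, "_2")]] <- draws[n + seq_len(n)]
  }
  hla_cohort(as.data.frame(cols, stringsAsFactors = FALSE), label = label)
}

#' One-hot encode cohorts by allele carriage
#'
#' One row per individual, one column per (gene, allele at resolution `k`)
#' over the union of all cohorts. The default encoding is presence/absence:
#' the entry is 1 when the individual carries at least one copy of the
#' allele. Homozygosity is therefore not recoverable from the encoding; use
#' `mode = "dosage"` (entries 0/1/2) to retain it.
#'
#' @param cohorts an [hla_cohort()] or list of cohorts.
#' @param k field resolution.
#' @param mode `"presence"` (default) or `"dosage"`.
#' @return List with `matrix` (numeric, rownames = individual ids), `labels`
#'   (cohort label per row) and `legend` (data frame gene/allele per column).
#' @export
one_hot <- function(cohorts, k = 3L, mode = c("presence", "dosage")) {
  mode <- match.arg(mode)
  if (inherits(cohorts, "hla_cohort")) cohorts <- list(cohorts)
  if (length(cohorts) == 0L) stop("need at least one cohort", call. = FALSE)
  trunc_calls <- lapply(cohorts, function(co) {
    lapply(stats::setNames(CLASS_I_GENES, CLASS_I_GENES), function(g) {
      cbind(truncate_resolution(co[[paste0(g, "_1")]], k),
            truncate_resolution(co[[paste0(g, "_2")]], k))
    })
  })
  legend <- do.call(rbind, lapply(CLASS_I_GENES, function(g) {
    alleles <- sort_alleles(unique(unlist(lapply(trunc_calls, function(tc) tc[[g]]))))
    data.frame(gene = g, allele = alleles, stringsAsFactors = FALSE)
  }))
  col_of <- stats::setNames(seq_len(nrow(legend)), legend$allele)
  n_total <- sum(vapply(cohorts, nrow, 0L))
  m <- matrix(0, n_total, nrow(legend),
              dimnames = list(NULL, legend$allele))
  labels <- character(n_total)
  ids <- character(n_total)
  row0 <- 0L
  for (ci in seq_along(cohorts)) {
    co <- cohorts[[ci]]
    rows <- row0 + seq_len(nrow(co))
    for (g in CLASS_I_GENES) {
      calls <- trunc_calls[[ci]][[g]]
      for (slot in 1:2) {
        idx <- cbind(rows, col_of[calls[, slot]])
        if (mode == "dosage") {
          m[idx] <- m[idx] + 1
        } else {
          m[idx] <- 1
        }
      }
    }
    labels[rows] <- cohort_label(co)
    ids[rows] <- co$id
    row0 <- row0 + nrow(co)
  }
  rownames(m) <- make.unique(ids)
  list(matrix = m, labels = labels, legend = legend)
}

#' PCA embedding with population centroids and centroid distances
#'
#' Columns are mean-centered (no variance scaling; presence/absence columns
#' are already on a common scale) and principal components are taken from the
#' singular value decomposition. Per-population centroids are means of PC
#' coordinates, and pairwise centroid distances are Euclidean in PC space,
#' optionally normalized so a chosen pair has distance 1.
#'
#' @param x numeric matrix (e.g. `one_hot()$matrix`), rows = individuals.
#' @param labels population label per row.
#' @param n_components number of PCs to keep (default 2).
#' @param normalize_to optional character pair of labels whose distance is
#'   scaled to 1 in `distances_normalized`.
#' @return Object of class `population_embedding`: list with `scores`
#'   (data frame label + PCs), `centroids` (matrix), `distances` (symmetric
#'   matrix, zero diagonal), optionally `distances_normalized`, and `sdev`.
#' @export
pca_centroids <- function(x, labels, n_components = 2L, normalize_to = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows", call. = FALSE)
  if (length(labels) != nrow(x)) stop("one label per row required", call. = FALSE)
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(xc) < 1e-12)) {
    warning("all rows identical: zero-variance embedding, distances are 0")
    scores <- matrix(0, nrow(x), n_components,
                     dimnames = list(NULL, paste0("PC", seq_len(n_components))))
    sdev <- rep(0, n_components)
  } else {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    keep <- seq_len(min(n_components, ncol(pc$x)))
    scores <- pc$x[, keep, drop = FALSE]
    sdev <- pc$sdev[keep]
    if (length(keep) < n_components) {
      warning("matrix rank supports only ", length(keep), " components")
    }
  }
  labs <- sort(unique(labels))
  centroids <- do.call(rbind, lapply(labs, function(l) {
    colMeans(scores[labels == l, , drop = FALSE])
  }))
  rownames(centroids) <- labs
  distances <- as.matrix(stats::dist(centroids))
  out <- list(scores = data.frame(label = labels, scores,
                                  stringsAsFactors = FALSE),
              centroids = centroids, distances = distances, sdev = sdev)
  if (!is.null(normalize_to)) {
    ref <- distances[normalize_to[1L], normalize_to[2L]]
    if (ref <= 0) stop("reference pair has zero distance; cannot normalize",
                       call. = FALSE)
    out$distances_normalized <- distances / ref
  }
  structure(out, class = "population_embedding")
}

#' @export
print.population_embedding <- function(x, ...) {
  cat("<population_embedding> ", nrow(x$scores), " individuals, ",
      nrow(x$centroids), " populations, ", ncol(x$centroids), " PCs\n", sep = "")
  cat("centroid distances:\n")
  print(round(x$distances, 3))
  invisible(x)
}
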