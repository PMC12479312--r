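.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract SpCas9 target sites from a gene sequence
#'
#' Scans both strands for every 20-nt protospacer immediately followed by an
#' NGG PAM, and records for each site its 30-nt scoring context (4 nt
#' upstream, protospacer, PAM, 3 nt downstream, on the site's own strand) and
#' its blunt cut position (between protospacer positions 17 and 18, i.e. 3 bp
#' 5' of the PAM), expressed on the plus strand. Sites whose 30-mer context
#' would run off either sequence end are dropped from the result and counted
#' in the `n_dropped_no_context` attribute. Minus-strand sites are reported
#' with plus-strand coordinates via reverse complement.
#'
#' @param x an [annotated_gene()] or a plain A/C/G/T sequence string.
#' @param score compute Rule Set 1 activity scores (default `TRUE`).
#' @return Data frame of class `guide_sites` with columns `allele`, `strand`
#'   (`"+"`/`"-"`), `proto_start` (1-based plus-strand position of the
#'   leftmost protospacer base), `cut_pos` (0-based plus-strand boundary: the
#'   cut falls between positions `cut_pos` and `cut_pos + 1` in 1-based
#'   terms), `protospacer`, `pam`, `context30`, `score`. Attribute
#'   `n_dropped_no_context` counts discarded edge sites.
#' @export
find_cas9_sites <- function(x, score = TRUE) {
  if (inherits(x, "annotated_gene")) {
    seq <- x$sequence
    allele <- x$allele
  } else {
    seq <- toupper(as.character(x))
    allele <- NA_character_
  }
  .check_acgt(seq)
  L <- nchar(seq)
  scan_strand <- function(s) {
    # 20-mer protospacer + N + GG, zero-width lookahead to catch overlaps
    m <- gregexpr("(?=[ACGT]{21}GG)", s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m)
  }
  rc <- .revcomp(seq)
  plus_i <- if (L >= 23L) scan_strand(seq) else integer(0)
  minus_j <- if (L >= 23L) scan_strand(rc) else integer(0)
  has_ctx_plus <- plus_i - 4L >= 1L & plus_i + 25L <= L
  has_ctx_minus <- minus_j - 4L >= 1L & minus_j + 25L <= L
  n_dropped <- sum(!has_ctx_plus) + sum(!has_ctx_minus)
  ip <- plus_i[has_ctx_plus]; mj <- minus_j[has_ctx_minus]
  sub_many <- function(s, first, last) {
    if (length(first) == 0L) character(0) else substring(s, first, last)
  }
  plus_df <- data.frame(
    allele = rep(allele, length(ip)), strand = rep("+", length(ip)),
    proto_start = ip,
    cut_pos = ip + 16L,                       # 0-based boundary (i-1)+17
    protospacer = sub_many(seq, ip, ip + 19L),
    pam = sub_many(seq, ip + 20L, ip + 22L),
    context30 = sub_many(seq, ip - 4L, ip + 25L),
    stringsAsFactors = FALSE)
  minus_df <- data.frame(
    allele = rep(allele, length(mj)), strand = rep("-", length(mj)),
    proto_start = L - mj - 18L,               # 1-based leftmost base, plus strand
    cut_pos = L - (mj + 16L),                 # boundary mapped through revcomp
    protospacer = sub_many(rc, mj, mj + 19L),
    pam = sub_many(rc, mj + 20L, mj + 22L),
    context30 = sub_many(rc, mj - 4L, mj + 25L),
    stringsAsFactors = FALSE)
  out <- rbind(plus_df, minus_df)
  out <- out[order(out$cut_pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$score <- if (score && nrow(out) > 0L) ruleset1_score(out$context30)
               else rep(NA_real_, nrow(out))
  structure(out, n_dropped_no_context = n_dropped,
            class = c("guide_sites", "data.frame"))
}

#' Flag sites by gene region and activity
#'
#' Region membership is decided by the cut position (the frameshift site
#' governs knockout efficacy): `in_exon` when the cut falls strictly inside
#' an exon; `in_ectodomain` when, additionally, the cut lies 5' of the first
#' nucleotide of the codon of the first transmembrane residue (cuts there can
#' abolish surface expression); `high_activity` when the site is in the
#' ectodomain and its Rule Set 1 score exceeds `score_threshold`. The flags
#' are nested: `high_activity` implies `in_ectodomain` implies `in_exon`
#' implies `in_gene_body`.
#'
#' @param sites a `guide_sites` data frame from [find_cas9_sites()].
#' @param gene the [annotated_gene()] the sites were extracted from.
#' @param score_threshold activity cutoff for `high_activity` (default 0.5).
#' @return `sites` with added logical columns `in_gene_body`, `in_exon`,
#'   `in_ectodomain`, `high_activity`.
#' @export
annotate_site_regions <- function(sites, gene, score_threshold = 0.5) {
  stopifnot(inherits(gene, "annotated_gene"))
  cut0 <- sites$cut_pos
  in_exon <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(gene$exons))) {
    in_exon <- in_exon |
      (cut0 > gene$exons$start[i] & cut0 < gene$exons$end[i])
  }
  tm_nt <- .tm_first_nt(gene)
  sites$in_gene_body <- rep(TRUE, nrow(sites))
  sites$in_exon <- in_exon
  sites$in_ectodomain <- in_exon & (cut0 < tm_nt)
  sites$high_activity <- sites$in_ectodomain &
    !is.na(sites$score) & sites$score > score_threshold
  sites
}

#' Extract, score and annotate sites for a panel of alleles
#'
#' Runs [find_cas9_sites()] and [annotate_site_regions()] over a list of
#' annotated genes and binds the results.
#'
#' @param genes list of [annotated_gene()] objects.
#' @param score_threshold activity cutoff (default 0.5).
#' @return A `guide_sites` data frame with region flags and an `allele`
#'   column.
#' @export
design_guides <- function(genes, score_threshold = 0.5) {
  parts <- lapply(genes, function(g) {
    annotate_site_regions(find_cas9_sites(g), g,
                          score_threshold = score_threshold)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  structure(out, class = c("guide_sites", "data.frame"))
}

#' Deduplicate sites across alleles and count the cascade stages
#'
#' Uniqueness is keyed on the protospacer + PAM string: the same 23-mer found
#' in several alleles (or at several positions) counts once. Region flags are
#' OR-combined over occurrences (a site counts at a stage when any allele
#' places it there) and the retained representative carries the maximum
#' score, so the nested stage counts `gene_body >= exon >= ectodomain >=
#' high_activity` summarize the whole panel.
#'
#' @param sites annotated `guide_sites` (e.g. from [design_guides()]),
#'   possibly spanning many alleles of one gene.
#' @return List with `sites` (one row per unique protospacer+PAM) and
#'   `counts` (named integer vector `gene_body`, `exon`, `ectodomain`,
#'   `high_activity`).
#' @export
unique_sites_across_alleles <- function(sites) {
  needed <- c("protospacer", "pam", "in_gene_body", "in_exon",
              "in_ectodomain", "high_activity")
  if (!all(needed %in% names(sites))) {
    stop("sites must be annotated (see annotate_site_regions)", call. = FALSE)
  }
  key <- paste0(sites$protospacer, sites$pam)
  ord <- order(key, -xtfrm(sites$score))
  sites <- sites[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  agg <- function(v) as.logical(tapply(v, key, any)[key[first]])
  uniq <- sites[first, , drop = FALSE]
  uniq$in_gene_body <- agg(sites$in_gene_body)
  uniq$in_exon <- agg(sites$in_exon)
  uniq$in_ectodomain <- agg(sites$in_ectodomain)
  uniq$high_activity <- agg(sites$high_activity)
  rownames(uniq) <- NULL
  counts <- c(gene_body = sum(uniq$in_gene_body),
              exon = sum(uniq$in_exon),
              ectodomain = sum(uniq$in_ectodomain),
              high_activity = sum(uniq$high_activity))
  list(sites = structure(uniq, class = c("guide_sites", "data.frame")),
       counts = counts)
}

#' Remove candidates that also occur in HLA-C
#'
#' For HLA-C-retained engineering, guides against HLA-A or HLA-B must not cut
#' HLA-C. A candidate is removed when its protospacer + PAM occurs verbatim,
#' on either strand, anywhere in any supplied HLA-C allele sequence.
#'
#' @param candidates a `guide_sites` data frame (HLA-A/HLA-B candidates).
#' @param hla_c_sequences character vector of HLA-C sequences, a
#'   `DNAStringSet`, or a list of [annotated_gene()]s.
#' @return The surviving subset of `candidates`.
#' @export
spare_hla_c_filter <- function(candidates, hla_c_sequences) {
  seqs <- if (is.list(hla_c_sequences) &&
              all(vapply(hla_c_sequences, inherits, TRUE, "annotated_gene"))) {
    vapply(hla_c_sequences, function(g) g$sequence, "")
  } else {
    toupper(as.character(hla_c_sequences))
  }
  if (nrow(candidates) == 0L) return(candidates)
  mers <- paste0(candidates$protospacer, candidates$pam)
  hit <- rep(FALSE, length(mers))
  for (s in seqs) {
    srev <- .revcomp(s)
    hit <- hit |
      vapply(mers, function(m) {
        grepl(m, s, fixed = TRUE) || grepl(m, srev, fixed = TRUE)
      }, TRUE)
    if (all(hit)) break
  }
  out <- candidates[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
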