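# Lenient IPD-IMGT/HLA-style FASTA header parsing: headers such as
# "HLA:HLA00001 A*01:01:01:01 3503 bp" yield the allele token; otherwise the
# first whitespace-separated token is used as the identifier.
.fasta_allele_name <- function(header) {
  tokens <- strsplit(trimws(header), "\\s+")[[1L]]
  hit <- tokens[grepl(.ALLELE_REGEX, toupper(tokens))]
  if (length(hit) >= 1L) canonical_alleles(hit[1L]) else tokens[1L]
}

#' Read annotated gene sequences from FASTA + annotation tables
#'
#' @param fasta_path FASTA of allele gene sequences (IPD-IMGT/HLA-style
#'   headers parsed leniently).
#' @param exons_path TSV with columns `allele`, `start`, `end`, `exon_index`
#'   (0-based half-open) and, optionally, `cds_start`, `cds_length`
#'   (constant per allele; defaults: CDS spans the whole spliced transcript).
#' @param tm_path TSV with columns `allele_or_gene`, `tm_start_res`,
#'   `tm_end_res`, `includes_signal_peptide` (`yes`/`no`) and, when `no`,
#'   `signal_peptide_len`. An entry keyed by locus (`A`, `B`, `C`) is the
#'   fallback for alleles without their own row.
#' @return Named list of [annotated_gene()] objects.
#' @export
read_gene_annotations <- function(fasta_path, exons_path, tm_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  alleles <- vapply(names(seqs), .fasta_allele_name, "")
  exons <- utils::read.delim(exons_path, stringsAsFactors = FALSE)
  need <- c("allele", "start", "end", "exon_index")
  if (!all(need %in% names(exons))) {
    stop(exons_path, ": expected columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tm <- utils::read.delim(tm_path, stringsAsFactors = FALSE)
  need_tm <- c("allele_or_gene", "tm_start_res", "tm_end_res",
               "includes_signal_peptide")
  if (!all(need_tm %in% names(tm))) {
    stop(tm_path, ": expected columns ", paste(need_tm, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (i in seq_along(seqs)) {
    al <- alleles[i]
    ex <- exons[exons$allele == al, , drop = FALSE]
    if (nrow(ex) == 0L) stop("no exon annotation for allele ", al, call. = FALSE)
    ex <- ex[order(ex$exon_index), , drop = FALSE]
    spliced_len <- sum(ex$end - ex$start)
    cds_start <- if ("cds_start" %in% names(ex)) ex$cds_start[1L] else 0L
    cds_length <- if ("cds_length" %in% names(ex)) ex$cds_length[1L] else
      spliced_len - spliced_len %% 3L
    tm_row <- tm[tm$allele_or_gene == al, , drop = FALSE]
    if (nrow(tm_row) == 0L) {
      locus <- sub("\\*.*$", "", al)
      tm_row <- tm[.norm_gene_safe(tm$allele_or_gene) == .norm_gene_safe(locus), ,
                   drop = FALSE]
    }
    if (nrow(tm_row) == 0L) stop("no transmembrane annotation for allele ", al,
                                 call. = FALSE)
    on_mature <- tolower(tm_row$includes_signal_peptide[1L]) %in% c("no", "false")
    sp_len <- 0L
    if (on_mature) {
      if (!"signal_peptide_len" %in% names(tm_row) ||
          is.na(tm_row$signal_peptide_len[1L])) {
        stop("transmembrane span on mature protein requires signal_peptide_len",
             call. = FALSE)
      }
      sp_len <- as.integer(tm_row$signal_peptide_len[1L])
    }
    out[[al]] <- annotated_gene(
      allele = al, sequence = as.character(seqs[[i]]),
      exons = ex[c("start", "end")],
      cds_start = cds_start, cds_length = cds_length,
      tm_span = c(tm_row$tm_start_res[1L], tm_row$tm_end_res[1L]),
      tm_on_mature = on_mature, signal_peptide_len = sp_len)
  }
  out
}

.norm_gene_safe <- function(x) toupper(sub("^HLA-", "", as.character(x)))

#' Write annotated genes to FASTA + annotation tables
#'
#' Inverse of [read_gene_annotations()]; the three files round-trip.
#'
#' @param genes list of [annotated_gene()] objects.
#' @param fasta_path,exons_path,tm_path output paths.
#' @return Invisibly, the three paths.
#' @export
write_gene_annotations <- function(genes, fasta_path, exons_path, tm_path) {
  seqs <- Biostrings::DNAStringSet(vapply(genes, function(g) g$sequence, ""))
  names(seqs) <- vapply(genes, function(g) g$allele, "")
  Biostrings::writeXStringSet(seqs, fasta_path)
  exons <- do.call(rbind, lapply(genes, function(g) {
    data.frame(allele = g$allele, start = g$exons$start, end = g$exons$end,
               exon_index = seq_len(nrow(g$exons)) - 1L,
               cds_start = g$cds_start, cds_length = g$cds_length,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(exons, exons_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tm <- do.call(rbind, lapply(genes, function(g) {
    data.frame(allele_or_gene = g$allele,
               tm_start_res = g$tm_span[1L], tm_end_res = g$tm_span[2L],
               includes_signal_peptide = if (g$tm_on_mature) "no" else "yes",
               signal_peptide_len = g$signal_peptide_len,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tm, tm_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, exons_path, tm_path))
}

#' Write a per-site guide table
#'
#' Human-facing TSV: coordinates are 1-based; `cut_after` is the plus-strand
#' position of the base immediately 5' of the blunt cut.
#'
#' @param sites a `guide_sites` data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_guide_sites <- function(sites, path) {
  out <- as.data.frame(sites)
  out$cut_after <- out$cut_pos  # 0-based boundary == 1-based position of 5' base
  out$cut_pos <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
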