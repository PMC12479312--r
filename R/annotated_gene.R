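#' Annotated gene sequence for guide design
#'
#' Container for an allele's genomic sequence (plus strand, 5'UTR through
#' 3'UTR) together with its exon structure, CDS placement and transmembrane
#' span, the inputs of the guide-design cascade. Coordinates are 0-based
#' half-open internally.
#'
#' @param allele allele name (canonicalized) or free-text identifier.
#' @param sequence nucleotide string (A/C/G/T).
#' @param exons data frame with columns `start`, `end` (0-based half-open,
#'   ascending, non-overlapping) on `sequence`.
#' @param cds_start 0-based offset of the CDS start within the *spliced*
#'   transcript (i.e. the 5'UTR length measured on exons).
#' @param cds_length CDS length in nucleotides; must be divisible by 3.
#' @param tm_span integer pair: 1-based inclusive residue interval of the
#'   transmembrane helix.
#' @param tm_on_mature `TRUE` when `tm_span` is given on the mature protein
#'   (signal peptide removed); then `signal_peptide_len` shifts it onto the
#'   full translated CDS.
#' @param signal_peptide_len signal peptide length in residues (used when
#'   `tm_on_mature`).
#' @return Object of class `annotated_gene`.
#' @export
annotated_gene <- function(allele, sequence, exons, cds_start, cds_length,
                           tm_span, tm_on_mature = FALSE,
                           signal_peptide_len = 0L) {
  sequence <- toupper(as.character(sequence))
  .check_acgt(sequence)
  exons <- as.data.frame(exons)[c("start", "end")]
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  if (nrow(exons) == 0L) stop("at least one exon required", call. = FALSE)
  if (any(exons$end <= exons$start)) stop("empty or inverted exon interval",
                                          call. = FALSE)
  if (is.unsorted(exons$start, strictly = TRUE) ||
      any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop("exons must be ascending and non-overlapping", call. = FALSE)
  }
  if (min(exons$start) < 0L || max(exons$end) > nchar(sequence)) {
    stop("exon interval outside the sequence", call. = FALSE)
  }
  spliced_len <- sum(exons$end - exons$start)
  cds_start <- as.integer(cds_start); cds_length <- as.integer(cds_length)
  if (cds_length %% 3L != 0L) stop("CDS length must be divisible by 3",
                                   call. = FALSE)
  if (cds_start < 0L || cds_start + cds_length > spliced_len) {
    stop("CDS does not fit inside the spliced exons", call. = FALSE)
  }
  protein_len <- cds_length %/% 3L
  tm_span <- as.integer(tm_span)
  tm_cds <- tm_span + if (tm_on_mature) as.integer(signal_peptide_len) else 0L
  if (length(tm_span) != 2L || tm_span[1L] > tm_span[2L] || tm_cds[1L] < 1L ||
      tm_cds[2L] > protein_len) {
    stop("transmembrane span outside the protein (length ", protein_len, ")",
         call. = FALSE)
  }
  structure(list(allele = allele, sequence = sequence, exons = exons,
                 cds_start = cds_start, cds_length = cds_length,
                 tm_span = tm_span, tm_on_mature = isTRUE(tm_on_mature),
                 signal_peptide_len = as.integer(signal_peptide_len),
                 protein_length = protein_len,
                 tm_span_cds = tm_cds),
            class = "annotated_gene")
}

#' @export
print.annotated_gene <- function(x, ...) {
  cat("<annotated_gene> ", x$allele, ": ", nchar(x$sequence), " nt, ",
      nrow(x$exons), " exons, CDS ", x$cds_length, " nt (",
      x$protein_length, " aa), TM residues ", x$tm_span_cds[1L], "-",
      x$tm_span_cds[2L], "\n", sep = "")
  invisible(x)
}

.check_acgt <- function(seq) {
  bad <- gregexpr("[^ACGT]", seq)[[1L]]
  if (bad[1L] != -1L) {
    stop("non-ACGT character(s) at position(s) ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# map spliced-transcript 0-based positions to genomic 0-based positions
.spliced_to_genomic <- function(gene, spliced_pos) {
  widths <- gene$exons$end - gene$exons$start
  cum <- cumsum(c(0L, widths))
  exon_idx <- findInterval(spliced_pos, cum, rightmost.closed = FALSE,
                           left.open = FALSE)
  # findInterval with vec cum: position p in exon i when cum[i] <= p < cum[i+1]
  gene$exons$start[exon_idx] + (spliced_pos - cum[exon_idx])
}

#' Genomic interval(s) of a codon
#'
#' Maps a 1-based residue index of the translated CDS (signal peptide
#' included) to the genomic positions of its codon, through the exon
#' structure. Codons split across an exon junction yield two intervals whose
#' lengths sum to 3.
#'
#' @param gene an [annotated_gene()].
#' @param residue_index 1-based residue position, within the protein length.
#' @return Data frame `start`, `end` (0-based half-open, ascending) covering
#'   exactly 3 nucleotides.
#' @export
protein_to_cds_coordinate <- function(gene, residue_index) {
  residue_index <- as.integer(residue_index)
  if (length(residue_index) != 1L || is.na(residue_index) ||
      residue_index < 1L || residue_index > gene$protein_length) {
    stop("residue index out of range 1..", gene$protein_length, call. = FALSE)
  }
  spliced <- gene$cds_start + (residue_index - 1L) * 3L + 0:2
  genomic <- .spliced_to_genomic(gene, spliced)
  # merge consecutive genomic positions into intervals
  breaks <- c(TRUE, diff(genomic) != 1L)
  grp <- cumsum(breaks)
  starts <- tapply(genomic, grp, min)
  ends <- tapply(genomic, grp, max) + 1L
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

# genomic 0-based position of the first nucleotide of the codon of the first
# transmembrane residue (on the full translated CDS)
.tm_first_nt <- function(gene) {
  protein_to_cds_coordinate(gene, gene$tm_span_cds[1L])$start[1L]
}

# is a genomic 0-based position inside any exon?
.pos_in_exon <- function(gene, pos) {
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(gene$exons))) {
    hit <- hit | (pos >= gene$exons$start[i] & pos < gene$exons$end[i])
  }
  hit
}
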