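COHORT_COLUMNS <- c("id", "A_1", "A_2", "B_1", "B_2", "C_1", "C_2")

#' Construct a genotype cohort
#'
#' A cohort is a data frame with one row per individual and two allele calls
#' per HLA class I gene. Allele names are canonicalized on construction and
#' checked against their column's locus. The `_1`/`_2` columns carry no phase
#' information: calls at a gene are an unordered pair.
#'
#' @param df data frame with columns `id, A_1, A_2, B_1, B_2, C_1, C_2`.
#' @param label optional cohort label (stored as an attribute).
#' @return A data frame of class `hla_cohort`.
#' @examples
#' hla_cohort(data.frame(id = "x1",
#'                       A_1 = "A*02:01:01", A_2 = "A*03:01:01",
#'                       B_1 = "B*07:02:01", B_2 = "B*07:02:01",
#'                       C_1 = "C*07:02:01", C_2 = "C*07:01:01"))
#' @export
hla_cohort <- function(df, label = "cohort") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[COHORT_COLUMNS]
  df$id <- as.character(df$id)
  dup <- df$id[duplicated(df$id)]
  if (length(dup) > 0L) {
    stop("duplicate individual id(s) in cohort: ",
         paste(unique(utils::head(dup, 5L)), collapse = ", "), call. = FALSE)
  }
  for (gene in CLASS_I_GENES) {
    for (slot in 1:2) {
      col <- paste0(gene, "_", slot)
      df[[col]] <- tryCatch(
        canonical_alleles(df[[col]], gene = gene),
        error = function(e) {
          stop("column ", col, ": ", conditionMessage(e), call. = FALSE)
        })
    }
  }
  rownames(df) <- NULL
  structure(df, label = label, class = c("hla_cohort", "data.frame"))
}

#' @export
print.hla_cohort <- function(x, ...) {
  cat("<hla_cohort> '", attr(x, "label"), "': ", nrow(x), " individuals\n", sep = "")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

cohort_label <- function(cohort) {
  attr(cohort, "label") %||% "cohort"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a genotype registry from CSV/TSV
#'
#' Expects a header with columns `id, A_1, A_2, B_1, B_2, C_1, C_2`.
#' Complete typing is assumed: missing values are an error. The separator is
#' taken from the file extension (`.tsv`/`.txt` tab, otherwise comma) unless
#' given explicitly.
#'
#' @param path file path.
#' @param sep field separator, or `NULL` to infer from the extension.
#' @param label cohort label; defaults to the file name.
#' @return An [hla_cohort()].
#' @export
read_cohort <- function(path, sep = NULL, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = TRUE, quote = "\"", comment.char = "")
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[COHORT_COLUMNS]
  na_like <- df == "" | toupper(as.matrix(df)) == "NA"
  if (any(na_like)) {
    bad_row <- which(apply(na_like, 1L, any))[1L]
    stop(path, ": empty or NA entry at data row ", bad_row,
         " (complete typing required)", call. = FALSE)
  }
  # re-validate per row so errors carry the offending data row number
  for (gene in CLASS_I_GENES) {
    for (slot in 1:2) {
      col <- paste0(gene, "_", slot)
      ok <- grepl(.ALLELE_REGEX, toupper(trimws(df[[col]])))
      if (!all(ok)) {
        bad <- which(!ok)[1L]
        stop(path, ": unparseable allele '", df[[col]][bad], "' in column ",
             col, ", data row ", bad, call. = FALSE)
      }
    }
  }
  dup <- df$id[duplicated(df$id)]
  if (length(dup) > 0L) {
    stop(path, ": duplicate id '", dup[1L], "' (data row ",
         which(duplicated(df$id))[1L], ")", call. = FALSE)
  }
  hla_cohort(df, label = label %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a cohort to CSV/TSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, p))` reproduces
#' `x` row for row (alleles are stored canonically).
#'
#' @param cohort an [hla_cohort()].
#' @param path output file; extension picks the separator as in [read_cohort()].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(cohort), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-individual homozygosity at one gene
#'
#' An individual is homozygous at `gene` when its two calls are identical
#' after truncation to `k` fields; call order is irrelevant. Suffixed alleles
#' (e.g. null `N` variants) compare as distinct from their unsuffixed
#' namesakes.
#'
#' @param cohort an [hla_cohort()] (a single-row cohort works for one
#'   genotype).
#' @param gene `"A"`, `"B"` or `"C"` (optionally `"HLA-"`-prefixed).
#' @param k field resolution for the comparison (default 3, the registry
#'   resolution).
#' @return Logical vector, one element per individual.
#' @export
is_homozygous <- function(cohort, gene, k = 3L) {
  gene <- .norm_gene(gene)
  a1 <- truncate_resolution(cohort[[paste0(gene, "_1")]], k)
  a2 <- truncate_resolution(cohort[[paste0(gene, "_2")]], k)
  a1 == a2
}
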