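# Class I loci handled by the package. Gene labels are stored as bare locus
# letters ("A", "B", "C"); the "HLA-" prefix is accepted on input and used in
# pretty printing only.
CLASS_I_GENES <- c("A", "B", "C")

# <locus>*<f1>[:<f2>[:<f3>[:<f4>]]][suffix], optional "HLA-" prefix.
# Expression suffixes follow WHO nomenclature (N/L/S/Q/C/A).
.ALLELE_REGEX <- "^(?:HLA-)?([ABC])\\*([0-9]{1,4}(?::[0-9]{1,4}){0,3})([NLSQCA]?)$"

.norm_gene <- function(gene) {
  g <- toupper(sub("^HLA-", "", as.character(gene)))
  if (!all(g %in% CLASS_I_GENES)) {
    stop("unknown HLA class I locus: ", paste(setdiff(g, CLASS_I_GENES), collapse = ", "),
         call. = FALSE)
  }
  g
}

#' Parse an HLA class I allele name
#'
#' Accepts WHO-style names such as `"A*02:01:01"` or `"HLA-B*07:02"`, with one
#' to four colon-separated numeric fields and an optional expression suffix
#' (N, L, S, Q, C, A). Leading zeros are not significant on input; the
#' canonical rendering zero-pads every field to at least two digits.
#'
#' @param text a single allele name.
#' @return An object of class `hla_allele` with elements `gene` (one of
#'   `"A"`, `"B"`, `"C"`), `fields` (integer vector, length 1--4) and
#'   `suffix` (`""` or a single letter).
#' @examples
#' parse_allele("A*02:01:01")
#' parse_allele("HLA-B*07:02")
#' @seealso [format.hla_allele()], [truncate_resolution()]
#' @export
parse_allele <- function(text) {
  if (length(text) != 1L || !is.character(text) || is.na(text)) {
    stop("parse_allele() expects a single allele string", call. = FALSE)
  }
  x <- toupper(trimws(text))
  m <- regmatches(x, regexec(.ALLELE_REGEX, x))[[1]]
  if (length(m) == 0L) {
    stop("malformed HLA allele name: '", text, "'", call. = FALSE)
  }
  new_hla_allele(gene = m[2],
                 fields = as.integer(strsplit(m[3], ":", fixed = TRUE)[[1]]),
                 suffix = m[4])
}

new_hla_allele <- function(gene, fields, suffix = "") {
  stopifnot(length(fields) >= 1L, length(fields) <= 4L)
  structure(list(gene = gene, fields = as.integer(fields), suffix = suffix),
            class = "hla_allele")
}

#' @export
format.hla_allele <- function(x, prefix = FALSE, ...) {
  paste0(if (prefix) "HLA-" else "", x$gene, "*",
         paste(sprintf("%02d", x$fields), collapse = ":"), x$suffix)
}

#' @export
print.hla_allele <- function(x, ...) {
  cat("<hla_allele> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.hla_allele` <- function(e1, e2) {
  identical(format(e1), format(e2))
}

#' Canonicalize a vector of allele names
#'
#' Vectorised parsing/re-rendering used by the registry readers: every element
#' is validated against WHO nomenclature and re-rendered with two-digit
#' zero-padded fields, so that `"A*2:1"` and `"A*02:01"` compare equal
#' downstream.
#'
#' @param x character vector of allele names.
#' @param gene optional locus each element must belong to (`"A"`, `"B"` or
#'   `"C"`); mismatches are an error.
#' @return character vector of canonical allele names (no `HLA-` prefix).
#' @export
canonical_alleles <- function(x, gene = NULL) {
  if (length(x) == 0L) return(character(0))
  x0 <- toupper(trimws(as.character(x)))
  m <- regmatches(x0, regexec(.ALLELE_REGEX, x0))
  bad <- which(lengths(m) == 0L | is.na(x0))
  if (length(bad) > 0L) {
    stop("malformed HLA allele name(s): ",
         paste0("'", x[utils::head(bad, 5L)], "' (entry ", utils::head(bad, 5L), ")",
                collapse = ", "),
         call. = FALSE)
  }
  loci <- vapply(m, `[`, "", 2L)
  if (!is.null(gene)) {
    gene <- .norm_gene(gene)
    off <- which(loci != gene)
    if (length(off) > 0L) {
      stop("allele(s) at wrong locus (expected HLA-", gene, "): ",
           paste0("'", x[utils::head(off, 5L)], "'", collapse = ", "), call. = FALSE)
    }
  }
  fields <- lapply(m, function(mm) as.integer(strsplit(mm[3], ":", fixed = TRUE)[[1]]))
  suffix <- vapply(m, `[`, "", 4L)
  paste0(loci, "*",
         vapply(fields, function(f) paste(sprintf("%02d", f), collapse = ":"), ""),
         suffix)
}

#' Truncate an allele to a lower field resolution
#'
#' Keeps the first `k` colon-separated fields of each allele name. The
#' expression suffix is dropped whenever fields are actually removed (a
#' truncated name no longer identifies the suffixed sequence) and kept when
#' `k` equals the allele's own resolution.
#'
#' @param a an `hla_allele`, or a character vector of allele names.
#' @param k number of fields to retain (1--4). It is an error to request more
#'   fields than an allele carries.
#' @return Same type as `a`, truncated.
#' @examples
#' truncate_resolution("A*02:01:01", 2)
#' @export
truncate_resolution <- function(a, k) {
  if (length(k) != 1L || is.na(k) || k < 1L) {
    stop("field count k must be a single integer >= 1", call. = FALSE)
  }
  k <- as.integer(k)
  if (inherits(a, "hla_allele")) {
    if (k > length(a$fields)) {
      stop("cannot truncate ", format(a), " to ", k, " fields: only ",
           length(a$fields), " available", call. = FALSE)
    }
    return(new_hla_allele(a$gene, a$fields[seq_len(k)],
                          if (k == length(a$fields)) a$suffix else ""))
  }
  x <- canonical_alleles(a)
  if (length(x) == 0L) return(character(0))
  parts <- strsplit(sub("^[ABC]\\*", "", sub("[NLSQCA]$", "", x)), ":", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < k)) {
    stop("cannot truncate to ", k, " fields: allele(s) with fewer fields: ",
         paste(utils::head(x[nf < k], 5L), collapse = ", "), call. = FALSE)
  }
  gene <- substr(x, 1L, 1L)
  has_suffix <- grepl("[NLSQCA]$", x)
  suffix <- ifelse(nf == k & has_suffix, substr(x, nchar(x), nchar(x)), "")
  paste0(gene, "*",
         vapply(parts, function(p) paste(p[seq_len(k)], collapse = ":"), ""),
         suffix)
}

# Ordering key for canonical allele names: lexicographic on
# (gene, numeric fields padded to 4, suffix).
allele_order_key <- function(x) {
  if (length(x) == 0L) return(character(0))
  x <- canonical_alleles(x)
  suffix <- ifelse(grepl("[NLSQCA]$", x), substr(x, nchar(x), nchar(x)), "")
  core <- sub("[NLSQCA]$", "", x)
  gene <- substr(core, 1L, 1L)
  parts <- strsplit(sub("^[ABC]\\*", "", core), ":", fixed = TRUE)
  padded <- vapply(parts, function(p) {
    p <- c(as.integer(p), rep(-1L, 4L - length(p)))
    paste(sprintf("%05d", p + 1L), collapse = ":")
  }, "")
  paste(gene, padded, suffix)
}

#' Sort allele names in nomenclature order
#'
#' Lexicographic on (locus, numeric fields, suffix); numeric comparison of
#' fields, so `A*09:01` sorts before `A*10:01`.
#'
#' @param x character vector of allele names.
#' @return `x` sorted.
#' @export
sort_alleles <- function(x) {
  x[order(allele_order_key(x))]
}
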