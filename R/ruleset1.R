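# Rule Set 1 on-target activity model (Doench et al. 2014, Nat Biotechnol,
# doi:10.1038/nbt.3026): a logistic regression on a 30-nt context
# (4 nt upstream + 20-nt protospacer + NGG PAM + 3 nt downstream) with
# position-specific single- and di-nucleotide indicator features and a
# GC-count term over the protospacer. The coefficient table ships as a CSV
# asset; its md5 is pinned here and the scorer refuses to run on a modified
# file, so a silently edited asset cannot change scores.
.RULESET1_MD5 <- "96aa82c4c83052690716c60f1932bbb3"

.ruleset1_cache <- new.env(parent = emptyenv())

#' Rule Set 1 coefficient table
#'
#' Loads (and caches) the bundled coefficient asset, verifying its checksum.
#'
#' @return Data frame with columns `feature`, `position` (1-based start on
#'   the 30-mer; NA for the intercept and GC terms), `nts`, `weight`.
#' @export
ruleset1_coefficients <- function() {
  if (!is.null(.ruleset1_cache$coef)) return(.ruleset1_cache$coef)
  path <- system.file("extdata", "ruleset1_coefficients.csv",
                      package = "superhla", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .RULESET1_MD5)) {
    stop("ruleset1_coefficients.csv checksum mismatch (", md5,
         "): the coefficient asset has been modified", call. = FALSE)
  }
  coef <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character",
                                         "numeric"))
  .ruleset1_cache$coef <- coef
  coef
}

#' Rule Set 1 on-target activity score
#'
#' Scores 30-nt contexts (protospacer at positions 5--24, PAM at 25--27,
#' 1-based) with the published logistic model: the linear predictor is the
#' intercept plus the GC-count term (`|GC - 10|` over the protospacer,
#' weighted by the low- or high-GC coefficient) plus the weights of every
#' matching position-specific nucleotide and dinucleotide feature; the score
#' is its logistic transform, in \[0, 1\]. Purely sequence-determined:
#' identical contexts always score identically.
#'
#' @param context30 character vector of 30-nt A/C/G/T strings.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
ruleset1_score <- function(context30) {
  context30 <- toupper(as.character(context30))
  if (any(is.na(context30)) || any(nchar(context30) != 30L)) {
    stop("every scoring context must be exactly 30 nt", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", context30))) {
    stop("scoring context contains non-ACGT characters", call. = FALSE)
  }
  coef <- ruleset1_coefficients()
  intercept <- coef$weight[coef$feature == "Intercept"]
  w_gc_low <- coef$weight[coef$feature == "GC_low"]
  w_gc_high <- coef$weight[coef$feature == "GC_high"]
  pos_coef <- coef[!is.na(coef$position), , drop = FALSE]
  # feature lookup by name: build each context's realised feature names and
  # sum the weights of those present in the table
  weights <- stats::setNames(pos_coef$weight, pos_coef$feature)
  singles <- pos_coef[nchar(pos_coef$nts) == 1L, ]
  dinucs <- pos_coef[nchar(pos_coef$nts) == 2L, ]
  eta <- rep(intercept, length(context30))
  proto <- substr(context30, 5L, 24L)
  gc <- nchar(gsub("[AT]", "", proto))
  eta <- eta + abs(gc - 10L) * ifelse(gc < 10L, w_gc_low, w_gc_high)
  for (pos in unique(singles$position)) {
    nt <- substr(context30, pos, pos)
    key <- paste0(nt, sprintf("%02d", pos))
    hit <- key %in% names(weights)
    eta[hit] <- eta[hit] + weights[key[hit]]
  }
  for (pos in unique(dinucs$position)) {
    nt2 <- substr(context30, pos, pos + 1L)
    key <- paste0(nt2, sprintf("%02d", pos))
    hit <- key %in% names(weights)
    eta[hit] <- eta[hit] + weights[key[hit]]
  }
  unname(stats::plogis(eta))
}
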