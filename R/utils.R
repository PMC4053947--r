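#' @keywords internal
"_PACKAGE"

#' Controlled vocabularies for the 450K-style annotation
#'
#' `GENE_REGIONS` are the recognised gene-region classes, `PROMOTER_REGIONS`
#' the subset treated as promoter-associated, `CGI_CLASSES` the CpG-island
#' relation classes.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
GENE_REGIONS <- c("TSS1500", "TSS200", "UTR5", "FirstExon", "Body", "UTR3")

#' @rdname vocabularies
#' @export
PROMOTER_REGIONS <- c("TSS1500", "TSS200", "UTR5", "FirstExon")

#' @rdname vocabularies
#' @export
CGI_CLASSES <- c("Island", "Shore", "Shelf", "OpenSea")

#' Percentage with half-up rounding
#'
#' Computes `numerator / denominator * 100` rounded half-up to a fixed number
#' of decimals. Half-up (4,688/11,242 -> 41.7) is the convention used in the
#' printed summary tables this package reproduces; R's `round()` rounds
#' half-even and would disagree on exact .x5 boundaries.
#'
#' @param numerator,denominator Non-negative counts.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage.
#' @examples
#' percent_half_up(4688, 11242) # 41.7
#' @export
percent_half_up <- function(numerator, denominator, digits = 1) {
  if (any(denominator == 0)) stop("percent_half_up: zero denominator")
  scale <- 10^digits
  floor(numerator / denominator * 100 * scale + 0.5) / scale
}

# Clamp to an open interval, used before logit transforms.
clamp <- function(x, lo = 1e-6, hi = 1 - 1e-6) pmin(pmax(x, lo), hi)

# Deterministic ordering of probes: chromosome (lexicographic), then position.
probe_order <- function(chromosome, position) {
  order(chromosome, position, method = "radix")
}

is_sorted_annotation <- function(ann) {
  identical(probe_order(ann$chromosome, ann$position), seq_len(nrow(ann)))
}
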