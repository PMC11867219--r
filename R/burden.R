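#' Construct a genotype matrix
#'
#' Container for per-sample, per-variant minor-allele dosages together with the
#' variant annotation (gene assignment, position, reference allele frequency)
#' needed for burden collapsing and variant filtering.
#'
#' @param calls Integer matrix of allele dosages, samples in rows and variants
#'   in columns. Allowed values are 0, 1, 2 and `NA` (missing call).
#' @param variants Data frame with one row per column of `calls`, columns
#'   `variant_id`, `gene`, `chrom`, `pos` (1-based) and `af` (reference-panel
#'   allele frequency in `[0, 1]`).
#' @param samples Character vector of sample ids, one per row of `calls`.
#'   Defaults to the rownames of `calls`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, variants, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(samples)) stop("sample ids are required (argument or rownames)")
  samples <- as.character(samples)
  if (length(samples) != nrow(calls)) {
    stop("length of 'samples' must equal nrow(calls)")
  }
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  required <- c("variant_id", "gene", "chrom", "pos", "af")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stop("variant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(variants) != ncol(calls)) {
    stop("nrow(variants) must equal ncol(calls)")
  }
  variants$variant_id <- as.character(variants$variant_id)
  variants$gene <- as.character(variants$gene)
  if (anyDuplicated(variants$variant_id)) stop("duplicate variant ids")
  ok <- is.na(calls) | calls %in% c(0L, 1L, 2L)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  if (any(!is.na(variants$af) & (variants$af < 0 | variants$af > 1))) {
    stop("allele frequencies must lie in [0, 1]")
  }
  dimnames(calls) <- list(samples, variants$variant_id)
  structure(list(calls = calls, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants in %d gene(s)\n",
              length(x$samples), nrow(x$variants),
              length(unique(x$variants$gene))))
  invisible(x)
}

#' Collapse variant dosages into a per-gene carrier indicator
#'
#' Implements the dominant burden coding G = 1 if the sample carries at least
#' one minor allele over the included variants of the gene, G = 0 otherwise.
#' Missing dosages are treated as 0 by default (the sample contributes no
#' carrier evidence at that site); the number of missing calls encountered is
#' recorded in the result so callers can audit genotyping completeness.
#'
#' @param matrix A [genotype_matrix()].
#' @param gene Gene id to collapse.
#' @param included Character vector of variant ids to include; all must belong
#'   to `gene`.
#' @param missing One of `"zero"` (default: missing dosage counts as 0) or
#'   `"drop"` (samples with any missing included call get `G = NA`).
#'
#' @return A `burden_vector`: list with `gene`, named integer vector `G`
#'   (0/1, possibly `NA` under `missing = "drop"`), `n_carriers` and
#'   `n_missing_calls`.
#' @export
collapse_burden <- function(matrix, gene, included,
                            missing = c("zero", "drop")) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  missing <- match.arg(missing)
  if (!gene %in% matrix$variants$gene) stop("unknown gene id: ", gene)
  if (length(included) == 0) {
    stop("empty included variant set for gene ", gene)
  }
  included <- as.character(included)
  unknown <- setdiff(included, matrix$variants$variant_id)
  if (length(unknown)) {
    stop("variant id(s) not in matrix: ", paste(unknown, collapse = ", "))
  }
  owner <- matrix$variants$gene[match(included, matrix$variants$variant_id)]
  if (any(owner != gene)) {
    stop("included variants not belonging to gene ", gene, ": ",
         paste(included[owner != gene], collapse = ", "))
  }
  sub <- matrix$calls[, included, drop = FALSE]
  n_missing <- sum(is.na(sub))
  if (missing == "zero") {
    carrier <- as.integer(rowSums(sub > 0, na.rm = TRUE) > 0)
  } else {
    any_na <- rowSums(is.na(sub)) > 0
    carrier <- as.integer(rowSums(sub > 0, na.rm = TRUE) > 0)
    carrier[any_na & carrier == 0L] <- NA_integer_
  }
  names(carrier) <- matrix$samples
  structure(list(gene = gene, G = carrier,
                 n_carriers = sum(carrier == 1L, na.rm = TRUE),
                 n_missing_calls = n_missing),
            class = "burden_vector")
}

#' Define the coding exon structure of a gene
#'
#' @param gene Gene id.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends 1-based inclusive genomic interval bounds of the coding
#'   exons. Supply them in transcription (5' to 3') order on the coding strand;
#'   for a minus-strand gene that means decreasing genomic coordinates.
#'
#' @return An `exon_structure` object.
#' @export
exon_structure <- function(gene, strand, starts, ends) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (length(starts) != length(ends) || length(starts) < 1) {
    stop("need at least one exon; starts and ends must have equal length")
  }
  if (any(ends < starts)) stop("exon end before start")
  # transcription order check: genomic order increasing on +, decreasing on -
  if (length(starts) > 1) {
    gaps_ok <- if (strand == "+") all(diff(starts) > 0) && all(utils::head(ends, -1) < utils::tail(starts, -1))
               else all(diff(starts) < 0) && all(utils::tail(ends, -1) < utils::head(starts, -1))
    if (!gaps_ok) stop("exons must be non-overlapping and in transcription order")
  }
  structure(list(gene = gene, strand = strand,
                 starts = as.numeric(starts), ends = as.numeric(ends)),
            class = "exon_structure")
}

#' Positional NMD-escape rule for protein-truncating variants
#'
#' A premature stop in the last coding exon, or within the final 50 bp (on the
#' coding strand, inclusive) of the penultimate exon, generally escapes
#' nonsense-mediated decay; such PTVs are excluded from burden collapsing.
#' Single-exon genes cannot trigger NMD, so every exonic position is excluded.
#'
#' @param position 1-based genomic bp position of the variant; must fall inside
#'   one of the gene's coding exons.
#' @param exons An [exon_structure()].
#'
#' @return `TRUE` if the PTV is predicted to escape NMD (and should be
#'   excluded), `FALSE` otherwise.
#' @export
nmd_escape_excluded <- function(position, exons) {
  stopifnot(inherits(exons, "exon_structure"))
  hit <- which(position >= exons$starts & position <= exons$ends)
  if (length(hit) == 0) {
    stop("position ", position, " falls in no coding exon of gene ",
         exons$gene, "; the NMD rule is defined for exonic PTVs only")
  }
  n <- length(exons$starts)
  if (n == 1) return(TRUE)
  if (hit == n) return(TRUE)  # last exon in transcription order
  if (hit == n - 1) {
    # final 50 bp at the 3' end of the penultimate exon, coding strand
    if (exons$strand == "+") {
      return(position >= exons$ends[hit] - 49)
    } else {
      return(position <= exons$starts[hit] + 49)
    }
  }
  FALSE
}

#' Filter variants on reference and in-sample allele frequency
#'
#' Keeps variants whose stored (reference-panel) allele frequency and whose
#' in-sample allele frequency are both strictly below the threshold. The
#' in-sample frequency is the minor-allele count divided by twice the number of
#' non-missing calls.
#'
#' @param matrix A [genotype_matrix()].
#' @param af_threshold Frequency threshold in `(0, 1]`; the conventional rare
#'   cut-off is `0.001`.
#'
#' @return Character vector of variant ids passing both conditions.
#' @export
rare_variant_filter <- function(matrix, af_threshold) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (!is.numeric(af_threshold) || af_threshold <= 0 || af_threshold > 1) {
    stop("af_threshold must lie in (0, 1]")
  }
  calls <- matrix$calls
  n_obs <- colSums(!is.na(calls))
  ac <- colSums(calls, na.rm = TRUE)
  in_af <- ifelse(n_obs > 0, ac / (2 * n_obs), 0)
  keep <- matrix$variants$af < af_threshold & in_af < af_threshold
  matrix$variants$variant_id[keep]
}
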