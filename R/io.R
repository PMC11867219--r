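# File conventions: tab-separated, UTF-8, '#' comment lines, "NA" for missing.

# Read a TSV keeping track of the original line number of each data row,
# so validation errors can cite the offending line in the file.
read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) < 1) stop("no content in ", path)
  df <- utils::read.delim(text = lines[keep], sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "line_numbers") <- idx[-1]  # first kept line is the header
  df
}

check_binary_column <- function(df, col, path) {
  bad <- which(!(df[[col]] %in% c(0, 1)))
  if (length(bad)) {
    ln <- attr(df, "line_numbers")[bad[1]]
    stop("column '", col, "' must be binary 0/1; first offending value '",
         df[[col]][bad[1]], "' on line ", ln, " of ", path)
  }
}

#' Read a phenotype table
#'
#' Expects a tab-separated file with a header and columns `sample_id`,
#' `case`, `fh`, `sex` (all three binary 0/1); any further numeric columns
#' are kept as covariates. Lines starting with `#` are comments. Offending
#' rows are reported with their line numbers.
#'
#' @param path Path to the phenotype TSV.
#' @return Data frame of validated phenotype records.
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv_lines(path)
  needed <- c("sample_id", "case", "fh", "sex")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("phenotype file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", path)
  for (col in c("case", "fh", "sex")) check_binary_column(df, col, path)
  extra <- setdiff(names(df), needed)
  for (col in extra) {
    if (!is.numeric(df[[col]])) {
      stop("covariate column '", col, "' in ", path, " is not numeric")
    }
    if (any(!is.finite(df[[col]]))) {
      stop("covariate column '", col, "' in ", path, " has non-finite values")
    }
  }
  attr(df, "line_numbers") <- NULL
  df
}

#' Write a phenotype table
#'
#' @param phenotypes Data frame as returned by [read_phenotypes()].
#' @param path Output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write_result_table(phenotypes, path, config = list(content = "phenotypes"))
}

#' Read per-gene carrier status
#'
#' Two input shapes are accepted: a long carrier table (columns `sample_id`,
#' `gene`, `G`) or a minimal VCF (GT field) together with a variant-to-gene
#' map, in which case dosages are collapsed per gene with [collapse_burden()].
#'
#' @param path Carrier TSV, or a VCF when `gene_map` is given.
#' @param gene_map Optional path to a variant map TSV with columns
#'   `variant_id`, `gene`, `chrom`, `pos`, `af`.
#' @param af_threshold Optional allele-frequency threshold applied through
#'   [rare_variant_filter()] when reading from a VCF.
#' @return Named list (by gene) of 0/1 carrier vectors keyed by sample id.
#' @export
read_carriers <- function(path, gene_map = NULL, af_threshold = NULL) {
  if (!is.null(gene_map)) {
    gm <- geno_from_vcf(path, gene_map)
    genes <- unique(gm$variants$gene)
    keep_ids <- if (is.null(af_threshold)) gm$variants$variant_id
                else rare_variant_filter(gm, af_threshold)
    out <- list()
    for (g in genes) {
      ids <- intersect(keep_ids,
                       gm$variants$variant_id[gm$variants$gene == g])
      if (!length(ids)) next
      out[[g]] <- collapse_burden(gm, g, ids)$G
    }
    return(out)
  }
  df <- read_tsv_lines(path)
  needed <- c("sample_id", "gene", "G")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("carrier file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  check_binary_column(df, "G", path)
  out <- lapply(split(df, df$gene), function(d) {
    stats::setNames(as.numeric(d$G), as.character(d$sample_id))
  })
  out
}

#' Read a sample-by-variant dosage matrix with its variant map
#'
#' The dosage file has a `sample_id` column followed by one 0/1/2/NA column
#' per variant; the map file assigns each variant to a gene and supplies its
#' position and reference allele frequency.
#'
#' @param dosage_path Dosage matrix TSV.
#' @param map_path Variant map TSV (`variant_id`, `gene`, `chrom`, `pos`, `af`).
#' @return A [genotype_matrix()].
#' @export
read_dosage_matrix <- function(dosage_path, map_path) {
  df <- read_tsv_lines(dosage_path)
  if (!"sample_id" %in% names(df)) {
    stop("dosage file ", dosage_path, " lacks a sample_id column")
  }
  vm <- read_gene_map(map_path)
  vids <- setdiff(names(df), "sample_id")
  miss <- setdiff(vids, vm$variant_id)
  if (length(miss)) {
    stop("variant(s) absent from map ", map_path, ": ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  calls <- as.matrix(df[, vids, drop = FALSE])
  genotype_matrix(calls, vm[match(vids, vm$variant_id), ],
                  samples = as.character(df$sample_id))
}

#' @rdname read_dosage_matrix
#' @param path Variant map path.
#' @export
read_gene_map <- function(path) {
  vm <- read_tsv_lines(path)
  needed <- c("variant_id", "gene", "chrom", "pos", "af")
  miss <- setdiff(needed, names(vm))
  if (length(miss)) {
    stop("gene map ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  attr(vm, "line_numbers") <- NULL
  vm
}

# Minimal VCF (GT only) -> genotype_matrix, via vcfR.
geno_from_vcf <- function(vcf_path, map_path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF input requires the vcfR package")
  }
  vm <- read_gene_map(map_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  if (is.null(ids) || anyNA(ids)) {
    ids <- paste0(v@fix[, "CHROM"], ":", v@fix[, "POS"])
  }
  dose <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_integer_)
    alleles <- strsplit(x, "[/|]")[[1]]
    sum(alleles != "0" & alleles != ".")
  })
  miss <- setdiff(ids, vm$variant_id)
  if (length(miss)) {
    stop("VCF variant(s) absent from gene map: ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  genotype_matrix(t(dose), vm[match(ids, vm$variant_id), ],
                  samples = colnames(gt))
}

#' Read exon structures
#'
#' BED-like TSV with columns `gene`, `strand`, `start`, `end`, one row per
#' coding exon in transcription order within each gene.
#'
#' @param path Path to the exon TSV.
#' @return Named list of [exon_structure()] objects.
#' @export
read_exons <- function(path) {
  df <- read_tsv_lines(path)
  needed <- c("gene", "strand", "start", "end")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("exon file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  lapply(split(df, df$gene), function(d) {
    exon_structure(d$gene[1], d$strand[1], d$start, d$end)
  })
}

#' Read a pedigree table
#'
#' Long-format TSV with columns `ped_id`, `member_id`, `relationship`
#' (`self` marks the proband), `status`, `age` and `genotype` (0/1/2 on the
#' proband row, `NA` elsewhere).
#'
#' @param path Path to the pedigree TSV.
#' @return Validated pedigree data frame for [score_test()].
#' @export
read_pedigrees <- function(path) {
  df <- read_tsv_lines(path)
  attr(df, "line_numbers") <- NULL
  validate_pedigrees(df)
}

#' Read an incidence table
#'
#' Two-column TSV (`age_start`, `cumhaz`) defining a piecewise-constant
#' cumulative hazard; see [incidence_model()].
#'
#' @param path Path to the incidence TSV.
#' @return An [incidence_model()] function.
#' @export
read_incidence <- function(path) {
  df <- read_tsv_lines(path)
  needed <- c("age_start", "cumhaz")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("incidence file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  incidence_model(df$age_start, df$cumhaz)
}

#' Write a result table with a reproducibility header
#'
#' Every output file begins with `#`-prefixed comment lines recording the
#' package version, the seed (when given) and the full configuration used,
#' so any result can be regenerated from its own header.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param config Named list echoed into the header.
#' @param seed Optional seed echoed into the header.
#' @export
write_result_table <- function(df, path, config = list(), seed = NULL) {
  hdr <- c(
    paste0("# fhburden ", as.character(utils::packageVersion("fhburden"))),
    if (!is.null(seed)) paste0("# seed: ", seed),
    if (length(config)) paste0("# config: ", paste(
      names(config), unlist(lapply(config, function(x)
        paste(format(x, trim = TRUE), collapse = ","))),
      sep = "=", collapse = " ")))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
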