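## Plain-text readers/writers for the pipeline's tabular formats:
## SNP weight tables, life tables, cohort tables, dosage matrices
## (TSV or VCF).

validate_snp_weights <- function(weights, need_raf = TRUE) {
  weights <- as.data.frame(weights)
  if (!"rsid" %in% names(weights))
    stop_invalid("weight table needs an `rsid` column")
  if (!"or" %in% names(weights))
    stop_invalid("weight table needs an `or` column")
  if (!"raf" %in% names(weights) && "raf_control" %in% names(weights))
    weights$raf <- weights$raf_control   # controls approximate the population
  if (need_raf) {
    if (!"raf" %in% names(weights))
      stop_invalid("weight table needs `raf` (or `raf_control`)")
    if (any(weights$raf <= 0 | weights$raf >= 1))
      stop_invalid("risk-allele frequencies must lie in (0, 1)")
  }
  if (any(weights$or <= 0))
    stop_invalid("per-allele odds ratios must be positive")
  if (anyDuplicated(weights$rsid))
    stop_invalid("duplicated rsids in weight table")
  weights
}

#' Read / write a SNP weight table
#'
#' Tab-separated with a header; required columns `rsid` and `or`, plus
#' `raf` or `raf_control` (the control risk-allele frequency, used as
#' the population frequency). Optional columns (`chrom`, `pos`,
#' `risk_allele`, `nonrisk_allele`, `raf_case`, `p`) are carried
#' through.
#'
#' @param path File path.
#' @return Validated weight data frame.
#' @export
read_snp_weights <- function(path) {
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_snp_weights(w)
}

#' @rdname read_snp_weights
#' @param weights Weight data frame.
#' @export
write_snp_weights <- function(weights, path) {
  utils::write.table(weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a life table
#'
#' Tab-separated with columns `age_lo`, `age_hi`, `sex`,
#' `incidence_per_1000py`, `mortality_per_10000py`.
#'
#' @param path File path.
#' @return A validated `life_table` data frame.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.delim(path, stringsAsFactors = FALSE)
  lt <- validate_life_table(lt)
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' @rdname read_life_table
#' @param life_table A `life_table` data frame.
#' @export
write_life_table <- function(life_table, path) {
  validate_life_table(life_table)
  utils::write.table(as.data.frame(life_table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a simulated cohort as TSV
#'
#' `write_cohort()` writes `<prefix>_samples.tsv` (covariates, family
#' history, status, cohort label) and, when genotypes are present,
#' `<prefix>_dosages.tsv` (samples x loci risk-allele counts).
#'
#' @param cohort A [simulate_cohort()] object.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "dcvd_cohort"))
  paths <- character(0)
  sp <- paste0(prefix, "_samples.tsv")
  utils::write.table(cohort$samples, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- sp
  if (!is.null(cohort$dosages)) {
    dp <- paste0(prefix, "_dosages.tsv")
    d <- data.frame(sample_id = cohort$samples$sample_id, cohort$dosages,
                    check.names = FALSE)
    utils::write.table(d, dp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, dp)
  }
  invisible(paths)
}

#' Read a dosage matrix from TSV
#'
#' First column `sample_id`, remaining columns one locus each (rsid
#' header), values 0/1/2 or NA.
#'
#' @param path File path.
#' @return Numeric matrix with sample-id rownames.
#' @export
read_dosages_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- d[[1]]
  if (any(!is.na(m) & !(m %in% 0:2)))
    stop_invalid("dosage values must be 0, 1, 2 or missing")
  m
}

#' Read risk-allele dosages from a VCF
#'
#' Parses GT fields and counts copies of the weight table's risk
#' allele at each locus, matching variants by rsid (ID column) and
#' requiring an exact allele match against REF/ALT in either
#' orientation; mismatched alleles are an error (strand flips are not
#' guessed). Requires the `vcfR` package.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param weights Weight table with `rsid`, `risk_allele`,
#'   `nonrisk_allele`.
#' @return Numeric matrix (samples x loci) of risk-allele counts.
#' @export
read_dosages_vcf <- function(path, weights) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the `vcfR` package is required to read VCF genotypes")
  weights <- validate_snp_weights(weights, need_raf = FALSE)
  if (!all(c("risk_allele", "nonrisk_allele") %in% names(weights)))
    stop_invalid("VCF matching needs `risk_allele` and `nonrisk_allele`")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  out <- matrix(NA_real_, ncol(gt), nrow(weights),
                dimnames = list(colnames(gt), weights$rsid))
  for (i in seq_len(nrow(weights))) {
    j <- which(fix$ID == weights$rsid[i])
    if (length(j) != 1L)
      stop_invalid("rsid %s not found exactly once in VCF", weights$rsid[i])
    ra <- weights$risk_allele[i]; na_ <- weights$nonrisk_allele[i]
    if (fix$REF[j] == na_ && fix$ALT[j] == ra) {
      alt_is_risk <- TRUE
    } else if (fix$REF[j] == ra && fix$ALT[j] == na_) {
      alt_is_risk <- FALSE
    } else {
      stop_invalid("allele mismatch at %s: VCF %s/%s vs weights %s/%s",
                   weights$rsid[i], fix$REF[j], fix$ALT[j], ra, na_)
    }
    alleles <- strsplit(gsub("\\|", "/", gt[j, ]), "/", fixed = TRUE)
    alt_count <- vapply(alleles, function(a) {
      if (any(a %in% c(".", NA))) return(NA_real_)
      sum(a == "1")
    }, 0)
    out[, i] <- if (alt_is_risk) alt_count else 2 - alt_count
  }
  out
}

#' Write genotype dosages as a minimal VCF
#'
#' One sample column per individual, GT field only; the risk allele is
#' written as ALT and the non-risk allele as REF (so the alternate
#' allele count equals the risk-allele dosage). Chromosome and
#' position default to placeholders when the weight table lacks them.
#'
#' @param dosages Matrix (samples x loci) of risk-allele counts.
#' @param weights Weight table with `rsid`, `risk_allele`,
#'   `nonrisk_allele` (optionally `chrom`, `pos`).
#' @param path Output path.
#' @export
write_dosages_vcf <- function(dosages, weights, path) {
  weights <- validate_snp_weights(weights, need_raf = FALSE)
  if (!all(c("risk_allele", "nonrisk_allele") %in% names(weights)))
    stop_invalid("VCF writing needs `risk_allele` and `nonrisk_allele`")
  dosages <- as.matrix(dosages[, weights$rsid, drop = FALSE])
  samples <- rownames(dosages) %||% sprintf("S%05d", seq_len(nrow(dosages)))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  chrom <- if ("chrom" %in% names(weights)) weights$chrom else "1"
  pos <- if ("pos" %in% names(weights) && !all(is.na(weights$pos)))
    weights$pos else seq_len(nrow(weights)) * 1000L
  body <- vapply(seq_len(nrow(weights)), function(i) {
    gts <- ifelse(is.na(dosages[, i]), "./.",
                  gt_code[as.character(dosages[, i])])
    paste(c(chrom[i], pos[i], weights$rsid[i], weights$nonrisk_allele[i],
            weights$risk_allele[i], ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a score set with its normalization sidecar
#'
#' The scores go to `<path>` as TSV (sample, raw, normalized,
#' score_type); the normalization parameters go to `<path>.json` for
#' reuse on held-out data.
#'
#' @param scores A `score_set` from [minmax_normalize()].
#' @param path Output TSV path.
#' @export
write_score_set <- function(scores, path) {
  stopifnot(inherits(scores, "score_set"))
  df <- as.data.frame(scores)
  df$score_type <- attr(scores, "score_type")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(x_min = attr(scores, "x_min"),
                            x_range = attr(scores, "x_range"),
                            score_type = attr(scores, "score_type")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
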