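# Polygenic risk score: weighted allele counting over PD susceptibility
# SNPs, with log odds-ratio weights.

#' Read a SNP weight table
#'
#' Tab-separated table with columns `rsid`, `effect_allele`,
#' `odds_ratio` and optionally `effect_allele_freq`. The per-SNP weight
#' is the natural log of the odds ratio, the standard weighted
#' allele-count convention. Odds ratios must be positive; an odds ratio
#' of exactly 1 yields weight 0 and a warning (the SNP is
#' non-informative); duplicated rsids are an error.
#'
#' @param path path to the TSV file.
#' @return Data frame with columns `rsid`, `effect_allele`,
#'   `odds_ratio`, `weight`, and `effect_allele_freq` (NA when absent).
#' @export
read_snp_weights <- function(path) {
  if (!file.exists(path)) stop("weight table not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("rsid", "effect_allele", "odds_ratio")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("weight table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) stop("weight table is empty")
  if (anyDuplicated(raw$rsid)) {
    stop("duplicated rsid in weight table: ",
         raw$rsid[duplicated(raw$rsid)][1])
  }
  or <- as.numeric(raw$odds_ratio)
  if (any(!is.finite(or)) || any(or <= 0)) {
    stop("odds ratios must be finite and > 0")
  }
  if (any(or == 1)) {
    warning("weight table contains odds ratio(s) of exactly 1 ",
            "(non-informative SNP): ",
            paste(raw$rsid[or == 1], collapse = ", "))
  }
  data.frame(
    rsid = as.character(raw$rsid),
    effect_allele = toupper(as.character(raw$effect_allele)),
    odds_ratio = or,
    weight = log(or),
    effect_allele_freq = if ("effect_allele_freq" %in% names(raw)) {
      as.numeric(raw$effect_allele_freq)
    } else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Read a genotype dosage CSV
#'
#' Wide table with a `subject_id` column and one column per rsid holding
#' effect-allele dosages in `{0, 1, 2}` (empty cells are missing).
#'
#' @param path path to the CSV file.
#' @return Numeric matrix (subjects x SNPs) with subject ids as row
#'   names and rsids as column names; missing dosages are `NA`.
#' @export
read_dosage_csv <- function(path) {
  if (!file.exists(path)) stop("dosage file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!"subject_id" %in% names(raw)) {
    stop("dosage CSV is missing a subject_id column")
  }
  ids <- as.character(raw$subject_id)
  g <- as.matrix(raw[setdiff(names(raw), "subject_id")])
  storage.mode(g) <- "double"
  bad <- !is.na(g) & !g %in% c(0, 1, 2)
  if (any(bad)) {
    stop("dosage values must be 0, 1, 2 or missing; found ",
         g[which(bad)[1]])
  }
  rownames(g) <- ids
  g
}

#' Read genotypes from a VCF into an effect-allele dosage matrix
#'
#' Parses the GT field of a (small) VCF and converts each genotype to a
#' dosage of the weight table's effect allele. The effect allele must be
#' the REF or the ALT allele of the matching record; anything else is an
#' error, since silently flipped strands would corrupt the score.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @param weights weight table from [read_snp_weights()].
#' @return Dosage matrix as in [read_dosage_csv()], restricted to the
#'   weight-table SNPs found in the VCF.
#' @export
read_genotypes_vcf <- function(path, weights) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF genotypes requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- fix[, "ID"] %in% weights$rsid
  if (!any(keep)) stop("no weight-table SNPs found in VCF")
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  n_sub <- ncol(gt)
  out <- matrix(NA_real_, nrow = n_sub, ncol = nrow(fix),
                dimnames = list(colnames(gt), fix[, "ID"]))
  for (j in seq_len(nrow(fix))) {
    eff <- weights$effect_allele[match(fix[j, "ID"], weights$rsid)]
    alleles <- c(fix[j, "REF"], strsplit(fix[j, "ALT"], ",")[[1]])
    eff_idx <- match(eff, alleles) - 1L  # VCF allele index of the effect allele
    if (is.na(eff_idx)) {
      stop("effect allele ", eff, " for ", fix[j, "ID"],
           " matches neither REF nor ALT in the VCF")
    }
    calls <- gt[j, ]
    split_calls <- strsplit(calls, "[/|]")
    out[, j] <- vapply(split_calls, function(a) {
      if (length(a) == 0 || any(a == ".") || any(is.na(a))) return(NA_real_)
      sum(as.integer(a) == eff_idx)
    }, numeric(1))
  }
  out
}

#' Compute per-subject polygenic risk scores
#'
#' Weighted allele count: for subject i, `S_i = sum_j g_ij * ln(OR_j)`
#' over the weight-table SNPs present in the genotype matrix. Missing
#' dosages are handled by policy: `"impute-freq"` substitutes the
#' Hardy-Weinberg expectation `2 * effect_allele_freq` (falling back to
#' the cohort mean dosage when no frequency is available), `"mean"` uses
#' the cohort mean dosage for that SNP, and `"drop"` omits the SNP for
#' that subject without rescaling. With `normalize = TRUE` the score is
#' divided by its maximum attainable value `sum_j 2 * ln(OR_j)`.
#'
#' @param genotypes dosage matrix (subjects x SNPs), rsids as column
#'   names, from [read_dosage_csv()] or [read_genotypes_vcf()].
#' @param weights weight table from [read_snp_weights()].
#' @param missing missing-dosage policy (see Details).
#' @param normalize divide scores by the maximum attainable score.
#' @return Data frame with `subject_id`, `score`, `n_snps_used`,
#'   `n_imputed`.
#' @export
compute_prs <- function(genotypes, weights,
                        missing = c("impute-freq", "mean", "drop"),
                        normalize = FALSE) {
  missing <- match.arg(missing)
  stopifnot(is.matrix(genotypes))
  shared <- intersect(weights$rsid, colnames(genotypes))
  if (length(shared) == 0) {
    stop("no overlap between weight-table SNPs and genotype columns")
  }
  absent <- setdiff(weights$rsid, shared)
  if (length(absent) > 0) {
    warning(length(absent), " weight-table SNP(s) absent from genotypes: ",
            paste(absent, collapse = ", "))
  }
  g <- genotypes[, shared, drop = FALSE]
  w <- weights$weight[match(shared, weights$rsid)]
  freq <- weights$effect_allele_freq[match(shared, weights$rsid)]

  miss <- is.na(g)
  n_imputed <- rowSums(miss)
  if (any(miss)) {
    if (missing == "drop") {
      g[miss] <- 0  # weight contributes nothing for that subject
    } else {
      col_mean <- colMeans(g, na.rm = TRUE)
      col_mean[!is.finite(col_mean)] <- 0
      fill <- if (missing == "impute-freq") {
        ifelse(is.finite(freq), 2 * freq, col_mean)
      } else {
        col_mean
      }
      idx <- which(miss, arr.ind = TRUE)
      g[miss] <- fill[idx[, 2]]
    }
  }
  # plain per-SNP accumulation (not BLAS) so scores are bitwise
  # reproducible across platforms and match naive summation
  score <- numeric(nrow(g))
  for (j in seq_along(w)) score <- score + g[, j] * w[j]
  if (normalize) score <- score / sum(2 * abs(w))
  n_used <- length(shared) - if (missing == "drop") n_imputed else 0
  data.frame(
    subject_id = rownames(genotypes),
    score = score,
    n_snps_used = as.integer(n_used),
    n_imputed = as.integer(n_imputed),
    stringsAsFactors = FALSE
  )
}
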