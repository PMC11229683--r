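#' FPKM normalisation
#'
#' Converts a raw fragment-count matrix to Fragments Per Kilobase of exon
#' model per Million mapped fragments:
#' \deqn{\mathrm{FPKM}_{ij} = \frac{10^9 \, c_{ij}}{L_i \sum_k c_{kj}}}
#' with \eqn{L_i} the summed exon length of feature \eqn{i} in bp. The
#' formula carries the conservation identity
#' \eqn{\sum_i \mathrm{FPKM}_{ij} L_i = 10^9} for every sample.
#'
#' @param counts Numeric matrix of non-negative counts, features in rows
#'   (rownames = feature ids), samples in columns.
#' @param lengths Named numeric vector of feature lengths in bp covering
#'   every row of `counts`, all positive.
#' @return Matrix of FPKM values with the same dimnames.
#' @examples
#' m <- matrix(c(100, 999900), ncol = 1,
#'             dimnames = list(c("a", "b"), "s1"))
#' fpkm(m, c(a = 1000, b = 1000))
#' @export
fpkm <- function(counts, lengths) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  len <- lengths[rownames(counts)]
  bad_len <- rownames(counts)[is.na(len) | len <= 0]
  if (length(bad_len))
    stop("missing or non-positive length for feature(s): ",
         paste(bad_len, collapse = ", "), call. = FALSE)
  csum <- colSums(counts)
  bad_col <- colnames(counts)[csum == 0]
  if (length(bad_col))
    stop("all-zero sample column(s): ", paste(bad_col, collapse = ", "),
         call. = FALSE)
  sweep(counts / len, 2, csum, "/") * 1e9
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, m\,p_{(j)}/j)}, returned in the
#' input order. A thin validating front end over
#' [stats::p.adjust()]`(method = "BH")`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || any(!is.finite(pvalues)))
    stop("p-values must be finite numeric", call. = FALSE)
  if (any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

# Median-of-ratios size factors (geometric-mean reference over features
# expressed in every sample).
size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable))
    stop("no feature is expressed in every sample; size factors undefined",
         call. = FALSE)
  apply(counts, 2, function(col)
    exp(stats::median(log(col[usable]) - log_geo[usable])))
}

#' Two-group differential-expression statistics
#'
#' A deterministic, self-contained two-group test used to exercise the
#' lncRNA pipeline end to end: counts are normalised by median-of-ratios
#' size factors, the fold change is
#' `log2((mean_norm_a + 0.5) / (mean_norm_b + 0.5))`, and the p-value
#' comes from Welch's t-test on `log2(norm + 1)` per feature. Features
#' with zero variance in both groups get `p = 1` by convention. This is
#' intentionally a simple fixed-formula procedure, not a
#' dispersion-modelling RNA-seq test.
#'
#' @param counts Count matrix (features x samples, dimnames required).
#' @param group_a,group_b Character vectors of column names; `group_a` is
#'   the treatment (numerator) group. At least 2 samples each.
#' @return Tibble with columns `feature_id`, `log2fc`, `pvalue`.
#' @export
de_stats <- function(counts, group_a, group_b) {
  stopifnot(is.matrix(counts), !is.null(colnames(counts)))
  missing <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(missing))
    stop("sample(s) not in counts: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 replicates", call. = FALSE)
  sf <- size_factors(counts[, c(group_a, group_b), drop = FALSE])
  norm <- sweep(counts[, c(group_a, group_b), drop = FALSE], 2, sf, "/")
  a <- norm[, group_a, drop = FALSE]
  b <- norm[, group_b, drop = FALSE]
  log2fc <- unname(log2((rowMeans(a) + 0.5) / (rowMeans(b) + 0.5)))
  la <- log2(a + 1)
  lb <- log2(b + 1)
  pvalue <- vapply(seq_len(nrow(norm)), function(i) {
    xa <- la[i, ]
    xb <- lb[i, ]
    if (stats::var(xa) == 0 && stats::var(xb) == 0) return(1)
    stats::t.test(xa, xb)$p.value
  }, numeric(1))
  tibble::tibble(feature_id = rownames(counts), log2fc = log2fc,
                 pvalue = pvalue)
}

#' Call differential expression at FDR and fold-change thresholds
#'
#' Assigns each feature a status: `up` when `qvalue < alpha` and
#' `log2fc > lfc_min`, `down` when `qvalue < alpha` and
#' `log2fc < -lfc_min` (strict inequalities on the absolute fold change),
#' otherwise `ns`. If `results` lacks a `qvalue` column it is added by
#' [bh_adjust()] over the whole tested set first.
#'
#' @param results Tibble from [de_stats()] (columns `feature_id`,
#'   `log2fc`, `pvalue`, optional `qvalue`).
#' @param alpha FDR threshold.
#' @param lfc_min Minimum absolute log2 fold change (exclusive).
#' @return `results` with `qvalue` and `status` columns.
#' @export
select_de <- function(results, alpha = 0.05, lfc_min = 2) {
  stopifnot(is.data.frame(results),
            all(c("log2fc", "pvalue") %in% names(results)))
  out <- tibble::as_tibble(results)
  if (!"qvalue" %in% names(out)) out$qvalue <- bh_adjust(out$pvalue)
  out$status <- dplyr::case_when(
    out$qvalue < alpha & out$log2fc > lfc_min ~ "up",
    out$qvalue < alpha & out$log2fc < -lfc_min ~ "down",
    TRUE ~ "ns"
  )
  out
}

#' One-call differential expression between two sample groups
#'
#' Convenience wrapper chaining [de_stats()], [bh_adjust()] and
#' [select_de()], adjusting within this one comparison (each contrast
#' forms its own Benjamini-Hochberg family).
#'
#' @inheritParams de_stats
#' @inheritParams select_de
#' @return Tibble with `feature_id`, `log2fc`, `pvalue`, `qvalue`,
#'   `status`.
#' @export
differential_expression <- function(counts, group_a, group_b,
                                    alpha = 0.05, lfc_min = 2) {
  select_de(de_stats(counts, group_a, group_b), alpha = alpha,
            lfc_min = lfc_min)
}

#' Select sample ids from a sample sheet
#'
#' @param samples Sample sheet (columns `sample_id`, `cultivar`,
#'   `condition`, `time_h`, `replicate`).
#' @param ... Filter conditions evaluated in the sheet, e.g.
#'   `condition == "drought", time_h == 36`.
#' @return Character vector of matching `sample_id`s.
#' @export
sample_ids <- function(samples, ...) {
  dplyr::filter(samples, ...)$sample_id
}
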