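#' Relative expression by the 2^-ddCT method
#'
#' Classic relative qRT-PCR quantification. The target gene's cycle
#' threshold is first normalised to the reference gene within each sample
#' (`dCT = CT_target - CT_ref`), then to the calibrator sample
#' (`ddCT = dCT_treated - dCT_calibrator`); the fold change is
#' `2^-ddCT`. The calibrator's self-ratio is 1 by construction, and
#' shifting every CT of a sample by a constant leaves the result
#' unchanged.
#'
#' @param target_ct_treated,ref_ct_treated CTs of target and reference
#'   gene in the treated sample.
#' @param target_ct_calib,ref_ct_calib CTs in the calibrator sample.
#' @return Fold change(s), strictly positive.
#' @examples
#' ddct_fold_change(20, 15, 22, 15) # ddCT = -2 -> 4
#' @export
ddct_fold_change <- function(target_ct_treated, ref_ct_treated,
                             target_ct_calib, ref_ct_calib) {
  cts <- c(target_ct_treated, ref_ct_treated, target_ct_calib, ref_ct_calib)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop("all CT values must be finite and positive", call. = FALSE)
  d_treated <- target_ct_treated - ref_ct_treated
  d_calib <- target_ct_calib - ref_ct_calib
  2^(-(d_treated - d_calib))
}

#' Fold changes for a qPCR plate table
#'
#' Table-level 2^-ddCT quantification with technical replicates. For each
#' gene and condition, replicate CTs are averaged on the CT scale before
#' the ddCT step; the reported spread is the standard deviation of
#' replicate-wise fold changes (each replicate's dCT against the
#' calibrator's mean dCT). Every (condition, replicate) must carry
#' exactly one reference-gene CT per replicate.
#'
#' @param data Long table with columns `gene`, `condition`, `replicate`,
#'   `ct`, `is_reference` (logical; the reference gene rows, e.g. the
#'   actin normaliser).
#' @param calibrator The condition used as calibrator (e.g. `"control"`).
#' @return Tibble with one row per non-reference gene x condition:
#'   `gene`, `condition`, `fold_change` (from mean CTs), `fold_sd`,
#'   `n_replicates`.
#' @export
relative_expression <- function(data, calibrator = "control") {
  req <- c("gene", "condition", "replicate", "ct", "is_reference")
  stopifnot(is.data.frame(data), all(req %in% names(data)))
  data <- tibble::as_tibble(data)
  if (!calibrator %in% data$condition)
    stop("calibrator condition '", calibrator, "' not present", call. = FALSE)

  ref <- data[data$is_reference, ]
  if (nrow(ref) == 0L)
    stop("no reference-gene rows (is_reference = TRUE)", call. = FALSE)
  ref_ct <- dplyr::summarise(
    dplyr::group_by(ref, .data$condition, .data$replicate),
    ref_ct = mean(.data$ct), .groups = "drop"
  )
  targets <- data[!data$is_reference, ]
  merged <- dplyr::inner_join(targets, ref_ct,
                              by = c("condition", "replicate"))
  if (nrow(merged) < nrow(targets))
    stop("missing reference CT for some (condition, replicate) pairs",
         call. = FALSE)
  merged$dct <- merged$ct - merged$ref_ct

  calib <- dplyr::summarise(
    dplyr::group_by(merged[merged$condition == calibrator, ], .data$gene),
    dct_calib = mean(.data$dct), .groups = "drop"
  )
  merged <- dplyr::inner_join(merged, calib, by = "gene")
  merged$fold_rep <- 2^(-(merged$dct - merged$dct_calib))

  dplyr::summarise(
    dplyr::group_by(merged, .data$gene, .data$condition),
    fold_change = 2^(-(mean(.data$dct) - .data$dct_calib[[1]])),
    fold_sd = stats::sd(.data$fold_rep),
    n_replicates = dplyr::n(),
    .groups = "drop"
  )
}
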