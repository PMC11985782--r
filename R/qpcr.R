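# Delta-Ct formulas for the validation arm: relative expression and ChIP
# fold enrichment from qPCR cycle thresholds, with replicate summaries.

# internal: shared 2^-(dCt) kernel
.two_minus_dct <- function(target_ct, reference_ct) {
  if (any(!is.finite(target_ct)) || any(!is.finite(reference_ct)))
    stop("Ct values must be finite")
  if (any(target_ct <= 0) || any(reference_ct <= 0))
    stop("Ct values must be positive")
  2^(-(target_ct - reference_ct))
}

#' Normalized transcript expression from Ct values
#'
#' `2^-(dCt)` with `dCt = Ct_target - Ct_control`, the standard relative
#' quantification against an internal reference transcript.
#'
#' @param target_ct,reference_ct Cycle-threshold values (positive, finite);
#'   vectorized.
#' @return Positive relative expression values.
#' @export
#' @examples
#' normalized_expression(25, 20)  # 2^-5 = 0.03125
normalized_expression <- function(target_ct, reference_ct) {
  .two_minus_dct(target_ct, reference_ct)
}

#' ChIP fold enrichment from Ct values
#'
#' `2^-(dCt)` with `dCt = Ct_target - Ct_input`, the input-normalized
#' enrichment of immunoprecipitated chromatin.
#'
#' @param target_ct,input_ct Cycle-threshold values (positive, finite);
#'   vectorized.
#' @return Positive fold-enrichment values.
#' @export
#' @examples
#' chip_fold_enrichment(21, 24)  # 2^3 = 8
chip_fold_enrichment <- function(target_ct, input_ct) {
  .two_minus_dct(target_ct, input_ct)
}

#' Read a Ct measurement table
#'
#' TSV with header `sample target_ct reference_ct replicate`.
#'
#' @param path File path.
#' @return Data frame of Ct measurements.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample", "target_ct", "reference_ct", "replicate")
  if (!all(need %in% names(df)))
    stop("Ct table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Per-sample summary of transformed replicate measurements
#'
#' Applies the `2^-(dCt)` transform per replicate and reports the
#' arithmetic mean, sample standard deviation (NA for a single replicate)
#' and replicate count per sample.
#'
#' @param measurements Data frame with `sample`, `target_ct`,
#'   `reference_ct` columns (one row per replicate).
#' @return Data frame `sample`, `mean`, `sd`, `n`, one row per sample.
#' @export
replicate_summary <- function(measurements) {
  if (nrow(measurements) == 0L)
    stop("replicate_summary needs at least one measurement")
  value <- normalized_expression(measurements$target_ct,
                                 measurements$reference_ct)
  groups <- split(value, measurements$sample)
  out <- data.frame(
    sample = names(groups),
    mean = vapply(groups, mean, 0),
    sd = vapply(groups, function(v)
      if (length(v) > 1L) stats::sd(v) else NA_real_, 0),
    n = vapply(groups, length, 0L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
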