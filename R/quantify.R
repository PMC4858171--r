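#' Relative expression from a Ct pair
#'
#' The classic comparative-Ct quantity against an internal-standard
#' transcript: `efficiency^(ct_reference - ct_target)`. With the default
#' perfect-doubling efficiency 2 this is `2^-dCt` where
#' `dCt = ct_target - ct_reference`. Adding a constant to both Cts leaves
#' the result unchanged; for a fixed reference it is strictly decreasing
#' in the target Ct (lower Ct = more transcript).
#'
#' @param ct_target Target-gene threshold cycle(s).
#' @param ct_reference Internal-standard threshold cycle(s).
#' @param efficiency Amplification factor per cycle, in `(1, 2]`
#'   (default 2).
#' @return Relative expression, vectorized over the inputs. `NA` Cts
#'   propagate to `NA` (a missing measurement).
#' @examples
#' relative_expression(22, 20)  # 0.25
#' @export
relative_expression <- function(ct_target, ct_reference, efficiency = 2) {
  if (length(efficiency) != 1L || !is.finite(efficiency) ||
      efficiency <= 1 || efficiency > 2) {
    stop("efficiency must be in (1, 2]")
  }
  bad <- function(ct) !is.na(ct) & (!is.finite(ct) | ct <= 0)
  if (any(bad(ct_target)) || any(bad(ct_reference))) {
    stop("Ct values must be finite and positive")
  }
  efficiency^(ct_reference - ct_target)
}

#' Quantify a Ct table against its internal standard
#'
#' Converts every target gene's Ct in every sample to relative expression
#' against that same sample's internal-standard Ct, then drops the
#' standard from the output. Composed with [ct_layer()] on noise-free data
#' this is the exact identity.
#'
#' @param ct_table A `ct` [measurement_table()] containing the internal
#'   standard in every sample that has any target row.
#' @param design A [design_spec()] naming the internal standard.
#' @param efficiency Amplification factor per cycle (default 2).
#' @return A [measurement_table()] with `value_kind = "relative_expression"`.
#' @export
quantify_table <- function(ct_table, design, efficiency = 2) {
  validate_table(ct_table, design = design)
  if (nrow(ct_table) && !identical(value_kind(ct_table), "ct")) {
    stop("quantify_table expects value_kind 'ct', got '",
         value_kind(ct_table), "'")
  }
  df <- as.data.frame(ct_table)
  is_std <- df$gene == design$internal_standard
  std_ct <- df$value[is_std]
  names(std_ct) <- df$sample_id[is_std]
  targets <- df[!is_std, , drop = FALSE]
  no_std <- setdiff(unique(targets$sample_id), names(std_ct))
  if (length(no_std)) {
    stop("sample(s) with target Cts but no internal standard ('",
         design$internal_standard, "'): ", paste(no_std, collapse = ", "))
  }
  targets$value <- relative_expression(targets$value,
                                       std_ct[targets$sample_id],
                                       efficiency)
  targets$value_kind <- "relative_expression"
  log_stage("quantify", nrow(df), " Ct rows -> ", nrow(targets),
            " expression rows (standard '", design$internal_standard,
            "' dropped)")
  measurement_table(targets, design = design)
}

#' Summarize replicate measurements
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of a
#' set of replicate relative-expression values, the quantities behind
#' mean-and-error-bar reporting. A single replicate has `sd = 0` by
#' convention.
#'
#' @param values Nonempty numeric vector of finite nonnegative values.
#' @return A list of class `replicate_summary` with `mean`, `sd`, `n`.
#' @examples
#' summarize_replicates(c(1, 3))  # mean 2, sd sqrt(2), n 2
#' @export
summarize_replicates <- function(values) {
  if (length(values) == 0L) stop("cannot summarize an empty replicate set")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("replicate values must be finite and nonnegative")
  }
  n <- length(values)
  structure(
    list(mean = mean(values),
         sd = if (n == 1L) 0 else stats::sd(values),
         n = n),
    class = "replicate_summary"
  )
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("mean %.4g, sd %.4g (n = %d)\n", x$mean, x$sd, x$n))
  invisible(x)
}

#' Aggregate replicates in a measurement table
#'
#' Collapses the replicate dimension of a table to one value per
#' (strain, condition, timepoint, gene), the form the screens consume.
#'
#' @param table A `relative_expression` [measurement_table()].
#' @return A [measurement_table()] with `replicate = 1` rows holding the
#'   replicate means.
#' @export
aggregate_replicates <- function(table) {
  validate_table(table)
  df <- as.data.frame(table)
  key <- paste(df$strain, df$condition, df$timepoint_h, df$gene, sep = "\r")
  agg <- df[!duplicated(key), , drop = FALSE]
  agg$value <- as.numeric(tapply(df$value, key, mean)[
    paste(agg$strain, agg$condition, agg$timepoint_h, agg$gene, sep = "\r")])
  agg$replicate <- 1L
  agg$sample_id <- make_sample_id(agg)
  log_stage("aggregate", nrow(df), " rows -> ", nrow(agg), " replicate means")
  measurement_table(agg)
}
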