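#' Measurement tables
#'
#' A measurement table is a tidy long-format data frame with one row per
#' (sample, gene) measurement and columns `sample_id`, `strain`,
#' `condition`, `timepoint_h`, `replicate`, `gene`, `value`, `value_kind`.
#' A single table carries exactly one value kind:
#' \describe{
#'   \item{`ct`}{raw qPCR threshold cycles, in `(0, ct_cap]`}
#'   \item{`relative_expression`}{expression relative to the internal
#'     standard, nonnegative}
#'   \item{`fold_change`}{expression divided by the across-strain cell
#'     mean, nonnegative}
#'   \item{`log2_fold_change`}{log2 of the above, finite}
#' }
#' Missing measurements are absent rows, never `NA` sentinels.
#'
#' @param df Data frame with the columns above (`sample_id` is derived if
#'   absent).
#' @param value_kind The value kind; defaults to the `value_kind` column.
#' @param design Optional [design_spec()] against which all labels are
#'   checked.
#' @param ct_cap Largest admissible Ct (default 40).
#' @return A validated data frame of class `measurement_table`.
#' @export
measurement_table <- function(df, value_kind = NULL, design = NULL,
                              ct_cap = 40) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!is.null(value_kind)) df$value_kind <- value_kind
  if (is.null(df$sample_id) && all(c("strain", "condition", "timepoint_h",
                                     "replicate") %in% names(df))) {
    df$sample_id <- make_sample_id(df)
  }
  cols <- c("sample_id", "strain", "condition", "timepoint_h", "replicate",
            "gene", "value", "value_kind")
  missing_c <- setdiff(cols, names(df))
  if (length(missing_c)) {
    stop("measurement table is missing column(s): ",
         paste(missing_c, collapse = ", "))
  }
  df <- df[cols]
  df$timepoint_h <- as.numeric(df$timepoint_h)
  df$replicate <- as.integer(df$replicate)
  df$value <- as.numeric(df$value)
  for (ch in c("sample_id", "strain", "condition", "gene", "value_kind")) {
    df[[ch]] <- as.character(df[[ch]])
  }
  class(df) <- c("measurement_table", "data.frame")
  validate_table(df, design = design, ct_cap = ct_cap)
  df
}

#' Value kind of a measurement table
#'
#' @param table A [measurement_table()].
#' @return The single value kind string; `NA` for an empty table.
#' @export
value_kind <- function(table) {
  k <- unique(table$value_kind)
  if (length(k) == 0L) NA_character_ else k
}

VALUE_KINDS <- c("ct", "relative_expression", "fold_change",
                 "log2_fold_change")

#' Validate a measurement table
#'
#' Checks the long-format invariants: a single known value kind, values in
#' the kind's admissible range, no `NA` values (missingness must be encoded
#' as absent rows), no duplicated (sample, gene) rows, consistent
#' `sample_id` derivation, and — when a design is supplied — all labels
#' drawn from the design vocabularies.
#'
#' @inheritParams measurement_table
#' @param table A `measurement_table` (or conforming data frame).
#' @return Invisibly, `table`; stops with a descriptive error otherwise.
#' @export
validate_table <- function(table, design = NULL, ct_cap = 40) {
  if (nrow(table) == 0L) return(invisible(table))
  kind <- unique(table$value_kind)
  if (length(kind) != 1L) {
    stop("table mixes value kinds: ", paste(kind, collapse = ", "))
  }
  if (!kind %in% VALUE_KINDS) {
    stop("unknown value_kind '", kind, "' (expected one of: ",
         paste(VALUE_KINDS, collapse = ", "), ")")
  }
  if (anyNA(table$value)) {
    i <- which(is.na(table$value))[1L]
    stop("NA value at row ", i, " (sample ", table$sample_id[i], ", gene ",
         table$gene[i], "); missing measurements must be absent rows")
  }
  bad <- switch(kind,
    ct = table$value <= 0 | table$value > ct_cap,
    relative_expression = table$value < 0,
    fold_change = table$value < 0,
    log2_fold_change = !is.finite(table$value)
  )
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("value ", table$value[i], " out of range for kind '", kind,
         "' at row ", i, " (sample ", table$sample_id[i], ", gene ",
         table$gene[i], ")")
  }
  key <- paste(table$sample_id, table$gene, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop("duplicated (sample, gene) row at row ", i, ": sample ",
         table$sample_id[i], ", gene ", table$gene[i])
  }
  derived <- make_sample_id(table)
  if (any(derived != table$sample_id)) {
    i <- which(derived != table$sample_id)[1L]
    stop("sample_id '", table$sample_id[i], "' at row ", i,
         " does not match its key fields ('", derived[i], "')")
  }
  if (!is.null(design)) {
    validate_design(design)
    check_vocab <- function(values, vocab, what) {
      unknown <- setdiff(unique(values), vocab)
      if (length(unknown)) {
        stop("unknown ", what, " label(s) not in design: ",
             paste(unknown, collapse = ", "))
      }
    }
    check_vocab(table$strain, design$strains, "strain")
    check_vocab(table$condition, design$conditions, "condition")
    check_vocab(table$gene, c(design$gene_panel, design$internal_standard),
                "gene")
    if (length(setdiff(unique(table$timepoint_h), design$timepoints))) {
      stop("unknown timepoint(s) not in design: ",
           paste(setdiff(unique(table$timepoint_h), design$timepoints),
                 collapse = ", "))
    }
  }
  invisible(table)
}

#' Read a measurement table from CSV
#'
#' Reads the tidy long-format dialect: UTF-8 comma-separated text with the
#' exact header
#' `sample_id,strain,condition,timepoint_h,replicate,gene,value,value_kind`.
#' The table is validated on the way in; malformed input (wrong header,
#' duplicate rows, out-of-range values, labels outside a supplied design)
#' is rejected, never repaired.
#'
#' @param path Path to the CSV file.
#' @param expected_value_kind If given, the table must carry this kind.
#' @param design Optional [design_spec()] for label checking.
#' @return A [measurement_table()].
#' @export
read_measurements <- function(path, expected_value_kind = NULL,
                              design = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  want <- c("sample_id", "strain", "condition", "timepoint_h", "replicate",
            "gene", "value", "value_kind")
  if (!identical(header, want)) {
    stop("malformed header in ", path, " (line 1): got '",
         paste(header, collapse = ","), "'")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character",
                                       strain = "character",
                                       condition = "character",
                                       timepoint_h = "numeric",
                                       replicate = "integer",
                                       gene = "character",
                                       value = "numeric",
                                       value_kind = "character"))
  tab <- measurement_table(df, design = design)
  if (!is.null(expected_value_kind) && nrow(tab) > 0L &&
      !identical(value_kind(tab), expected_value_kind)) {
    stop("expected value_kind '", expected_value_kind, "' but file carries '",
         value_kind(tab), "'")
  }
  tab
}

#' Write a measurement table to CSV
#'
#' Values are serialized at full double precision (`%.17g`), so
#' `read_measurements(write_measurements(t))` reproduces `t` exactly,
#' including the absent-row encoding of missing measurements.
#'
#' @param table A [measurement_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_measurements <- function(table, path) {
  validate_table(table)
  out <- as.data.frame(table)
  out$value <- sprintf("%.17g", out$value)
  out$timepoint_h <- format_timepoint(out$timepoint_h)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.measurement_table <- function(x, ...) {
  cat("Measurement table:", nrow(x), "rows;",
      length(unique(x$sample_id)), "samples;",
      length(unique(x$gene)), "genes; value_kind =",
      if (nrow(x)) value_kind(x) else "(empty)", "\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

# stage logging used across the pipeline, off unless
# options(coexscreen.verbose = TRUE)
log_stage <- function(stage, ..., verbose = getOption("coexscreen.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[", stage, "] ", ...)
  invisible(NULL)
}
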