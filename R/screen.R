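#' Mean-centre expression within condition/time cells
#'
#' Normalizes out environmental variation before the correlation screen.
#' Within each (gene, condition, timepoint) cell, every strain's value is
#' divided by the arithmetic mean of that cell's values across all strains
#' with data (wild type included), yielding "fold change relative to the
#' mean". After this step, what remains of a gene's variation is
#' genotypic (plus noise), which is precisely what the screen should
#' correlate on. Cells with fewer than two strains carry no information
#' about relative behaviour and yield missing outputs (rows dropped); an
#' all-zero cell likewise, with a warning.
#'
#' @param table A `relative_expression` [measurement_table()].
#' @param design Optional [design_spec()] for label validation.
#' @return A [measurement_table()] with `value_kind = "fold_change"`. The
#'   across-strain mean of every retained cell is exactly 1 (to floating
#'   tolerance).
#' @examples
#' # a cell with values 2, 4, 6 across three strains becomes 0.5, 1, 1.5
#' @export
mean_center <- function(table, design = NULL) {
  validate_table(table, design = design)
  if (nrow(table) && !identical(value_kind(table), "relative_expression")) {
    stop("mean_center expects value_kind 'relative_expression', got '",
         value_kind(table), "'")
  }
  df <- as.data.frame(table)
  cell <- paste(df$gene, df$condition, df$timepoint_h, sep = "\r")
  cell_mean <- stats::ave(df$value, cell, FUN = mean)
  n_strains <- stats::ave(as.integer(factor(df$strain)), cell,
                          FUN = function(s) length(unique(s)))
  zero_cells <- cell_mean == 0
  if (any(zero_cells)) {
    warning("dropping ", length(unique(cell[zero_cells])),
            " all-zero cell(s); fold change undefined there")
  }
  keep <- n_strains >= 2L & !zero_cells
  out <- df[keep, , drop = FALSE]
  out$value <- df$value[keep] / cell_mean[keep]
  out$value_kind <- "fold_change"
  log_stage("mean_center", nrow(df), " rows -> ", nrow(out),
            " fold-change rows (", sum(!keep), " dropped)")
  measurement_table(out, design = design)
}

#' log2-transform a fold-change table
#'
#' Replaces each fold change `v` by `log2(max(v, floor))`. The floor keeps
#' exact zeros (e.g. knockouts in non-excluded strains) informative
#' instead of deleting them.
#'
#' @param table A `fold_change` [measurement_table()].
#' @param floor Positive substitution floor (default `2^-10`).
#' @return A [measurement_table()] with `value_kind = "log2_fold_change"`.
#' @export
log2_transform <- function(table, floor = 2^-10) {
  validate_table(table)
  if (nrow(table) && !identical(value_kind(table), "fold_change")) {
    stop("log2_transform expects value_kind 'fold_change', got '",
         value_kind(table), "'")
  }
  if (!is.finite(floor) || floor <= 0) stop("floor must be > 0")
  df <- as.data.frame(table)
  n_floored <- sum(df$value < floor)
  df$value <- log2(pmax(df$value, floor))
  df$value_kind <- "log2_fold_change"
  log_stage("log2_transform", nrow(df), " rows (", n_floored,
            " floored at ", floor, ")")
  measurement_table(df)
}

#' Drop each gene's own-mutant measurements
#'
#' A gene's values measured in the strain carrying its own insertional
#' knockout reflect the insertion, not regulation, so they are not
#' considered at all for that gene: the correlation screen removes them
#' before the centring means are computed. This makes the screen exactly
#' invariant to whatever value the disrupted gene takes in its own mutant.
#'
#' @param table A [measurement_table()].
#' @param design A [design_spec()].
#' @return The table without own-mutant rows.
#' @export
drop_own_mutant_rows <- function(table, design) {
  validate_design(design)
  g2m <- design$gene_to_mutant
  g2m <- g2m[g2m %in% design$strains]
  if (!length(g2m)) return(table)
  own <- table$strain == unname(g2m)[match(table$gene, names(g2m))]
  own[is.na(own)] <- FALSE
  log_stage("drop_own_mutant", sum(own), " own-mutant rows removed")
  table[!own, , drop = FALSE]
}

#' Strains excluded from a gene's correlations
#'
#' A gene measured in the strain carrying its own insertional knockout is
#' trivially misexpressed there, so those samples must not contribute to
#' its correlations. The mask is the gene's own profiled mutant (if any)
#' plus any user leave-out strains; genes whose mutant was never profiled
#' contribute nothing.
#'
#' @param gene A gene label in the design's panel.
#' @param design A [design_spec()].
#' @param extra_leave_out Character vector of additional strains to drop
#'   (leave-strain-out robustness analysis).
#' @return Character vector of strain labels.
#' @examples
#' exclusion_mask("CYG56", default_design())      # "cyg56"
#' exclusion_mask("42.49CG1", default_design())   # none: 42.49 not profiled
#' @export
exclusion_mask <- function(gene, design, extra_leave_out = character()) {
  validate_design(design)
  if (!gene %in% design$gene_panel) {
    stop("unknown gene '", gene, "' (not in the design's gene panel)")
  }
  unknown <- setdiff(extra_leave_out, design$strains)
  if (length(unknown)) {
    stop("leave-out strain(s) not in design: ", paste(unknown, collapse = ", "))
  }
  own <- design$gene_to_mutant[gene]
  own <- own[!is.na(own) & own %in% design$strains]
  union(unname(own), extra_leave_out)
}

#' Pearson correlation with exact t-transform p-value
#'
#' Textbook sample Pearson coefficient of a complete pair of vectors, with
#' the two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom. A perfect correlation (`|r| = 1`) reports
#' the smallest representable positive double as its p-value.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, neither constant.
#' @return A list with `r`, `r2`, `p`, `n`.
#' @examples
#' pearson_cor(c(1, 2, 3), c(1, 3, 2))  # r = 0.5
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("insufficient data: need n >= 3 complete pairs, have ", n)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    stop("undefined correlation: ", if (sxx == 0) "x" else "y",
         " is constant")
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) {
    .Machine$double.xmin
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, r2 = r^2, p = max(p, .Machine$double.xmin), n = n)
}

#' Squared correlation implied by a Pearson p-value
#'
#' Inverts the two-sided t transform: given a p-value and a sample size,
#' returns the `R^2` that would have produced it. Useful as a consistency
#' check between a reported (R^2, p) pair and the sample count behind it.
#'
#' @param p Two-sided p-value.
#' @param n Sample size(s), `n >= 3` (vectorized).
#' @return `R^2 = t^2 / (t^2 + n - 2)` where
#'   `t = qt(p/2, n - 2, lower.tail = FALSE)`.
#' @export
invert_pearson_p <- function(p, n) {
  if (any(n < 3)) stop("n must be >= 3")
  if (p <= 0 || p > 1) stop("p must be in (0, 1]")
  tstat <- stats::qt(p / 2, df = n - 2, lower.tail = FALSE)
  tstat^2 / (tstat^2 + n - 2)
}

#' Co-expression screen against a reference gene
#'
#' The core computation: correlate every candidate gene's log2 fold change
#' with the reference gene's across all admissible samples of the
#' factorial design. A `relative_expression` input is first taken through
#' [mean_center()] and [log2_transform()]; a `fold_change` or
#' `log2_fold_change` input resumes the pipeline mid-way. For each
#' candidate, samples from excluded strains are removed — by default the
#' union of the candidate's and the reference's own profiled mutants (a
#' sample must be admissible for both members of the pair), plus any
#' `leave_out` strains — and the correlation runs on pairwise-complete
#' rows. Results are ranked by `r2` (ties broken by gene label), with the
#' reference-vs-itself control row (`r2 = 1`) included. Degenerate genes
#' (constant, or fewer than 3 complete pairs) appear as flagged rows, not
#' errors.
#'
#' @param table A [measurement_table()] of kind `relative_expression`,
#'   `fold_change` or `log2_fold_change`.
#' @param design A [design_spec()].
#' @param reference Reference gene (default the design's).
#' @param leave_out Strains removed from every pair (leave-strain-out
#'   robustness).
#' @param pair_exclusion `"union"` (default): drop both genes' own
#'   mutants; `"per_gene"`: drop only the candidate's own mutant.
#' @param log2_floor Floor passed to [log2_transform()].
#' @return An object of class `coex_screen`: a list with `results` (data
#'   frame of gene, r, r2, p, n, excluded_strains, note), `reference`,
#'   `leave_out`, `pair_exclusion`, `design`, `n_samples`, `call`.
#' @examples
#' tab <- simulate_dataset(default_config(), seed = 1)
#' scr <- coexpression_screen(tab, default_design())
#' head(coef(scr), 3)
#' @export
coexpression_screen <- function(table, design,
                                reference = design$reference_gene,
                                leave_out = character(),
                                pair_exclusion = c("union", "per_gene"),
                                log2_floor = 2^-10) {
  pair_exclusion <- match.arg(pair_exclusion)
  validate_design(design)
  validate_table(table, design = design)
  kind <- value_kind(table)
  if (identical(kind, "relative_expression")) {
    table <- drop_own_mutant_rows(table, design)
    table <- log2_transform(mean_center(table, design), floor = log2_floor)
  } else if (identical(kind, "fold_change")) {
    table <- log2_transform(table, floor = log2_floor)
  } else if (!identical(kind, "log2_fold_change")) {
    stop("cannot screen a table of value_kind '", kind, "'")
  }
  if (!reference %in% design$gene_panel) {
    stop("reference gene '", reference, "' is not in the design's panel")
  }
  if (!reference %in% table$gene) {
    stop("reference gene '", reference, "' has no data in the table")
  }

  df <- as.data.frame(table)
  samples <- unique(df$sample_id)
  genes <- intersect(design$gene_panel, unique(df$gene))
  wide <- matrix(NA_real_, nrow = length(samples), ncol = length(genes),
                 dimnames = list(samples, genes))
  wide[cbind(match(df$sample_id, samples), match(df$gene, genes))] <- df$value
  strain_of <- df$strain[match(samples, df$sample_id)]

  ref_mask <- exclusion_mask(reference, design)
  rows <- lapply(genes, function(g) {
    own <- exclusion_mask(g, design)
    excl <- switch(pair_exclusion,
                   union = union(own, if (g == reference) character() else ref_mask),
                   per_gene = own)
    reasons <- c(
      if (length(intersect(own, excl)))
        paste0(intersect(own, excl), ":own_mutant"),
      if (pair_exclusion == "union" && g != reference)
        paste0(setdiff(intersect(ref_mask, excl), own), ":reference_mutant"),
      if (length(leave_out)) paste0(leave_out, ":leave_out")
    )
    excl <- union(excl, leave_out)
    use <- !strain_of %in% excl
    x <- wide[use, g]
    y <- wide[use, reference]
    res <- if (g == reference) {
      n_ok <- sum(is.finite(x))
      if (n_ok >= 3L) {
        list(r = 1, r2 = 1, p = .Machine$double.xmin, n = n_ok)
      } else {
        NULL
      }
    } else {
      tryCatch(pearson_cor(x, y), error = function(e) e)
    }
    if (is.null(res) || inherits(res, "error")) {
      data.frame(gene = g, r = NA_real_, r2 = NA_real_, p = NA_real_,
                 n = sum(is.finite(x) & is.finite(y)),
                 excluded_strains = paste(reasons, collapse = ";"),
                 note = if (is.null(res)) "insufficient data"
                        else conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene = g, r = res$r, r2 = res$r2, p = res$p, n = res$n,
                 excluded_strains = paste(reasons, collapse = ";"),
                 note = if (g == reference) "reference self-correlation" else "",
                 stringsAsFactors = FALSE)
    }
  })
  results <- do.call(rbind, rows)
  ord <- order(-results$r2, results$gene, na.last = TRUE,
               method = "radix")
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  log_stage("correlate", length(genes), " genes vs ", reference, " over ",
            length(samples), " samples")
  structure(
    list(results = results, reference = reference, leave_out = leave_out,
         pair_exclusion = pair_exclusion, design = design,
         n_samples = length(samples), call = match.call()),
    class = "coex_screen"
  )
}

#' @export
print.coex_screen <- function(x, ...) {
  cat("Co-expression screen vs", x$reference,
      if (length(x$leave_out))
        paste0("(leave-out: ", paste(x$leave_out, collapse = ", "), ")"),
      "\n")
  cat(x$n_samples, "samples;", nrow(x$results), "genes;",
      "pair exclusion:", x$pair_exclusion, "\n\n")
  top <- x$results[x$results$gene != x$reference, , drop = FALSE]
  top <- utils::head(top, 5L)
  print(data.frame(gene = top$gene, r2 = round(top$r2, 3),
                   p = signif(top$p, 3), n = top$n), row.names = FALSE)
  invisible(x)
}

#' @export
summary.coex_screen <- function(object, ...) {
  res <- object$results
  cat("Co-expression screen vs", object$reference, "\n")
  cat("  pair exclusion:", object$pair_exclusion,
      "| leave-out:", if (length(object$leave_out))
        paste(object$leave_out, collapse = ", ") else "(none)", "\n\n")
  show <- res
  show$r <- round(show$r, 4)
  show$r2 <- round(show$r2, 4)
  show$p <- signif(show$p, 3)
  print(show, row.names = FALSE)
  invisible(res)
}

#' @describeIn coexpression_screen Named vector of `r2` per gene, in
#'   ranked order (reference control row excluded).
#' @param object,... A `coex_screen` object (S3 method arguments).
#' @export
coef.coex_screen <- function(object, ...) {
  res <- object$results[object$results$gene != object$reference, ]
  stats::setNames(res$r2, res$gene)
}

#' @export
plot.coex_screen <- function(x, highlight = 3, ...) {
  r2 <- coef(x)
  cols <- rep("grey70", length(r2))
  cols[seq_len(min(highlight, length(r2)))] <- "grey30"
  graphics::barplot(r2, col = cols, las = 2, ylim = c(0, 1),
                    ylab = expression(R^2),
                    main = paste("Correlation with", x$reference), ...)
  invisible(x)
}
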