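#' Mean fold change of one gene in one strain
#'
#' Averages all of a strain's fold-change values for a gene across the
#' full factorial of conditions and timepoints (16 points under the
#' default design with complete data), so the profile reflects the
#' general behaviour of the gene in that mutant and is robust to
#' occasional misregulation in a single condition.
#'
#' @param fc_table A `fold_change` [measurement_table()].
#' @param strain,gene The (strain, gene) cell to profile.
#' @param mean_type `"linear"` (default): arithmetic mean of fold changes;
#'   `"geometric"`: back-transformed mean of log2 fold changes (zeros
#'   floored at `2^-10`).
#' @return A list of class `misreg_profile` with `strain`, `gene`,
#'   `mean_fold_change`, `n_points` (and no flag yet; see
#'   [flag_misregulation()]).
#' @export
strain_mean <- function(fc_table, strain, gene,
                        mean_type = c("linear", "geometric")) {
  mean_type <- match.arg(mean_type)
  validate_table(fc_table)
  if (nrow(fc_table) && !identical(value_kind(fc_table), "fold_change")) {
    stop("strain_mean expects value_kind 'fold_change', got '",
         value_kind(fc_table), "'")
  }
  v <- fc_table$value[fc_table$strain == strain & fc_table$gene == gene]
  if (!length(v)) {
    stop("no data points for gene '", gene, "' in strain '", strain, "'")
  }
  m <- switch(mean_type,
              linear = mean(v),
              geometric = 2^mean(log2(pmax(v, 2^-10))))
  structure(list(strain = strain, gene = gene, mean_fold_change = m,
                 n_points = length(v)),
            class = "misreg_profile")
}

#' @export
print.misreg_profile <- function(x, ...) {
  cat(sprintf("%s in %s: mean fold change %.3g (n = %d)%s\n",
              x$gene, x$strain, x$mean_fold_change, x$n_points,
              if (!is.null(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Flag misregulation at a fold cutoff
#'
#' Classifies mean fold changes against a symmetric threshold: `"down"`
#' strictly below `1/cutoff`, `"up"` strictly above `cutoff`, `"none"`
#' otherwise. Boundary values are not flagged (the cutoff delimits a
#' highlight zone, not a test).
#'
#' @param x A `misreg_profile` from [strain_mean()], or a numeric vector
#'   of mean fold changes.
#' @param cutoff Fold threshold, `> 1` (default 3).
#' @return The profile with a `flag` field added, or a character vector of
#'   flags for numeric input.
#' @examples
#' flag_misregulation(c(0.2, 1, 3, 3.01))  # down none none up
#' @export
flag_misregulation <- function(x, cutoff = 3) {
  if (!is.finite(cutoff) || cutoff <= 1) stop("cutoff must be > 1")
  if (inherits(x, "misreg_profile")) {
    x$flag <- flag_misregulation(x$mean_fold_change, cutoff)
    x$cutoff <- cutoff
    return(x)
  }
  ifelse(x < 1 / cutoff, "down", ifelse(x > cutoff, "up", "none"))
}

#' Misregulation screen over all mutants
#'
#' Profiles every (mutant strain, panel gene) pair: the mean fold change
#' over all of the strain's samples, flagged at the fold cutoff. The wild
#' type contributes to the centring means but is not itself profiled. A
#' `relative_expression` input is mean-centred first.
#'
#' @param table A [measurement_table()] of kind `relative_expression` or
#'   `fold_change`.
#' @param design A [design_spec()].
#' @param cutoff Fold threshold (default 3).
#' @param mean_type Passed to [strain_mean()].
#' @return An object of class `misreg_screen`: a list with `results`
#'   (data frame of strain, gene, mean_fold_change, n_points, flag, note;
#'   strain-major, gene-minor in design order), `cutoff`, `design`,
#'   `call`.
#' @examples
#' tab <- simulate_dataset(default_config(), seed = 1)
#' mis <- misregulation_screen(tab, default_design())
#' subset(mis$results, flag != "none" & strain == "54.10")
#' @export
misregulation_screen <- function(table, design, cutoff = 3,
                                 mean_type = c("linear", "geometric")) {
  mean_type <- match.arg(mean_type)
  if (!is.finite(cutoff) || cutoff <= 1) stop("cutoff must be > 1")
  validate_design(design)
  validate_table(table, design = design)
  kind <- value_kind(table)
  if (identical(kind, "relative_expression")) {
    table <- mean_center(table, design)
  } else if (!identical(kind, "fold_change")) {
    stop("cannot profile a table of value_kind '", kind, "'")
  }
  mutants <- setdiff(design$strains, design$wild_type)
  grid <- expand.grid(gene = design$gene_panel, strain = mutants,
                      stringsAsFactors = FALSE)[, c("strain", "gene")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pr <- tryCatch(
      flag_misregulation(
        strain_mean(table, grid$strain[i], grid$gene[i], mean_type),
        cutoff),
      error = function(e) e)
    if (inherits(pr, "error")) {
      data.frame(strain = grid$strain[i], gene = grid$gene[i],
                 mean_fold_change = NA_real_, n_points = 0L,
                 flag = NA_character_, note = conditionMessage(pr),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(strain = pr$strain, gene = pr$gene,
                 mean_fold_change = pr$mean_fold_change,
                 n_points = pr$n_points, flag = pr$flag, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  log_stage("misregulation", nrow(results), " (strain, gene) profiles at ",
            cutoff, "-fold cutoff")
  structure(
    list(results = results, cutoff = cutoff, mean_type = mean_type,
         design = design, call = match.call()),
    class = "misreg_screen"
  )
}

#' @export
print.misreg_screen <- function(x, ...) {
  res <- x$results
  hits <- res[!is.na(res$flag) & res$flag != "none", , drop = FALSE]
  cat("Misregulation screen:", nrow(res), "profiles over",
      length(unique(res$strain)), "mutants at a", x$cutoff, "fold cutoff\n")
  cat(nrow(hits), "flagged profile(s)\n")
  if (nrow(hits)) {
    hits$mean_fold_change <- signif(hits$mean_fold_change, 3)
    print(hits[c("strain", "gene", "mean_fold_change", "n_points", "flag")],
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.misreg_screen <- function(object, ...) {
  res <- object$results
  res$mean_fold_change <- signif(res$mean_fold_change, 4)
  print(res, row.names = FALSE)
  invisible(object$results)
}

#' @export
plot.misreg_screen <- function(x, strain = NULL, ...) {
  res <- x$results
  if (is.null(strain)) strain <- res$strain[1L]
  res <- res[res$strain == strain & !is.na(res$mean_fold_change), ]
  graphics::barplot(stats::setNames(log2(res$mean_fold_change), res$gene),
                    las = 2, ylab = "log2 mean fold change",
                    main = paste("Misregulation in", strain), ...)
  graphics::abline(h = c(-1, 1) * log2(x$cutoff), lty = 2, col = "grey40")
  invisible(x)
}
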