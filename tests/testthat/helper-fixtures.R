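# Shared fixtures: small designs and in-code tables.

tiny_design <- function(n_strains = 3, n_conditions = 2, n_timepoints = 2,
                        n_genes = 3, with_mutants = FALSE) {
  strains <- c("wt", if (n_strains > 1) paste0("mut", seq_len(n_strains - 1)))
  genes <- c("REF", if (n_genes > 1) paste0("g", seq_len(n_genes - 1)))
  g2m <- character()
  if (with_mutants) {
    # each non-reference gene knocked out in its own mutant where one exists
    k <- min(n_genes - 1, n_strains - 1)
    g2m <- stats::setNames(paste0("mut", seq_len(k)), paste0("g", seq_len(k)))
  }
  design_spec(
    strains = strains, wild_type = "wt",
    conditions = paste0("cond", seq_len(n_conditions)),
    timepoints = seq_len(n_timepoints),
    gene_panel = genes, reference_gene = "REF",
    internal_standard = "STD",
    gene_to_mutant = g2m
  )
}

# complete table over a design with values supplied or drawn lognormally
full_table <- function(design, values = NULL, value_kind = "relative_expression",
                       seed = NULL) {
  keys <- enumerate_design(design)
  genes <- design$gene_panel
  df <- data.frame(
    sample_id = rep(keys$sample_id, each = length(genes)),
    strain = rep(keys$strain, each = length(genes)),
    condition = rep(keys$condition, each = length(genes)),
    timepoint_h = rep(keys$timepoint_h, each = length(genes)),
    replicate = rep(keys$replicate, each = length(genes)),
    gene = rep(genes, times = nrow(keys)),
    stringsAsFactors = FALSE
  )
  if (is.null(values)) {
    if (!is.null(seed)) set.seed(seed)
    values <- 2^stats::rnorm(nrow(df), 0, 1)
  }
  df$value <- values
  measurement_table(df, value_kind = value_kind, design = design)
}

# textbook Pearson oracle, written independently of pearson_cor():
# explicit loops and the raw sum formulas.
oracle_pearson <- function(x, y) {
  keep <- which(is.finite(x) & is.finite(y))
  n <- length(keep)
  sx <- 0; sy <- 0; sxx <- 0; syy <- 0; sxy <- 0
  for (i in keep) {
    sx <- sx + x[i]; sy <- sy + y[i]
    sxx <- sxx + x[i]^2; syy <- syy + y[i]^2
    sxy <- sxy + x[i] * y[i]
  }
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), n - 2), n = n)
}

# brute-force screen oracle: per gene, loop over samples applying the
# exclusion rule directly on the long table.
oracle_screen <- function(log_table, design, reference,
                          leave_out = character()) {
  df <- as.data.frame(log_table)
  ref_mut <- unname(design$gene_to_mutant[reference])
  out <- list()
  for (g in setdiff(unique(df$gene), reference)) {
    g_mut <- unname(design$gene_to_mutant[g])
    banned <- c(g_mut, ref_mut, leave_out)
    banned <- banned[!is.na(banned)]
    x <- c(); y <- c()
    for (sid in unique(df$sample_id)) {
      strain <- df$strain[df$sample_id == sid][1]
      if (strain %in% banned) next
      vg <- df$value[df$sample_id == sid & df$gene == g]
      vr <- df$value[df$sample_id == sid & df$gene == reference]
      if (length(vg) == 1 && length(vr) == 1) {
        x <- c(x, vg); y <- c(y, vr)
      }
    }
    if (length(x) >= 3 && stats::sd(x) > 0 && stats::sd(y) > 0) {
      out[[g]] <- c(oracle_pearson(x, y), gene = g)
    }
  }
  out
}
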