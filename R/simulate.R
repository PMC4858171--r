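#' Generator configuration for synthetic screen data
#'
#' Describes a phenomenological model of the factorial qRT-PCR experiment
#' on the log2 scale. For sample s (strain, condition, timepoint) and gene
#' g the simulated relative expression is
#' \deqn{2^{b_g + c_{g,cond} + t_{g,time} + e_{g,strain} + \epsilon}}
#' with baseline `b`, condition effect `c`, time effect `t`, genotype
#' effect `e` (this is where shared-regulator co-regulation across strains
#' lives) and Gaussian noise `eps ~ N(0, noise_sd_log2^2)` (multiplicative
#' lognormal noise on the linear scale). A gene measured in the strain
#' carrying its own insertional knockout is set to
#' `2^knockout_floor_log2` exactly. All values are clipped below at
#' `detection_floor`.
#'
#' @param design A [design_spec()].
#' @param baseline_log2 Scalar or gene-named vector of baseline log2
#'   expression (relative units; default 0, i.e. expression 1).
#' @param condition_effects Numeric matrix `gene x condition` of log2
#'   shifts (dimnames required), or `NULL` for none. Partial matrices are
#'   zero-filled for unlisted genes/conditions.
#' @param time_effects Numeric matrix `gene x timepoint` (column names are
#'   the timepoints as written by `as.character`), or `NULL`.
#' @param genotype_effects Numeric matrix `gene x strain`, or `NULL`.
#' @param knockout_floor_log2 log2 value assigned to a gene in its own
#'   profiled mutant (default -10, i.e. ~0.1% of baseline).
#' @param noise_sd_log2 SD of additive Gaussian noise on the log2 scale
#'   (default 0.5, a typical qRT-PCR-scale scatter; treat as a free
#'   parameter).
#' @param detection_floor Smallest reportable relative expression
#'   (default `2^-10`).
#' @param seed Integer RNG seed stored with the config.
#' @return An object of class `generator_config`.
#' @seealso [simulate_dataset()], [default_config()], [null_config()]
#' @export
generator_config <- function(design,
                             baseline_log2 = 0,
                             condition_effects = NULL,
                             time_effects = NULL,
                             genotype_effects = NULL,
                             knockout_floor_log2 = -10,
                             noise_sd_log2 = 0.5,
                             detection_floor = 2^-10,
                             seed = 1L) {
  validate_design(design)
  genes <- design$gene_panel
  base <- rep(0, length(genes))
  names(base) <- genes
  if (length(baseline_log2) == 1L && is.null(names(baseline_log2))) {
    base[] <- baseline_log2
  } else {
    unknown <- setdiff(names(baseline_log2), genes)
    if (length(unknown)) stop("baseline_log2 names not in panel: ",
                              paste(unknown, collapse = ", "))
    base[names(baseline_log2)] <- baseline_log2
  }
  cfg <- structure(
    list(
      design = design,
      baseline_log2 = base,
      condition_effects = fill_effects(condition_effects, genes,
                                       design$conditions, "condition"),
      time_effects = fill_effects(time_effects, genes,
                                  format_timepoint(design$timepoints),
                                  "timepoint"),
      genotype_effects = fill_effects(genotype_effects, genes,
                                      design$strains, "strain"),
      knockout_floor_log2 = knockout_floor_log2,
      noise_sd_log2 = noise_sd_log2,
      detection_floor = detection_floor,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
  validate_config(cfg)
  cfg
}

# expand a possibly partial effects matrix to full gene x level, zero-filled
fill_effects <- function(m, genes, levels, what) {
  full <- matrix(0, nrow = length(genes), ncol = length(levels),
                 dimnames = list(genes, levels))
  if (is.null(m)) return(full)
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(what, " effects matrix needs gene rownames and ", what,
         " colnames")
  }
  if (length(setdiff(rownames(m), genes))) {
    stop(what, " effects reference unknown gene(s): ",
         paste(setdiff(rownames(m), genes), collapse = ", "))
  }
  if (length(setdiff(colnames(m), levels))) {
    stop(what, " effects reference unknown ", what, "(s): ",
         paste(setdiff(colnames(m), levels), collapse = ", "))
  }
  full[rownames(m), colnames(m)] <- m
  full
}

#' Validate a generator configuration
#'
#' @param config A `generator_config`.
#' @return Invisibly, `config`; stops with an error naming the violated
#'   invariant otherwise.
#' @export
validate_config <- function(config) {
  validate_design(config$design)
  if (!is.finite(config$noise_sd_log2) || config$noise_sd_log2 < 0) {
    stop("noise_sd_log2 must be >= 0")
  }
  if (!is.finite(config$detection_floor) || config$detection_floor <= 0) {
    stop("detection_floor must be > 0")
  }
  if (!is.finite(config$knockout_floor_log2)) {
    stop("knockout_floor_log2 must be finite")
  }
  if (anyNA(config$baseline_log2) || anyNA(config$condition_effects) ||
      anyNA(config$time_effects) || anyNA(config$genotype_effects)) {
    stop("effect maps must not contain NA")
  }
  invisible(config)
}

#' Default generator configuration
#'
#' Encodes the qualitative regulatory structure the screen assumes, with
#' effect magnitudes chosen as plausible qRT-PCR-scale values:
#' \itemize{
#'   \item ammonium induction of `CYG56` and `CDP1` (+2 log2 in the
#'     8 mM ammonium media, +1 under 1 mM ammonium), with a mild decay of
#'     both by 24 h;
#'   \item a latent shared regulator whose activity differs across strains
#'     and onto which `CYG56`, `42.49CG1` (loading 1) and `85.37CG`,
#'     `209.82CG` (loading 0.9) load — this is what makes the planted trio
#'     co-expressed with the reference; `CDP1` loads weakly (0.1);
#'   \item the strain 54.10 signature: -3 log2 on `CYG56`, `CDP1` and
#'     `42.49CG1`, -1 on `85.37CG`, 0 on `209.82CG` and the stable genes;
#'   \item stable genes (`20.40CG1`, `258.90CG`, `42.49CG2`,
#'     `106.20CG1/2`, placeholders) carry no genotype effects;
#'   \item insertional knockouts of each panel gene in its own profiled
#'     mutant at `knockout_floor_log2 = -10`.
#' }
#'
#' @param noise_sd_log2 Noise SD on the log2 scale (default 0.5).
#' @param seed Stored RNG seed (default 1).
#' @return A [generator_config()] over [default_design()].
#' @export
default_config <- function(noise_sd_log2 = 0.5, seed = 1L) {
  design <- default_design()
  genes <- design$gene_panel

  cond <- matrix(0, nrow = 2, ncol = 3,
                 dimnames = list(c("CYG56", "CDP1"),
                                 c("NH4_8mM", "NO3_4mM+NH4_8mM",
                                   "NO3_4mM+NH4_1mM")))
  cond[, c("NH4_8mM", "NO3_4mM+NH4_8mM")] <- 2
  cond[, "NO3_4mM+NH4_1mM"] <- 1

  tim <- matrix(0, nrow = 2, ncol = 1,
                dimnames = list(c("CYG56", "CDP1"), "24"))
  tim[, "24"] <- -0.5

  latent <- c("704" = 0, "cyg56" = 0.5, "cdp1" = -2, "20.40" = 1.5,
              "54.10" = 0, "258.90" = -1, "259.89" = 2,
              "N10" = -2.5, "N24" = 1)
  loading <- c("CYG56" = 1, "42.49CG1" = 1, "85.37CG" = 0.9,
               "209.82CG" = 0.9, "CDP1" = 0.1)
  geno <- outer(loading, latent)
  geno[c("CYG56", "CDP1", "42.49CG1"), "54.10"] <- -3
  geno["85.37CG", "54.10"] <- -1
  geno["209.82CG", "54.10"] <- 0

  generator_config(
    design = design,
    baseline_log2 = stats::setNames(rep(0, length(genes)), genes),
    condition_effects = cond,
    time_effects = tim,
    genotype_effects = geno,
    knockout_floor_log2 = -10,
    noise_sd_log2 = noise_sd_log2,
    detection_floor = 2^-10,
    seed = seed
  )
}

#' Null generator configuration
#'
#' Strips all genotype effects and knockouts from a configuration, leaving
#' only condition effects, time effects and noise. Data generated under
#' the null carry no genotypic co-regulation by construction, so the
#' downstream correlation screen should find nothing: its p-values are
#' uniform. Used for type-I-error calibration.
#'
#' @param config A [generator_config()].
#' @return A `generator_config` with zeroed genotype structure.
#' @export
null_config <- function(config) {
  validate_config(config)
  config$genotype_effects[] <- 0
  config$design$gene_to_mutant <- character()
  config
}

#' Simulate a synthetic measurement table
#'
#' Draws one relative-expression value per (sample, gene) over
#' `enumerate_design(config$design, 1)` under the model described in
#' [generator_config()]. The noise stream is drawn sample-major,
#' gene-minor from a single RNG seeded once, so an identical seed yields a
#' bit-identical table and adding genes at the end of the panel does not
#' perturb earlier columns within a sample. Knockout cells (a gene in its
#' own profiled mutant) take `2^knockout_floor_log2` exactly, without
#' noise. All values are clipped below at `detection_floor`.
#'
#' @param config A [generator_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A [measurement_table()] with `value_kind = "relative_expression"`.
#' @examples
#' tab <- simulate_dataset(default_config(), seed = 7)
#' nrow(tab)  # 144 samples x 12 genes
#' @export
simulate_dataset <- function(config, seed = NULL) {
  validate_config(config)
  design <- config$design
  keys <- enumerate_design(design, 1L)
  genes <- design$gene_panel
  n_s <- nrow(keys)
  n_g <- length(genes)

  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  noise <- matrix(stats::rnorm(n_s * n_g, 0, config$noise_sd_log2),
                  nrow = n_s, ncol = n_g, byrow = TRUE)

  base_part <- matrix(rep(config$baseline_log2, each = n_s), nrow = n_s)
  cond_part <- t(config$condition_effects[, keys$condition, drop = FALSE])
  time_part <- t(config$time_effects[, format_timepoint(keys$timepoint_h),
                                     drop = FALSE])
  geno_part <- t(config$genotype_effects[, keys$strain, drop = FALSE])
  log2val <- base_part + cond_part + time_part + geno_part + noise

  g2m <- design$gene_to_mutant
  g2m <- g2m[g2m %in% design$strains]
  for (g in names(g2m)) {
    log2val[keys$strain == g2m[[g]], match(g, genes)] <-
      config$knockout_floor_log2
  }

  value <- pmax(2^log2val, config$detection_floor)
  out <- data.frame(
    sample_id = rep(keys$sample_id, each = n_g),
    strain = rep(keys$strain, each = n_g),
    condition = rep(keys$condition, each = n_g),
    timepoint_h = rep(keys$timepoint_h, each = n_g),
    replicate = rep(keys$replicate, each = n_g),
    gene = rep(genes, times = n_s),
    value = as.vector(t(value)),
    value_kind = "relative_expression",
    stringsAsFactors = FALSE
  )
  log_stage("simulate", n_s, " samples x ", n_g, " genes -> ", nrow(out),
            " rows (seed ", seed, ")")
  measurement_table(out, design = design)
}

#' Overlay a raw-Ct layer on simulated expression
#'
#' Converts a relative-expression table into the raw qPCR threshold-cycle
#' signal that would have produced it under perfect doubling:
#' `Ct_gene = reference_ct - log2(relative_expression)`, plus one
#' internal-standard row per sample with `Ct = reference_ct`. Cts above
#' `ct_cap` fall below the detection limit and are emitted as missing
#' (absent rows). `quantify_table()` inverts this layer exactly.
#'
#' @param table A `relative_expression` [measurement_table()] with
#'   strictly positive values.
#' @param design A [design_spec()] naming the internal standard.
#' @param reference_ct Ct of the internal standard in every sample
#'   (default 20).
#' @param ct_cap Detection cap (default 40).
#' @return A [measurement_table()] with `value_kind = "ct"`.
#' @export
ct_layer <- function(table, design, reference_ct = 20, ct_cap = 40) {
  validate_table(table, design = design)
  if (nrow(table) && !identical(value_kind(table), "relative_expression")) {
    stop("ct_layer expects value_kind 'relative_expression', got '",
         value_kind(table), "'")
  }
  if (any(table$value <= 0)) stop("nonpositive expression cannot be Ct-encoded")
  if (!is.finite(reference_ct) || reference_ct <= 0) {
    stop("reference_ct must be positive")
  }
  targets <- as.data.frame(table)
  targets$value <- reference_ct - log2(targets$value)
  dropped <- targets$value > ct_cap
  targets <- targets[!dropped, , drop = FALSE]
  std <- unique(as.data.frame(table)[c("sample_id", "strain", "condition",
                                       "timepoint_h", "replicate")])
  std$gene <- design$internal_standard
  std$value <- reference_ct
  out <- rbind(targets[names(std)], std)
  out$value_kind <- "ct"
  log_stage("ct_layer", nrow(table), " expression rows -> ", nrow(out),
            " Ct rows (", sum(dropped), " beyond cap ", ct_cap, ")")
  measurement_table(out, design = design, ct_cap = ct_cap)
}
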