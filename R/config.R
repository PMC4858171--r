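#' Read a generator configuration from YAML
#'
#' The file mirrors [generator_config()]: a `design` block (see
#' [read_design()]) plus `baseline_log2` (map gene -> log2),
#' `condition_effects`, `time_effects`, `genotype_effects` (nested maps
#' gene -> level -> log2 shift), `knockout_floor_log2`, `noise_sd_log2`,
#' `detection_floor` and `seed`. Omitted effects default to zero. The
#' shipped default lives at
#' `system.file("extdata", "non1_screen.yaml", package = "coexscreen")`.
#'
#' @param path Path to a YAML file.
#' @return A validated [generator_config()].
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  design <- as_design_spec(cfg$design)
  nested_to_matrix <- function(nested) {
    if (is.null(nested) || !length(nested)) return(NULL)
    cols <- unique(unlist(lapply(nested, names)))
    m <- matrix(0, nrow = length(nested), ncol = length(cols),
                dimnames = list(names(nested), cols))
    for (g in names(nested)) {
      m[g, names(nested[[g]])] <- unlist(nested[[g]])
    }
    m
  }
  pick <- function(name, default) {
    if (is.null(cfg[[name]])) default else cfg[[name]]
  }
  generator_config(
    design = design,
    baseline_log2 = if (is.null(cfg$baseline_log2)) 0 else unlist(cfg$baseline_log2),
    condition_effects = nested_to_matrix(cfg$condition_effects),
    time_effects = nested_to_matrix(cfg$time_effects),
    genotype_effects = nested_to_matrix(cfg$genotype_effects),
    knockout_floor_log2 = pick("knockout_floor_log2", -10),
    noise_sd_log2 = pick("noise_sd_log2", 0.5),
    detection_floor = pick("detection_floor", 2^-10),
    seed = pick("seed", 1L)
  )
}

#' Write a generator configuration to YAML
#'
#' Inverse of [read_config()]; zero effect entries are omitted to keep
#' the file readable.
#'
#' @param config A [generator_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  matrix_to_nested <- function(m) {
    rows <- lapply(rownames(m), function(g) {
      v <- m[g, m[g, ] != 0, drop = TRUE]
      if (is.null(names(v))) names(v) <- colnames(m)[m[g, ] != 0]
      as.list(v)
    })
    names(rows) <- rownames(m)
    rows[vapply(rows, length, 1L) > 0]
  }
  d <- config$design
  out <- list(
    design = list(
      strains = d$strains, wild_type = d$wild_type,
      conditions = d$conditions, timepoints = d$timepoints,
      gene_panel = d$gene_panel, reference_gene = d$reference_gene,
      internal_standard = d$internal_standard,
      gene_to_mutant = as.list(d$gene_to_mutant)
    ),
    baseline_log2 = as.list(config$baseline_log2[config$baseline_log2 != 0]),
    condition_effects = matrix_to_nested(config$condition_effects),
    time_effects = matrix_to_nested(config$time_effects),
    genotype_effects = matrix_to_nested(config$genotype_effects),
    knockout_floor_log2 = config$knockout_floor_log2,
    noise_sd_log2 = config$noise_sd_log2,
    detection_floor = config$detection_floor,
    seed = config$seed
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Generator config over:\n")
  print(x$design)
  nz <- function(m) sum(m != 0)
  cat("  nonzero effects: condition ", nz(x$condition_effects),
      ", time ", nz(x$time_effects),
      ", genotype ", nz(x$genotype_effects), "\n", sep = "")
  cat("  noise sd (log2):", x$noise_sd_log2,
      "| knockout floor (log2):", x$knockout_floor_log2,
      "| detection floor:", x$detection_floor,
      "| seed:", x$seed, "\n")
  invisible(x)
}
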