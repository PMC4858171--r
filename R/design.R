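#' Experimental design specification
#'
#' Constructs and validates the vocabulary of a factorial
#' strain x nitrogen-condition x time-course expression experiment:
#' which strains were profiled, which nitrogen contexts and harvest times
#' were sampled, which genes were measured, which gene anchors the
#' co-expression screen, which transcript is the qPCR internal standard,
#' and which profiled strain (if any) carries an insertional knockout of
#' each gene.
#'
#' @param strains Character vector of strain labels (no duplicates).
#' @param wild_type Label of the wild-type strain; must appear in `strains`.
#' @param conditions Character vector of nitrogen-condition labels.
#' @param timepoints Numeric vector of harvest times in hours.
#' @param gene_panel Character vector of measured gene labels.
#' @param reference_gene Gene against which all candidates are correlated;
#'   must appear in `gene_panel`.
#' @param internal_standard Label of the qPCR internal-standard transcript
#'   (a reference gene such as the ubiquitin ligase). Kept outside
#'   `gene_panel`: it is consumed by quantification and never screened.
#' @param gene_to_mutant Named character vector mapping a gene label to the
#'   strain carrying its insertional knockout. Genes whose mutant was not
#'   profiled may map to a strain absent from `strains`; such entries are
#'   inert downstream.
#'
#' @return An object of class `design_spec` (a validated list with the
#'   fields above).
#' @seealso [default_design()], [enumerate_design()], [read_design()]
#' @examples
#' d <- design_spec(
#'   strains = c("wt", "mutA"), wild_type = "wt",
#'   conditions = c("NO3", "NH4"), timepoints = c(1, 24),
#'   gene_panel = c("REF", "geneA"), reference_gene = "REF",
#'   gene_to_mutant = c(geneA = "mutA")
#' )
#' nrow(enumerate_design(d))
#' @export
design_spec <- function(strains, wild_type, conditions, timepoints,
                        gene_panel, reference_gene,
                        internal_standard = "UBQ",
                        gene_to_mutant = character()) {
  d <- structure(
    list(
      strains = as.character(strains),
      wild_type = as.character(wild_type),
      conditions = as.character(conditions),
      timepoints = as.numeric(timepoints),
      gene_panel = as.character(gene_panel),
      reference_gene = as.character(reference_gene),
      internal_standard = as.character(internal_standard),
      gene_to_mutant = gene_to_mutant
    ),
    class = "design_spec"
  )
  validate_design(d)
  d
}

#' Validate a design specification
#'
#' Checks every structural invariant of a [design_spec()]: no duplicated
#' labels, wild type among strains, reference gene in the panel, numeric
#' finite positive timepoints, and a well-formed gene-to-mutant map whose
#' profiled mutant strains are unique per gene.
#'
#' @param design A `design_spec` object (or list with the same fields).
#' @return Invisibly, `design`. Stops with an error naming the violated
#'   invariant otherwise.
#' @export
validate_design <- function(design) {
  need <- c("strains", "wild_type", "conditions", "timepoints",
            "gene_panel", "reference_gene", "internal_standard",
            "gene_to_mutant")
  missing_f <- setdiff(need, names(design))
  if (length(missing_f)) {
    stop("design is missing field(s): ", paste(missing_f, collapse = ", "))
  }
  for (f in c("strains", "conditions", "gene_panel")) {
    v <- design[[f]]
    if (!length(v)) stop("design field '", f, "' is empty")
    if (anyDuplicated(v)) {
      stop("duplicate label(s) in design field '", f, "': ",
           paste(unique(v[duplicated(v)]), collapse = ", "))
    }
    if (any(is.na(v) | v == "")) stop("empty/NA label in design field '", f, "'")
  }
  if (length(design$wild_type) != 1L || !design$wild_type %in% design$strains) {
    stop("wild_type '", design$wild_type, "' is not among the design strains")
  }
  if (anyDuplicated(design$timepoints)) stop("duplicate timepoints in design")
  if (!length(design$timepoints) || any(!is.finite(design$timepoints)) ||
      any(design$timepoints <= 0)) {
    stop("timepoints must be finite positive hours")
  }
  if (length(design$reference_gene) != 1L ||
      !design$reference_gene %in% design$gene_panel) {
    stop("reference_gene '", design$reference_gene,
         "' is not in the gene panel")
  }
  if (length(design$internal_standard) != 1L || is.na(design$internal_standard)) {
    stop("internal_standard must be a single gene label")
  }
  if (design$internal_standard %in% design$gene_panel) {
    stop("internal_standard '", design$internal_standard,
         "' must not be part of the screened gene panel")
  }
  g2m <- design$gene_to_mutant
  if (length(g2m)) {
    if (is.null(names(g2m)) || any(names(g2m) == "")) {
      stop("gene_to_mutant must be a named map gene -> strain")
    }
    unknown <- setdiff(names(g2m), design$gene_panel)
    if (length(unknown)) {
      stop("gene_to_mutant names not in gene panel: ",
           paste(unknown, collapse = ", "))
    }
    if (anyDuplicated(names(g2m))) stop("duplicate gene in gene_to_mutant")
    profiled <- g2m[g2m %in% design$strains]
    if (anyDuplicated(profiled)) {
      stop("gene_to_mutant maps several genes to the same profiled strain: ",
           paste(unique(profiled[duplicated(profiled)]), collapse = ", "))
    }
  }
  invisible(design)
}

#' Default screen design
#'
#' The factorial design of the co-expression screen: wild type 704 plus six
#' ammonium-insensitive (AI) insertional mutants (cyg56, cdp1, 20.40, 54.10,
#' 258.90, 259.89) and two chlorate-sensitive-in-ammonium (CSA) mutants
#' (N10, N24); four nitrogen contexts (4 mM nitrate, 8 mM ammonium, and two
#' nitrate+ammonium mixtures); four harvest times (0.5, 1, 3, 24 h) — 144
#' samples in all. The 12-gene panel holds the reference CYG56, CDP1, two
#' stably expressed controls (20.40CG1, 258.90CG), two configurable
#' placeholder candidates (CG-A, CG-B), and the six candidates identified
#' in the unprofiled AI mutants 42.49, 85.37, 106.20 and 209.82. The
#' ubiquitin-ligase transcript "UBQ" is the qPCR internal standard.
#'
#' @return A [design_spec()] object.
#' @examples
#' d <- default_design()
#' length(d$strains) * length(d$conditions) * length(d$timepoints)
#' @export
default_design <- function() {
  design_spec(
    strains = c("704", "cyg56", "cdp1", "20.40", "54.10",
                "258.90", "259.89", "N10", "N24"),
    wild_type = "704",
    conditions = c("NO3_4mM", "NH4_8mM", "NO3_4mM+NH4_8mM", "NO3_4mM+NH4_1mM"),
    timepoints = c(0.5, 1, 3, 24),
    gene_panel = c("CYG56", "CDP1", "20.40CG1", "258.90CG", "CG-A", "CG-B",
                   "42.49CG1", "42.49CG2", "85.37CG",
                   "106.20CG1", "106.20CG2", "209.82CG"),
    reference_gene = "CYG56",
    internal_standard = "UBQ",
    gene_to_mutant = c(
      "CYG56" = "cyg56", "CDP1" = "cdp1",
      "20.40CG1" = "20.40", "258.90CG" = "258.90",
      "42.49CG1" = "42.49", "42.49CG2" = "42.49",
      "85.37CG" = "85.37",
      "106.20CG1" = "106.20", "106.20CG2" = "106.20",
      "209.82CG" = "209.82"
    )
  )
}

#' Enumerate all samples of a design
#'
#' Expands the full Cartesian product strains x conditions x timepoints x
#' replicates in design order (strain slowest, replicate fastest), one row
#' per harvested culture.
#'
#' @param design A [design_spec()].
#' @param replicates Number of replicates per cell (default 1; the screen
#'   design has no replicate dimension).
#' @return A data frame with columns `sample_id`, `strain`, `condition`,
#'   `timepoint_h`, `replicate`; `sample_id` is
#'   `strain|condition|timepoint_h|replicate`.
#' @examples
#' nrow(enumerate_design(default_design()))  # 144
#' @export
enumerate_design <- function(design, replicates = 1L) {
  validate_design(design)
  replicates <- as.integer(replicates)
  if (length(replicates) != 1L || is.na(replicates) || replicates < 1L) {
    stop("replicates must be a positive integer")
  }
  n_s <- length(design$strains)
  n_c <- length(design$conditions)
  n_t <- length(design$timepoints)
  keys <- data.frame(
    strain = rep(design$strains, each = n_c * n_t * replicates),
    condition = rep(rep(design$conditions, each = n_t * replicates), times = n_s),
    timepoint_h = rep(rep(design$timepoints, each = replicates),
                      times = n_s * n_c),
    replicate = rep(seq_len(replicates), times = n_s * n_c * n_t),
    stringsAsFactors = FALSE
  )
  keys <- cbind(sample_id = make_sample_id(keys), keys)
  rownames(keys) <- NULL
  keys
}

make_sample_id <- function(df) {
  paste(df$strain, df$condition, format_timepoint(df$timepoint_h),
        df$replicate, sep = "|")
}

# canonical text form of a timepoint (avoids "24" vs "24.0" mismatches)
format_timepoint <- function(t) {
  as.character(as.numeric(t))
}

#' Read a design specification from a YAML/JSON config file
#'
#' The config file mirrors the [design_spec()] fields: `strains`,
#' `wild_type`, `conditions`, `timepoints`, `gene_panel`, `reference_gene`,
#' `internal_standard`, and a `gene_to_mutant` map.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file.
#' @return A validated [design_spec()].
#' @export
read_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_design_spec(cfg)
}

#' Coerce a plain list to a design specification
#'
#' @param x A list with `design_spec` fields (e.g. parsed from YAML).
#' @return A validated [design_spec()].
#' @export
as_design_spec <- function(x) {
  if (inherits(x, "design_spec")) return(validate_design(x))
  g2m <- x$gene_to_mutant
  g2m <- if (length(g2m)) unlist(g2m) else character()
  design_spec(
    strains = x$strains, wild_type = x$wild_type,
    conditions = x$conditions, timepoints = x$timepoints,
    gene_panel = x$gene_panel, reference_gene = x$reference_gene,
    internal_standard = if (is.null(x$internal_standard)) "UBQ" else x$internal_standard,
    gene_to_mutant = g2m
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Design:", length(x$strains), "strains x", length(x$conditions),
      "conditions x", length(x$timepoints), "timepoints\n")
  cat("  strains:   ", paste(x$strains, collapse = ", "), "\n")
  cat("  wild type: ", x$wild_type, "\n")
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("  timepoints:", paste(x$timepoints, collapse = ", "), "h\n")
  cat("  gene panel:", paste(x$gene_panel, collapse = ", "), "\n")
  cat("  reference gene:", x$reference_gene,
      "| internal standard:", x$internal_standard, "\n")
  profiled <- x$gene_to_mutant[x$gene_to_mutant %in% x$strains]
  if (length(profiled)) {
    cat("  profiled knockouts:",
        paste(names(profiled), "in", profiled, collapse = "; "), "\n")
  }
  invisible(x)
}
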