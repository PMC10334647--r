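#' Pipeline configuration
#'
#' Builds the tunable-parameter set shared by all pipeline stages. Defaults
#' target chromosome-scale mammalian/invertebrate assemblies with 100 kb
#' contact-map bins; [desk_config()] provides a proportionally scaled-down
#' profile for small simulated genomes.
#'
#' @param bin_size Contact-map bin width in bases.
#' @param s_threshold Threshold \code{s} on the sum of normalised separation
#'   scores \code{S_upper/S_upper0 + S_lower/S_lower0} above which a junction
#'   is called erroneous.
#' @param r_threshold Threshold \code{r} on \code{R_upper + R_lower}.
#' @param k_max Largest diagonal distance (in bins) entering the separation
#'   and misassembly scores.
#' @param min_matrix_scaffold Minimum scaffold length (bases) contributing to
#'   the genome-wide contact distance-decay profile.
#' @param min_link Long-read/PE link count that an end pair must exceed to be
#'   accepted without further checks (\code{minLink}).
#' @param hic_edge_min_weight_small_L,hic_edge_min_weight_large_L Minimum
#'   Hi-C end-graph edge weights for \code{L} below / at-or-above
#'   \code{large_L_cutoff}.
#' @param large_L_cutoff Boundary (bases) between the two edge-weight regimes.
#' @param L_schedule Strictly increasing end-window lengths \code{L} (bases)
#'   used by the iterative Hi-C scaffolder.
#' @param C_consensus Coverage constant \code{C} assigned to contigs paired
#'   with an opposite contig (unpaired contigs receive \code{2*C}).
#' @param r_upper_threshold Non-bubble contigs with coverage below
#'   \code{C_hetero * r_upper_threshold} are classed heterozygous.
#' @param identity_min Minimum alignment identity retained by the
#'   self-alignment step.
#' @param end_search_window Window (bases) from a scaffold end searched for
#'   misassemblies during the long-read edge check.
#' @param hic_join_gap Run of \code{N} (bases) inserted between Hi-C-joined
#'   scaffolds.
#' @param min_opposite_alignment Minimum alignment length (bases) that can
#'   create an opposite-contig assignment.
#' @param min_piece Minced pieces shorter than this (bases) are merged into a
#'   neighbouring piece.
#' @param kmer_size k-mer length for unique-match short-read/Hi-C mapping.
#' @param min_longread_alignment Minimum accepted long-read alignment length.
#' @param peak_window Half-width (bins) of the local-maximum window used by
#'   misassembly peak detection.
#' @param seed Integer seed used wherever the pipeline needs randomness.
#' @return A list of class \code{"hapscaf_config"}.
#' @export
scaffold_config <- function(bin_size = 1e5,
                            s_threshold = 1.0,
                            r_threshold = 1.6,
                            k_max = 10L,
                            min_matrix_scaffold = 3e5,
                            min_link = 0L,
                            hic_edge_min_weight_small_L = 50,
                            hic_edge_min_weight_large_L = 100,
                            large_L_cutoff = 1e5,
                            L_schedule = c(seq(1e4, 1e5, by = 1e4),
                                           seq(2e5, 1e6, by = 1e5)),
                            C_consensus = 40,
                            r_upper_threshold = 1.75,
                            identity_min = 0.80,
                            end_search_window = 3e5,
                            hic_join_gap = 500,
                            min_opposite_alignment = 1000,
                            min_piece = 200,
                            kmer_size = 32L,
                            min_longread_alignment = 500,
                            peak_window = 2L,
                            seed = 1L) {
  cfg <- list(bin_size = bin_size, s_threshold = s_threshold,
              r_threshold = r_threshold, k_max = as.integer(k_max),
              min_matrix_scaffold = min_matrix_scaffold,
              min_link = as.integer(min_link),
              hic_edge_min_weight_small_L = hic_edge_min_weight_small_L,
              hic_edge_min_weight_large_L = hic_edge_min_weight_large_L,
              large_L_cutoff = large_L_cutoff,
              L_schedule = L_schedule,
              C_consensus = C_consensus,
              r_upper_threshold = r_upper_threshold,
              identity_min = identity_min,
              end_search_window = end_search_window,
              hic_join_gap = hic_join_gap,
              min_opposite_alignment = min_opposite_alignment,
              min_piece = min_piece,
              kmer_size = as.integer(kmer_size),
              min_longread_alignment = min_longread_alignment,
              peak_window = as.integer(peak_window),
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "hapscaf_config"
  cfg
}

validate_config <- function(cfg) {
  pos <- c("bin_size", "s_threshold", "r_threshold", "k_max",
           "min_matrix_scaffold", "hic_edge_min_weight_small_L",
           "hic_edge_min_weight_large_L", "large_L_cutoff", "C_consensus",
           "r_upper_threshold", "identity_min", "end_search_window",
           "hic_join_gap", "min_opposite_alignment", "kmer_size",
           "min_longread_alignment")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0)
      stop("config field '", nm, "' must be a positive scalar", call. = FALSE)
  }
  if (cfg$min_link < 0) stop("min_link must be >= 0", call. = FALSE)
  if (length(cfg$L_schedule) < 1L || any(diff(cfg$L_schedule) <= 0))
    stop("L_schedule must be strictly increasing", call. = FALSE)
  invisible(cfg)
}

#' Desk-scale configuration profile
#'
#' Configuration for small simulated genomes (a few hundred kb per
#' chromosome): 5 kb bins with all length-based thresholds scaled by the
#' same factor (1/20) relative to [scaffold_config()] defaults. Edge-weight
#' thresholds are kept at their defaults since they depend on sequencing
#' depth, not genome length.
#'
#' @param ... Overrides passed on to [scaffold_config()].
#' @return A \code{"hapscaf_config"} list.
#' @export
desk_config <- function(...) {
  args <- list(bin_size = 5e3,
               min_matrix_scaffold = 1.5e4,
               large_L_cutoff = 1e4,
               L_schedule = c(seq(2e3, 1e4, by = 2e3),
                              seq(2e4, 5e4, by = 1e4)),
               end_search_window = 1.5e4)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scaffold_config, args)
}

#' Read a key=value configuration file
#'
#' Plain-text \code{key=value} lines (\code{#} comments allowed); values are
#' parsed as numeric scalars or comma-separated numeric vectors and passed to
#' [scaffold_config()].
#'
#' @param path File path.
#' @return A \code{"hapscaf_config"} list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: '", ln, "'", call. = FALSE)
    key <- trimws(kv[1L])
    val <- suppressWarnings(as.numeric(strsplit(trimws(kv[2L]), ",")[[1L]]))
    if (anyNA(val)) stop("non-numeric config value for '", key, "'", call. = FALSE)
    args[[key]] <- val
  }
  do.call(scaffold_config, args)
}

#' @export
print.hapscaf_config <- function(x, ...) {
  cat("hapscaf pipeline configuration\n")
  cat(sprintf("  bin_size: %g bp, k_max: %d, s/r thresholds: %g / %g\n",
              x$bin_size, x$k_max, x$s_threshold, x$r_threshold))
  cat(sprintf("  L schedule: %s bp\n",
              paste(format(x$L_schedule, scientific = FALSE, trim = TRUE),
                    collapse = ", ")))
  cat(sprintf("  C_consensus: %g, r_upper_threshold: %g, identity_min: %g\n",
              x$C_consensus, x$r_upper_threshold, x$identity_min))
  invisible(x)
}
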