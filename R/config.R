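#' Pipeline configuration
#'
#' Collects every numeric threshold used by the clustering and screening
#' stages. Defaults correspond to the standard operating point of the
#' pipeline: BlastP-style initial gate E < 1 with the low-complexity filter
#' off, Inparanoid-style BBH gates of bit score 50 and 50% sequence overlap,
#' the uniform top-3 extension rule (top 2 for clusters of size 2), the
#' distant-homolog criterion of E <= 1e-3 with a query/hit length ratio of
#' at least 0.6, a secretome majority fraction of one half, and the 80-residue
#' floor for Sec-only proteins.
#'
#' @param initial_evalue_max Initial E-value gate applied when hit tables are
#'   read or produced; hits above it are discarded before any ranking.
#' @param low_complexity_filter Logical; kept for provenance in the run
#'   manifest. The built-in aligner never masks low-complexity sequence.
#' @param bbh_min_bitscore Minimum bit score for a hit to participate in
#'   bidirectional-best-hit (BBH) detection.
#' @param bbh_min_overlap Minimum aligned overlap fraction for BBH detection.
#'   The denominator is controlled by `bbh_overlap_denominator`.
#' @param bbh_overlap_denominator `"longer"` (alignment span over the longer
#'   sequence, the Inparanoid convention) or `"shorter"`.
#' @param top_k Number of top-ranked hits that must agree for cluster
#'   extension (automatically 2 when the target cluster has size 2).
#' @param top3_skip_unclustered Logical; if `TRUE`, hits to unclustered
#'   proteins are skipped (do not occupy ranks) when applying the uniform
#'   top-k rule. The default `FALSE` reads the rule literally: such hits
#'   occupy ranks and veto assignment.
#' @param distant_evalue_max E-value gate of the distant-homolog criterion.
#' @param distant_length_ratio_min Minimum length ratio (or query coverage)
#'   of the distant-homolog criterion.
#' @param distant_criterion_mode `"length_ratio"` (min(qlen, slen) /
#'   max(qlen, slen)) or `"query_coverage"` (aligned fraction of the query).
#' @param secretome_majority_fraction Minimum fraction of cluster members
#'   with a secretome location for the cluster to be exported.
#' @param min_len_sec_only Minimum length (residues) for proteins whose only
#'   positive feature is a Sec-type signal peptide; shorter ones are dropped
#'   from the predicted secretome.
#' @param new_cluster_prefix Leading digit(s) of newly formed cluster numbers.
#' @param bbh_core_mode `"clique"` (greedy maximal cliques of the BBH graph,
#'   the stringent reading) or `"component"` (connected components).
#' @param fragment_length_fraction A protein shorter than this fraction of
#'   the family median length is a pseudogene-fragment candidate.
#' @param fragment_subject_cov_max Fragment candidates must cover less than
#'   this fraction of their best family hit's subject.
#' @param max_fragment_gap Maximum nucleotide gap between adjacent gene
#'   regions joined into one pseudogene assembly.
#' @param ubiquitous_max_missing A cluster missing from at most this many
#'   genomes is classified ubiquitous.
#' @param kd_window Window length of the Kyte-Doolittle hydropathy scan.
#' @param kd_threshold Mean window hydropathy above which a position belongs
#'   to a transmembrane stretch.
#' @param positive_inside_window Residues downstream of a transmembrane
#'   helix inspected for positive charge by the outside-in topology rule.
#' @param prefilter_kmer K-mer length of the all-vs-all candidate prefilter
#'   used by the built-in search (0 disables prefiltering).
#' @param prefilter_min_shared Minimum number of distinct shared k-mers for
#'   a pair of proteins to be aligned by the built-in search.
#' @param rng_seed Integer seed recorded in the run manifest and used by any
#'   stage that draws random numbers.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(initial_evalue_max = 1.0,
                            low_complexity_filter = FALSE,
                            bbh_min_bitscore = 50,
                            bbh_min_overlap = 0.50,
                            bbh_overlap_denominator = c("longer", "shorter"),
                            top_k = 3L,
                            top3_skip_unclustered = FALSE,
                            distant_evalue_max = 1e-3,
                            distant_length_ratio_min = 0.6,
                            distant_criterion_mode = c("length_ratio", "query_coverage"),
                            secretome_majority_fraction = 0.5,
                            min_len_sec_only = 80L,
                            new_cluster_prefix = "9",
                            bbh_core_mode = c("clique", "component"),
                            fragment_length_fraction = 0.6,
                            fragment_subject_cov_max = 0.6,
                            max_fragment_gap = 300L,
                            ubiquitous_max_missing = 1L,
                            kd_window = 7L,
                            kd_threshold = 1.5,
                            positive_inside_window = 10L,
                            prefilter_kmer = 4L,
                            prefilter_min_shared = 2L,
                            rng_seed = 1L) {
  cfg <- list(
    initial_evalue_max = as.numeric(initial_evalue_max),
    low_complexity_filter = isTRUE(low_complexity_filter),
    bbh_min_bitscore = as.numeric(bbh_min_bitscore),
    bbh_min_overlap = as.numeric(bbh_min_overlap),
    bbh_overlap_denominator = match.arg(bbh_overlap_denominator),
    top_k = as.integer(top_k),
    top3_skip_unclustered = isTRUE(top3_skip_unclustered),
    distant_evalue_max = as.numeric(distant_evalue_max),
    distant_length_ratio_min = as.numeric(distant_length_ratio_min),
    distant_criterion_mode = match.arg(distant_criterion_mode),
    secretome_majority_fraction = as.numeric(secretome_majority_fraction),
    min_len_sec_only = as.integer(min_len_sec_only),
    new_cluster_prefix = as.character(new_cluster_prefix),
    bbh_core_mode = match.arg(bbh_core_mode),
    fragment_length_fraction = as.numeric(fragment_length_fraction),
    fragment_subject_cov_max = as.numeric(fragment_subject_cov_max),
    max_fragment_gap = as.integer(max_fragment_gap),
    ubiquitous_max_missing = as.integer(ubiquitous_max_missing),
    kd_window = as.integer(kd_window),
    kd_threshold = as.numeric(kd_threshold),
    positive_inside_window = as.integer(positive_inside_window),
    prefilter_kmer = as.integer(prefilter_kmer),
    prefilter_min_shared = as.integer(prefilter_min_shared),
    rng_seed = as.integer(rng_seed)
  )
  for (f in c("bbh_min_overlap", "distant_length_ratio_min",
              "secretome_majority_fraction", "fragment_length_fraction",
              "fragment_subject_cov_max")) {
    v <- cfg[[f]]
    if (!is.finite(v) || v <= 0 || v > 1) {
      stop(sprintf("config field '%s' must lie in (0, 1], got %s", f, v))
    }
  }
  if (cfg$top_k < 2L) stop("top_k must be >= 2")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_pipeline_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.null(config)) return(pipeline_config())
  if (is.list(config)) return(do.call(pipeline_config, config))
  stop("config must be NULL, a list, or a pipeline_config object")
}
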