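#' Classify unclustered proteins as distant homologs or ORFans
#'
#' Proteins left outside all clusters are searched against reference (non-
#' LAB) proteomes; a protein with at least one reference hit passing the
#' distant-homolog criterion (the same E-value and length-ratio gates as
#' the quality-control sweep) is a distant homolog, and a protein with no
#' surviving reference hit is an ORFan.
#'
#' @param unclustered Character vector of unclustered protein ids.
#' @param reference_hits A ranked `hit_table` of searches against the
#'   reference proteomes.
#' @param config A [pipeline_config()].
#' @param clusters Optional `lacog_set`; supplying it lets the function
#'   verify that no input protein is clustered.
#' @return A data frame `protein_id`, `category`
#'   (`DISTANT_HOMOLOG_NONLAB` or `ORFAN`), and the best reference hit
#'   fields (`best_ref_subject`, `best_ref_evalue`, `best_ref_bitscore`;
#'   `NA` for ORFans).
#' @export
classify_unclustered <- function(unclustered, reference_hits,
                                 config = pipeline_config(),
                                 clusters = NULL) {
  config <- as_pipeline_config(config)
  unclustered <- sort(unique(as.character(unclustered)))
  if (!is.null(clusters)) {
    both <- intersect(unclustered, clusters$protein_id)
    if (length(both) > 0) {
      stop(sprintf("protein(s) already in a LaCOG: %s",
                   paste(both, collapse = ", ")))
    }
  }
  hits <- as.data.frame(reference_hits)
  hits <- hits[hits$query_id %in% unclustered, , drop = FALSE]
  if (nrow(hits) > 0) {
    hits <- hits[distant_criterion_pass(hits, config), , drop = FALSE]
    hits <- hits[order(hits$query_id, hits$rank), , drop = FALSE]
    best <- hits[!duplicated(hits$query_id), , drop = FALSE]
  } else {
    best <- hits
  }
  idx <- match(unclustered, best$query_id)
  data.frame(
    protein_id = unclustered,
    category = ifelse(is.na(idx), "ORFAN", "DISTANT_HOMOLOG_NONLAB"),
    best_ref_subject = ifelse(is.na(idx), NA_character_, best$subject_id[idx]),
    best_ref_evalue = ifelse(is.na(idx), NA_real_, best$evalue[idx]),
    best_ref_bitscore = ifelse(is.na(idx), NA_real_, best$bitscore[idx]),
    stringsAsFactors = FALSE
  )
}

#' Flag pseudogene-suspect ORFans
#'
#' An ORFan with no signal peptide but carrying domains typical of
#' extracellular proteins is suspicious: it may be a pseudogene fragment.
#' Suspects are flagged, never reclassified.
#'
#' @param verdicts Output of [classify_unclustered()].
#' @param scl_calls SCL call table (see [screen_scl()]).
#' @param domains Domain hit table ([read_domain_table()]).
#' @param extracellular_domains Character vector of domain accessions
#'   regarded as extracellular-typical.
#' @return `verdicts` with an added logical column `pseudo_suspect`.
#' @export
flag_pseudo_suspect_orfans <- function(verdicts, scl_calls, domains,
                                       extracellular_domains = character(0)) {
  scl <- stats::setNames(scl_calls$scl_class, scl_calls$protein_id)
  has_extracellular_domain <- verdicts$protein_id %in%
    domains$protein_id[domains$domain_accession %in% extracellular_domains]
  verdicts$pseudo_suspect <- verdicts$category == "ORFAN" &
    unname(scl[verdicts$protein_id]) == "INTRACELLULAR" &
    has_extracellular_domain
  verdicts$pseudo_suspect[is.na(verdicts$pseudo_suspect)] <- FALSE
  verdicts
}
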