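#' Extract secretome clusters by the majority rule
#'
#' A cluster is exported as a secretome cluster when at least the majority
#' fraction (default one half, ties included) of its members carry a
#' secretome subcellular location. Within exported clusters only the
#' secretome members are kept; clusters that also contain non-secretome
#' members are flagged mixed. Secretome members of below-majority clusters
#' are not dropped silently: they are reported in a side table.
#'
#' @param clusters A `lacog_set`.
#' @param scl_calls SCL call table from [screen_scl()] covering every
#'   member (post-filter).
#' @param config A [pipeline_config()].
#' @return A list with `clusters` (data frame: `cluster_id`,
#'   `secretome_fraction`, `n_members`, `n_secretome`, `mixed_flag`),
#'   `members` (the exported secretome members per emitted cluster) and
#'   `below_majority_members` (secretome members of non-emitted clusters).
#' @export
extract_secretome_lacogs <- function(clusters, scl_calls,
                                     config = pipeline_config()) {
  config <- as_pipeline_config(config)
  df <- as.data.frame(clusters)
  missing <- setdiff(df$protein_id, scl_calls$protein_id)
  if (length(missing) > 0) {
    stop(sprintf("cluster member(s) without an SCL call: %s",
                 paste(missing, collapse = ", ")))
  }
  sec <- stats::setNames(scl_calls$is_secretome, scl_calls$protein_id)
  df$is_secretome <- unname(sec[df$protein_id])
  if (nrow(df) == 0) {
    return(list(
      clusters = data.frame(cluster_id = character(0),
                            secretome_fraction = numeric(0),
                            n_members = integer(0), n_secretome = integer(0),
                            mixed_flag = logical(0), stringsAsFactors = FALSE),
      members = df[, c("cluster_id", "protein_id")],
      below_majority_members = df[, c("cluster_id", "protein_id")]
    ))
  }
  agg <- stats::aggregate(is_secretome ~ cluster_id, data = df,
                          FUN = function(v) c(sum(v), length(v)))
  summary <- data.frame(
    cluster_id = agg$cluster_id,
    n_secretome = as.integer(agg$is_secretome[, 1]),
    n_members = as.integer(agg$is_secretome[, 2]),
    stringsAsFactors = FALSE
  )
  summary$secretome_fraction <- summary$n_secretome / summary$n_members
  summary$mixed_flag <- summary$n_secretome < summary$n_members &
    summary$n_secretome > 0
  emitted <- summary$secretome_fraction >= config$secretome_majority_fraction &
    summary$n_secretome > 0
  out_clusters <- summary[emitted,
                          c("cluster_id", "secretome_fraction", "n_members",
                            "n_secretome", "mixed_flag"), drop = FALSE]
  out_clusters <- out_clusters[order(out_clusters$cluster_id), , drop = FALSE]
  rownames(out_clusters) <- NULL
  members <- df[df$cluster_id %in% out_clusters$cluster_id & df$is_secretome,
                c("cluster_id", "protein_id"), drop = FALSE]
  below <- df[!(df$cluster_id %in% out_clusters$cluster_id) & df$is_secretome,
              c("cluster_id", "protein_id"), drop = FALSE]
  members <- members[order(members$cluster_id, members$protein_id), , drop = FALSE]
  below <- below[order(below$cluster_id, below$protein_id), , drop = FALSE]
  rownames(members) <- rownames(below) <- NULL
  list(clusters = out_clusters, members = members,
       below_majority_members = below)
}

#' Per-genome secretome summary
#'
#' Counts, for each genome, the predicted secretome proteins and their
#' split over clustered proteins, distant homologs and ORFans, plus the
#' number of secretome clusters with at least one member from the genome.
#' The split is exhaustive: every secretome protein is clustered, a distant
#' homolog, or an ORFan.
#'
#' @param proteins A `protein_set` of all input proteins.
#' @param scl_calls SCL call table from [screen_scl()] (post-filter).
#' @param clusters The final `lacog_set`.
#' @param verdicts Output of [classify_unclustered()] for the unclustered
#'   proteins.
#' @param secretome Output of [extract_secretome_lacogs()].
#' @return A data frame with one row per genome: `genome_id`,
#'   `total_proteins`, `secretome_size`, `secretome_pct`, `in_lacog`,
#'   `distant_homologs`, `orfans`, `n_lacogs`.
#' @export
summarize_genomes <- function(proteins, scl_calls, clusters, verdicts,
                              secretome) {
  sec <- stats::setNames(scl_calls$is_secretome, scl_calls$protein_id)
  clustered <- clusters$protein_id
  distant <- verdicts$protein_id[verdicts$category == "DISTANT_HOMOLOG_NONLAB"]
  orfan <- verdicts$protein_id[verdicts$category == "ORFAN"]
  genomes <- sort(unique(proteins$genome_id))
  cluster_genomes <- merge(
    secretome$members,
    proteins[, c("protein_id", "genome_id")], by = "protein_id"
  )
  rows <- lapply(genomes, function(g) {
    ids <- proteins$protein_id[proteins$genome_id == g]
    sec_ids <- ids[unname(sec[ids]) %in% TRUE]
    data.frame(
      genome_id = g,
      total_proteins = length(ids),
      secretome_size = length(sec_ids),
      secretome_pct = round(100 * length(sec_ids) / max(1L, length(ids)), 2),
      in_lacog = sum(sec_ids %in% clustered),
      distant_homologs = sum(sec_ids %in% distant),
      orfans = sum(sec_ids %in% orfan),
      n_lacogs = length(unique(cluster_genomes$cluster_id[
        cluster_genomes$genome_id == g])),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(genome_id = character(0), total_proteins = integer(0),
                      secretome_size = integer(0), secretome_pct = numeric(0),
                      in_lacog = integer(0), distant_homologs = integer(0),
                      orfans = integer(0), n_lacogs = integer(0),
                      stringsAsFactors = FALSE)
  }
  out
}
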