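#' Classify cluster phyletic patterns
#'
#' From the per-genome presence counts of each cluster, assigns exactly one
#' category with a fixed precedence: `UBIQUITOUS` when the cluster is
#' missing from at most `ubiquitous_max_missing` genomes (fully conserved,
#' or lacking in one genome, under the default); else `NICHE_SPECIFIC` when
#' every present genome carries one common niche tag and at least two
#' genomes of that niche are present; else `SPECIES_SPECIFIC` when all
#' present genomes are strains of one species and at least two are present;
#' else `STRAIN_SPECIFIC` when exactly one genome is present; else
#' `VARIABLE`.
#'
#' @param clusters A `lacog_set` (or the member table of a secretome
#'   extraction).
#' @param genomes A list of `genome_bundle` objects, or a data frame with
#'   `genome_id`, `species_label` and a `niche_tags` list-column or
#'   comma-separated string column.
#' @param proteins A `protein_set` mapping members to genomes.
#' @param config A [pipeline_config()].
#' @return A data frame with one row per cluster: `cluster_id`, one
#'   `n_<genome>` count column per genome, `n_present`, `n_missing`,
#'   `category`, `niche_tag`.
#' @export
classify_phyletic_patterns <- function(clusters, genomes, proteins,
                                       config = pipeline_config()) {
  config <- as_pipeline_config(config)
  meta <- genome_metadata(genomes)
  genome_ids <- meta$genome_id
  df <- as.data.frame(clusters)
  df$genome_id <- unname(genome_of(proteins)[df$protein_id])
  ids <- sort(unique(df$cluster_id))
  counts <- matrix(0L, nrow = length(ids), ncol = length(genome_ids),
                   dimnames = list(ids, genome_ids))
  if (nrow(df) > 0) {
    tab <- table(df$cluster_id, df$genome_id)
    counts[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  rows <- lapply(seq_along(ids), function(i) {
    pres <- counts[i, ] > 0
    cat <- classify_presence_vector(pres, meta, config$ubiquitous_max_missing)
    cbind(data.frame(cluster_id = ids[i], stringsAsFactors = FALSE),
          stats::setNames(as.data.frame(t(counts[i, ])),
                          paste0("n_", genome_ids)),
          data.frame(n_present = sum(pres),
                     n_missing = sum(!pres),
                     category = cat$category, niche_tag = cat$niche_tag,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cluster_id = character(0), n_present = integer(0),
                      n_missing = integer(0), category = character(0),
                      niche_tag = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# One presence vector -> category, by the fixed precedence order.
classify_presence_vector <- function(pres, meta, max_missing) {
  present <- meta$genome_id[pres]
  if (length(present) == 0) stop("cluster present in no genome")
  if (sum(!pres) <= max_missing) {
    return(list(category = "UBIQUITOUS", niche_tag = NA_character_))
  }
  tags <- sort(unique(unlist(meta$niche_tags)))
  for (tag in tags) {
    group <- meta$genome_id[vapply(meta$niche_tags, function(t) tag %in% t,
                                   logical(1))]
    if (length(present) >= 2 && all(present %in% group)) {
      return(list(category = "NICHE_SPECIFIC", niche_tag = tag))
    }
  }
  species <- unique(meta$species_label[match(present, meta$genome_id)])
  if (length(species) == 1 && length(present) >= 2) {
    return(list(category = "SPECIES_SPECIFIC", niche_tag = NA_character_))
  }
  if (length(present) == 1) {
    return(list(category = "STRAIN_SPECIFIC", niche_tag = NA_character_))
  }
  list(category = "VARIABLE", niche_tag = NA_character_)
}

genome_metadata <- function(genomes) {
  if (is.data.frame(genomes)) {
    nt <- genomes$niche_tags
    if (!is.list(nt)) {
      nt <- lapply(as.character(nt), function(s) {
        if (is.na(s) || !nzchar(s)) character(0) else
          strsplit(s, ",", fixed = TRUE)[[1]]
      })
    }
    return(list(genome_id = as.character(genomes$genome_id),
                species_label = as.character(genomes$species_label),
                niche_tags = nt))
  }
  list(genome_id = vapply(genomes, `[[`, character(1), "genome_id"),
       species_label = vapply(genomes, `[[`, character(1), "species_label"),
       niche_tags = lapply(genomes, `[[`, "niche_tags"))
}

#' Profile domain architectures within a cluster
#'
#' Builds, for each member, the N-to-C ordered string of its domain
#' accessions with adjacent repeats collapsed to `accession x count`
#' (written `LysMx2`); only domains lying wholly inside the protein span
#' are used, and overlapping hits are resolved by higher score, then
#' earlier start. The cluster is heterogeneous when members disagree.
#'
#' @param family_members Character vector of member ids.
#' @param domains Domain hit table ([read_domain_table()]).
#' @param proteins A `protein_set` (for protein lengths).
#' @param sep,repeat_sep Separators of the architecture string.
#' @return A list with `members` (data frame `protein_id`, `architecture`)
#'   and `heterogeneous_flag`.
#' @export
profile_architectures <- function(family_members, domains, proteins,
                                  sep = "+", repeat_sep = "x") {
  lens <- length_of(proteins)
  rows <- lapply(sort(family_members), function(pid) {
    d <- domains[domains$protein_id == pid, , drop = FALSE]
    L <- unname(lens[[pid]])
    d <- d[!is.na(d$start) & d$start >= 1 & d$end <= L, , drop = FALSE]
    arch <- ""
    if (nrow(d) > 0) {
      d <- d[order(-d$score, d$start), , drop = FALSE]
      chosen <- d[0, ]
      for (i in seq_len(nrow(d))) {
        overlaps <- nrow(chosen) > 0 &&
          any(d$start[i] <= chosen$end & d$end[i] >= chosen$start)
        if (!overlaps) chosen <- rbind(chosen, d[i, ])
      }
      chosen <- chosen[order(chosen$start), , drop = FALSE]
      r <- rle(chosen$domain_accession)
      parts <- ifelse(r$lengths > 1,
                      paste0(r$values, repeat_sep, r$lengths), r$values)
      arch <- paste(parts, collapse = sep)
    }
    data.frame(protein_id = pid, architecture = arch, stringsAsFactors = FALSE)
  })
  members <- do.call(rbind, rows)
  if (is.null(members)) {
    members <- data.frame(protein_id = character(0), architecture = character(0),
                          stringsAsFactors = FALSE)
  }
  list(members = members,
       heterogeneous_flag = length(unique(members$architecture)) >= 2)
}

#' Suggest architecture-based sub-division of a cluster
#'
#' Groups members by architecture string. The grouping is a suggestion
#' only; cluster membership is never modified.
#'
#' @inheritParams profile_architectures
#' @return A data frame `architecture`, `n_members`, `member_ids`.
#' @export
suggest_architecture_split <- function(family_members, domains, proteins) {
  prof <- profile_architectures(family_members, domains, proteins)
  m <- prof$members
  if (nrow(m) == 0) {
    return(data.frame(architecture = character(0), n_members = integer(0),
                      member_ids = character(0), stringsAsFactors = FALSE))
  }
  sp <- split(m$protein_id, m$architecture)
  data.frame(architecture = names(sp),
             n_members = lengths(sp),
             member_ids = vapply(sp, paste, character(1), collapse = ","),
             stringsAsFactors = FALSE, row.names = NULL)
}
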