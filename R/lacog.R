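#' Construct a LaCOG membership table
#'
#' Clusters are kept "long": one row per (cluster, member) pair, with the
#' provenance of each membership (`seed`, `top3_extension`, `bbh_core`,
#' `new_top3`, `qc_distant`, `pseudo_assembly`) and the cluster origin
#' (`seed_extended` or `new`). A protein belongs to at most one cluster.
#'
#' @param cluster_id Character vector of cluster ids.
#' @param protein_id Character vector of member protein ids.
#' @param provenance Membership provenance labels (recycled).
#' @param origin Cluster origin labels (recycled).
#' @return A data frame with class `lacog_set`.
#' @export
lacog_set <- function(cluster_id = character(0), protein_id = character(0),
                      provenance = character(0), origin = character(0)) {
  n <- length(protein_id)
  df <- data.frame(cluster_id = as.character(cluster_id),
                   protein_id = as.character(protein_id),
                   provenance = rep_len(as.character(provenance), n),
                   origin = rep_len(as.character(origin), n),
                   stringsAsFactors = FALSE)
  dup <- df$protein_id[duplicated(df$protein_id)]
  if (length(dup) > 0) {
    stop(sprintf("protein in more than one cluster: %s",
                 paste(unique(dup), collapse = ", ")))
  }
  df <- df[order(df$cluster_id, df$protein_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("lacog_set", "data.frame")
  df
}

as_lacog_set <- function(df) {
  lacog_set(df$cluster_id, df$protein_id,
            if ("provenance" %in% names(df)) df$provenance else NA_character_,
            if ("origin" %in% names(df)) df$origin else NA_character_)
}

#' Sizes of the clusters of a `lacog_set`
#'
#' @param clusters A `lacog_set` data frame.
#' @return Named integer vector of member counts.
#' @export
cluster_sizes <- function(clusters) {
  if (nrow(clusters) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(clusters$cluster_id)
  stats::setNames(as.integer(tab), names(tab))
}

# protein_id -> cluster_id lookup (named character vector)
cluster_of <- function(clusters) {
  stats::setNames(clusters$cluster_id, clusters$protein_id)
}

rbind_lacogs <- function(...) {
  as_lacog_set(do.call(rbind, lapply(list(...), as.data.frame)))
}

#' @export
print.lacog_set <- function(x, ...) {
  cat(sprintf("<lacog_set> %d clusters, %d members\n",
              length(unique(x$cluster_id)), nrow(x)))
  invisible(x)
}
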