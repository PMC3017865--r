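#' Extend clusters with the uniform top-3 rule
#'
#' A query protein is added to cluster C exactly when all of its top-k
#' ranked hits belong to C, with k = 3, or k = 2 when C has exactly two
#' members. Hits to unclustered proteins occupy ranks and therefore veto
#' assignment (set `config$top3_skip_unclustered` to skip them instead).
#' All queries of one pass are evaluated against a frozen snapshot of the
#' cluster memberships, then applied together, so the outcome does not
#' depend on query order.
#'
#' @param clusters A `lacog_set` of target clusters (all of size >= 2).
#' @param hit_table A ranked `hit_table` with self hits excluded.
#' @param queries Character vector of unclustered protein ids to place.
#' @param config A [pipeline_config()].
#' @param provenance Provenance label recorded for new memberships.
#' @return A list with `clusters` (the updated `lacog_set`) and `decisions`
#'   (one row per query: target cluster, rule used, hits examined).
#' @export
extend_by_uniform_top3 <- function(clusters, hit_table, queries,
                                   config = pipeline_config(),
                                   provenance = "top3_extension") {
  config <- as_pipeline_config(config)
  queries <- sort(unique(as.character(queries)))
  already <- intersect(queries, clusters$protein_id)
  if (length(already) > 0) {
    stop(sprintf("query protein(s) already clustered: %s",
                 paste(already, collapse = ", ")))
  }
  sizes <- cluster_sizes(clusters)
  if (length(sizes) > 0 && any(sizes < 2)) {
    stop("target clusters must have size >= 2")
  }
  memb <- cluster_of(clusters)
  hits <- as.data.frame(hit_table)
  hits <- hits[hits$query_id %in% queries, , drop = FALSE]
  hits <- hits[order(hits$query_id, hits$rank), , drop = FALSE]
  by_query <- split(hits, hits$query_id)

  decide_one <- function(q) {
    h <- by_query[[q]]
    none <- list(protein_id = q, target_cluster_id = NA_character_,
                 rule = "none", top_hits_examined = "")
    if (is.null(h) || nrow(h) == 0) return(none)
    cl <- unname(memb[h$subject_id])
    if (config$top3_skip_unclustered) {
      keep <- !is.na(cl)
      h <- h[keep, , drop = FALSE]
      cl <- cl[keep]
      if (nrow(h) == 0) return(none)
    }
    target <- cl[1]
    if (is.na(target)) {
      none$top_hits_examined <- examined_string(h, cl, 1L)
      return(none)
    }
    k <- if (sizes[[target]] == 2L) 2L else config$top_k
    examined <- examined_string(h, cl, min(k, nrow(h)))
    if (nrow(h) < k) {
      none$top_hits_examined <- examined
      return(none)
    }
    topk <- cl[seq_len(k)]
    if (all(!is.na(topk)) && all(topk == target)) {
      list(protein_id = q, target_cluster_id = target,
           rule = if (k == 2L && sizes[[target]] == 2L) "top2_size2" else "top3",
           top_hits_examined = examined)
    } else {
      none$top_hits_examined <- examined
      none
    }
  }

  decisions <- do.call(rbind, lapply(queries, function(q) {
    as.data.frame(decide_one(q), stringsAsFactors = FALSE)
  }))
  if (is.null(decisions)) {
    decisions <- data.frame(protein_id = character(0),
                            target_cluster_id = character(0),
                            rule = character(0),
                            top_hits_examined = character(0),
                            stringsAsFactors = FALSE)
  }
  hitrows <- decisions[!is.na(decisions$target_cluster_id), , drop = FALSE]
  updated <- if (nrow(hitrows) > 0) {
    rbind_lacogs(clusters,
                 lacog_set(hitrows$target_cluster_id, hitrows$protein_id,
                           provenance = provenance,
                           origin = NA_character_))
  } else {
    clusters
  }
  list(clusters = updated, decisions = decisions)
}

examined_string <- function(h, cl, k) {
  if (k < 1) return("")
  paste(sprintf("%s:%s", h$subject_id[seq_len(k)],
                ifelse(is.na(cl[seq_len(k)]), "-", cl[seq_len(k)])),
        collapse = ";")
}

#' Build ortholog cores from the BBH graph
#'
#' In the default `clique` mode, cores are greedy maximal cliques of the
#' BBH graph: the highest-total-bitscore unused pair seeds a core, which
#' grows by repeatedly adding the unused protein adjacent to every current
#' member with the highest total bit score to the core (ties broken by
#' protein id); every protein is used at most once. In `component` mode
#' cores are the connected components of the BBH graph, so each member is
#' the BBH of at least one other member.
#'
#' @param bbh_pairs A data frame from [compute_bbh()].
#' @param config A [pipeline_config()] (supplies `bbh_core_mode`).
#' @return A list of character vectors (sorted member ids), ordered by
#'   smallest member id.
#' @export
build_bbh_cores <- function(bbh_pairs, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  if (nrow(bbh_pairs) == 0) return(list())
  if (config$bbh_core_mode == "component") {
    g <- igraph::graph_from_data_frame(
      bbh_pairs[, c("protein_a", "protein_b")], directed = FALSE)
    comp <- igraph::components(g)
    cores <- split(names(comp$membership), comp$membership)
    cores <- lapply(unname(cores), sort)
  } else {
    cores <- greedy_clique_cores(bbh_pairs)
  }
  cores[order(vapply(cores, `[[`, character(1), 1))]
}

greedy_clique_cores <- function(bbh_pairs) {
  pairs <- bbh_pairs
  pairs$w <- pairs$bitscore_ab + pairs$bitscore_ba
  adj <- new.env(parent = emptyenv())
  add_edge <- function(a, b, w) {
    cur <- get0(a, envir = adj, ifnotfound = numeric(0))
    cur[b] <- w
    assign(a, cur, envir = adj)
  }
  for (i in seq_len(nrow(pairs))) {
    add_edge(pairs$protein_a[i], pairs$protein_b[i], pairs$w[i])
    add_edge(pairs$protein_b[i], pairs$protein_a[i], pairs$w[i])
  }
  used <- new.env(parent = emptyenv())
  is_used <- function(v) isTRUE(get0(v, envir = used))
  ord <- order(-pairs$w, pairs$protein_a, pairs$protein_b)
  pairs <- pairs[ord, , drop = FALSE]
  cores <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$protein_a[i]
    b <- pairs$protein_b[i]
    if (is_used(a) || is_used(b)) next
    clique <- c(a, b)
    repeat {
      cand <- Reduce(intersect, lapply(clique, function(v) names(get(v, envir = adj))))
      cand <- setdiff(cand, clique)
      cand <- cand[!vapply(cand, is_used, logical(1))]
      if (length(cand) == 0) break
      tot <- vapply(cand, function(v) {
        sum(vapply(clique, function(m) get(m, envir = adj)[[v]], numeric(1)))
      }, numeric(1))
      best <- cand[order(-tot, cand)][1]
      clique <- c(clique, best)
    }
    for (v in clique) assign(v, TRUE, envir = used)
    cores[[length(cores) + 1L]] <- sort(clique)
  }
  cores
}

#' Name BBH cores and absorb remaining proteins into new clusters
#'
#' The unnamed cores become new clusters; remaining unclustered proteins
#' are placed by the uniform top-3 rule against the cores (and any extended
#' seed clusters supplied). New clusters are then assigned fresh ids whose
#' numeric part starts with `config$new_cluster_prefix`, numbered
#' sequentially in order of their smallest member id (the first new cluster
#' is `LaCOG90001` under the defaults).
#'
#' @param cores A list of member vectors from [build_bbh_cores()].
#' @param remaining Character vector of proteins still unclustered.
#' @param hit_table A ranked `hit_table`.
#' @param config A [pipeline_config()].
#' @param seed_clusters Optional `lacog_set` of already-named clusters that
#'   also serve as assignment targets (and must not collide with new ids).
#' @return A list with `clusters` (seed clusters plus named new clusters)
#'   and `decisions` (the assignment audit of the top-3 pass).
#' @export
form_new_clusters <- function(cores, remaining, hit_table,
                              config = pipeline_config(),
                              seed_clusters = NULL) {
  config <- as_pipeline_config(config)
  if (is.null(seed_clusters)) seed_clusters <- lacog_set()
  tmp_ids <- sprintf(".core%06d", seq_along(cores))
  core_set <- if (length(cores) > 0) {
    lacog_set(rep(tmp_ids, lengths(cores)), unlist(cores),
              provenance = "bbh_core", origin = "new")
  } else {
    lacog_set()
  }
  targets <- rbind_lacogs(seed_clusters, core_set)
  remaining <- setdiff(remaining, targets$protein_id)
  res <- extend_by_uniform_top3(targets, hit_table, remaining, config,
                                provenance = "new_top3")
  combined <- res$clusters
  combined$provenance[combined$provenance == "new_top3" &
                        !(combined$cluster_id %in% tmp_ids)] <- "top3_extension"
  # name the temporary cores by smallest member id
  is_new <- combined$cluster_id %in% tmp_ids
  if (any(is_new)) {
    newdf <- combined[is_new, , drop = FALSE]
    smallest <- tapply(newdf$protein_id, newdf$cluster_id, min)
    order_ids <- names(sort(smallest))
    # numbering continues after any existing prefixed ids, so incremental
    # reruns never rename or collide with earlier new clusters
    existing <- unique(seed_clusters$cluster_id)
    pat <- sprintf("^LaCOG%s[0-9]{4}$", config$new_cluster_prefix)
    prev <- existing[grepl(pat, existing)]
    offset <- if (length(prev) > 0) {
      max(as.integer(sub(sprintf("^LaCOG%s", config$new_cluster_prefix), "",
                         prev)))
    } else 0L
    fresh <- sprintf("LaCOG%s%04d", config$new_cluster_prefix,
                     offset + seq_along(order_ids))
    collide <- intersect(fresh, unique(seed_clusters$cluster_id))
    if (length(collide) > 0) {
      stop(sprintf("new cluster id collides with seed cluster id: %s",
                   paste(collide, collapse = ", ")))
    }
    map <- stats::setNames(fresh, order_ids)
    combined$cluster_id[is_new] <- unname(map[combined$cluster_id[is_new]])
    combined$origin[is_new] <- "new"
    dec_tmp <- res$decisions$target_cluster_id %in% names(map)
    res$decisions$target_cluster_id[dec_tmp] <-
      unname(map[res$decisions$target_cluster_id[dec_tmp]])
  }
  combined <- as_lacog_set(as.data.frame(combined))
  list(clusters = combined, decisions = res$decisions)
}

# Shared distant-homolog gate: E-value plus a length-ratio or
# query-coverage criterion.
distant_criterion_pass <- function(hits, config) {
  ok_e <- hits$evalue <= config$distant_evalue_max
  ok_len <- if (config$distant_criterion_mode == "length_ratio") {
    pmin(hits$qlen, hits$slen) / pmax(hits$qlen, hits$slen) >=
      config$distant_length_ratio_min
  } else {
    hits$q_cov >= config$distant_length_ratio_min
  }
  ok_e & ok_len
}

#' Iterative distant-homolog quality-control sweep
#'
#' Repeatedly scans the unclustered proteins: a protein joins the cluster
#' of its best-ranked hit that passes the distant-homolog criterion
#' (E-value at most `distant_evalue_max` and, in the default mode, a
#' query/hit length ratio of at least `distant_length_ratio_min`) and whose
#' subject is clustered. Each round is evaluated against the memberships at
#' the start of the round; newly placed proteins become targets in the next
#' round, and the sweep stops at the first round with no change.
#'
#' @param clusters A `lacog_set` of finalized clusters.
#' @param unclustered Character vector of unclustered protein ids.
#' @param hit_table A ranked `hit_table`.
#' @param config A [pipeline_config()].
#' @return A list with `clusters` (updated), `rounds` (number of rounds
#'   that placed at least one protein) and `assignments` (protein, cluster,
#'   round).
#' @export
qc_distant_sweep <- function(clusters, unclustered, hit_table,
                             config = pipeline_config()) {
  config <- as_pipeline_config(config)
  unclustered <- sort(setdiff(unique(as.character(unclustered)),
                              clusters$protein_id))
  hits <- as.data.frame(hit_table)
  hits <- hits[hits$query_id %in% unclustered, , drop = FALSE]
  hits <- hits[distant_criterion_pass(hits, config), , drop = FALSE]
  hits <- hits[order(hits$query_id, hits$rank), , drop = FALSE]
  assignments <- data.frame(protein_id = character(0), cluster_id = character(0),
                            round = integer(0), stringsAsFactors = FALSE)
  round <- 0L
  repeat {
    memb <- cluster_of(clusters)
    h <- hits[hits$query_id %in% unclustered, , drop = FALSE]
    h$cl <- unname(memb[h$subject_id])
    h <- h[!is.na(h$cl), , drop = FALSE]
    if (nrow(h) == 0) break
    best <- h[!duplicated(h$query_id), , drop = FALSE]
    if (nrow(best) == 0) break
    round <- round + 1L
    clusters <- rbind_lacogs(clusters,
                             lacog_set(best$cl, best$query_id,
                                       provenance = "qc_distant",
                                       origin = NA_character_))
    assignments <- rbind(assignments,
                         data.frame(protein_id = best$query_id,
                                    cluster_id = best$cl, round = round,
                                    stringsAsFactors = FALSE))
    unclustered <- setdiff(unclustered, best$query_id)
    if (length(unclustered) == 0) break
  }
  list(clusters = clusters, rounds = round, assignments = assignments)
}
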