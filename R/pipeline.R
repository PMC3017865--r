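#' Run the full secretome-clustering pipeline
#'
#' Executes the stages in order: all-vs-all homology search (or an external
#' hit table), seed-cluster extension by the uniform top-3 rule, BBH core
#' construction among the still-unclustered proteins, new-cluster formation
#' (9-prefixed ids), the iterative distant-homolog quality-control sweep,
#' subcellular-location screening with the false-positive filters,
#' pseudogene fragment detection / concatenation / reassignment, secretome
#' extraction by the majority rule, ORFan vs distant-homolog classification
#' of the leftovers, phyletic-pattern classification and domain
#' architecture profiling of the secretome clusters, and the per-genome
#' summary. Identical inputs and seed give byte-identical outputs.
#'
#' @param bundles List of [genome_bundle()] objects.
#' @param config A [pipeline_config()].
#' @param hit_table Optional precomputed ranked `hit_table`; when `NULL`
#'   the built-in aligner runs all-vs-all.
#' @param scl_table Optional SCL annotation table overriding the heuristic.
#' @param domains Optional domain hit table.
#' @param features Optional gene feature table (needed for pseudogene
#'   assembly).
#' @param reference_hits Optional hit table against non-LAB reference
#'   proteomes (for distant-homolog/ORFan classification).
#' @param seed_clusters Optional seed `lacog_set` (existing clusters to
#'   extend; their ids are never changed).
#' @param exclude_plasmids Drop proteins whose contig id contains
#'   "plasmid" before clustering.
#' @param out_dir Optional directory; when given, [write_outputs()] is
#'   called on the result.
#' @param verbose Log per-stage counts to standard error.
#' @return A list with all intermediate and final products (`proteins`,
#'   `hits`, `clusters`, `scl_calls`, `assemblies`, `secretome`,
#'   `verdicts`, `phyletic`, `architectures`, `genome_summary`,
#'   `decisions`, `flagged_unassembled`, `start_anomalies`, `manifest`).
#' @export
run_secretome_pipeline <- function(bundles, config = pipeline_config(),
                                   hit_table = NULL, scl_table = NULL,
                                   domains = NULL, features = NULL,
                                   reference_hits = NULL,
                                   seed_clusters = NULL,
                                   exclude_plasmids = FALSE,
                                   out_dir = NULL, verbose = TRUE) {
  config <- as_pipeline_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  proteins <- combined_proteins(bundles)
  if (exclude_plasmids) {
    drop <- grepl("plasmid", proteins$contig_id, ignore.case = TRUE)
    drop[is.na(drop)] <- FALSE
    proteins <- validate_protein_set(proteins[!drop, , drop = FALSE])
  }
  say("stage homology: %d proteins from %d genomes", nrow(proteins),
      length(unique(proteins$genome_id)))
  hits <- if (is.null(hit_table)) all_vs_all_hits(proteins, config) else hit_table
  say("stage homology: %d ranked hits", nrow(hits))

  if (is.null(seed_clusters)) seed_clusters <- lacog_set()
  singleton_seeds <- attr(seed_clusters, "singleton_members") %||% character(0)
  clusters <- seed_clusters
  unclustered <- setdiff(proteins$protein_id, clusters$protein_id)
  decisions_ext <- NULL
  if (nrow(clusters) > 0) {
    ext <- extend_by_uniform_top3(clusters, hits, unclustered, config)
    clusters <- ext$clusters
    decisions_ext <- ext$decisions
    unclustered <- setdiff(unclustered, clusters$protein_id)
    say("stage extend: %d proteins added to %d seed clusters",
        sum(clusters$provenance == "top3_extension"),
        length(unique(seed_clusters$cluster_id)))
  }

  core_hits <- hits[hits$query_id %in% unclustered &
                      hits$subject_id %in% unclustered, , drop = FALSE]
  bbh <- compute_bbh(core_hits, proteins, config)
  cores <- build_bbh_cores(bbh, config)
  say("stage cores: %d BBH pairs -> %d cores (%s mode)", nrow(bbh),
      length(cores), config$bbh_core_mode)
  remaining <- setdiff(unclustered, unlist(cores))
  fn <- form_new_clusters(cores, remaining, hits, config,
                          seed_clusters = clusters)
  clusters <- fn$clusters
  decisions <- rbind(decisions_ext, fn$decisions)
  unclustered <- setdiff(proteins$protein_id, clusters$protein_id)
  say("stage new clusters: %d clusters, %d proteins unclustered",
      length(unique(clusters$cluster_id)), length(unclustered))

  qc <- qc_distant_sweep(clusters, unclustered, hits, config)
  clusters <- qc$clusters
  unclustered <- setdiff(proteins$protein_id, clusters$protein_id)
  say("stage qc sweep: %d proteins added in %d rounds",
      nrow(qc$assignments), qc$rounds)

  scl_calls <- screen_scl(proteins, scl_table, config)
  say("stage scl: %d secretome calls of %d proteins",
      sum(scl_calls$is_secretome), nrow(scl_calls))

  # --- pseudogene fragments -------------------------------------------
  contigs <- do.call(c, c(lapply(bundles, function(b) as.list(b$contigs)),
                          list(list())))
  contigs <- unlist(contigs)
  ps <- pseudogene_stage(proteins, clusters, hits, features, contigs, config)
  assemblies <- ps$assemblies
  clusters <- ps$clusters
  proteins_final <- ps$proteins
  scl_calls <- merge_assembly_scl(scl_calls, assemblies)
  consumed <- ps$consumed
  say("stage pseudo: %d candidates, %d assemblies (%d fragments consumed)",
      length(ps$candidates), nrow(assemblies), length(consumed))

  unclustered <- setdiff(proteins_final$protein_id, clusters$protein_id)
  verdicts <- classify_unclustered(unclustered,
                                   reference_hits %||% empty_hit_table(TRUE),
                                   config, clusters = clusters)
  say("stage orfans: %d distant homologs, %d ORFans",
      sum(verdicts$category == "DISTANT_HOMOLOG_NONLAB"),
      sum(verdicts$category == "ORFAN"))

  secretome <- extract_secretome_lacogs(clusters, scl_calls, config)
  say("stage secretome: %d secretome clusters (%d members)",
      nrow(secretome$clusters), nrow(secretome$members))

  sec_lacogs <- as.data.frame(clusters)
  sec_lacogs <- sec_lacogs[sec_lacogs$cluster_id %in%
                             secretome$clusters$cluster_id, , drop = FALSE]
  phyletic <- classify_phyletic_patterns(sec_lacogs, bundles, proteins_final,
                                         config)
  domains <- domains %||% read_domain_table(NULL)
  arch_rows <- lapply(sort(unique(sec_lacogs$cluster_id)), function(cid) {
    mem <- sec_lacogs$protein_id[sec_lacogs$cluster_id == cid]
    prof <- profile_architectures(mem, domains, proteins_final)
    cbind(cluster_id = cid, prof$members,
          heterogeneous_flag = prof$heterogeneous_flag,
          stringsAsFactors = FALSE)
  })
  architectures <- if (length(arch_rows) > 0) do.call(rbind, arch_rows) else
    data.frame(cluster_id = character(0), protein_id = character(0),
               architecture = character(0), heterogeneous_flag = logical(0),
               stringsAsFactors = FALSE)

  anomalies <- start_anomaly_stage(sec_lacogs, proteins_final, config,
                                   features, contigs)
  genome_summary <- summarize_genomes(proteins_final, scl_calls, clusters,
                                      verdicts, secretome)
  say("stage report: %d genomes summarized", nrow(genome_summary))

  manifest <- list(
    tool = "labsecretome",
    version = as.character(utils::packageVersion("labsecretome")),
    seed = config$rng_seed,
    config = unclass(config),
    n_genomes = length(unique(proteins$genome_id)),
    n_proteins = nrow(proteins),
    singleton_seed_members = length(singleton_seeds),
    stages = c("homology", "extend", "cores", "new_clusters", "qc_sweep",
               "scl", "pseudo", "orfans", "secretome", "compare", "report")
  )
  run <- list(proteins = proteins_final, hits = hits, clusters = clusters,
              scl_calls = scl_calls, assemblies = assemblies,
              flagged_unassembled = ps$flagged_unassembled,
              candidates = ps$candidates, consumed = consumed,
              secretome = secretome, verdicts = verdicts,
              phyletic = phyletic, architectures = architectures,
              start_anomalies = anomalies, genome_summary = genome_summary,
              decisions = decisions, qc = qc, bbh = bbh, manifest = manifest)
  if (!is.null(out_dir)) write_outputs(run, out_dir)
  run
}

# Fragment detection, concatenation and reassignment. Candidates are
# proteins whose best hit lands in a cluster and which look like fragments
# of that family.
pseudogene_stage <- function(proteins, clusters, hits, features, contigs,
                             config) {
  no_assemblies <- assemble_adjacent_fragments(character(0),
                                               read_feature_table(NULL),
                                               character(0), proteins, config)
  res <- list(assemblies = no_assemblies, clusters = clusters,
              proteins = proteins, candidates = character(0),
              consumed = character(0),
              flagged_unassembled = character(0))
  if (is.null(features) || nrow(features) == 0 || length(contigs) == 0) {
    return(res)
  }
  # candidate families: a clustered protein is tested against its own
  # family; an unclustered protein only against the family of its best
  # clustered hit, and only when that hit passes the distant-homolog gate
  # (weak motif-level matches must not nominate fragments)
  memb <- cluster_of(clusters)
  h <- as.data.frame(hits)
  h$subj_cl <- unname(memb[h$subject_id])
  h <- h[!is.na(h$subj_cl), , drop = FALSE]
  h <- h[order(h$query_id, h$rank), , drop = FALSE]
  best <- h[!duplicated(h$query_id), , drop = FALSE]
  candidates <- character(0)
  for (i in seq_len(nrow(best))) {
    pid <- best$query_id[i]
    fam <- unname(memb[pid])
    if (is.na(fam)) {
      if (!distant_criterion_pass(best[i, , drop = FALSE], config)) next
      fam <- best$subj_cl[i]
    }
    members <- clusters$protein_id[clusters$cluster_id == fam]
    if (flag_fragment_candidates(pid, members, proteins, hits, config)) {
      candidates <- c(candidates, pid)
    }
  }
  candidates <- sort(candidates)
  if (length(candidates) == 0) return(res)
  assemblies <- assemble_adjacent_fragments(candidates, features, contigs,
                                            proteins, config)
  consumed <- unlist(strsplit(assemblies$fragment_ids, ",", fixed = TRUE))
  kept <- as.data.frame(clusters)
  kept <- kept[!(kept$protein_id %in% consumed), , drop = FALSE]
  clusters2 <- as_lacog_set(kept)
  sizes <- cluster_sizes(clusters2)
  targets <- as.data.frame(clusters2)
  targets <- as_lacog_set(targets[targets$cluster_id %in%
                                    names(sizes)[sizes >= 2], , drop = FALSE])
  assemblies <- reassign_assemblies(assemblies, targets, proteins, config)
  assigned <- assemblies[!is.na(assemblies$assigned_cluster), , drop = FALSE]
  if (nrow(assigned) > 0) {
    clusters2 <- rbind_lacogs(clusters2,
                              lacog_set(assigned$assigned_cluster,
                                        assigned$assembly_id,
                                        provenance = "pseudo_assembly",
                                        origin = NA_character_))
  }
  proteins2 <- proteins
  proteins2$is_pseudo_fragment[proteins2$protein_id %in% candidates] <- TRUE
  keep <- !(proteins2$protein_id %in% consumed)
  proteins2 <- proteins2[keep, , drop = FALSE]
  if (nrow(assemblies) > 0) {
    add <- protein_records(
      protein_id = assemblies$assembly_id,
      genome_id = assemblies$genome_id,
      sequence = assemblies$assembled_sequence,
      contig_id = assemblies$contig_id,
      start = assemblies$span_start, end = assemblies$span_end,
      strand = assemblies$strand,
      description = sprintf("pseudogene assembly of %s",
                            assemblies$fragment_ids)
    )
    proteins2 <- validate_protein_set(rbind(as.data.frame(proteins2),
                                            as.data.frame(add)))
  }
  list(assemblies = assemblies, clusters = clusters2, proteins = proteins2,
       candidates = candidates, consumed = consumed,
       flagged_unassembled = setdiff(candidates, consumed))
}

merge_assembly_scl <- function(scl_calls, assemblies) {
  if (nrow(assemblies) == 0) return(scl_calls)
  add <- data.frame(
    protein_id = assemblies$assembly_id,
    scl_class = assemblies$scl_after,
    is_secretome = assemblies$is_secretome_after,
    source = "heuristic", tm_start = NA_integer_, tm_end = NA_integer_,
    filters_fired = "", stringsAsFactors = FALSE
  )
  rbind(scl_calls, add)
}

start_anomaly_stage <- function(sec_lacogs, proteins, config, features,
                                contigs) {
  rows <- lapply(sort(unique(sec_lacogs$cluster_id)), function(cid) {
    mem <- sec_lacogs$protein_id[sec_lacogs$cluster_id == cid]
    if (length(mem) < 3) return(NULL)
    fl <- flag_start_anomalies(mem, proteins, config, features = features,
                               contigs = contigs)
    if (nrow(fl) == 0) return(NULL)
    cbind(cluster_id = cid, fl, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cluster_id = character(0), protein_id = character(0),
                      ref_id = character(0), n_term_shift = integer(0),
                      suggested_starts = character(0), stringsAsFactors = FALSE)
  }
  out
}

#' Write the pipeline's output files
#'
#' Emits deterministic tab-separated tables (clusters, secretome clusters
#' and their members, below-majority secretome members, ORFans, distant
#' homologs, phyletic patterns, architectures, per-genome summary, SCL
#' screening report, assignment audit), the pseudogene assembly FASTA/TSV
#' pair, start-anomaly suggestions and a JSON run manifest. Clusters are
#' sorted by id and members lexicographically, so identical runs give
#' byte-identical files.
#'
#' @param run Result of [run_secretome_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  genome <- genome_of(run$proteins)

  cl <- as.data.frame(run$clusters)
  cl$genome_id <- unname(genome[cl$protein_id])
  write_tsv(cl[order(cl$cluster_id, cl$protein_id),
               c("cluster_id", "protein_id", "genome_id", "provenance",
                 "origin")],
            file.path(out_dir, "clusters.tsv"))

  sc <- run$secretome$clusters
  mem <- run$secretome$members
  sc$members <- vapply(sc$cluster_id, function(cid) {
    paste(sort(mem$protein_id[mem$cluster_id == cid]), collapse = ",")
  }, character(1))
  write_tsv(sc, file.path(out_dir, "secretome_clusters.tsv"))
  write_tsv(run$secretome$below_majority_members,
            file.path(out_dir, "below_majority_secretome.tsv"))

  v <- run$verdicts
  v$genome_id <- unname(genome[v$protein_id])
  v <- v[, c("protein_id", "genome_id", "category", "best_ref_subject",
             "best_ref_evalue", "best_ref_bitscore")]
  write_tsv(v[v$category == "ORFAN", , drop = FALSE],
            file.path(out_dir, "orfans.tsv"))
  write_tsv(v[v$category == "DISTANT_HOMOLOG_NONLAB", , drop = FALSE],
            file.path(out_dir, "distant_homologs.tsv"))

  a <- run$assemblies
  write_tsv(a[, setdiff(names(a), "assembled_sequence")],
            file.path(out_dir, "pseudo_assemblies.tsv"))
  fa <- file.path(out_dir, "pseudo_assemblies.fasta")
  con <- file(fa, open = "wb")
  for (i in seq_len(nrow(a))) {
    writeLines(c(sprintf(">%s genome_id=%s contig=%s fragments=%s cluster=%s",
                         a$assembly_id[i], a$genome_id[i], a$contig_id[i],
                         a$fragment_ids[i],
                         a$assigned_cluster[i] %||% "-"),
                 a$assembled_sequence[i]), con)
  }
  close(con)
  write_tsv(data.frame(protein_id = run$flagged_unassembled,
                       stringsAsFactors = FALSE),
            file.path(out_dir, "flagged_unassembled.tsv"))
  write_tsv(run$start_anomalies, file.path(out_dir, "start_anomalies.tsv"))
  write_tsv(run$phyletic, file.path(out_dir, "phyletic_patterns.tsv"))
  write_tsv(run$architectures, file.path(out_dir, "architectures.tsv"))
  write_tsv(run$genome_summary, file.path(out_dir, "genome_summary.tsv"))
  write_tsv(run$scl_calls[order(run$scl_calls$protein_id), , drop = FALSE],
            file.path(out_dir, "scl_calls.tsv"))
  if (!is.null(run$decisions) && nrow(run$decisions) > 0) {
    write_tsv(run$decisions[order(run$decisions$protein_id), , drop = FALSE],
              file.path(out_dir, "assignment_audit.tsv"))
  } else {
    write_tsv(data.frame(protein_id = character(0),
                         target_cluster_id = character(0),
                         rule = character(0), top_hits_examined = character(0),
                         stringsAsFactors = FALSE),
              file.path(out_dir, "assignment_audit.tsv"))
  }
  invisible(out_dir)
}
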