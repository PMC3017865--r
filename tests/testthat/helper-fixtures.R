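# Shared fixtures. The full-scale study fixture (4 genomes x 500 proteins,
# 100 families, within-family identity 0.8, seed 42) is expensive, so it is
# generated once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

study_fixture <- function() {
  if (!is.null(.fixture_cache$study)) return(.fixture_cache$study)
  ds <- generate_synthetic_genomes(seed = 42)
  cfg <- pipeline_config()
  prot <- combined_proteins(ds$bundles)
  hits <- all_vs_all_hits(prot, cfg)
  run <- run_secretome_pipeline(ds$bundles, cfg, hit_table = hits,
                                domains = ds$domains, features = ds$features,
                                reference_hits = ds$reference_hits,
                                verbose = FALSE)
  .fixture_cache$study <- list(ds = ds, cfg = cfg, proteins = prot,
                               hits = hits, run = run)
  .fixture_cache$study
}

small_fixture <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  ds <- generate_synthetic_genomes(n_genomes = 3, proteins_per_genome = 60,
                                   n_families = 10, pseudogene_pairs = 2,
                                   seed = 7)
  cfg <- pipeline_config()
  run <- run_secretome_pipeline(ds$bundles, cfg,
                                hit_table = synthetic_hit_table(ds),
                                domains = ds$domains, features = ds$features,
                                reference_hits = ds$reference_hits,
                                verbose = FALSE)
  .fixture_cache$small <- list(ds = ds, cfg = cfg, run = run)
  .fixture_cache$small
}

# Cluster partition over the original input proteins, with consumed
# pseudogene fragments mapped to the cluster of their assembly.
final_partition <- function(run, proteins) {
  memb <- stats::setNames(run$clusters$cluster_id, run$clusters$protein_id)
  got <- memb[proteins$protein_id]
  names(got) <- proteins$protein_id
  for (i in seq_len(nrow(run$assemblies))) {
    fr <- strsplit(run$assemblies$fragment_ids[i], ",", fixed = TRUE)[[1]]
    got[fr] <- run$assemblies$assigned_cluster[i]
  }
  got
}

planted_partition <- function(ds, proteins) {
  pl <- unname(ds$truth$family_of[proteins$protein_id])
  pl[is.na(pl)] <- paste0("singleton_", seq_len(sum(is.na(pl))))
  pl
}

# A hand-built ranked hit table from a compact spec:
# list(c(query, subject, bitscore [, evalue, qlen, slen, alen, qcov, scov]))
mk_hits <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    qlen <- as.numeric(r[["qlen"]] %||% 100)
    slen <- as.numeric(r[["slen"]] %||% 100)
    alen <- as.numeric(r[["alen"]] %||% min(qlen, slen))
    data.frame(query_id = r[["q"]], subject_id = r[["s"]],
               identity = 0.8, aln_length = alen,
               qstart = 1L, qend = alen, sstart = 1L, send = alen,
               evalue = as.numeric(r[["evalue"]] %||% 1e-10),
               bitscore = as.numeric(r[["bits"]]),
               qlen = qlen, slen = slen,
               q_cov = alen / qlen, s_cov = alen / slen,
               stringsAsFactors = FALSE)
  }))
  rank_hits(df, exclude_self = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_lacog_set_for_test <- function(df) {
  lacog_set(df$cluster_id, df$protein_id, df$provenance, df$origin)
}

empty_hit_table_for_test <- function() rank_hits(data.frame(
  query_id = character(0), subject_id = character(0), bitscore = numeric(0),
  evalue = numeric(0)))

hit <- function(q, s, bits, evalue = NULL, qlen = NULL, slen = NULL,
                alen = NULL) {
  out <- list(q = q, s = s, bits = bits)
  if (!is.null(evalue)) out$evalue <- evalue
  if (!is.null(qlen)) out$qlen <- qlen
  if (!is.null(slen)) out$slen <- slen
  if (!is.null(alen)) out$alen <- alen
  out
}
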