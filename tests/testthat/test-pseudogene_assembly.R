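test_that("fragment candidates are flagged by length and coverage", {
  fam <- sprintf("m%d", 1:4)
  prot <- protein_records(c(fam, "frag", "full"), "G1",
                          c(strrep("K", 500), strrep("K", 500),
                            strrep("K", 500), strrep("K", 500),
                            strrep("K", 150), strrep("K", 480)))
  ht <- mk_hits(list(hit("frag", "m1", 90, qlen = 150, slen = 500, alen = 140),
                     hit("full", "m1", 300, qlen = 480, slen = 500,
                         alen = 475)))
  expect_true(flag_fragment_candidates("frag", fam, prot, ht))
  expect_false(flag_fragment_candidates("full", fam, prot, ht))
})

test_that("the length boundary is strict across a parameter sweep", {
  fam <- sprintf("m%d", 1:3)
  med <- 300L
  for (len in c(150L, 179L, 180L, 181L, 250L)) {
    prot <- protein_records(c(fam, "p"), "G1",
                            c(strrep("K", med), strrep("K", med),
                              strrep("K", med), strrep("K", len)))
    ht <- mk_hits(list(hit("p", "m1", 90, qlen = len, slen = med,
                           alen = min(len, 170))))
    want <- len < 0.6 * med && min(len, 170) / med < 0.6
    expect_equal(flag_fragment_candidates("p", fam, prot, ht), want,
                 label = sprintf("length %d", len))
  }
})

planted_pair_fixture <- function(strand = "+", split = NULL, seed = 123) {
  set.seed(seed)
  cfg <- pipeline_config()
  g <- labsecretome:::make_grammar("SEC_SECRETED")
  body <- labsecretome:::sanitize_body(labsecretome:::rand_seq(220), cfg)
  full <- labsecretome:::apply_grammar(g, body)
  k <- if (is.null(split)) floor(nchar(full) / 2) else split
  fs <- labsecretome:::plant_frameshift(full, k, "ctg1", c("fragA", "fragB"),
                                        strand = strand)
  list(full = full, k = k, fs = fs, cfg = cfg)
}

test_that("planted frameshift pairs reassemble to the original protein", {
  for (strand in c("+", "-")) {
    px <- planted_pair_fixture(strand)
    prot <- protein_records(c("fragA", "fragB"), "G1", px$fs$frag_seqs,
                            contig_id = "ctg1",
                            start = px$fs$features$start,
                            end = px$fs$features$end, strand = strand)
    asm <- assemble_adjacent_fragments(c("fragA", "fragB"), px$fs$features,
                                       c(ctg1 = px$fs$contig), prot, px$cfg)
    expect_equal(nrow(asm), 1L)
    expect_equal(asm$n_fragments, 2L)
    expect_equal(lengths(regmatches(asm$assembled_sequence,
                                    gregexpr("x", asm$assembled_sequence))),
                 1L)  # junctions = fragments - 1
    joined <- gsub("x", "", asm$assembled_sequence, fixed = TRUE)
    expect_equal(joined, px$full)   # exact reconstruction here
    aln <- align_local(joined, px$full)
    expect_gte(aln$identity, 0.95)
  }
})

test_that("lone candidates and cross-strand fragments never assemble", {
  px <- planted_pair_fixture()
  prot <- protein_records(c("fragA", "fragB"), "G1", px$fs$frag_seqs,
                          contig_id = "ctg1", start = px$fs$features$start,
                          end = px$fs$features$end, strand = "+")
  only_a <- assemble_adjacent_fragments("fragA",
                                        px$fs$features[1, , drop = FALSE],
                                        c(ctg1 = px$fs$contig), prot, px$cfg)
  expect_equal(nrow(only_a), 0L)

  ft <- px$fs$features
  ft$strand <- c("+", "-")
  mixed <- assemble_adjacent_fragments(c("fragA", "fragB"), ft,
                                       c(ctg1 = px$fs$contig), prot, px$cfg)
  expect_equal(nrow(mixed), 0L)

  ft2 <- px$fs$features
  ft2$start[2] <- ft2$start[1] + 6L   # overlaps first ORF by > 1 codon
  expect_error(assemble_adjacent_fragments(c("fragA", "fragB"), ft2,
                                           c(ctg1 = px$fs$contig), prot,
                                           px$cfg),
               "overlap")
})

test_that("assemblies are reassigned to their family and re-screened", {
  fx <- small_fixture()
  run <- fx$run
  asm <- run$assemblies
  expect_equal(nrow(asm), 2L)
  expect_true(all(!is.na(asm$assigned_cluster)))
  memb <- stats::setNames(run$clusters$cluster_id, run$clusters$protein_id)
  for (i in seq_len(nrow(fx$ds$truth$pseudo_pairs))) {
    pp <- fx$ds$truth$pseudo_pairs[i, ]
    row <- asm[grepl(pp$frag1, asm$fragment_ids, fixed = TRUE), ]
    fam_cl <- unique(memb[fx$ds$truth$families[[pp$family]]])
    fam_cl <- fam_cl[!is.na(fam_cl)]
    expect_equal(length(fam_cl), 1L)
    expect_equal(row$assigned_cluster, unname(fam_cl))
    expect_equal(row$scl_after,
                 unname(fx$ds$truth$family_class[pp$family]))
  }
})

test_that("intracellular fragments can become a secretome protein on assembly", {
  # split inside the signal peptide: neither fragment shows a signal,
  # the concatenated protein does
  set.seed(321)
  cfg <- pipeline_config()
  body <- paste0("D", labsecretome:::strip_cleavage_start(
    labsecretome:::sanitize_body(labsecretome:::rand_seq(200), cfg)))
  full <- paste0("MKKDD", strrep("L", 7), "AQA", body)
  expect_equal(heuristic_scl(full, config = cfg)$scl_class, "SEC_SECRETED")
  fs <- labsecretome:::plant_frameshift(full, 9L, "ctg1", c("fragA", "fragB"),
                                        strand = "+")
  px <- list(full = full, fs = fs, cfg = cfg)
  sclA <- heuristic_scl(px$fs$frag_seqs[1])$scl_class
  sclB <- heuristic_scl(px$fs$frag_seqs[2])$scl_class
  expect_false(sclA %in% SCL_SECRETOME_CLASSES)
  expect_false(sclB %in% SCL_SECRETOME_CLASSES)

  fam_ids <- sprintf("fam%d", 1:3)
  fam_seqs <- vapply(1:3, function(i) {
    paste0(substr(px$full, 1, 15),
           labsecretome:::mutate_seq(substr(px$full, 16, nchar(px$full)), 0.9))
  }, character(1))
  prot <- protein_records(c(fam_ids, "fragA", "fragB"),
                          c("G2", "G3", "G4", "G1", "G1"),
                          c(fam_seqs, px$fs$frag_seqs),
                          contig_id = c(NA, NA, NA, "ctg1", "ctg1"),
                          start = c(NA, NA, NA, px$fs$features$start),
                          end = c(NA, NA, NA, px$fs$features$end),
                          strand = c(NA, NA, NA, "+", "+"))
  clusters <- lacog_set(rep("LaCOG00001", 3), fam_ids,
                        provenance = "seed", origin = "seed_extended")
  asm <- assemble_adjacent_fragments(c("fragA", "fragB"), px$fs$features,
                                     c(ctg1 = px$fs$contig), prot, px$cfg)
  asm <- reassign_assemblies(asm, clusters, prot, px$cfg)
  expect_equal(asm$assigned_cluster, "LaCOG00001")
  expect_equal(asm$scl_after, "SEC_SECRETED")
  expect_true(asm$is_secretome_after)
})

test_that("unmatched assemblies stay unassigned", {
  px <- planted_pair_fixture(seed = 55)
  prot <- protein_records(c("fragA", "fragB", "other1", "other2"),
                          c("G1", "G1", "G2", "G2"),
                          c(px$fs$frag_seqs,
                            labsecretome:::sanitize_body(labsecretome:::rand_seq(200)),
                            labsecretome:::sanitize_body(labsecretome:::rand_seq(200))),
                          contig_id = c("ctg1", "ctg1", NA, NA),
                          start = c(px$fs$features$start, NA, NA),
                          end = c(px$fs$features$end, NA, NA),
                          strand = c("+", "+", NA, NA))
  clusters <- lacog_set(c("C1", "C1"), c("other1", "other2"))
  asm <- assemble_adjacent_fragments(c("fragA", "fragB"), px$fs$features,
                                     c(ctg1 = px$fs$contig), prot, px$cfg)
  asm <- reassign_assemblies(asm, clusters, prot, px$cfg)
  expect_true(is.na(asm$assigned_cluster))
})

test_that("fragments consumed by assemblies leave the genome bookkeeping", {
  fx <- small_fixture()
  run <- fx$run
  expect_false(any(run$consumed %in% run$proteins$protein_id))
  expect_false(any(run$consumed %in% run$clusters$protein_id))
  expect_true(all(run$assemblies$assembly_id %in% run$proteins$protein_id))
  # x-count invariant over all emitted assemblies
  nx <- vapply(run$assemblies$assembled_sequence, function(s) {
    sum(strsplit(s, "")[[1]] == "x")
  }, integer(1))
  expect_equal(unname(nx), run$assemblies$n_fragments - 1L)
})

test_that("start anomalies are suggested for truncated members only", {
  set.seed(9)
  base <- labsecretome:::sanitize_body(labsecretome:::rand_seq(240))
  prot <- protein_records(c("m1", "m2", "m3", "short"), "G1",
                          c(base,
                            labsecretome:::mutate_seq(base, 0.9),
                            labsecretome:::mutate_seq(base, 0.9),
                            substr(labsecretome:::mutate_seq(base, 0.9), 41, 240)))
  out <- flag_start_anomalies(c("m1", "m2", "m3", "short"), prot)
  expect_equal(out$protein_id, "short")
  expect_gt(abs(out$n_term_shift), 20)
  homo <- flag_start_anomalies(c("m1", "m2", "m3"), prot)
  expect_equal(nrow(homo), 0L)
})
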