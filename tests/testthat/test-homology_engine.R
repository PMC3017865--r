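test_that("self-alignment gives identity 1 and full coverage", {
  for (s in c("MKVLLWHE", "PAWHEAE", "ACDEFGHIKLMNPQRSTVWY")) {
    h <- align_local(s, s)
    expect_equal(h$identity, 1)
    expect_equal(h$q_cov, 1)
    expect_equal(h$s_cov, 1)
  }
})

test_that("aligner raw scores match a brute-force dynamic-programming oracle", {
  mat <- blosum62_wildcard()
  expect_equal(align_local("PAWHEAE", "HEAGAWGHEE")$score_raw,
               oracle_sw_score("PAWHEAE", "HEAGAWGHEE", mat))
  set.seed(101)
  for (i in 1:20) {
    a <- paste(sample(rownames(mat)[1:20], sample(8:30, 1), TRUE), collapse = "")
    b <- paste(sample(rownames(mat)[1:20], sample(8:30, 1), TRUE), collapse = "")
    got <- align_local(a, b)
    want <- oracle_sw_score(a, b, mat)
    if (is.null(got)) {
      expect_lte(want, 0)
    } else {
      expect_equal(got$score_raw, want)
    }
  }
})

test_that("degenerate alignments are handled", {
  expect_error(align_local("", "MK"), "empty")
  # tryptophan against a charged/proline stretch: no positive-scoring pair
  expect_null(align_local("WWW", "PPP"))
  # the junction wildcard scores zero against everything
  mat <- blosum62_wildcard()
  expect_true(all(mat["X", ] == 0))
  h <- align_local("MKVxLLW", "MKVLLW")
  expect_gt(h$score_raw, 0)
})

test_that("rank_hits orders by bitscore, then evalue, then subject id", {
  ht <- mk_hits(list(hit("q", "c", 50), hit("q", "b", 70), hit("q", "a", 70)))
  expect_equal(ht$subject_id, c("a", "b", "c"))
  expect_equal(ht$rank, 1:3)

  self_only <- rank_hits(data.frame(
    query_id = "q", subject_id = "q", identity = 1, aln_length = 10L,
    qstart = 1L, qend = 10L, sstart = 1L, send = 10L, evalue = 1e-5,
    bitscore = 50, qlen = 10L, slen = 10L, q_cov = 1, s_cov = 1,
    stringsAsFactors = FALSE), exclude_self = TRUE)
  expect_equal(nrow(self_only), 0L)
})

test_that("rank_hits agrees with an independent full sort on 1000 random hits", {
  set.seed(202)
  rt <- random_hit_table(30, 3, 1000)
  h <- as.data.frame(rt$hits)
  # oracle: dedupe + sort from scratch
  raw <- h[sample(nrow(h)), ]
  want <- raw[order(raw$query_id, -raw$bitscore, raw$evalue, raw$subject_id), ]
  got <- as.data.frame(rank_hits(raw, exclude_self = TRUE))
  expect_equal(got$subject_id, want$subject_id)
  expect_equal(got$bitscore, want$bitscore)
})

test_that("compute_bbh applies the bit score and overlap gates", {
  genomes <- c(a = "gX", b = "gY")
  mutual <- function(bits, alen = 100, qlen = 100, slen = 100) {
    mk_hits(list(hit("a", "b", bits, qlen = qlen, slen = slen, alen = alen),
                 hit("b", "a", bits, qlen = slen, slen = qlen, alen = alen)))
  }
  expect_equal(nrow(compute_bbh(mutual(60), genomes)), 1L)
  expect_equal(nrow(compute_bbh(mutual(45), genomes)), 0L)   # below bit score 50
  expect_equal(nrow(compute_bbh(mutual(60, alen = 40), genomes)), 0L)
})

test_that("one-sided best hits never form a BBH pair", {
  genomes <- c(a = "gX", c = "gX", b = "gY")
  ht <- mk_hits(list(hit("a", "b", 80), hit("b", "c", 90), hit("b", "a", 70),
                     hit("c", "b", 85)))
  got <- compute_bbh(ht, genomes)
  expect_false(any(got$protein_a == "a" & got$protein_b == "b"))
  expect_equal(got$protein_a, "b")   # b<->c are mutual best
  expect_equal(got$protein_b, "c")
})

test_that("compute_bbh matches exhaustive enumeration on random instances", {
  set.seed(303)
  for (i in 1:25) {
    rt <- random_hit_table(sample(6:20, 1), sample(2:4, 1), sample(30:150, 1))
    got <- compute_bbh(rt$hits, rt$genomes)
    want <- oracle_bbh(rt$hits, rt$genomes)
    expect_equal(got[, c("protein_a", "protein_b")],
                 want[, c("protein_a", "protein_b")],
                 ignore_attr = TRUE)
  }
})

test_that("BBH is symmetric in direction order and monotone in the gate", {
  set.seed(404)
  rt <- random_hit_table(15, 3, 120)
  h <- as.data.frame(rt$hits)
  fwd_first <- rank_hits(h[order(h$query_id), ])
  rev_first <- rank_hits(h[order(h$query_id, decreasing = TRUE), ])
  expect_equal(compute_bbh(fwd_first, rt$genomes),
               compute_bbh(rev_first, rt$genomes))
  lo <- compute_bbh(rt$hits, rt$genomes, pipeline_config(bbh_min_bitscore = 50))
  hi <- compute_bbh(rt$hits, rt$genomes, pipeline_config(bbh_min_bitscore = 80))
  expect_true(all(paste(hi$protein_a, hi$protein_b) %in%
                    paste(lo$protein_a, lo$protein_b)))
})

test_that("the all-vs-all search finds planted orthologs in both directions", {
  ds <- generate_synthetic_genomes(n_genomes = 2, proteins_per_genome = 20,
                                   n_families = 5, pseudogene_pairs = 0,
                                   secretome_fraction = 0, seed = 5)
  prot <- combined_proteins(ds$bundles)
  ht <- all_vs_all_hits(prot, pipeline_config())
  fams <- ds$truth$families
  for (f in names(fams)) {
    mem <- fams[[f]]
    if (length(mem) < 2) next
    expect_true(any(ht$query_id == mem[1] & ht$subject_id == mem[2]))
    expect_true(any(ht$query_id == mem[2] & ht$subject_id == mem[1]))
  }
  # exhaustive mode agrees with the prefiltered search on planted pairs
  ht2 <- all_vs_all_hits(prot, pipeline_config(prefilter_kmer = 0))
  fam_rows <- function(h) {
    fam_of <- ds$truth$family_of
    keep <- !is.na(fam_of[h$query_id]) & !is.na(fam_of[h$subject_id]) &
      fam_of[h$query_id] == fam_of[h$subject_id]
    h <- h[keep, c("query_id", "subject_id", "bitscore")]
    h[order(h$query_id, h$subject_id), ]
  }
  expect_equal(fam_rows(as.data.frame(ht)), fam_rows(as.data.frame(ht2)),
               ignore_attr = TRUE)
})
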