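clusters_AB <- lacog_set(c("A", "A", "A", "B", "B"),
                         c("p1", "p2", "p3", "p4", "p5"),
                         provenance = "seed", origin = "seed_extended")

test_that("uniform top-3 assigns only when the top hits agree", {
  ht <- mk_hits(list(hit("q", "p1", 90), hit("q", "p3", 80),
                     hit("q", "p2", 70), hit("q", "p4", 60)))
  res <- extend_by_uniform_top3(clusters_AB, ht, "q")
  expect_equal(res$decisions$target_cluster_id, "A")
  expect_equal(res$decisions$rule, "top3")
  expect_true("q" %in% res$clusters$protein_id)

  ht2 <- mk_hits(list(hit("q", "p1", 90), hit("q", "p4", 80),
                      hit("q", "p2", 70)))
  res2 <- extend_by_uniform_top3(clusters_AB, ht2, "q")
  expect_true(is.na(res2$decisions$target_cluster_id))
  expect_equal(res2$decisions$rule, "none")
})

test_that("clusters of size two use the top-2 clause", {
  ht <- mk_hits(list(hit("q", "p4", 90), hit("q", "p5", 80),
                     hit("q", "p1", 70)))
  res <- extend_by_uniform_top3(clusters_AB, ht, "q")
  expect_equal(res$decisions$target_cluster_id, "B")
  expect_equal(res$decisions$rule, "top2_size2")
})

test_that("queries without hits stay unassigned; clustered queries error", {
  res <- extend_by_uniform_top3(clusters_AB, mk_hits(list(hit("x", "y", 50))),
                                "q")
  expect_equal(res$decisions$rule, "none")
  expect_error(extend_by_uniform_top3(clusters_AB, empty_hit_table_for_test(),
                                      "p1"), "already clustered")
})

test_that("hits to unclustered proteins veto assignment unless skipped", {
  ht <- mk_hits(list(hit("q", "p1", 90), hit("q", "z", 85),
                     hit("q", "p2", 80), hit("q", "p3", 75)))
  res <- extend_by_uniform_top3(clusters_AB, ht, "q")
  expect_true(is.na(res$decisions$target_cluster_id))
  res2 <- extend_by_uniform_top3(clusters_AB, ht, "q",
                                 pipeline_config(top3_skip_unclustered = TRUE))
  expect_equal(res2$decisions$target_cluster_id, "A")
})

test_that("uniform top-3 matches the exhaustive rule checker on random instances", {
  set.seed(77)
  for (i in 1:30) {
    n_prot <- sample(10:50, 1)
    n_cl <- sample(2:8, 1)
    ids <- sprintf("m%02d", seq_len(n_prot))
    cl_assign <- sample(c(sprintf("C%d", seq_len(n_cl)), NA), n_prot,
                        replace = TRUE)
    keep <- !is.na(cl_assign)
    sizes <- table(cl_assign[keep])
    # target clusters need >= 2 members
    ok_cl <- names(sizes)[sizes >= 2]
    cl_assign[keep & !(cl_assign %in% ok_cl)] <- NA
    membership <- stats::setNames(cl_assign, ids)
    clustered <- ids[!is.na(cl_assign)]
    if (length(clustered) < 2) next
    clusters <- lacog_set(membership[clustered], clustered)
    queries <- setdiff(ids, clustered)
    if (length(queries) == 0) next
    rows <- list()
    for (q in queries) {
      subj <- sample(setdiff(ids, q), sample(0:8, 1))
      for (s in subj) rows[[length(rows) + 1L]] <- hit(q, s, round(runif(1, 30, 120), 1))
    }
    ht <- if (length(rows) > 0) mk_hits(rows) else empty_hit_table_for_test()
    res <- extend_by_uniform_top3(clusters, ht, queries)
    sz <- cluster_sizes(clusters)
    h <- as.data.frame(ht)
    for (q in queries) {
      ranked <- h$subject_id[h$query_id == q][order(h$rank[h$query_id == q])]
      want <- oracle_top3(q, ranked, membership, as.list(sz))
      got <- res$decisions$target_cluster_id[res$decisions$protein_id == q]
      expect_equal(got, want, label = sprintf("instance %d query %s", i, q))
    }
  }
})

test_that("BBH cores: clique versus component mode", {
  pair <- function(a, b, w) data.frame(protein_a = a, protein_b = b,
                                       bitscore_ab = w, bitscore_ba = w,
                                       stringsAsFactors = FALSE)
  expect_equal(build_bbh_cores(pair("a", "b", 60)), list(c("a", "b")))
  expect_equal(build_bbh_cores(pair("a", "b", 60),
                               pipeline_config(bbh_core_mode = "component")),
               list(c("a", "b")))

  chain <- rbind(pair("a", "b", 80), pair("b", "c", 60))
  expect_equal(build_bbh_cores(chain), list(c("a", "b")))  # c left out
  expect_equal(build_bbh_cores(chain, pipeline_config(bbh_core_mode = "component")),
               list(c("a", "b", "c")))
  expect_equal(build_bbh_cores(chain[0, ]), list())

  # triangle: clique mode recovers all three
  tri <- rbind(pair("a", "b", 80), pair("b", "c", 60), pair("a", "c", 70))
  expect_equal(build_bbh_cores(tri), list(c("a", "b", "c")))
})

test_that("new clusters are named sequentially with the 9 prefix", {
  pair <- data.frame(protein_a = c("a", "x"), protein_b = c("b", "y"),
                     bitscore_ab = c(60, 70), bitscore_ba = c(60, 70),
                     stringsAsFactors = FALSE)
  cores <- build_bbh_cores(pair)
  res <- form_new_clusters(cores, character(0), empty_hit_table_for_test())
  ids <- sort(unique(res$clusters$cluster_id))
  expect_equal(ids, c("LaCOG90001", "LaCOG90002"))
  # first new cluster is seeded by the smallest member id
  expect_equal(sort(res$clusters$protein_id[res$clusters$cluster_id == "LaCOG90001"]),
               c("a", "b"))

  seeds <- lacog_set(c("LaCOG90001", "LaCOG90001"), c("s1", "s2"))
  res2 <- form_new_clusters(cores, character(0), empty_hit_table_for_test(),
                            seed_clusters = seeds)
  expect_true(all(c("LaCOG90002", "LaCOG90003") %in% res2$clusters$cluster_id))

  # absorbing a remaining singleton into a core
  ht <- mk_hits(list(hit("q", "a", 90), hit("q", "b", 80)))
  res3 <- form_new_clusters(list(c("a", "b")), "q", ht)
  expect_equal(res3$decisions$target_cluster_id, "LaCOG90001")
  expect_equal(res3$decisions$rule, "top2_size2")
})

test_that("the QC sweep iterates to a fixpoint and respects its gates", {
  clusters <- lacog_set(c("C", "C"), c("m1", "m2"))
  # u1 reaches a member directly; u2 reaches only u1
  ht <- mk_hits(list(hit("u1", "m1", 80, evalue = 1e-4, qlen = 100, slen = 120),
                     hit("u2", "u1", 75, evalue = 1e-5, qlen = 95, slen = 100)))
  res <- qc_distant_sweep(clusters, c("u1", "u2"), ht)
  expect_equal(res$rounds, 2L)
  expect_equal(res$assignments$round[res$assignments$protein_id == "u1"], 1L)
  expect_equal(res$assignments$round[res$assignments$protein_id == "u2"], 2L)
  expect_equal(sort(res$clusters$protein_id), c("m1", "m2", "u1", "u2"))
  expect_true(all(res$clusters$provenance[res$clusters$protein_id %in%
                                            c("u1", "u2")] == "qc_distant"))

  # no unclustered proteins: zero rounds
  res0 <- qc_distant_sweep(clusters, character(0), ht)
  expect_equal(res0$rounds, 0L)
})

test_that("QC thresholds are enforced exactly at the boundary", {
  clusters <- lacog_set(c("C", "C"), c("m1", "m2"))
  gate <- function(evalue, qlen, slen) {
    ht <- mk_hits(list(hit("u", "m1", 80, evalue = evalue,
                           qlen = qlen, slen = slen)))
    nrow(qc_distant_sweep(clusters, "u", ht)$assignments) == 1L
  }
  expect_true(gate(1e-3, 60, 100))    # E-value boundary included
  expect_false(gate(2e-3, 60, 100))
  expect_true(gate(1e-4, 60, 100))    # length ratio 0.6 passes
  expect_false(gate(1e-4, 59, 100))   # 0.59 fails
})

test_that("QC sweep only grows clusters and terminates", {
  set.seed(88)
  for (i in 1:10) {
    clusters <- lacog_set(c("C", "C"), c("m1", "m2"))
    un <- sprintf("u%d", 1:6)
    rows <- list()
    for (q in un) {
      s <- sample(c("m1", un), 1)
      if (s != q) rows[[length(rows) + 1L]] <-
        hit(q, s, 60, evalue = 1e-5, qlen = 100, slen = 100)
    }
    ht <- if (length(rows)) mk_hits(rows) else empty_hit_table_for_test()
    res <- qc_distant_sweep(clusters, un, ht)
    expect_lte(res$rounds, length(un))
    expect_true(all(c("m1", "m2") %in% res$clusters$protein_id))
  }
})

test_that("the cluster partition stays disjoint through the pipeline", {
  fx <- small_fixture()
  cl <- fx$run$clusters
  expect_equal(anyDuplicated(cl$protein_id), 0L)
  sizes <- cluster_sizes(cl)
  expect_equal(sum(sizes), nrow(cl))
})

test_that("planted families are recovered exactly on the small fixture", {
  fx <- small_fixture()
  prot <- combined_proteins(fx$ds$bundles)
  got <- final_partition(fx$run, prot)
  got[is.na(got)] <- paste0("u", seq_len(sum(is.na(got))))
  planted <- planted_partition(fx$ds, prot)
  expect_equal(mclust::adjustedRandIndex(planted, unname(got)), 1.0)
})
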