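hydrophilic_tail <- function(n) paste(rep(c("D", "Q", "S", "N", "E", "T", "G"),
                                          length.out = n), collapse = "")

test_that("the rule cascade classifies constructed signals", {
  # hydrophilic protein falls through to INTRACELLULAR
  plain <- paste0("M", hydrophilic_tail(20))
  call <- heuristic_scl(plain)
  expect_equal(call$scl_class, "INTRACELLULAR")
  expect_false(call$is_secretome)

  # Sec signal: positive N-terminus, hydrophobic core, A-x-A cleavage
  sec <- paste0("MKK", strrep("L", 10), "AQA", hydrophilic_tail(80))
  expect_equal(heuristic_scl(sec)$scl_class, "SEC_SECRETED")

  # twin-arginine upstream of the core
  tat <- paste0("MSRRTN", strrep("L", 10), "AQA", hydrophilic_tail(80))
  expect_equal(heuristic_scl(tat)$scl_class, "TAT_SECRETED")

  # lipobox within the first 35 residues
  lip <- paste0("MKKLAGC", hydrophilic_tail(60))
  expect_equal(heuristic_scl(lip)$scl_class, "LIPID_ANCHORED")

  # N-terminal anchor without a cleavage site
  nanch <- paste0("MKKN", strrep("L", 12), hydrophilic_tail(80))
  callN <- heuristic_scl(nanch)
  expect_equal(callN$scl_class, "N_ANCHORED")
  expect_false(is.na(callN$tm_start))

  # sortase substrate: LPxTG + hydrophobic + charged tail at the C-terminus
  cw <- paste0("M", hydrophilic_tail(100), "LPKTG", strrep("A", 12), "KRK")
  expect_equal(heuristic_scl(cw)$scl_class, "CELL_WALL_ANCHORED")

  # single C-terminal transmembrane stretch
  canch <- paste0("M", hydrophilic_tail(100), "GG", strrep("L", 12), "GG")
  expect_equal(heuristic_scl(canch)$scl_class, "C_ANCHORED")

  # two internal stretches: integral membrane, never secretome
  multi <- paste0("M", hydrophilic_tail(30), strrep("L", 12),
                  hydrophilic_tail(30), strrep("I", 12), hydrophilic_tail(30))
  callM <- heuristic_scl(multi)
  expect_equal(callM$scl_class, "MULTI_TM")
  expect_false(callM$is_secretome)
})

test_that("the heuristic is deterministic and the vocabulary closed", {
  seqs <- c(paste0("MKK", strrep("L", 10), "AQA", hydrophilic_tail(50)),
            paste0("M", hydrophilic_tail(40)))
  for (s in seqs) {
    expect_identical(heuristic_scl(s), heuristic_scl(s))
    expect_true(heuristic_scl(s)$scl_class %in% SCL_CLASSES)
  }
})

test_that("outside-in topology: positives only downstream of the helix", {
  cfg <- pipeline_config()
  # K before the helix: not outside-in
  seq_ok <- paste0("MKKN", strrep("L", 12), "D", "K", hydrophilic_tail(60))
  call_ok <- heuristic_scl(seq_ok, config = cfg)
  expect_equal(call_ok$scl_class, "N_ANCHORED")
  expect_false(detect_outside_in(seq_ok, call_ok, cfg))

  # no K/R before, K just after the helix: outside-in
  seq_in <- paste0("MSTN", strrep("L", 12), "DDK", hydrophilic_tail(60))
  call_in <- heuristic_scl(seq_in, config = cfg)
  expect_equal(call_in$scl_class, "N_ANCHORED")
  expect_true(detect_outside_in(seq_in, call_in, cfg))

  # no K/R within ten residues after the helix: not outside-in
  seq_far <- paste0("MSTN", strrep("L", 12), hydrophilic_tail(15), "K",
                    hydrophilic_tail(40))
  call_far <- heuristic_scl(seq_far, config = cfg)
  expect_equal(call_far$scl_class, "N_ANCHORED")
  expect_false(detect_outside_in(seq_far, call_far, cfg))

  expect_error(detect_outside_in(seq_ok, heuristic_scl("MDDDDDDD")),
               "N_ANCHORED")
})

test_that("screen_scl reclassifies outside-in calls as intracellular", {
  seq_in <- paste0("MSTN", strrep("L", 12), "DDK", hydrophilic_tail(60))
  prot <- protein_records("p_in", "G1", seq_in)
  out <- screen_scl(prot)
  expect_equal(out$scl_class, "INTRACELLULAR")
  expect_false(out$is_secretome)
  expect_match(out$filters_fired, "outside_in")
})

test_that("the 80-residue Sec-only rule drops exactly the small Sec proteins", {
  cfg <- pipeline_config()
  mk_sec <- function(tail_n) paste0("MKK", strrep("L", 10), "AQA",
                                    hydrophilic_tail(tail_n))
  sec79 <- mk_sec(79 - 16)
  sec80 <- mk_sec(80 - 16)
  expect_equal(nchar(sec79), 79L)
  call79 <- heuristic_scl(sec79, config = cfg)
  expect_equal(call79$scl_class, "SEC_SECRETED")
  expect_equal(small_sec_filter(sec79, call79, cfg), "drop")
  call80 <- heuristic_scl(sec80, config = cfg)
  expect_equal(small_sec_filter(sec80, call80, cfg), "keep")

  # a 75-residue lipoprotein is kept: the rule is Sec-only
  lip75 <- paste0("MKKLAGC", hydrophilic_tail(68))
  expect_equal(nchar(lip75), 75L)
  call_lip <- heuristic_scl(lip75, config = cfg)
  expect_equal(call_lip$scl_class, "LIPID_ANCHORED")
  expect_equal(small_sec_filter(lip75, call_lip, cfg), "keep")

  # junction markers do not count toward the length
  sec_x <- paste0(substr(sec79, 1, 40), "x", substr(sec79, 41, 79))
  call_x <- heuristic_scl(sec_x, config = cfg)
  expect_equal(small_sec_filter(sec_x, call_x, cfg), "drop")
})

test_that("annotation-table entries always override the heuristic", {
  sec <- paste0("MKK", strrep("L", 10), "AQA", hydrophilic_tail(80))
  prot <- protein_records(c("pA", "pB"), "G1", c(sec, sec))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tscl_class", "pA\tINTRACELLULAR"), f)
  out <- screen_scl(prot, read_scl_table(f))
  expect_equal(out$scl_class[out$protein_id == "pA"], "INTRACELLULAR")
  expect_equal(out$source[out$protein_id == "pA"], "table")
  expect_equal(out$scl_class[out$protein_id == "pB"], "SEC_SECRETED")
})

test_that("every planted grammar is recovered by the cascade", {
  set.seed(99)
  cfg <- pipeline_config()
  classes <- c("SEC_SECRETED", "TAT_SECRETED", "LIPID_ANCHORED", "N_ANCHORED",
               "CELL_WALL_ANCHORED", "C_ANCHORED")
  for (cls in classes) {
    for (i in 1:25) {
      g <- labsecretome:::make_grammar(cls)
      body <- labsecretome:::sanitize_body(
        labsecretome:::rand_seq(sample(90:250, 1)), cfg)
      if (cls == "N_ANCHORED") body <- labsecretome:::strip_cleavage_start(body)
      seq <- labsecretome:::apply_grammar(g, body)
      expect_equal(heuristic_scl(seq, config = cfg)$scl_class, cls,
                   label = sprintf("%s grammar %d", cls, i))
    }
  }
})
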