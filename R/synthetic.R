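#' @title Synthetic proteomes with planted ground truth
#' @description The generator fabricates a set of bacterial genomes in
#' exactly the on-disk dialects the pipeline consumes, with every planted
#' feature recorded in a truth object: an ortholog family partition,
#' per-protein subcellular-location classes realized as unambiguous signal
#' grammars, frameshifted pseudogene pairs with nucleotide context, ORFan
#' singletons, fabricated non-LAB reference hits, and per-genome
#' species/niche labels.
#' @name synthetic_data
NULL

# Background residue frequencies, mildly hydrophilic-biased so random
# sequence rarely fakes a membrane segment before sanitation.
BG_FREQS <- c(A = 0.07, C = 0.01, D = 0.06, E = 0.07, F = 0.03, G = 0.07,
              H = 0.02, I = 0.05, K = 0.07, L = 0.08, M = 0.02, N = 0.05,
              P = 0.05, Q = 0.05, R = 0.05, S = 0.07, T = 0.06, V = 0.06,
              W = 0.01, Y = 0.03)

HYDROPHILIC <- c("D", "E", "K", "N", "Q", "S", "T", "G")

rand_seq <- function(n) {
  paste(sample(names(BG_FREQS), n, replace = TRUE, prob = BG_FREQS),
        collapse = "")
}

# Remove motifs a planted-intracellular body must not carry: membrane
# stretches, an N-terminal lipobox, a C-terminal LPxTG.
sanitize_body <- function(seq, config = pipeline_config()) {
  for (iter in 1:300) {
    ch <- strsplit(seq, "")[[1]]
    tm <- find_tm_stretches(seq, config$kd_window, config$kd_threshold)
    if (nrow(tm) > 0) {
      span <- tm$start[1]:tm$end[1]
      kd <- KD_SCALE[ch[span]]
      pos <- span[which.max(kd)]
      ch[pos] <- sample(HYDROPHILIC, 1)
      seq <- paste(ch, collapse = "")
      next
    }
    m <- regexpr(LIPOBOX_RE, substr(seq, 1, 40))
    if (m[1] > 0) {
      ch[m[1] + 3L] <- "S"
      seq <- paste(ch, collapse = "")
      next
    }
    m <- regexpr(LPXTG_RE, seq)
    if (m[1] > 0) {
      ch[m[1] + 1L] <- "Q"
      seq <- paste(ch, collapse = "")
      next
    }
    return(seq)
  }
  stop("sanitize_body did not converge")
}

# Substitute residues to reach the target identity to the input.
mutate_seq <- function(seq, identity) {
  ch <- strsplit(seq, "")[[1]]
  n_mut <- round((1 - identity) * length(ch))
  if (n_mut > 0) {
    pos <- sample(length(ch), n_mut)
    for (p in pos) {
      ch[p] <- sample(setdiff(names(BG_FREQS), ch[p]), 1)
    }
  }
  paste(ch, collapse = "")
}

# Signal grammar for a secretome class, drawn once per family so signals
# are conserved within a family but differ across families. Hydrophobic
# cores and linkers are sampled per position so that unrelated proteins of
# the same class share only the short invariant motif of the class -- the
# alignment score of such a motif match stays far below the distant-
# homolog significance gate, as with real signal peptides.
make_grammar <- function(class) {
  hyd_core <- function(alpha = c("L", "I", "V", "F", "A"),
                       p = c(0.35, 0.2, 0.2, 0.1, 0.15)) {
    paste(sample(alpha, sample(8:13, 1), replace = TRUE, prob = p),
          collapse = "")
  }
  philic <- function(n) {
    if (n < 1) return("")
    paste(sample(c("S", "T", "Q", "N", "G"), n, replace = TRUE), collapse = "")
  }
  hyd <- hyd_core()
  # no Ala in anchors that must not expose an A-x-A cleavage site
  hyd_noA <- hyd_core(alpha = c("L", "I", "V", "F"),
                      p = c(0.45, 0.2, 0.2, 0.15))
  pos <- sample(c("K", "R"), 1)
  spacer <- sample(c("Q", "S", "N", "E", "G", "T"), 1)
  cleave <- paste0("A", spacer, "A")
  switch(class,
    SEC_SECRETED = list(prefix = paste0("M", pos, philic(sample(0:2, 1)),
                                        hyd, cleave), suffix = ""),
    TAT_SECRETED = list(prefix = paste0("M", philic(sample(1:2, 1)), "RR",
                                        paste(sample(c("D", "E", "N", "Q"), 2,
                                                     replace = TRUE),
                                              collapse = ""),
                                        hyd, cleave), suffix = ""),
    LIPID_ANCHORED = list(prefix = paste0("M", pos, pos, philic(sample(0:2, 1)),
                                          sample(c("L", "V", "I"), 1),
                                          sample(c("A", "S", "T"), 1),
                                          sample(c("G", "A", "S"), 1), "C"),
                          suffix = ""),
    N_ANCHORED = list(prefix = paste0("M", pos, pos, philic(sample(1:2, 1)),
                                      hyd_noA), suffix = ""),
    CELL_WALL_ANCHORED = list(prefix = "",
                              suffix = paste0("LP", spacer, "TG",
                                              philic(sample(1:3, 1)), hyd,
                                              paste(sample(c("K", "R"), 3,
                                                           replace = TRUE),
                                                    collapse = ""))),
    C_ANCHORED = list(prefix = "",
                      suffix = paste0(philic(2), hyd_noA, philic(2))),
    INTRACELLULAR = list(prefix = "", suffix = "")
  )
}

apply_grammar <- function(grammar, body) {
  paste0(grammar$prefix, body, grammar$suffix)
}

# Bodies attached to an N-anchor grammar must not expose an accidental
# A-x-A cleavage site where the anchor stretch could reach.
strip_cleavage_start <- function(body) {
  ch <- strsplit(body, "")[[1]]
  n <- min(18L, length(ch))
  ch[seq_len(n)][ch[seq_len(n)] == "A"] <- "G"
  paste(ch, collapse = "")
}

build_member <- function(class, grammar, body, config) {
  body <- sanitize_body(body, config)
  if (class == "N_ANCHORED") body <- strip_cleavage_start(body)
  seq <- apply_grammar(grammar, body)
  call <- heuristic_scl(seq, config = config)
  if (call$scl_class != class) {
    stop(sprintf("planted grammar for %s classified as %s", class,
                 call$scl_class))
  }
  seq
}

CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

backtranslate <- function(aa_seq) {
  ch <- strsplit(aa_seq, "")[[1]]
  paste(vapply(ch, function(a) {
    cods <- CODON_TABLE[[a]]
    cods[sample.int(length(cods), 1)]
  }, character(1)), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Turn a full-length protein into a frameshifted pseudogene: back-translate,
# insert one base after `split_codon` codons, and annotate the two resulting
# open reading frames. Returns fragment sequences, the contig and the two
# feature rows (forward or reverse strand).
plant_frameshift <- function(full_seq, split_codon, contig_id, frag_ids,
                             strand = "+", spacer = 60L) {
  L <- nchar(full_seq)
  stopifnot(split_codon >= 2, split_codon <= L - 2)
  gene <- backtranslate(full_seq)
  gene_fs <- paste0(substr(gene, 1, 3 * split_codon), "A",
                    substr(gene, 3 * split_codon + 1, 3 * L), "TAA")
  M <- nchar(gene_fs)
  orf1 <- c(1L, 3L * split_codon)
  orf2 <- c(3L * split_codon + 2L, M)
  sp1 <- paste(sample(c("A", "C", "G", "T"), spacer, replace = TRUE),
               collapse = "")
  sp2 <- paste(sample(c("A", "C", "G", "T"), spacer, replace = TRUE),
               collapse = "")
  if (strand == "+") {
    contig <- paste0(sp1, gene_fs, sp2)
    coords <- list(orf1 + spacer, orf2 + spacer)
  } else {
    contig <- paste0(sp1, revcomp_chr(gene_fs), sp2)
    flip <- function(iv) c(spacer + M - iv[2] + 1L, spacer + M - iv[1] + 1L)
    coords <- list(flip(orf1), flip(orf2))
  }
  features <- data.frame(
    protein_id = frag_ids,
    contig = contig_id,
    start = c(coords[[1]][1], coords[[2]][1]),
    end = c(coords[[1]][2], coords[[2]][2]),
    strand = strand,
    stringsAsFactors = FALSE
  )
  list(
    frag_seqs = c(substr(full_seq, 1, split_codon),
                  substr(full_seq, split_codon + 1, L)),
    contig = contig,
    features = features
  )
}

#' Generate synthetic genomes with planted ground truth
#'
#' Builds `n_genomes` proteomes of `proteins_per_genome` proteins each:
#' ortholog families derived from random ancestors by point substitution
#' (no indels, so length-ratio criteria hold trivially within families),
#' secretome members carrying per-family conserved signal grammars that the
#' rule cascade of [heuristic_scl()] classifies unambiguously, frameshifted
#' pseudogene pairs with contig sequence and gene features, and independent
#' singleton proteins (the planted ORFans, a fraction of which receive
#' fabricated non-LAB reference hits and are thus planted distant
#' homologs). Secretome counts are planted exactly: every genome carries
#' `round(secretome_fraction * proteins_per_genome)` secretome proteins
#' (counting each pseudogene pair once, via its assembled protein).
#'
#' @param n_genomes Number of genomes (>= 2; the first two are strains of
#'   one species, later genomes are one species each; the first half of the
#'   genomes is tagged `dairy`, the second half `GI-tract`).
#' @param proteins_per_genome Proteins per genome.
#' @param n_families Number of planted ortholog families.
#' @param family_all_fraction Fraction of families present in every genome;
#'   the rest are present in random subsets of 2 to `n_genomes - 1` genomes.
#' @param ortholog_identity Identity of each derived ortholog to its family
#'   ancestor, in (0, 1).
#' @param secretome_fraction Planted secretome fraction per genome.
#' @param pseudogene_pairs Number of planted frameshift pseudogene pairs
#'   (each replaces nothing: it is an extra, fifth-wheel family ortholog
#'   split into two annotated ORFs).
#' @param distant_fraction Fraction of singleton proteins given fabricated
#'   reference hits (planted distant homologs); the rest are planted ORFans.
#' @param ancestor_length_range Ancestor body length range (residues).
#' @param seed Integer seed; output is byte-identical across runs for a
#'   fixed seed.
#' @param config A [pipeline_config()] (used to verify planted grammars).
#' @return A list with `bundles` (list of [genome_bundle()]), `features`,
#'   `domains`, `reference_hits`, and `truth` (see Details in the package
#'   vignette).
#' @export
generate_synthetic_genomes <- function(n_genomes = 4L,
                                       proteins_per_genome = 500L,
                                       n_families = 100L,
                                       family_all_fraction = 0.7,
                                       ortholog_identity = 0.8,
                                       secretome_fraction = 0.08,
                                       pseudogene_pairs = 10L,
                                       distant_fraction = 0.2,
                                       ancestor_length_range = c(120L, 300L),
                                       seed = 42L,
                                       config = pipeline_config()) {
  config <- as_pipeline_config(config)
  if (secretome_fraction < 0 || secretome_fraction > 1) {
    stop("secretome_fraction must lie in [0, 1]")
  }
  if (ortholog_identity <= 0 || ortholog_identity >= 1) {
    stop("ortholog_identity must lie in (0, 1)")
  }
  if (n_genomes < 2) stop("need at least 2 genomes")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  genome_ids <- sprintf("G%d", seq_len(n_genomes))
  species <- c("SPC01", "SPC01",
               sprintf("SPC%02d", seq_len(max(0, n_genomes - 2)) + 1L))
  species <- species[seq_len(n_genomes)]
  half <- ceiling(n_genomes / 2)
  niches <- ifelse(seq_len(n_genomes) <= half, "dairy", "GI-tract")

  target_sec <- round(secretome_fraction * proteins_per_genome)
  n_sec_fam <- min(round(secretome_fraction * n_families), target_sec)
  n_all <- round(family_all_fraction * n_families)
  if (n_all < n_sec_fam) n_all <- n_sec_fam

  fam_ids <- sprintf("FAM%03d", seq_len(n_families))
  sec_classes <- rep("INTRACELLULAR", n_families)
  if (n_sec_fam > 0) {
    pool <- c("SEC_SECRETED", "SEC_SECRETED", "SEC_SECRETED", "SEC_SECRETED",
              "LIPID_ANCHORED", "N_ANCHORED", "CELL_WALL_ANCHORED",
              "TAT_SECRETED")
    sec_classes[seq_len(n_sec_fam)] <- rep_len(pool, n_sec_fam)
  }
  presence <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    presence[[f]] <- if (f <= n_all) genome_ids else {
      sizes <- 2:max(2L, n_genomes - 1L)
      sort(sample(genome_ids, sizes[sample.int(length(sizes), 1)]))
    }
  }

  # --- family members -------------------------------------------------
  fam_grammar <- vector("list", n_families)
  fam_body <- character(n_families)
  for (f in seq_len(n_families)) {
    L <- sample(seq(ancestor_length_range[1], ancestor_length_range[2]), 1)
    fam_body[f] <- sanitize_body(rand_seq(L), config)
    fam_grammar[[f]] <- make_grammar(sec_classes[f])
  }

  per_genome <- stats::setNames(vector("list", n_genomes), genome_ids)
  truth_family <- list()
  truth_scl <- list()
  counter <- stats::setNames(rep(0L, n_genomes), genome_ids)
  next_pid <- function(g) {
    counter[[g]] <<- counter[[g]] + 1L
    sprintf("%s_P%04d", g, counter[[g]])
  }
  add_protein <- function(g, seq, family = NA_character_,
                          scl = "INTRACELLULAR", role = "family",
                          contig = NA_character_, start = NA_integer_,
                          end = NA_integer_, strand = NA_character_) {
    pid <- next_pid(g)
    per_genome[[g]][[length(per_genome[[g]]) + 1L]] <<- list(
      protein_id = pid, sequence = seq, contig = contig,
      start = start, end = end, strand = strand)
    truth_family[[pid]] <<- family
    truth_scl[[pid]] <<- scl
    pid
  }

  member_region <- list()   # fragment id -> c(from, to) in the full protein
  for (f in seq_len(n_families)) {
    for (g in presence[[f]]) {
      body <- mutate_seq(fam_body[f], ortholog_identity)
      seq <- build_member(sec_classes[f], fam_grammar[[f]], body, config)
      add_protein(g, seq, fam_ids[f], sec_classes[f], "family")
    }
  }

  # --- frameshift pseudogene pairs -------------------------------------
  # one pair per family (secretome families first, then intracellular
  # all-present families), so fragments of different pairs never compete
  # for ranks in one family
  pseudo_fam_pool <- c(which(sec_classes != "INTRACELLULAR"),
                       which(sec_classes == "INTRACELLULAR" &
                               seq_len(n_families) <= n_all))
  if (pseudogene_pairs > length(pseudo_fam_pool)) {
    stop("more pseudogene pairs requested than families available")
  }
  contigs <- stats::setNames(vector("list", n_genomes), genome_ids)
  feature_rows <- list()
  pseudo_truth <- list()
  for (p in seq_len(pseudogene_pairs)) {
    f <- pseudo_fam_pool[p]
    g <- presence[[f]][(p - 1L) %% length(presence[[f]]) + 1L]
    body <- mutate_seq(fam_body[f], ortholog_identity)
    full <- build_member(sec_classes[f], fam_grammar[[f]], body, config)
    L <- nchar(full)
    k <- floor(L / 2)
    contig_id <- sprintf("%s_ctg%02d", g, length(contigs[[g]]) + 1L)
    ids <- c(sprintf("%s_P%04d", g, counter[[g]] + 1L),
             sprintf("%s_P%04d", g, counter[[g]] + 2L))
    fs <- plant_frameshift(full, k, contig_id, ids,
                           strand = if (p %% 2 == 0) "-" else "+")
    scl1 <- heuristic_scl(fs$frag_seqs[1], config = config)$scl_class
    scl2 <- heuristic_scl(fs$frag_seqs[2], config = config)$scl_class
    for (i in 1:2) {
      ft <- fs$features[i, ]
      add_protein(g, fs$frag_seqs[i], fam_ids[f], c(scl1, scl2)[i], "fragment",
                  contig = ft$contig, start = ft$start, end = ft$end,
                  strand = ft$strand)
      member_region[[ids[i]]] <- if (i == 1) c(1L, k) else c(k + 1L, L)
    }
    contigs[[g]][[contig_id]] <- fs$contig
    feature_rows[[length(feature_rows) + 1L]] <- fs$features
    pseudo_truth[[p]] <- data.frame(
      pair_id = sprintf("PAIR%02d", p), genome_id = g, family = fam_ids[f],
      frag1 = ids[1], frag2 = ids[2], contig = contig_id,
      split_codon = k, full_length = L, full_sequence = full,
      stringsAsFactors = FALSE
    )
  }

  # --- singletons -------------------------------------------------------
  single_classes <- c("SEC_SECRETED", "N_ANCHORED", "LIPID_ANCHORED",
                      "CELL_WALL_ANCHORED", "C_ANCHORED", "TAT_SECRETED")
  orfan_ids <- character(0)
  frag_ids_all <- unlist(lapply(pseudo_truth, function(pt) c(pt$frag1, pt$frag2)))
  # planted singletons must live up to their label: no detectable homolog
  # among the clustered proteins under the distant-homolog criterion. Only
  # secretome singletons are at risk (class signal motifs give unrelated
  # same-class proteins a scoring head start), so candidates are
  # rejection-sampled against the secretome family members until their best
  # raw alignment score sits below the scale of the initial E < 1 gate
  # (raw 55 is about 26 bits, i.e. E ~ 1 against a 4 x 500-protein set).
  sec_ref <- character(0)
  for (g in genome_ids) {
    for (p in per_genome[[g]]) {
      if (truth_scl[[p$protein_id]] %in% SCL_SECRETOME_CLASSES) {
        sec_ref <- c(sec_ref, p$sequence)
      }
    }
  }
  sub_mat <- blosum62_wildcard()
  unrelated_to_families <- function(seq, max_raw = 55) {
    if (length(sec_ref) == 0) return(TRUE)
    sc <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(rep(seq, length(sec_ref))),
      Biostrings::AAStringSet(sec_ref), type = "local",
      substitutionMatrix = sub_mat, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    max(sc) < max_raw
  }
  for (g in genome_ids) {
    # count secretome proteins as they stand after pseudogene assembly:
    # fragments are consumed and each pair contributes via its assembled
    # protein, whose class is the family class
    n_sec_now <- sum(vapply(per_genome[[g]], function(p) {
      truth_scl[[p$protein_id]] %in% SCL_SECRETOME_CLASSES &&
        !p$protein_id %in% frag_ids_all
    }, logical(1)))
    n_pairs_g <- sum(vapply(pseudo_truth, function(pt) {
      pt$genome_id == g &&
        sec_classes[match(pt$family, fam_ids)] %in% SCL_SECRETOME_CLASSES
    }, logical(1)))
    n_sec_now <- n_sec_now + n_pairs_g
    n_sec_single <- max(0L, target_sec - n_sec_now)
    for (i in seq_len(n_sec_single)) {
      cls <- single_classes[(i - 1L) %% length(single_classes) + 1L]
      for (try in 1:60) {
        body <- sanitize_body(rand_seq(sample(90:250, 1)), config)
        seq <- build_member(cls, make_grammar(cls), body, config)
        if (unrelated_to_families(seq)) break
        if (try == 60) stop("could not plant an unrelated secretome singleton")
      }
      add_protein(g, seq, NA_character_, cls, "singleton")
    }
    n_plain <- proteins_per_genome - length(per_genome[[g]])
    if (n_plain < 0) stop("proteins_per_genome too small for planted content")
    for (i in seq_len(n_plain)) {
      seq <- sanitize_body(rand_seq(sample(80:250, 1)), config)
      add_protein(g, seq, NA_character_, "INTRACELLULAR", "singleton")
    }
  }
  singles <- names(truth_family)[is.na(unlist(truth_family))]
  n_distant <- round(distant_fraction * length(singles))
  distant_ids <- if (n_distant > 0) sort(sample(singles, n_distant)) else character(0)
  orfan_ids <- setdiff(singles, distant_ids)

  # --- assemble bundles -------------------------------------------------
  bundles <- lapply(seq_len(n_genomes), function(gi) {
    g <- genome_ids[gi]
    recs <- per_genome[[g]]
    proteins <- protein_records(
      protein_id = vapply(recs, `[[`, character(1), "protein_id"),
      genome_id = g,
      sequence = vapply(recs, `[[`, character(1), "sequence"),
      contig_id = vapply(recs, function(r) r$contig, character(1)),
      start = vapply(recs, function(r) as.integer(r$start), integer(1)),
      end = vapply(recs, function(r) as.integer(r$end), integer(1)),
      strand = vapply(recs, function(r) r$strand, character(1))
    )
    genome_bundle(g, species_label = species[gi],
                  niche_tags = niches[gi], proteins = proteins,
                  contigs = unlist(contigs[[g]]))
  })
  features <- if (length(feature_rows) > 0) do.call(rbind, feature_rows) else
    read_feature_table(NULL)

  # --- fabricated reference hits ---------------------------------------
  reference_hits <- fabricate_reference_hits(distant_ids, bundles)

  # --- planted domain annotations (LysM-style repeats + one catalytic
  # domain) for the first three intracellular all-present families --------
  dom_fams <- which(sec_classes == "INTRACELLULAR")[1:3]
  dom_rows <- list()
  all_prot <- combined_proteins(bundles)
  fam_of <- unlist(truth_family)
  for (j in seq_along(dom_fams)) {
    f <- dom_fams[j]
    members <- names(fam_of)[!is.na(fam_of) & fam_of == fam_ids[f]]
    for (m in sort(members)) {
      L <- all_prot$length[all_prot$protein_id == m]
      n_rep <- if (j == 1) 1L + (match(m, sort(members)) - 1L) %% 3L else 1L
      s <- 5L
      for (r in seq_len(n_rep)) {
        dom_rows[[length(dom_rows) + 1L]] <- data.frame(
          protein_id = m, domain_accession = "LysM",
          start = s, end = s + 19L, score = 60, stringsAsFactors = FALSE)
        s <- s + 25L
      }
      dom_rows[[length(dom_rows) + 1L]] <- data.frame(
        protein_id = m, domain_accession = "CAT",
        start = max(s, L - 40L), end = L - 5L, score = 90,
        stringsAsFactors = FALSE)
    }
  }
  domains <- if (length(dom_rows) > 0) do.call(rbind, dom_rows) else
    read_domain_table(NULL)

  truth <- list(
    family_of = fam_of,
    families = split(names(fam_of)[!is.na(fam_of)],
                     fam_of[!is.na(fam_of)]),
    scl = unlist(truth_scl),
    pseudo_pairs = if (length(pseudo_truth) > 0) do.call(rbind, pseudo_truth)
      else NULL,
    member_region = member_region,
    orfan_ids = orfan_ids,
    distant_homolog_ids = distant_ids,
    genome_ids = genome_ids,
    species = stats::setNames(species, genome_ids),
    niches = stats::setNames(niches, genome_ids),
    family_presence = stats::setNames(presence, fam_ids),
    family_class = stats::setNames(sec_classes, fam_ids),
    target_secretome_per_genome = target_sec,
    seed = seed
  )
  list(bundles = bundles, features = features, domains = domains,
       reference_hits = reference_hits, truth = truth)
}

# Fabricated reference (non-LAB) hit table: each planted distant homolog
# gets one strong full-length reference hit; ORFans get nothing.
fabricate_reference_hits <- function(distant_ids, bundles) {
  if (length(distant_ids) == 0) return(empty_hit_table(TRUE))
  prot <- combined_proteins(bundles)
  lens <- length_of(prot)
  qlen <- unname(lens[distant_ids])
  df <- data.frame(
    query_id = distant_ids,
    subject_id = sprintf("NONLAB_%04d", seq_along(distant_ids)),
    identity = 0.35, aln_length = qlen,
    qstart = 1L, qend = qlen, sstart = 1L, send = qlen,
    evalue = 1e-6, bitscore = 80, qlen = qlen, slen = qlen,
    q_cov = 1, s_cov = 1, stringsAsFactors = FALSE
  )
  rank_hits(df, exclude_self = TRUE)
}

#' Fabricate a hit table directly from planted truth
#'
#' For aligner-free unit testing: every ordered pair of members of one
#' planted family receives a hit whose bit score is twice the number of
#' identical residues in the implied ungapped alignment (a monotone
#' stand-in -- only the ranking matters to the clustering rules) and whose
#' E-value is the Karlin-Altschul expectation at that bit score. Fragments
#' align over their planted region of the full-length protein. Cross-family
#' pairs get no hits.
#'
#' @param dataset Output of [generate_synthetic_genomes()].
#' @param config A [pipeline_config()].
#' @return A ranked `hit_table`.
#' @export
synthetic_hit_table <- function(dataset, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  prot <- combined_proteins(dataset$bundles)
  seqs <- stats::setNames(prot$sequence, prot$protein_id)
  lens <- length_of(prot)
  region <- dataset$truth$member_region
  rows <- list()
  for (members in dataset$truth$families) {
    members <- sort(members)
    if (length(members) < 2) next
    for (i in seq_along(members)) {
      for (j in seq_along(members)) {
        if (i == j) next
        q <- members[i]; s <- members[j]
        rq <- region[[q]] %||% c(1L, unname(lens[[q]]))
        rs <- region[[s]] %||% c(1L, unname(lens[[s]]))
        from <- max(rq[1], rs[1]); to <- min(rq[2], rs[2])
        if (to - from + 1 < 10) next
        sq <- substr(seqs[[q]], from - rq[1] + 1L, to - rq[1] + 1L)
        ss <- substr(seqs[[s]], from - rs[1] + 1L, to - rs[1] + 1L)
        nid <- sum(strsplit(sq, "")[[1]] == strsplit(ss, "")[[1]])
        alen <- to - from + 1L
        bits <- 2 * nid
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = q, subject_id = s,
          identity = nid / alen, aln_length = alen,
          qstart = from - rq[1] + 1L, qend = from - rq[1] + alen,
          sstart = from - rs[1] + 1L, send = from - rs[1] + alen,
          evalue = unname(lens[[q]]) * unname(lens[[s]]) * 2^(-bits),
          bitscore = bits, qlen = unname(lens[[q]]), slen = unname(lens[[s]]),
          q_cov = alen / unname(lens[[q]]), s_cov = alen / unname(lens[[s]]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) return(empty_hit_table(TRUE))
  df <- do.call(rbind, rows)
  df <- df[df$evalue <= config$initial_evalue_max, , drop = FALSE]
  rank_hits(df, exclude_self = TRUE)
}

#' Write a synthetic dataset to disk in the pipeline's on-disk dialects
#'
#' Emits one protein FASTA per genome, one contig FASTA per genome with
#' contigs, the feature/domain tables, the fabricated reference hit table,
#' a genome metadata table and `truth.json`.
#'
#' @param dataset Output of [generate_synthetic_genomes()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in dataset$bundles) {
    write_protein_fasta(b$proteins,
                        file.path(dir, sprintf("%s.faa", b$genome_id)))
    if (length(b$contigs) > 0) {
      write_contig_fasta(b$contigs,
                         file.path(dir, sprintf("%s.fna", b$genome_id)))
    }
  }
  write_tsv(dataset$features, file.path(dir, "features.tsv"))
  write_tsv(dataset$domains, file.path(dir, "domains.tsv"))
  write_hit_table(dataset$reference_hits, file.path(dir, "reference_hits.tsv"))
  meta <- data.frame(
    genome_id = dataset$truth$genome_ids,
    species_label = unname(dataset$truth$species),
    niche_tags = unname(dataset$truth$niches),
    stringsAsFactors = FALSE
  )
  write_tsv(meta, file.path(dir, "genomes.tsv"))
  truth <- dataset$truth
  truth$member_region <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
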