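#' Flag a protein as a pseudogene-fragment candidate
#'
#' A family member (or a protein with hits into a family) is a fragment
#' candidate when it is substantially shorter than the family and its best
#' family hit covers only part of the subject: length below
#' `fragment_length_fraction` times the median length of the other family
#' members (strict) and best-hit subject coverage below
#' `fragment_subject_cov_max`.
#'
#' @param protein_id The protein to test.
#' @param family_members Character vector of the family's member ids.
#' @param proteins A `protein_set` covering the protein and the family.
#' @param hit_table A ranked `hit_table`.
#' @param config A [pipeline_config()].
#' @return `TRUE` when the protein looks like a fragment of the family.
#' @export
flag_fragment_candidates <- function(protein_id, family_members, proteins,
                                     hit_table, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  lens <- length_of(proteins)
  others <- setdiff(family_members, protein_id)
  if (length(others) == 0) return(FALSE)
  med <- stats::median(unname(lens[others]))
  plen <- unname(lens[[protein_id]])
  hits <- as.data.frame(hit_table)
  hits <- hits[hits$query_id == protein_id & hits$subject_id %in% others, ,
               drop = FALSE]
  if (nrow(hits) == 0) return(FALSE)
  best <- hits[order(hits$rank), , drop = FALSE][1, ]
  plen < config$fragment_length_fraction * med &&
    best$s_cov < config$fragment_subject_cov_max
}

# Translate a gene region in its annotated frame, from the region start to
# the first stop codon (exclusive); no start codon is required. Trailing
# partial codons are ignored.
translate_region <- function(contig_seq, start, end, strand) {
  nt <- substr(contig_seq, start, end)
  if (identical(strand, "-")) {
    nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  }
  L <- nchar(nt) - nchar(nt) %% 3
  if (L < 3) return("")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(substr(nt, 1, L)),
                                           if.fuzzy.codon = "X"))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) substr(aa, 1, stop_at - 1) else aa
}

#' Concatenate adjacent pseudogene fragments
#'
#' Fragment candidates on the same contig and strand whose gene regions lie
#' within `max_fragment_gap` nucleotides of each other are grouped; each
#' region is translated in its annotated frame regardless of start codons,
#' and the translations are joined in the 5'-to-3' order of the coding
#' strand with a literal `x` marking every junction. Groups of one are not
#' assembled. Fragments overlapping by more than one codon make the
#' assembly ambiguous and raise an error.
#'
#' @param candidates Character vector of fragment-candidate protein ids.
#' @param features Gene feature table ([read_feature_table()]).
#' @param contigs Named character vector of contig nucleotide sequences.
#' @param proteins A `protein_set` (supplies the genome of each fragment).
#' @param config A [pipeline_config()].
#' @return A data frame with one row per assembly: `assembly_id`,
#'   `genome_id`, `contig_id`, `strand`, `span_start`, `span_end`,
#'   `fragment_ids` (comma-separated, in concatenation order),
#'   `n_fragments`, `assembled_sequence`.
#' @export
assemble_adjacent_fragments <- function(candidates, features, contigs,
                                        proteins, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  empty <- data.frame(assembly_id = character(0), genome_id = character(0),
                      contig_id = character(0), strand = character(0),
                      span_start = integer(0), span_end = integer(0),
                      fragment_ids = character(0), n_fragments = integer(0),
                      assembled_sequence = character(0), stringsAsFactors = FALSE)
  ft <- features[features$protein_id %in% candidates, , drop = FALSE]
  if (nrow(ft) < 2) return(empty)
  genome <- genome_of(proteins)
  groups <- list()
  for (key in sort(unique(paste(ft$contig, ft$strand, sep = "\r")))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- ft[ft$contig == parts[1] & ft$strand == parts[2], , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) < 2) next
    cur <- sub[1, , drop = FALSE]
    for (i in seq_len(nrow(sub))[-1]) {
      gap <- sub$start[i] - cur$end[nrow(cur)] - 1L
      if (gap < -3L) {
        stop(sprintf("fragments %s and %s overlap by more than a codon",
                     cur$protein_id[nrow(cur)], sub$protein_id[i]))
      }
      if (gap <= config$max_fragment_gap) {
        cur <- rbind(cur, sub[i, , drop = FALSE])
      } else {
        if (nrow(cur) >= 2) groups[[length(groups) + 1L]] <- cur
        cur <- sub[i, , drop = FALSE]
      }
    }
    if (nrow(cur) >= 2) groups[[length(groups) + 1L]] <- cur
  }
  if (length(groups) == 0) return(empty)
  rows <- lapply(groups, function(g) {
    contig_id <- g$contig[1]
    strand <- g$strand[1]
    if (!contig_id %in% names(contigs)) {
      stop(sprintf("no contig sequence for %s", contig_id))
    }
    # concatenation order: 5'->3' of the coding strand
    g <- g[order(if (identical(strand, "-")) -g$start else g$start), ,
           drop = FALSE]
    frags <- vapply(seq_len(nrow(g)), function(i) {
      translate_region(contigs[[contig_id]], g$start[i], g$end[i], strand)
    }, character(1))
    data.frame(
      genome_id = unname(genome[g$protein_id[1]]),
      contig_id = contig_id, strand = strand,
      span_start = min(g$start), span_end = max(g$end),
      fragment_ids = paste(g$protein_id, collapse = ","),
      n_fragments = nrow(g),
      assembled_sequence = paste(frags, collapse = "x"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$genome_id, out$contig_id, out$span_start), , drop = FALSE]
  out <- cbind(assembly_id = sprintf("PSA%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Reassign a pseudogene assembly to a family and re-screen its location
#'
#' The concatenated sequence (junction `x` scored as a zero-cost wildcard)
#' is aligned against all clustered proteins, the hits are ranked, and the
#' uniform top-3 rule decides the target family. The subcellular location
#' of the assembled protein is predicted afresh -- fragments classified
#' intracellular frequently become secretome proteins once concatenated.
#'
#' @param assemblies Output of [assemble_adjacent_fragments()].
#' @param clusters A `lacog_set` of target clusters (fragments removed).
#' @param proteins A `protein_set` covering the cluster members.
#' @param config A [pipeline_config()].
#' @return `assemblies` with added columns `assigned_cluster` (`NA` when no
#'   family accepts the assembly), `scl_after` and `is_secretome_after`.
#' @export
reassign_assemblies <- function(assemblies, clusters, proteins,
                                config = pipeline_config()) {
  config <- as_pipeline_config(config)
  assemblies$assigned_cluster <- NA_character_
  assemblies$scl_after <- NA_character_
  assemblies$is_secretome_after <- NA
  if (nrow(assemblies) == 0) return(assemblies)
  members <- proteins[proteins$protein_id %in% clusters$protein_id, ,
                      drop = FALSE]
  for (i in seq_len(nrow(assemblies))) {
    aseq <- assemblies$assembled_sequence[i]
    aid <- assemblies$assembly_id[i]
    hits <- align_one_vs_many(aid, aseq, members, config)
    if (nrow(hits) > 0) {
      res <- extend_by_uniform_top3(clusters, hits, aid, config,
                                    provenance = "pseudo_assembly")
      dec <- res$decisions
      assemblies$assigned_cluster[i] <- dec$target_cluster_id[1]
    }
    call <- heuristic_scl(aseq, aid, config)
    if (call$is_secretome &&
        small_sec_filter(aseq, call, config) == "drop") {
      call$is_secretome <- FALSE
    }
    assemblies$scl_after[i] <- call$scl_class
    assemblies$is_secretome_after[i] <- call$is_secretome
  }
  assemblies
}

# Ranked hits of one query sequence against a protein set, using the
# built-in aligner with the k-mer prefilter.
align_one_vs_many <- function(query_id, query_seq, proteins,
                              config = pipeline_config()) {
  if (nrow(proteins) == 0) return(empty_hit_table(TRUE))
  seqs <- c(stats::setNames(query_seq, query_id),
            stats::setNames(proteins$sequence, proteins$protein_id))
  if (config$prefilter_kmer > 0) {
    cand <- kmer_candidate_pairs(seqs, k = config$prefilter_kmer,
                                 min_shared = config$prefilter_min_shared)
    cand <- cand[cand$i == 1L | cand$j == 1L, , drop = FALSE]
    subj <- setdiff(unique(c(cand$i, cand$j)), 1L)
  } else {
    subj <- seq_along(seqs)[-1]
  }
  if (length(subj) == 0) return(empty_hit_table(TRUE))
  res <- align_pairs(rep(query_seq, length(subj)), unname(seqs[subj]))
  res$query_id <- query_id
  res$subject_id <- names(seqs)[subj]
  res$evalue <- res$qlen * sum(proteins$length) * 2^(-res$bitscore)
  res <- res[!is.na(res$score_raw) & res$evalue <= config$initial_evalue_max, ,
             drop = FALSE]
  rank_hits(res, exclude_self = TRUE)
}

#' Flag start-codon anomalies within a family
#'
#' Members whose alignment to the family's longest member leaves an
#' N-terminal overhang or truncation of more than `threshold` residues are
#' flagged as possible mis-annotated starts. When gene coordinates and
#' contig sequence are available, in-frame alternative start codons
#' (ATG/GTG/TTG) near the annotated start are suggested; nothing is ever
#' modified.
#'
#' @param family_members Character vector of member ids (>= 3 members).
#' @param proteins A `protein_set`.
#' @param config A [pipeline_config()].
#' @param threshold Residue shift beyond which a member is flagged.
#' @param features Optional feature table for suggestions.
#' @param contigs Optional named contig sequences for suggestions.
#' @return A data frame `protein_id`, `ref_id`, `n_term_shift`,
#'   `suggested_starts` (comma-separated genomic positions, possibly "").
#' @export
flag_start_anomalies <- function(family_members, proteins,
                                 config = pipeline_config(), threshold = 20L,
                                 features = NULL, contigs = NULL) {
  config <- as_pipeline_config(config)
  empty <- data.frame(protein_id = character(0), ref_id = character(0),
                      n_term_shift = integer(0), suggested_starts = character(0),
                      stringsAsFactors = FALSE)
  if (length(family_members) < 3) return(empty)
  sub <- proteins[match(family_members, proteins$protein_id), , drop = FALSE]
  ref <- sub[order(-sub$length, sub$protein_id), , drop = FALSE][1, ]
  rows <- list()
  for (i in seq_len(nrow(sub))) {
    if (sub$protein_id[i] == ref$protein_id) next
    aln <- align_local(sub$sequence[i], ref$sequence)
    if (is.null(aln)) next
    shift <- aln$sstart - aln$qstart  # residues of ref missing from member's N-terminus
    if (abs(shift) > threshold) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = sub$protein_id[i], ref_id = ref$protein_id,
        n_term_shift = as.integer(shift),
        suggested_starts = suggest_starts(sub$protein_id[i], shift,
                                          features, contigs),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

START_CODONS <- c("ATG", "GTG", "TTG")

suggest_starts <- function(protein_id, shift, features, contigs) {
  if (is.null(features) || is.null(contigs)) return("")
  ft <- features[features$protein_id == protein_id, , drop = FALSE]
  if (nrow(ft) == 0 || !ft$contig[1] %in% names(contigs)) return("")
  contig <- contigs[[ft$contig[1]]]
  span <- 3L * (abs(shift) + 10L)
  if (identical(ft$strand[1], "-")) {
    anchor <- ft$end[1]
    pos <- seq(anchor - span, anchor + span, by = 3L)
    pos <- pos[pos - 2 >= 1 & pos <= nchar(contig)]
    codons <- vapply(pos, function(p) {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(contig, p - 2, p))))
    }, character(1))
  } else {
    anchor <- ft$start[1]
    pos <- seq(anchor - span, anchor + span, by = 3L)
    pos <- pos[pos >= 1 & pos + 2 <= nchar(contig)]
    codons <- vapply(pos, function(p) substr(contig, p, p + 2), character(1))
  }
  hits <- pos[codons %in% START_CODONS]
  paste(hits, collapse = ",")
}
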