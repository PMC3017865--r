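#' @import data.table
NULL

KA_LAMBDA <- 0.267
KA_K <- 0.041

#' BLOSUM62 with a zero-scoring wildcard
#'
#' Returns the BLOSUM62 substitution matrix with the `X` row and column set
#' to zero so that unknown residues and the `x` junction marker of
#' concatenated pseudogene assemblies neither reward nor penalize any
#' pairing.
#'
#' @return A numeric substitution matrix.
#' @export
blosum62_wildcard <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

# Internal: optimal local alignments for paired vectors of sequences.
# Lowercase 'x' junction markers are mapped to the zero-scoring 'X' before
# alignment. Returns one row per pair; pairs with score <= 0 get NA rows.
align_pairs <- function(seq_q, seq_s, gap_open = 11, gap_extend = 1,
                        mat = blosum62_wildcard()) {
  stopifnot(length(seq_q) == length(seq_s))
  if (length(seq_q) == 0) {
    return(data.frame(score_raw = numeric(0), bitscore = numeric(0),
                      evalue = numeric(0), identity = numeric(0),
                      aln_length = integer(0), qstart = integer(0),
                      qend = integer(0), sstart = integer(0), send = integer(0),
                      qlen = integer(0), slen = integer(0),
                      q_cov = numeric(0), s_cov = numeric(0)))
  }
  if (any(!nzchar(seq_q)) || any(!nzchar(seq_s))) {
    stop("cannot align an empty sequence")
  }
  qs <- Biostrings::AAStringSet(gsub("x", "X", seq_q, fixed = TRUE))
  ss <- Biostrings::AAStringSet(gsub("x", "X", seq_s, fixed = TRUE))
  aln <- Biostrings::pairwiseAlignment(qs, ss, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  sc <- Biostrings::score(aln)
  bits <- (KA_LAMBDA * sc - log(KA_K)) / log(2)
  qlen <- nchar(seq_q)
  slen <- nchar(seq_s)
  ev <- qlen * slen * 2^(-bits)
  alen <- Biostrings::nchar(aln)
  nmat <- Biostrings::nmatch(aln)
  pr <- Biostrings::pattern(aln)
  su <- Biostrings::subject(aln)
  out <- data.frame(
    score_raw = sc, bitscore = bits, evalue = ev,
    identity = ifelse(alen > 0, nmat / alen, 0),
    aln_length = alen,
    qstart = Biostrings::start(pr), qend = Biostrings::end(pr),
    sstart = Biostrings::start(su), send = Biostrings::end(su),
    qlen = qlen, slen = slen
  )
  out$q_cov <- (out$qend - out$qstart + 1) / out$qlen
  out$s_cov <- (out$send - out$sstart + 1) / out$slen
  out[sc <= 0, setdiff(names(out), c("qlen", "slen"))] <- NA
  out
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman alignment under BLOSUM62 with affine gap penalties (open
#' 11, extend 1). The bit score follows the Karlin-Altschul transform with
#' fixed gapped parameters (lambda = 0.267, K = 0.041) and the expectation
#' value is `m * n * 2^-bits` with `m`, `n` the two sequence lengths; no
#' database-size term enters, so results do not depend on batch composition.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings (`seq_a` is the query).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param mat Substitution matrix; defaults to [blosum62_wildcard()].
#' @return A one-row data frame of alignment statistics, or `NULL` when no
#'   positive-scoring local alignment exists.
#' @export
align_local <- function(seq_a, seq_b, gap_open = 11, gap_extend = 1,
                        mat = blosum62_wildcard()) {
  stopifnot(length(seq_a) == 1, length(seq_b) == 1)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("cannot align an empty sequence")
  res <- align_pairs(seq_a, seq_b, gap_open, gap_extend, mat)
  if (is.na(res$score_raw[1])) return(NULL)
  res
}

empty_hit_table <- function(exclude_self = TRUE) {
  df <- data.frame(query_id = character(0), subject_id = character(0),
                   identity = numeric(0), aln_length = integer(0),
                   qstart = integer(0), qend = integer(0),
                   sstart = integer(0), send = integer(0),
                   evalue = numeric(0), bitscore = numeric(0),
                   qlen = integer(0), slen = integer(0),
                   q_cov = numeric(0), s_cov = numeric(0),
                   rank = integer(0), stringsAsFactors = FALSE)
  class(df) <- c("hit_table", "data.frame")
  attr(df, "self_hits_excluded") <- exclude_self
  df
}

#' Rank raw hits into the canonical hit-table order
#'
#' Within each query, hits are ordered by bit score (descending), then
#' E-value (ascending), then subject id (ascending); this total order is
#' what "top 3 hits" refers to everywhere in the pipeline. Only the
#' best-scoring HSP is kept per (query, subject) pair.
#'
#' @param hits A data frame with at least `query_id`, `subject_id`,
#'   `bitscore`, `evalue` (plus the other hit columns).
#' @param exclude_self Drop hits of a protein to itself.
#' @return A `hit_table` data frame with a per-query `rank` column.
#' @export
rank_hits <- function(hits, exclude_self = TRUE) {
  df <- as.data.frame(hits)
  if (nrow(df) == 0) return(empty_hit_table(exclude_self))
  if (exclude_self) df <- df[df$query_id != df$subject_id, , drop = FALSE]
  if (nrow(df) == 0) return(empty_hit_table(exclude_self))
  o <- order(df$query_id, -df$bitscore, df$evalue, df$subject_id)
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(df[, c("query_id", "subject_id")]), , drop = FALSE]
  df$rank <- stats::ave(seq_len(nrow(df)), df$query_id, FUN = seq_along)
  keep <- c("query_id", "subject_id", "identity", "aln_length", "qstart",
            "qend", "sstart", "send", "evalue", "bitscore", "qlen", "slen",
            "q_cov", "s_cov", "rank")
  extra <- setdiff(keep, names(df))
  for (col in extra) df[[col]] <- NA
  df <- df[, keep, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hit_table", "data.frame")
  attr(df, "self_hits_excluded") <- exclude_self
  df
}

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf("<hit_table> %d hits, %d queries (self hits %s)\n",
              nrow(x), length(unique(x$query_id)),
              if (isTRUE(attr(x, "self_hits_excluded"))) "excluded" else "retained"))
  invisible(x)
}

# Internal: candidate pairs sharing at least `min_shared` distinct k-mers.
# Very common k-mers (in > max_occ sequences) are skipped to bound the join.
kmer_candidate_pairs <- function(seqs, k = 5L, min_shared = 2L, max_occ = 500L) {
  n <- length(seqs)
  if (n < 2) return(data.frame(i = integer(0), j = integer(0)))
  km <- lapply(seqs, function(s) {
    s <- gsub("x", "X", s, fixed = TRUE)
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1), k:L))
  })
  dt <- data.table::data.table(kmer = unlist(km), idx = rep(seq_len(n), lengths(km)))
  occ <- dt[, .N, by = "kmer"]
  dt <- dt[dt$kmer %in% occ$kmer[occ$N <= max_occ & occ$N >= 2], ]
  if (nrow(dt) == 0) return(data.frame(i = integer(0), j = integer(0)))
  joined <- dt[dt, on = "kmer", allow.cartesian = TRUE]
  joined <- joined[joined$idx < joined$i.idx, ]
  if (nrow(joined) == 0) return(data.frame(i = integer(0), j = integer(0)))
  cnt <- joined[, .N, by = c("idx", "i.idx")]
  cnt <- cnt[cnt$N >= min_shared, ]
  data.frame(i = cnt$idx, j = cnt$i.idx)
}

#' Built-in all-vs-all protein similarity search
#'
#' Aligns every candidate pair of proteins with the Smith-Waterman aligner
#' of [align_local()] and returns a ranked [rank_hits()] table, including
#' within-genome hits (the uniform top-3 rule counts paralog hits; the BBH
#' computation ignores them). A shared-k-mer prefilter restricts the
#' quadratic pair space to pairs with detectable word-level similarity;
#' pairs it skips could only yield alignments far below every downstream
#' acceptance gate. Set `config$prefilter_kmer = 0` for the exhaustive
#' all-pairs search.
#'
#' @param proteins A `protein_set` data frame.
#' @param config A [pipeline_config()].
#' @param chunk_size Number of pairs aligned per vectorized batch.
#' @return A `hit_table` with hits in both directions for every surviving
#'   pair, gated at `config$initial_evalue_max`.
#' @export
all_vs_all_hits <- function(proteins, config = pipeline_config(),
                            chunk_size = 4000L) {
  config <- as_pipeline_config(config)
  n <- nrow(proteins)
  if (n < 2) return(empty_hit_table(TRUE))
  seqs <- stats::setNames(proteins$sequence, proteins$protein_id)
  if (config$prefilter_kmer > 0) {
    cand <- kmer_candidate_pairs(seqs, k = config$prefilter_kmer,
                                 min_shared = config$prefilter_min_shared)
  } else {
    idx <- utils::combn(n, 2)
    cand <- data.frame(i = idx[1, ], j = idx[2, ])
  }
  if (nrow(cand) == 0) return(empty_hit_table(TRUE))
  mat <- blosum62_wildcard()
  pieces <- split(seq_len(nrow(cand)), ceiling(seq_len(nrow(cand)) / chunk_size))
  rows <- lapply(pieces, function(ix) {
    res <- align_pairs(seqs[cand$i[ix]], seqs[cand$j[ix]], mat = mat)
    res$query_id <- proteins$protein_id[cand$i[ix]]
    res$subject_id <- proteins$protein_id[cand$j[ix]]
    res[!is.na(res$score_raw), , drop = FALSE]
  })
  fw <- do.call(rbind, rows)
  if (is.null(fw) || nrow(fw) == 0) return(empty_hit_table(TRUE))
  rv <- data.frame(query_id = fw$subject_id, subject_id = fw$query_id,
                   identity = fw$identity, aln_length = fw$aln_length,
                   qstart = fw$sstart, qend = fw$send,
                   sstart = fw$qstart, send = fw$qend,
                   evalue = fw$evalue, bitscore = fw$bitscore,
                   qlen = fw$slen, slen = fw$qlen,
                   q_cov = fw$s_cov, s_cov = fw$q_cov,
                   stringsAsFactors = FALSE)
  fw <- fw[, c("query_id", "subject_id", "identity", "aln_length", "qstart",
               "qend", "sstart", "send", "evalue", "bitscore", "qlen", "slen",
               "q_cov", "s_cov")]
  all <- rbind(fw, rv)
  # search-wide expectation: query length times the total residue count of
  # the searched set (the BLAST database-length convention), so E-values
  # are on the same scale as externally computed hit files
  n_db <- sum(proteins$length)
  all$evalue <- all$qlen * n_db * 2^(-all$bitscore)
  all <- all[all$evalue <= config$initial_evalue_max, , drop = FALSE]
  rank_hits(all, exclude_self = TRUE)
}

bbh_overlap <- function(hits, denominator = "longer") {
  if (denominator == "longer") {
    hits$aln_length / pmax(hits$qlen, hits$slen)
  } else {
    hits$aln_length / pmin(hits$qlen, hits$slen)
  }
}

#' Bidirectional best hits between genomes
#'
#' A hit survives the BBH gates when its bit score is at least
#' `config$bbh_min_bitscore` and its overlap (alignment length over the
#' longer of the two sequences, by default) is at least
#' `config$bbh_min_overlap`. A pair (a, b) from two different genomes is a
#' BBH when b is a's best-ranked surviving hit within b's genome and vice
#' versa; ties at the top are broken by the [rank_hits()] order, so a
#' protein has at most one best hit per genome.
#'
#' @param hit_table A ranked `hit_table` covering both search directions.
#' @param genomes Named character vector mapping protein id to genome id,
#'   or a `protein_set` data frame.
#' @param config A [pipeline_config()].
#' @return A data frame `protein_a`, `protein_b`, `bitscore_ab`,
#'   `bitscore_ba` with `protein_a < protein_b`.
#' @export
compute_bbh <- function(hit_table, genomes, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  if (is.data.frame(genomes)) genomes <- genome_of(genomes)
  empty <- data.frame(protein_a = character(0), protein_b = character(0),
                      bitscore_ab = numeric(0), bitscore_ba = numeric(0),
                      stringsAsFactors = FALSE)
  df <- as.data.frame(hit_table)
  if (nrow(df) == 0) return(empty)
  df$qgenome <- unname(genomes[df$query_id])
  df$sgenome <- unname(genomes[df$subject_id])
  ov <- bbh_overlap(df, config$bbh_overlap_denominator)
  df <- df[df$bitscore >= config$bbh_min_bitscore &
             ov >= config$bbh_min_overlap &
             !is.na(df$qgenome) & !is.na(df$sgenome) &
             df$qgenome != df$sgenome, , drop = FALSE]
  if (nrow(df) == 0) return(empty)
  # hit_table order is the ranking; first surviving row per (query, subject
  # genome) is the best hit in that genome
  df <- df[order(df$query_id, df$rank), , drop = FALSE]
  best <- df[!duplicated(df[, c("query_id", "sgenome")]), , drop = FALSE]
  key_fwd <- paste(best$query_id, best$subject_id)
  key_rev <- paste(best$subject_id, best$query_id)
  mutual <- best[key_rev %in% key_fwd, , drop = FALSE]
  if (nrow(mutual) == 0) return(empty)
  a_first <- mutual$query_id < mutual$subject_id
  # each BBH appears as two rows (a->b and b->a); build one row per pair
  fwd <- mutual[a_first, , drop = FALSE]
  rev <- mutual[!a_first, , drop = FALSE]
  out <- data.frame(protein_a = fwd$query_id, protein_b = fwd$subject_id,
                    bitscore_ab = fwd$bitscore, stringsAsFactors = FALSE)
  ba <- stats::setNames(rev$bitscore, paste(rev$subject_id, rev$query_id))
  out$bitscore_ba <- unname(ba[paste(out$protein_a, out$protein_b)])
  out <- out[!is.na(out$bitscore_ba), , drop = FALSE]
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
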