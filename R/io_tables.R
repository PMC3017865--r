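#' @name scl_classes
#' @title The controlled vocabulary of subcellular-location classes
#' @description Nine location classes are recognized. The seven secretome
#' classes cover lipid-anchored, N-/C-terminally membrane-anchored, Sec- and
#' Tat-pathway secreted, non-classically secreted and cell-wall anchored
#' proteins; `MULTI_TM` (integral membrane) and `INTRACELLULAR` are never
#' part of the secretome.
#' @export
SCL_CLASSES <- c("LIPID_ANCHORED", "N_ANCHORED", "C_ANCHORED", "SEC_SECRETED",
                 "TAT_SECRETED", "NONCLASSICAL_SECRETED", "CELL_WALL_ANCHORED",
                 "MULTI_TM", "INTRACELLULAR")

#' @rdname scl_classes
#' @export
SCL_SECRETOME_CLASSES <- c("LIPID_ANCHORED", "N_ANCHORED", "C_ANCHORED",
                           "SEC_SECRETED", "TAT_SECRETED",
                           "NONCLASSICAL_SECRETED", "CELL_WALL_ANCHORED")

HIT_COLS <- c("query_id", "subject_id", "identity", "aln_length", "mismatches",
              "gapopens", "qstart", "qend", "sstart", "send", "evalue",
              "bitscore", "qlen", "slen")

#' Read a tabular hit file
#'
#' The dialect is the 12-column tab-separated format of BLAST `outfmt 6`
#' (query, subject, percent identity, alignment length, mismatches, gap
#' opens, query start/end, subject start/end, E-value, bit score) extended
#' with two required columns 13-14 holding the full query and subject
#' lengths; coverage- and length-ratio rules are uncomputable without them.
#' Rows failing the initial E-value gate are dropped and the surviving hits
#' are ranked per query by (bit score desc, E-value asc, subject id asc)
#' with the best-scoring HSP kept per (query, subject) pair.
#'
#' @param path Path to the tab-separated hit file (no header row).
#' @param config A [pipeline_config()] (supplies `initial_evalue_max`).
#' @param exclude_self Drop hits of a protein to itself.
#' @return A `hit_table` data frame (see [rank_hits()]).
#' @export
read_hit_table <- function(path, config = pipeline_config(), exclude_self = TRUE) {
  config <- as_pipeline_config(config)
  if (!file.exists(path)) stop(sprintf("hit file does not exist: %s", path))
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(raw) & !grepl("^#", raw)]
  if (length(raw) == 0) return(empty_hit_table(exclude_self))
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf == 12L)) {
    stop(sprintf("line %d: 12-column hit file; this pipeline requires the 14-column dialect (standard outfmt-6 columns plus qlen and slen as columns 13-14)",
                 which(nf == 12L)[1]))
  }
  if (any(nf != 14L)) {
    stop(sprintf("line %d: malformed hit row (%d fields, expected 14)",
                 which(nf != 14L)[1], nf[which(nf != 14L)[1]]))
  }
  m <- do.call(rbind, parts)
  df <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    identity = as.numeric(m[, 3]) / 100,
    aln_length = as.integer(m[, 4]), mismatches = as.integer(m[, 5]),
    gapopens = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    qlen = as.integer(m[, 13]), slen = as.integer(m[, 14]),
    stringsAsFactors = FALSE
  )
  bad <- which(!stats::complete.cases(df[, c("identity", "aln_length", "evalue",
                                             "bitscore", "qlen", "slen")]))
  if (length(bad) > 0) stop(sprintf("line %d: malformed hit row (non-numeric field)", bad[1]))
  df$q_cov <- (abs(df$qend - df$qstart) + 1) / df$qlen
  df$s_cov <- (abs(df$send - df$sstart) + 1) / df$slen
  df <- df[df$evalue <= config$initial_evalue_max, , drop = FALSE]
  rank_hits(df, exclude_self = exclude_self)
}

#' Write a hit table in the 14-column tabular dialect of [read_hit_table()]
#'
#' @param hits A `hit_table` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  df <- as.data.frame(hits)
  out <- data.frame(
    df$query_id, df$subject_id, sprintf("%.2f", df$identity * 100),
    df$aln_length,
    if ("mismatches" %in% names(df)) df$mismatches else 0L,
    if ("gapopens" %in% names(df)) df$gapopens else 0L,
    df$qstart, df$qend, df$sstart, df$send,
    format_evalue(df$evalue), sprintf("%.1f", df$bitscore),
    df$qlen, df$slen
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_evalue <- function(e) {
  ifelse(e == 0, "0.0", formatC(e, format = "e", digits = 2))
}

#' Read the per-protein subcellular-location table
#'
#' Two tab-separated columns with a header: `protein_id`, `scl_class`. The
#' class must come from [SCL_CLASSES]; table entries override the built-in
#' heuristic classifier downstream.
#'
#' @param path Path to the SCL table, or `NULL` for an empty map.
#' @return A data frame `protein_id`, `scl_class`, `is_secretome`, `source`.
#' @export
read_scl_table <- function(path = NULL) {
  empty <- data.frame(protein_id = character(0), scl_class = character(0),
                      is_secretome = logical(0), source = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(path)) return(empty)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (nrow(df) == 0) return(empty)
  bad <- setdiff(unique(df$scl_class), SCL_CLASSES)
  if (length(bad) > 0) {
    stop(sprintf("unknown SCL class label(s): %s; valid labels are: %s",
                 paste(bad, collapse = ", "), paste(SCL_CLASSES, collapse = ", ")))
  }
  data.frame(protein_id = as.character(df$protein_id),
             scl_class = df$scl_class,
             is_secretome = df$scl_class %in% SCL_SECRETOME_CLASSES,
             source = "table", stringsAsFactors = FALSE)
}

#' Read the per-protein domain annotation table
#'
#' Tab-separated with header `protein_id`, `domain_accession`, `start`,
#' `end`, `score`. Stands in for externally computed Pfam/HMMER hits.
#'
#' @param path Path to the table, or `NULL` for an empty map.
#' @return A data frame of domain hits.
#' @export
read_domain_table <- function(path = NULL) {
  empty <- data.frame(protein_id = character(0), domain_accession = character(0),
                      start = integer(0), end = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(path)) return(empty)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (nrow(df) == 0) return(empty)
  data.frame(protein_id = as.character(df$protein_id),
             domain_accession = as.character(df$domain_accession),
             start = as.integer(df$start), end = as.integer(df$end),
             score = as.numeric(df$score), stringsAsFactors = FALSE)
}

#' Read the gene feature table
#'
#' Tab-separated with header `protein_id`, `contig`, `start`, `end`,
#' `strand`; coordinates are 1-based inclusive on the forward strand.
#'
#' @param path Path to the table, or `NULL` for an empty map.
#' @return A data frame of gene features.
#' @export
read_feature_table <- function(path = NULL) {
  empty <- data.frame(protein_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(path)) return(empty)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (nrow(df) == 0) return(empty)
  data.frame(protein_id = as.character(df$protein_id),
             contig = as.character(df$contig),
             start = as.integer(df$start), end = as.integer(df$end),
             strand = as.character(df$strand), stringsAsFactors = FALSE)
}

#' Read a seed cluster file
#'
#' Tab-separated, two columns, no header: cluster id and a comma-separated
#' member list. Clusters of size >= 2 are flagged extendable; singleton
#' clusters are flagged re-clusterable (their members re-enter clustering as
#' unattached queries).
#'
#' @param path Path to the cluster file, or `NULL` for no seed clusters.
#' @return A `lacog_set` data frame (see [lacog_set()]), with attribute
#'   `singleton_members` listing members of size-1 seed clusters.
#' @export
read_cluster_file <- function(path = NULL) {
  if (is.null(path)) {
    out <- lacog_set()
    attr(out, "singleton_members") <- character(0)
    return(out)
  }
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(raw) & !grepl("^#", raw)]
  if (length(raw) > 0 && grepl("^cluster_id\t", raw[1])) raw <- raw[-1]
  if (length(raw) == 0) {
    out <- lacog_set()
    attr(out, "singleton_members") <- character(0)
    return(out)
  }
  parts <- strsplit(raw, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  members <- lapply(parts, function(p) {
    if (length(p) < 2) character(0) else strsplit(p[2], ",", fixed = TRUE)[[1]]
  })
  sizes <- lengths(members)
  singletons <- unlist(members[sizes < 2])
  keep <- sizes >= 2
  out <- lacog_set(cluster_id = rep(ids[keep], lengths(members[keep])),
                   protein_id = unlist(members[keep]),
                   provenance = "seed", origin = "seed_extended")
  attr(out, "singleton_members") <- as.character(singletons %||% character(0))
  out
}

#' Write a cluster table in the two-column dialect of [read_cluster_file()]
#'
#' @param clusters A `lacog_set` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cluster_file <- function(clusters, path) {
  df <- as.data.frame(clusters)
  ids <- sort(unique(df$cluster_id))
  lines <- vapply(ids, function(cid) {
    paste(cid, paste(sort(df$protein_id[df$cluster_id == cid]), collapse = ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
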