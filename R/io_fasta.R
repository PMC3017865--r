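#' Read a protein FASTA file
#'
#' Headers follow the dialect `>protein_id key=value ...` where the
#' recognized keys are `genome_id=`, `contig=`, `start=`, `end=`, `strand=`;
#' any remaining header text is kept as the description. Sequences are
#' uppercased (the lowercase `x` junction marker of pseudogene assemblies is
#' preserved) and a trailing `*` stop symbol is stripped.
#'
#' @param path Path to a FASTA file.
#' @param default_genome_id Genome id used when a header carries no
#'   `genome_id=` key.
#' @return A `protein_set` data frame.
#' @export
read_protein_fasta <- function(path, default_genome_id = NA_character_) {
  if (!file.exists(path)) stop(sprintf("FASTA file does not exist: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^;", lines)]
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0) {
    return(protein_records(character(0), character(0), character(0)))
  }
  first_nonempty <- which(nzchar(trimws(lines)))[1]
  if (!is.na(first_nonempty) && !(first_nonempty %in% hdr_idx)) {
    stop(sprintf("line %d: sequence data before first FASTA header", first_nonempty))
  }
  ends <- c(hdr_idx[-1] - 1L, length(lines))
  recs <- vector("list", length(hdr_idx))
  for (i in seq_along(hdr_idx)) {
    hline <- sub("^>", "", lines[hdr_idx[i]])
    toks <- strsplit(trimws(hline), "\\s+")[[1]]
    if (length(toks) == 0 || !nzchar(toks[1])) {
      stop(sprintf("line %d: empty FASTA header", hdr_idx[i]))
    }
    pid <- toks[1]
    kv <- toks[-1][grepl("^[A-Za-z_]+=", toks[-1])]
    rest <- toks[-1][!grepl("^[A-Za-z_]+=", toks[-1])]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[A-Za-z_]+=", "", kv)
    get <- function(k, default = NA_character_) {
      if (k %in% keys) vals[match(k, keys)] else default
    }
    seq_lines <- if (hdr_idx[i] + 1L <= ends[i]) {
      trimws(lines[seq.int(hdr_idx[i] + 1L, ends[i])])
    } else character(0)
    for (j in seq_along(seq_lines)) {
      sl <- seq_lines[j]
      chk <- sub("\\*$", "", sl)
      if (grepl("[^A-Za-z]", chk) || grepl("[BJOUZbjouz]", chk)) {
        stop(sprintf("line %d: non-amino-acid character in sequence of '%s'",
                     hdr_idx[i] + j, pid))
      }
    }
    seq <- paste(seq_lines, collapse = "")
    seq <- sub("\\*$", "", seq)
    recs[[i]] <- list(
      protein_id = pid,
      genome_id = get("genome_id", default_genome_id),
      sequence = seq,
      contig_id = get("contig"),
      start = suppressWarnings(as.integer(get("start"))),
      end = suppressWarnings(as.integer(get("end"))),
      strand = get("strand"),
      description = paste(rest, collapse = " ")
    )
  }
  ids <- vapply(recs, `[[`, character(1), "protein_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate protein_id in %s: %s", path, paste(dup, collapse = ", ")))
  }
  protein_records(
    protein_id = ids,
    genome_id = vapply(recs, `[[`, character(1), "genome_id"),
    sequence = vapply(recs, `[[`, character(1), "sequence"),
    contig_id = vapply(recs, `[[`, character(1), "contig_id"),
    start = vapply(recs, function(r) r$start %||% NA_integer_, integer(1)),
    end = vapply(recs, function(r) r$end %||% NA_integer_, integer(1)),
    strand = vapply(recs, `[[`, character(1), "strand"),
    description = vapply(recs, `[[`, character(1), "description")
  )
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Write a protein set to FASTA in the header dialect of [read_protein_fasta()]
#'
#' @param proteins A `protein_set` data frame.
#' @param path Output file path.
#' @param width Line width for wrapped sequence.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path, width = 70L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    p <- proteins[i, ]
    kv <- character(0)
    if (!is.na(p$genome_id)) kv <- c(kv, sprintf("genome_id=%s", p$genome_id))
    if (!is.na(p$contig_id)) kv <- c(kv, sprintf("contig=%s", p$contig_id))
    if (!is.na(p$start)) kv <- c(kv, sprintf("start=%d", p$start))
    if (!is.na(p$end)) kv <- c(kv, sprintf("end=%d", p$end))
    if (!is.na(p$strand) && nzchar(p$strand)) kv <- c(kv, sprintf("strand=%s", p$strand))
    desc <- if (nzchar(p$description)) paste0(" ", p$description) else ""
    hdr <- sprintf(">%s%s%s", p$protein_id,
                   if (length(kv)) paste0(" ", paste(kv, collapse = " ")) else "",
                   desc)
    writeLines(hdr, con, sep = "\n")
    s <- p$sequence
    starts <- seq.int(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con, sep = "\n")
  }
  invisible(path)
}

#' Read a nucleotide FASTA file into a named character vector of contigs
#'
#' @param path Path to a nucleotide FASTA file.
#' @return Named character vector (names are contig ids).
#' @export
read_contig_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file does not exist: %s", path))
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write contigs to a nucleotide FASTA file
#'
#' @param contigs Named character vector of contig sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contig_fasta <- function(contigs, path) {
  ss <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
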