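#' Construct a protein record table
#'
#' Proteins are kept as a plain data frame with one row per protein. This is
#' the canonical in-memory form used across the pipeline; every stage that
#' consumes proteins accepts this table.
#'
#' @param protein_id Character vector of unique protein identifiers.
#' @param genome_id Character vector of genome identifiers (recycled).
#' @param sequence Amino-acid sequences (standard 20 letters plus `X`; a
#'   lowercase `x` marks the junction of a concatenated pseudogene assembly).
#' @param contig_id,start,end,strand Optional gene coordinates (1-based,
#'   inclusive, forward-strand; strand `+` or `-`).
#' @param description Free-text description.
#' @param is_pseudo_fragment Logical; marks proteins flagged as pseudogene
#'   fragments (input default `FALSE`; set by the detection stage).
#' @return A `data.frame` with class `protein_set`.
#' @export
protein_records <- function(protein_id, genome_id, sequence,
                            contig_id = NA_character_,
                            start = NA_integer_, end = NA_integer_,
                            strand = NA_character_,
                            description = "",
                            is_pseudo_fragment = FALSE) {
  protein_id <- as.character(protein_id)
  n <- length(protein_id)
  df <- data.frame(
    protein_id = protein_id,
    genome_id = rep_len(as.character(genome_id), n),
    sequence = toupper_keep_x(rep_len(as.character(sequence), n)),
    contig_id = rep_len(as.character(contig_id), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    strand = rep_len(as.character(strand), n),
    description = rep_len(as.character(description), n),
    is_pseudo_fragment = rep_len(as.logical(is_pseudo_fragment), n),
    stringsAsFactors = FALSE
  )
  df$length <- nchar(df$sequence)
  df <- df[, c("protein_id", "genome_id", "sequence", "length", "contig_id",
               "start", "end", "strand", "description", "is_pseudo_fragment")]
  validate_protein_set(df)
}

# Uppercase a sequence but preserve the lowercase 'x' junction marker of
# pseudogene assemblies.
toupper_keep_x <- function(s) {
  up <- toupper(s)
  has_x <- grepl("x", s, fixed = TRUE)
  if (any(has_x)) {
    up[has_x] <- vapply(which(has_x), function(i) {
      ch <- strsplit(s[i], "")[[1]]
      keep <- ch == "x"
      ch <- toupper(ch)
      ch[keep] <- "x"
      paste(ch, collapse = "")
    }, character(1))
  }
  up
}

AA_ALPHABET_20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

validate_protein_set <- function(df) {
  stopifnot(is.data.frame(df))
  dup <- df$protein_id[duplicated(df$protein_id)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate protein_id: %s", paste(unique(dup), collapse = ", ")))
  }
  bad <- grepl(sprintf("[^%sXx]", paste(AA_ALPHABET_20, collapse = "")), df$sequence)
  if (any(bad)) {
    stop(sprintf("non-amino-acid character in sequence of: %s",
                 paste(df$protein_id[bad], collapse = ", ")))
  }
  if (any(nchar(df$sequence) != df$length)) stop("length field disagrees with sequence")
  both <- !is.na(df$start) & !is.na(df$end)
  if (any(both & df$start > df$end)) {
    stop(sprintf("start > end for: %s",
                 paste(df$protein_id[both & df$start > df$end], collapse = ", ")))
  }
  class(df) <- c("protein_set", "data.frame")
  df
}

#' Bundle a genome's proteins with its labels and contigs
#'
#' @param genome_id Genome identifier.
#' @param species_label Species the genome belongs to (strains of one species
#'   share the label).
#' @param niche_tags Character vector of niche tags (e.g. `"GI-tract"`,
#'   `"dairy"`, `"plant"`); may be empty.
#' @param proteins A `protein_set` table whose rows all carry `genome_id`.
#' @param contigs Optional named character vector of nucleotide contig
#'   sequences (names are contig ids).
#' @param is_lab Logical; `FALSE` marks a non-LAB reference genome.
#' @return An object of class `genome_bundle`.
#' @export
genome_bundle <- function(genome_id, species_label = genome_id,
                          niche_tags = character(0), proteins,
                          contigs = NULL, is_lab = TRUE) {
  proteins <- validate_protein_set(as.data.frame(proteins))
  if (nrow(proteins) > 0 && !all(proteins$genome_id == genome_id)) {
    stop("all proteins in a genome_bundle must carry its genome_id")
  }
  structure(list(genome_id = as.character(genome_id),
                 species_label = as.character(species_label),
                 niche_tags = as.character(niche_tags),
                 proteins = proteins,
                 contigs = contigs,
                 is_lab = isTRUE(is_lab)),
            class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf("<genome_bundle> %s (%s): %d proteins, %d contigs, niches: %s\n",
              x$genome_id, x$species_label, nrow(x$proteins),
              length(x$contigs),
              if (length(x$niche_tags)) paste(x$niche_tags, collapse = ",") else "-"))
  invisible(x)
}

#' Combine the protein tables of several genome bundles
#'
#' @param bundles A list of `genome_bundle` objects.
#' @return A single `protein_set` data frame.
#' @export
combined_proteins <- function(bundles) {
  stopifnot(is.list(bundles))
  df <- do.call(rbind, lapply(bundles, function(b) as.data.frame(b$proteins)))
  if (is.null(df)) df <- protein_records(character(0), character(0), character(0))
  validate_protein_set(df)
}

genome_of <- function(proteins) {
  stats::setNames(proteins$genome_id, proteins$protein_id)
}

length_of <- function(proteins) {
  stats::setNames(proteins$length, proteins$protein_id)
}
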