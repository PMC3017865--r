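KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2, X = 0)

LIPOBOX_RE <- "[LVI][ASTVIG][GAS]C"
LPXTG_RE <- "LP.TG"

#' Transmembrane stretches of a sequence
#'
#' Scans the Kyte-Doolittle hydropathy profile with a sliding window; every
#' maximal run of window positions whose mean exceeds the threshold is
#' reported as one stretch (interval from the first window's start to the
#' last window's end, so each stretch spans at least `window` residues).
#'
#' @param sequence Amino-acid string.
#' @param window Window length (residues).
#' @param threshold Mean hydropathy above which a window is hydrophobic.
#' @return A data frame `start`, `end` (possibly empty).
#' @export
find_tm_stretches <- function(sequence, window = 7L, threshold = 1.5) {
  ch <- strsplit(sequence, "")[[1]]
  kd <- unname(KD_SCALE[ch])
  kd[is.na(kd)] <- 0
  L <- length(kd)
  if (L < window) return(data.frame(start = integer(0), end = integer(0)))
  wm <- as.numeric(stats::filter(kd, rep(1 / window, window), sides = 1))
  wm <- wm[window:L]  # wm[i] = mean over positions i..i+window-1 (i = 1..L-window+1)
  hot <- wm > threshold
  if (!any(hot)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(hot)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  keep <- r$values
  iv <- data.frame(start = starts_idx[keep], end = ends_idx[keep] + window - 1L)
  # separate runs of hot windows can produce overlapping residue intervals;
  # such intervals are one membrane stretch
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= merged$end[nrow(merged)] + 1L) {
      merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], iv$end[i])
    } else {
      merged <- rbind(merged, iv[i, , drop = FALSE])
    }
  }
  merged
}

strip_junctions <- function(sequence) gsub("x", "", sequence, fixed = TRUE)

has_lipobox <- function(sequence, within = 35L) {
  m <- regexpr(LIPOBOX_RE, substr(sequence, 1, within))
  m[1] > 0
}

lpxtg_site <- function(sequence, last = 50L) {
  L <- nchar(sequence)
  from <- max(1L, L - last + 1L)
  m <- gregexpr(LPXTG_RE, sequence)[[1]]
  m <- m[m > 0 & m >= from]
  if (length(m) == 0) NA_integer_ else m[1]
}

#' Rule-based subcellular-location classifier
#'
#' A deterministic cascade over sequence features standing in for a
#' dedicated location predictor: (i) a lipobox within the first 35 residues
#' gives `LIPID_ANCHORED`; (ii) an N-terminal hydrophobic stretch followed
#' by an A-x-A cleavage site, with no further stretch, gives `SEC_SECRETED`
#' (`TAT_SECRETED` when a twin-arginine precedes the stretch); (iii) a sole
#' N-terminal stretch without a cleavage site gives `N_ANCHORED`; (iv) an
#' LPxTG motif in the last 50 residues followed by a hydrophobic stretch
#' and a positively charged tail gives `CELL_WALL_ANCHORED`; (v) a sole
#' stretch in the last 50 residues gives `C_ANCHORED`; (vi) two or more
#' stretches give `MULTI_TM`; (vii) everything else is `INTRACELLULAR`.
#' Junction markers (`x`) are ignored. `NONCLASSICAL_SECRETED` is only ever
#' assigned via an external annotation table.
#'
#' @param sequence Amino-acid string (one protein).
#' @param protein_id Optional id carried through to the output.
#' @param config A [pipeline_config()] (hydropathy window/threshold).
#' @return A one-row data frame: `protein_id`, `scl_class`, `is_secretome`,
#'   `source`, `tm_start`, `tm_end`.
#' @export
heuristic_scl <- function(sequence, protein_id = NA_character_,
                          config = pipeline_config()) {
  config <- as_pipeline_config(config)
  seq0 <- strip_junctions(sequence)
  if (nchar(seq0) < 1) stop("cannot classify an empty sequence")
  L <- nchar(seq0)
  tm <- find_tm_stretches(seq0, config$kd_window, config$kd_threshold)
  n_tm <- nrow(tm)
  call <- function(class, s = NA_integer_, e = NA_integer_) {
    data.frame(protein_id = protein_id, scl_class = class,
               is_secretome = class %in% SCL_SECRETOME_CLASSES,
               source = "heuristic", tm_start = s, tm_end = e,
               stringsAsFactors = FALSE)
  }
  if (has_lipobox(seq0)) return(call("LIPID_ANCHORED"))
  nterm <- tm[tm$start <= 45L, , drop = FALSE]
  if (nrow(nterm) > 0) {
    s1 <- nterm[1, ]
    cle <- cleavage_after(seq0, s1$start, s1$end)
    further <- any(tm$start > s1$end)
    if (!is.na(cle) && !further) {
      if (grepl("RR", substr(seq0, 1, max(0L, s1$start - 1L)))) {
        return(call("TAT_SECRETED", s1$start, s1$end))
      }
      return(call("SEC_SECRETED", s1$start, s1$end))
    }
    if (is.na(cle) && n_tm == 1L) return(call("N_ANCHORED", s1$start, s1$end))
  }
  lp <- lpxtg_site(seq0)
  if (!is.na(lp)) {
    # the anchor helix must extend past the motif; the detected stretch can
    # start earlier when the sliding window fuses it with the motif itself
    after_tm <- tm[tm$end > lp + 4L, , drop = FALSE]
    if (nrow(after_tm) > 0) {
      tail_part <- substr(seq0, after_tm$end[1] + 1L, L)
      if (grepl("[KR]", tail_part)) {
        return(call("CELL_WALL_ANCHORED", after_tm$start[1], after_tm$end[1]))
      }
    }
  }
  if (n_tm == 1L && tm$start[1] >= L - 49L) {
    return(call("C_ANCHORED", tm$start[1], tm$end[1]))
  }
  if (n_tm >= 2L) return(call("MULTI_TM", tm$start[1], tm$end[1]))
  call("INTRACELLULAR")
}

# A-x-A cleavage motif near the end of the signal. Mildly hydrophobic Ala
# residues ride the tail of the detected stretch (and the stretch itself
# may be extended past the true signal by the sliding window), so the
# search covers everything after the hydrophobic core start plus 10
# residues downstream of the stretch.
cleavage_after <- function(sequence, stretch_start, stretch_end, within = 10L) {
  from <- stretch_start + 7L
  win <- substr(sequence, from, min(nchar(sequence), stretch_end + within))
  m <- regexpr("A.A", win)
  if (m[1] > 0) from + m[1] - 1L else NA_integer_
}

#' Outside-in (C-in) topology test for N-anchored proteins
#'
#' An N-terminally anchored protein whose positively charged residues lie
#' exclusively just downstream of the transmembrane helix -- none upstream
#' -- has its bulk inside the cell (the positive-inside rule read in
#' reverse). Such calls are false-positive secretome predictions and are
#' reclassified as intracellular by [screen_scl()].
#'
#' @param sequence Amino-acid string.
#' @param call A one-row SCL call with class `N_ANCHORED` and a `tm_start`
#'   / `tm_end` span.
#' @param config A [pipeline_config()] (downstream window length).
#' @return `TRUE` when the topology is outside-in.
#' @export
detect_outside_in <- function(sequence, call, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  if (call$scl_class != "N_ANCHORED") {
    stop("detect_outside_in applies only to N_ANCHORED calls")
  }
  if (is.na(call$tm_start) || is.na(call$tm_end)) {
    stop("N_ANCHORED call lacks a transmembrane span")
  }
  seq0 <- strip_junctions(sequence)
  before <- substr(seq0, 1, call$tm_start - 1L)
  after <- substr(seq0, call$tm_end + 1L,
                  min(nchar(seq0), call$tm_end + config$positive_inside_window))
  !grepl("[KR]", before) && grepl("[KR]", after)
}

#' The small Sec-only filter
#'
#' Proteins shorter than `config$min_len_sec_only` residues whose only
#' positive feature is a Sec-type N-terminal signal sequence are removed
#' from the predicted secretome: their mature part is too small to form an
#' extracellular domain. Junction markers do not count toward the length.
#' Non-Sec classes and proteins with any additional feature (lipobox,
#' LPxTG, an extra transmembrane stretch) are kept.
#'
#' @param sequence Amino-acid string.
#' @param call A one-row SCL call for the protein.
#' @param config A [pipeline_config()].
#' @return `"drop"` or `"keep"`.
#' @export
small_sec_filter <- function(sequence, call, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  seq0 <- strip_junctions(sequence)
  if (call$scl_class != "SEC_SECRETED") return("keep")
  if (nchar(seq0) >= config$min_len_sec_only) return("keep")
  if (has_lipobox(seq0)) return("keep")
  if (!is.na(lpxtg_site(seq0))) return("keep")
  tm <- find_tm_stretches(seq0, config$kd_window, config$kd_threshold)
  extra <- if (!is.na(call$tm_end)) any(tm$start > call$tm_end) else nrow(tm) > 1
  if (extra) return("keep")
  "drop"
}

#' Assign and screen subcellular locations for a protein set
#'
#' Every protein receives an SCL call: the annotation-table entry when one
#' exists (tables always override the heuristic), otherwise the
#' [heuristic_scl()] cascade. Two false-positive screens then run:
#' heuristic N-anchored calls with outside-in topology are reclassified as
#' `INTRACELLULAR`, and small Sec-only proteins are removed from the
#' secretome ([small_sec_filter()]). The `filters_fired` column records
#' which screens acted on each protein.
#'
#' @param proteins A `protein_set` data frame.
#' @param scl_table Optional table from [read_scl_table()].
#' @param config A [pipeline_config()].
#' @return A data frame with one SCL call per protein: `protein_id`,
#'   `scl_class`, `is_secretome`, `source`, `tm_start`, `tm_end`,
#'   `filters_fired`.
#' @export
screen_scl <- function(proteins, scl_table = NULL, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  if (is.null(scl_table)) scl_table <- read_scl_table(NULL)
  override <- stats::setNames(scl_table$scl_class, scl_table$protein_id)
  calls <- lapply(seq_len(nrow(proteins)), function(i) {
    pid <- proteins$protein_id[i]
    seq <- proteins$sequence[i]
    if (pid %in% names(override)) {
      cls <- unname(override[pid])
      cl <- data.frame(protein_id = pid, scl_class = cls,
                       is_secretome = cls %in% SCL_SECRETOME_CLASSES,
                       source = "table", tm_start = NA_integer_,
                       tm_end = NA_integer_, stringsAsFactors = FALSE)
    } else {
      cl <- heuristic_scl(seq, pid, config)
    }
    fired <- character(0)
    if (cl$scl_class == "N_ANCHORED" && cl$source == "heuristic" &&
        detect_outside_in(seq, cl, config)) {
      cl$scl_class <- "INTRACELLULAR"
      cl$is_secretome <- FALSE
      fired <- c(fired, "outside_in")
    }
    if (cl$is_secretome && small_sec_filter(seq, cl, config) == "drop") {
      cl$is_secretome <- FALSE
      fired <- c(fired, "small_sec")
    }
    cl$filters_fired <- paste(fired, collapse = ";")
    cl
  })
  out <- do.call(rbind, calls)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), scl_class = character(0),
                      is_secretome = logical(0), source = character(0),
                      tm_start = integer(0), tm_end = integer(0),
                      filters_fired = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
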