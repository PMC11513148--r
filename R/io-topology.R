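# Two interchange dialects for membrane-topology predictions are supported:
#  * "gff3": `# <id> Length: <L>` comment, then `<id>\t<label>\t<start>\t<end>`
#    rows (1-based inclusive), records separated by `//` lines;
#  * "three_line": `>id | TM=<k>` / sequence / per-residue label string over
#    {I, O, M, S} (inside, outside, membrane helix, signal).

.label_from_letter <- c(I = "inside", O = "outside", M = "TMhelix", S = "signal")
.letter_from_label <- c(inside = "I", outside = "O", TMhelix = "M", signal = "S")

.normalize_label <- function(label) {
  lab <- tolower(label)
  out <- character(length(lab))
  out[lab %in% c("inside", "cytoplasmic", "cyto")] <- "inside"
  out[lab %in% c("outside", "extracellular", "lumenal", "luminal",
                 "periplasm", "periplasmic")] <- "outside"
  out[lab %in% c("tmhelix", "tm", "membrane", "m")] <- "TMhelix"
  out[lab %in% c("signal", "signal_peptide", "sp")] <- "signal"
  bad <- out == ""
  if (any(bad)) {
    abort(sprintf("Unknown topology label(s): %s",
                  paste(unique(label[bad]), collapse = ", ")))
  }
  out
}

.as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    readr::read_lines(text)
  } else if (length(text) == 1L) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
}

#' Parse a membrane-topology annotation
#'
#' Reads either supported dialect (auto-detected by default), normalizes
#' labels to `inside` / `outside` / `TMhelix` / `signal`, and validates that
#' each protein's segments tile `[1, length]` with no gaps or overlaps.
#'
#' @param text A file path, a single string, or a character vector of lines.
#' @param dialect `"auto"`, `"gff3"`, or `"three_line"`.
#' @return A tibble (`protein_id`, `label`, `start`, `end`) with attributes
#'   `seq_length` (named integer vector) and, for the three-line dialect,
#'   `sequences` (named character vector).
#' @export
parse_topology <- function(text, dialect = c("auto", "gff3", "three_line")) {
  dialect <- match.arg(dialect)
  lines <- .as_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("Empty topology input.")
  if (dialect == "auto") {
    dialect <- if (startsWith(trimws(lines[1]), ">")) "three_line" else "gff3"
  }
  ann <- if (dialect == "gff3") .parse_topology_gff3(lines) else .parse_topology_3line(lines)
  .validate_tiling(ann, attr(ann, "seq_length"))
  ann
}

.parse_topology_gff3 <- function(lines) {
  lines <- lines[!grepl("^\\s*//\\s*$", lines)]
  is_comment <- startsWith(trimws(lines), "#")
  lens <- integer(0)
  for (cm in lines[is_comment]) {
    m <- regmatches(cm, regexec("^#\\s*(\\S+)\\s+Length:\\s*(\\d+)", cm))[[1]]
    if (length(m) == 3L) lens[m[2]] <- as.integer(m[3])
  }
  rows <- strsplit(lines[!is_comment], "\t", fixed = TRUE)
  bad <- vapply(rows, length, 1L) < 4L
  if (any(bad)) {
    abort(sprintf("Malformed topology row: '%s' (expected id<TAB>label<TAB>start<TAB>end).",
                  lines[!is_comment][which(bad)[1]]))
  }
  ann <- tibble(
    protein_id = vapply(rows, `[[`, "", 1L),
    label = .normalize_label(vapply(rows, `[[`, "", 2L)),
    start = as.integer(vapply(rows, `[[`, "", 3L)),
    end = as.integer(vapply(rows, `[[`, "", 4L))
  )
  got <- tapply(ann$end, ann$protein_id, max)
  missing <- setdiff(unique(ann$protein_id), names(lens))
  lens[missing] <- as.integer(got[missing])
  attr(ann, "seq_length") <- lens
  ann
}

.parse_topology_3line <- function(lines) {
  starts <- which(startsWith(lines, ">"))
  if (!length(starts)) abort("No '>' records found in three-line topology input.")
  out <- vector("list", length(starts))
  seqs <- character(0)
  lens <- integer(0)
  for (i in seq_along(starts)) {
    s <- starts[i]
    if (s + 2L > length(lines)) abort("Truncated three-line topology record.")
    id <- sub("^>\\s*", "", lines[s])
    id <- trimws(strsplit(id, "|", fixed = TRUE)[[1]][1])
    seq <- trimws(lines[s + 1L])
    lab <- trimws(lines[s + 2L])
    if (nchar(seq) != nchar(lab)) {
      abort(sprintf("Protein %s: sequence (%d) and label string (%d) lengths differ.",
                    id, nchar(seq), nchar(lab)))
    }
    letters <- strsplit(lab, "", fixed = TRUE)[[1]]
    unknown <- setdiff(unique(letters), names(.label_from_letter))
    if (length(unknown)) {
      abort(sprintf("Protein %s: unknown per-residue label(s) %s.",
                    id, paste(unknown, collapse = ", ")))
    }
    r <- rle(letters)
    end <- cumsum(r$lengths)
    out[[i]] <- tibble(protein_id = id,
                       label = unname(.label_from_letter[r$values]),
                       start = end - r$lengths + 1L, end = end)
    seqs[id] <- seq
    lens[id] <- nchar(seq)
  }
  ann <- bind_rows(out)
  attr(ann, "seq_length") <- lens
  attr(ann, "sequences") <- seqs
  ann
}

.validate_tiling <- function(ann, lens) {
  for (id in unique(ann$protein_id)) {
    seg <- arrange(filter(ann, .data$protein_id == id), .data$start)
    if (seg$start[1] != 1L) {
      abort(sprintf("Protein %s: segments must start at residue 1 (first starts at %d).",
                    id, seg$start[1]))
    }
    if (any(seg$end < seg$start)) {
      i <- which(seg$end < seg$start)[1]
      abort(sprintf("Protein %s: segment at %d-%d is empty.", id, seg$start[i], seg$end[i]))
    }
    if (nrow(seg) > 1L) {
      gap <- seg$start[-1] != seg$end[-nrow(seg)] + 1L
      if (any(gap)) {
        i <- which(gap)[1]
        abort(sprintf("Protein %s: gap or overlap between residue %d and %d.",
                      id, seg$end[i], seg$start[i + 1L]))
      }
    }
    if (!is.null(lens) && !is.na(lens[id]) && seg$end[nrow(seg)] != lens[id]) {
      abort(sprintf("Protein %s: segments end at %d but sequence length is %d.",
                    id, seg$end[nrow(seg)], lens[id]))
    }
  }
  invisible(ann)
}

#' Write a topology annotation in either dialect
#'
#' @param topology Tibble (`protein_id`, `label`, `start`, `end`).
#' @param path Output file.
#' @param dialect `"gff3"` or `"three_line"`.
#' @param sequences Named character vector; required for `"three_line"`.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path, dialect = c("gff3", "three_line"),
                           sequences = NULL) {
  dialect <- match.arg(dialect)
  ids <- unique(topology$protein_id)
  lines <- character(0)
  for (id in ids) {
    seg <- arrange(filter(topology, .data$protein_id == id), .data$start)
    len <- max(seg$end)
    if (dialect == "gff3") {
      lines <- c(lines,
                 sprintf("# %s Length: %d", id, len),
                 sprintf("%s\t%s\t%d\t%d", id, seg$label, seg$start, seg$end),
                 "//")
    } else {
      if (is.null(sequences) || is.na(sequences[id])) {
        abort("three_line dialect needs `sequences` covering every protein.")
      }
      letters <- rep(unname(.letter_from_label[seg$label]),
                     seg$end - seg$start + 1L)
      n_tm <- sum(seg$label == "TMhelix")
      lines <- c(lines,
                 sprintf(">%s | TM=%d", id, n_tm),
                 unname(sequences[id]),
                 paste(letters, collapse = ""))
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}
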