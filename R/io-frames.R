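# Frame interchange formats: an XYZ-like text format (natoms / comment /
# `tag x y z` per point, one block per frame) and multi-MODEL PDB. The PDB
# reader goes through bio3d; the writer emits fixed-width ATOM records
# because multi-model writing is not covered by the library.

#' Write trajectory frames in the XYZ-like text format
#'
#' @param frames Frame tibble (`frame`, `lipid_id`, `leaflet`, `x`, `y`, `z`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_frames_xyz <- function(frames, path) {
  lines <- character(0)
  for (f in sort(unique(frames$frame))) {
    fr <- filter(frames, .data$frame == f)
    lines <- c(lines,
               as.character(nrow(fr)),
               sprintf("frame %d", f),
               sprintf("%s %.4f %.4f %.4f", fr$leaflet, fr$x, fr$y, fr$z))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read trajectory frames from the XYZ-like text format
#'
#' @param path Input file.
#' @return Frame tibble (`frame`, `lipid_id`, `leaflet`, `x`, `y`, `z`).
#' @export
read_frames_xyz <- function(path) {
  lines <- readr::read_lines(path)
  out <- vector("list", 0L)
  i <- 1L
  f <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) abort(sprintf("Expected an atom count at line %d.", i))
    f <- f + 1L
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(vapply(parts, length, 1L) != 4L)) {
      abort(sprintf("Malformed point record in frame %d.", f))
    }
    out[[f]] <- tibble(frame = f,
                       lipid_id = seq_len(n),
                       leaflet = vapply(parts, `[[`, "", 1L),
                       x = as.numeric(vapply(parts, `[[`, "", 2L)),
                       y = as.numeric(vapply(parts, `[[`, "", 3L)),
                       z = as.numeric(vapply(parts, `[[`, "", 4L)))
    i <- i + 2L + n
  }
  if (!length(out)) abort("No frames found.")
  bind_rows(out)
}

#' Write trajectory frames as a multi-MODEL PDB
#'
#' One pseudo-atom per lipid reference point (atom `P`, residue `LIP`),
#' leaflet encoded in the chain identifier (`U` upper / `L` lower / `X`
#' unassigned).
#'
#' @param frames Frame tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_frames_pdb <- function(frames, path) {
  chain_of <- c(upper = "U", lower = "L", unassigned = "X")
  lines <- character(0)
  for (f in sort(unique(frames$frame))) {
    fr <- filter(frames, .data$frame == f)
    atoms <- sprintf(
      "ATOM  %5d  P   LIP %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           P",
      seq_len(nrow(fr)) %% 100000L, chain_of[fr$leaflet],
      seq_len(nrow(fr)) %% 10000L, fr$x, fr$y, fr$z)
    lines <- c(lines, sprintf("MODEL     %4d", f), atoms, "ENDMDL")
  }
  readr::write_lines(c(lines, "END"), path)
  invisible(path)
}

#' Read a multi-MODEL PDB as trajectory frames
#'
#' Parsed with bio3d; every atom is taken as a lipid reference point and the
#' chain identifier maps back to the leaflet tag (`U`/`L`/anything else ->
#' `unassigned`).
#'
#' @param path PDB file.
#' @return Frame tibble (`frame`, `lipid_id`, `leaflet`, `x`, `y`, `z`).
#' @export
read_frames_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  n_atoms <- nrow(pdb$atom)
  n_frames <- nrow(xyz)
  leaflet <- dplyr::recode(pdb$atom$chain, U = "upper", L = "lower",
                           .default = "unassigned")
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    m <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    out[[f]] <- tibble(frame = f, lipid_id = seq_len(n_atoms),
                       leaflet = leaflet, x = m[, 1], y = m[, 2], z = m[, 3])
  }
  bind_rows(out)
}
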