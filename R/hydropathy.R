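# Kyte-Doolittle hydropathy scale.
.kd_scale <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

#' Heuristic TMD detection by sliding-window hydropathy
#'
#' A deliberately simple stand-in predictor: positions whose centred
#' `window`-residue mean Kyte-Doolittle hydropathy reaches `cutoff` are
#' merged into maximal runs, and each run's above-cutoff core is reported as
#' a putative TMD. It is non-authoritative — intended for tests, smoke runs
#' and inputs for which no topology prediction is available — and makes no
#' orientation call (`orientation` is `NA`).
#'
#' @param sequence Single amino-acid sequence (20-letter alphabet).
#' @param window Sliding-window width in residues (odd; default 19).
#' @param cutoff Mean-hydropathy threshold (default 1.6).
#' @return Tibble with the same columns as [extract_tmds()]; empty when the
#'   sequence is shorter than `window`.
#' @export
hydropathy_fallback_tmds <- function(sequence, window = 19L, cutoff = 1.6) {
  stopifnot(length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), names(.kd_scale))
  if (length(bad)) {
    abort(sprintf("Sequence contains non-standard residues: %s",
                  paste(bad, collapse = ", ")))
  }
  empty <- tibble(protein_id = character(0), index = integer(0),
                  start = integer(0), end = integer(0), length = integer(0),
                  orientation = character(0), oriented_seq = character(0))
  L <- length(chars)
  if (L < window) return(empty)
  h <- unname(.kd_scale[chars])
  win_mean <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  half <- window %/% 2L
  centers <- (half + 1L):(L - half)
  above <- !is.na(win_mean) & win_mean >= cutoff
  r <- rle(above[centers])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(empty)
  res <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    s <- centers[starts[keep[j]]]
    e <- centers[ends[keep[j]]]
    res[[j]] <- tibble(protein_id = NA_character_, index = j,
                       start = s, end = e, length = e - s + 1L,
                       orientation = NA_character_,
                       oriented_seq = substr(sequence, s, e))
  }
  bind_rows(res)
}
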