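# Residue alphabets. TMD cores are drawn hydrophobic-heavy (Leu/Ile/Val/Phe
# dominated, as in natural bilayer-spanning helices); linkers polar-heavy so
# that hydropathy-based detection has a realistic contrast to work against.
.tmd_alphabet <- c(L = 0.24, I = 0.16, V = 0.16, F = 0.12, A = 0.12,
                   M = 0.06, W = 0.04, C = 0.04, T = 0.03, G = 0.03)
.linker_alphabet <- c(S = 0.11, T = 0.09, D = 0.09, E = 0.10, K = 0.10,
                      R = 0.08, N = 0.08, Q = 0.08, G = 0.09, P = 0.07,
                      H = 0.04, A = 0.04, Y = 0.03)

.sample_residues <- function(n, alphabet) {
  paste(sample(names(alphabet), n, replace = TRUE, prob = alphabet), collapse = "")
}

#' Specification for a synthetic membrane proteome
#'
#' Bundles the parameters of [generate_proteome()]: how many proteins, what
#' fraction carry transmembrane domains (TMDs), and the samplers governing
#' TMD counts, TMD lengths (residues) and inter-TMD linker lengths.
#'
#' @param n_proteins Number of proteins to generate.
#' @param membrane_fraction Fraction of proteins eligible to carry TMDs; the
#'   remainder are soluble (zero TMDs, single-compartment topology).
#' @param tmd_count_sampler Sampler (see [draw_from()]) over non-negative TMD
#'   counts per membrane protein.
#' @param tmd_length_sampler Sampler over TMD lengths in residues; support
#'   must lie in \[10, 30\].
#' @param linker_length_sampler Sampler over linker lengths (>= 1 residue).
#' @param start_side Side of the membrane where each protein's N-terminus
#'   sits: `"inside"` (cytosolic), `"outside"` (luminal), or `"alternating"`
#'   across proteins.
#' @param seed Integer seed; identical specs and seeds give byte-identical
#'   output.
#' @return A `proteome_spec` list.
#' @export
proteome_spec <- function(n_proteins,
                          membrane_fraction = 1,
                          tmd_count_sampler = 1:12,
                          tmd_length_sampler = 14:26,
                          linker_length_sampler = 5:60,
                          start_side = c("inside", "outside", "alternating"),
                          seed = 1L) {
  stopifnot_scalar_number(n_proteins, "n_proteins", lower = 1)
  stopifnot_scalar_number(membrane_fraction, "membrane_fraction", 0, 1)
  start_side <- match.arg(start_side)
  structure(list(n_proteins = as.integer(n_proteins),
                 membrane_fraction = membrane_fraction,
                 tmd_count_sampler = tmd_count_sampler,
                 tmd_length_sampler = tmd_length_sampler,
                 linker_length_sampler = linker_length_sampler,
                 start_side = start_side,
                 seed = as.integer(seed)),
            class = "proteome_spec")
}

#' Generate a synthetic membrane proteome with known TMD topology
#'
#' Builds protein sequences as alternating polar linkers and hydrophobic TMD
#' stretches, with a matching per-residue topology annotation. TMD intervals
#' are non-overlapping, ordered, and separated by at least one non-TMD
#' residue; membrane sidedness alternates across consecutive TMDs.
#'
#' @param spec A [proteome_spec()].
#' @return A list with elements `sequences` (named character vector of
#'   amino-acid sequences), `topology` (tibble: `protein_id`, `label`,
#'   `start`, `end`), `proteins` (tibble: `protein_id`, `is_membrane`,
#'   `n_tmds`, `length`), and `tmds` (tibble of planted TMD intervals).
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "proteome_spec"))
  with_seed(spec$seed, {
    n <- spec$n_proteins
    ids <- sprintf("SYN%04d", seq_len(n))
    is_mem <- seq_len(n) <= round(spec$membrane_fraction * n)
    start_sides <- switch(spec$start_side,
      inside = rep("inside", n),
      outside = rep("outside", n),
      alternating = rep(c("inside", "outside"), length.out = n))

    seqs <- character(n)
    topo <- vector("list", n)
    tmds <- vector("list", n)
    for (i in seq_len(n)) {
      k <- if (is_mem[i]) draw_from(spec$tmd_count_sampler, 1L) else 0L
      if (k < 0L) abort("tmd_count_sampler produced a negative count.")
      tmd_len <- draw_from(spec$tmd_length_sampler, k)
      if (k > 0L && (any(tmd_len < 10L) || any(tmd_len > 30L))) {
        abort("tmd_length_sampler support must lie within [10, 30] residues.")
      }
      linker_len <- draw_from(spec$linker_length_sampler, k + 1L)
      if (any(linker_len < 1L)) abort("linker_length_sampler must draw lengths >= 1.")
      if (k == 0L) linker_len <- sum(draw_from(spec$linker_length_sampler, 2L))

      pieces <- character(0)
      labels <- tibble(label = character(0), start = integer(0), end = integer(0))
      side <- start_sides[i]
      pos <- 1L
      add_seg <- function(lab, len, piece) {
        labels <<- bind_rows(labels, tibble(label = lab, start = pos,
                                            end = pos + len - 1L))
        pieces <<- c(pieces, piece)
        pos <<- pos + len
      }
      if (k == 0L) {
        add_seg(side, linker_len, .sample_residues(linker_len, .linker_alphabet))
      } else {
        for (j in seq_len(k)) {
          add_seg(side, linker_len[j],
                  .sample_residues(linker_len[j], .linker_alphabet))
          add_seg("TMhelix", tmd_len[j],
                  .sample_residues(tmd_len[j], .tmd_alphabet))
          side <- if (side == "inside") "outside" else "inside"
        }
        add_seg(side, linker_len[k + 1L],
                .sample_residues(linker_len[k + 1L], .linker_alphabet))
      }
      seqs[i] <- paste(pieces, collapse = "")
      if (nchar(seqs[i]) == 0L) abort("Generated a zero-length protein; check samplers.")
      topo[[i]] <- mutate(labels, protein_id = ids[i], .before = 1)
      tm <- filter(labels, .data$label == "TMhelix")
      tmds[[i]] <- if (nrow(tm)) {
        tibble(protein_id = ids[i], index = seq_len(nrow(tm)),
               start = tm$start, end = tm$end,
               length = tm$end - tm$start + 1L)
      } else {
        tibble(protein_id = character(0), index = integer(0),
               start = integer(0), end = integer(0), length = integer(0))
      }
    }
    names(seqs) <- ids
    list(sequences = seqs,
         topology = bind_rows(topo),
         proteins = tibble(protein_id = ids, is_membrane = is_mem,
                           n_tmds = vapply(tmds, nrow, 1L),
                           length = nchar(seqs)),
         tmds = bind_rows(tmds))
  })
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}

#' Read a protein FASTA as a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), names(aa))
}
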