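#' Specification for a synthetic SILAC peptide-ratio experiment
#'
#' Emulates heavy/light peptide ratio tables from a label-swap comparison of
#' two strains across biological replicates: each protein has a true
#' -log2(H/L) shift (0 unless listed in `effect_map`), peptide-level
#' Gaussian noise in log2 space, and uniform-at-random missingness.
#'
#' @param n_proteins Number of proteins.
#' @param n_replicates Biological replicates (default 3).
#' @param effect_map Named numeric vector: protein id -> true -log2(H/L)
#'   shift. Proteins not listed have shift 0.
#' @param peptides_per_protein_sampler Sampler over per-protein distinct
#'   peptide counts (>= 0).
#' @param peptide_noise_sd Peptide-level noise SD in log2 units.
#' @param missingness_rate Fraction of peptide x replicate observations
#'   dropped uniformly at random.
#' @param seed Integer seed.
#' @return A `silac_spec` list.
#' @export
silac_spec <- function(n_proteins,
                       n_replicates = 3L,
                       effect_map = numeric(0),
                       peptides_per_protein_sampler = 2:8,
                       peptide_noise_sd = 0.2,
                       missingness_rate = 0,
                       seed = 1L) {
  stopifnot_scalar_number(n_proteins, "n_proteins", lower = 1)
  stopifnot_scalar_number(n_replicates, "n_replicates", lower = 1)
  stopifnot_scalar_number(peptide_noise_sd, "peptide_noise_sd", lower = 0)
  stopifnot_scalar_number(missingness_rate, "missingness_rate", 0, 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 n_replicates = as.integer(n_replicates),
                 effect_map = effect_map,
                 peptides_per_protein_sampler = peptides_per_protein_sampler,
                 peptide_noise_sd = peptide_noise_sd,
                 missingness_rate = missingness_rate,
                 seed = as.integer(seed)),
            class = "silac_spec")
}

#' Generate a synthetic SILAC peptide ratio table
#'
#' @param spec A [silac_spec()].
#' @return Long tibble: `protein_id`, `replicate`, `peptide_id`, `log2_hl`.
#'   The observed `log2_hl` is `-shift + noise` so that an upregulated
#'   protein (positive -log2(H/L) shift) shows a depressed H/L ratio.
#' @export
generate_silac_table <- function(spec) {
  stopifnot(inherits(spec, "silac_spec"))
  ids <- sprintf("P%04d", seq_len(spec$n_proteins))
  unknown <- setdiff(names(spec$effect_map), ids)
  if (length(unknown)) {
    abort(sprintf("effect_map names not among generated protein ids: %s",
                  paste(unknown, collapse = ", ")))
  }
  shifts <- setNames(rep(0, spec$n_proteins), ids)
  shifts[names(spec$effect_map)] <- spec$effect_map
  with_seed(spec$seed, {
    n_pep <- draw_from(spec$peptides_per_protein_sampler, spec$n_proteins)
    if (any(n_pep < 0L)) abort("peptides_per_protein_sampler drew a negative count.")
    tab <- tidyr::expand_grid(protein_id = ids,
                              replicate = seq_len(spec$n_replicates))
    tab <- tab[rep(seq_len(nrow(tab)), n_pep[match(tab$protein_id, ids)]), ]
    tab <- group_by(tab, .data$protein_id, .data$replicate)
    tab <- ungroup(mutate(tab, peptide_id = sprintf("%s_pep%02d", .data$protein_id,
                                                    seq_len(n()))))
    tab$log2_hl <- -shifts[tab$protein_id] +
      rnorm(nrow(tab), 0, spec$peptide_noise_sd)
    if (spec$missingness_rate > 0) {
      tab <- tab[runif(nrow(tab)) >= spec$missingness_rate, ]
    }
    as_tibble(tab[, c("protein_id", "replicate", "peptide_id", "log2_hl")])
  })
}
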