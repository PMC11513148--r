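#' Specification for a synthetic shotgun lipidome
#'
#' Emulates class-structured lipid species tables: a species catalog (class
#' plus per-chain carbons:double-bonds), baseline mol% per species,
#' multiplicative group effects applied before per-class renormalization,
#' and log-normal replicate noise at a given coefficient of variation.
#'
#' @param species_catalog Tibble with columns `class`, `chain1`, `chain2`
#'   (chains as `"C:D"` strings, `NA` allowed for sum-composition species).
#' @param baseline_molpct Numeric vector (> 0), one value per catalog row.
#' @param group_effects Named list: group -> named numeric vector of
#'   multiplicative factors keyed by `"class chain1/chain2"` species keys
#'   (see [lipid_species_key()]).
#' @param n_replicates_per_group Replicates per group (default 4).
#' @param noise_cv Coefficient of variation of the replicate noise.
#' @param seed Integer seed.
#' @return A `lipidome_spec` list.
#' @export
lipidome_spec <- function(species_catalog, baseline_molpct, group_effects,
                          n_replicates_per_group = 4L, noise_cv = 0.1,
                          seed = 1L) {
  stopifnot(is.data.frame(species_catalog),
            all(c("class", "chain1", "chain2") %in% names(species_catalog)))
  if (length(baseline_molpct) != nrow(species_catalog)) {
    abort("`baseline_molpct` must have one value per catalog species.")
  }
  if (any(baseline_molpct <= 0)) abort("Baseline mol% must be > 0 for all species.")
  stopifnot_scalar_number(noise_cv, "noise_cv", lower = 0)
  keys <- lipid_species_key(species_catalog)
  for (g in names(group_effects)) {
    unknown <- setdiff(names(group_effects[[g]]), keys)
    if (length(unknown)) {
      abort(sprintf("group_effects[['%s']] names unknown species: %s",
                    g, paste(unknown, collapse = ", ")))
    }
  }
  structure(list(species_catalog = as_tibble(species_catalog),
                 baseline_molpct = baseline_molpct,
                 group_effects = group_effects,
                 n_replicates_per_group = as.integer(n_replicates_per_group),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "lipidome_spec")
}

#' Canonical species key `"CLASS chain1/chain2"`
#'
#' @param species Tibble with `class`, `chain1`, `chain2`.
#' @return Character vector of keys, e.g. `"PI 10:0/16:0"`.
#' @export
lipid_species_key <- function(species) {
  paste0(species$class, " ",
         ifelse(is.na(species$chain1), "?", species$chain1), "/",
         ifelse(is.na(species$chain2), "?", species$chain2))
}

#' Generate a synthetic lipidome table
#'
#' Applies group effects to the baseline, multiplies in log-normal noise per
#' replicate, then renormalizes within each (sample, class) to mol%/class.
#'
#' @param spec A [lipidome_spec()].
#' @return Tibble: `class`, `chain1`, `chain2`, `sample`, `group`,
#'   `mol_percent` (summing to 100 within each sample x class).
#' @export
generate_lipidome <- function(spec) {
  stopifnot(inherits(spec, "lipidome_spec"))
  cat_tbl <- spec$species_catalog
  keys <- lipid_species_key(cat_tbl)
  groups <- names(spec$group_effects)
  if (is.null(groups) || !length(groups)) abort("At least one group is required.")
  with_seed(spec$seed, {
    out <- vector("list", 0L)
    for (g in groups) {
      eff <- setNames(rep(1, nrow(cat_tbl)), keys)
      ge <- spec$group_effects[[g]]
      eff[names(ge)] <- ge
      for (r in seq_len(spec$n_replicates_per_group)) {
        noise <- if (spec$noise_cv > 0) {
          sdlog <- sqrt(log(1 + spec$noise_cv^2))
          exp(rnorm(nrow(cat_tbl), -sdlog^2 / 2, sdlog))
        } else rep(1, nrow(cat_tbl))
        val <- unname(spec$baseline_molpct * eff * noise)
        smp <- mutate(cat_tbl,
                      sample = sprintf("%s_rep%d", g, r), group = g,
                      mol_percent = val)
        out <- c(out, list(smp))
      }
    }
    normalize_per_class(bind_rows(out))
  })
}
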