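#' Parse acyl-chain descriptors
#'
#' @param chain Character vector of `"carbons:double_bonds"` descriptors
#'   (e.g. `"10:0"`); `NA` or empty strings give `NA` components.
#' @return Tibble with columns `carbons`, `double_bonds`.
#' @export
parse_chain <- function(chain) {
  chain[!is.na(chain) & !nzchar(trimws(chain))] <- NA_character_
  parts <- strsplit(as.character(chain), ":", fixed = TRUE)
  bad <- !is.na(chain) & vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    abort(sprintf("Malformed chain descriptor(s): %s (expected 'C:D').",
                  paste(unique(chain[bad]), collapse = ", ")))
  }
  tibble(carbons = as.integer(vapply(parts, function(x)
           if (length(x) == 2L) x[1] else NA_character_, "")),
         double_bonds = as.integer(vapply(parts, function(x)
           if (length(x) == 2L) x[2] else NA_character_, "")))
}

#' Normalize lipid abundances to mol% of class
#'
#' Within each (sample, class) the values are rescaled to sum to 100 — the
#' mol%/class convention. Idempotent.
#'
#' @param table Tibble with at least `class`, `sample`, `mol_percent`.
#' @return The table with `mol_percent` renormalized.
#' @export
normalize_per_class <- function(table) {
  if (any(table$mol_percent < 0)) abort("Negative mol% values in input.")
  tot <- summarise(group_by(table, .data$sample, .data$class),
                   total = sum(.data$mol_percent), .groups = "drop")
  zero <- filter(tot, .data$total == 0)
  if (nrow(zero)) {
    abort(sprintf("Class total is zero for sample '%s', class '%s'.",
                  zero$sample[1], zero$class[1]))
  }
  ungroup(mutate(group_by(table, .data$sample, .data$class),
                 mol_percent = 100 * .data$mol_percent / sum(.data$mol_percent)))
}

#' Total acyl-carbon label for a lipid species
#'
#' @param chain1,chain2 Chain descriptors (`"C:D"`), possibly `NA`.
#' @param total_carbons Optional known total when chains are unknown.
#' @return Character labels like `"C-26"`, or `NA` when nothing is known.
#' @export
total_acyl_label <- function(chain1, chain2, total_carbons = NULL) {
  c1 <- parse_chain(chain1)
  c2 <- parse_chain(chain2)
  if (any(stats::na.omit(c(c1$carbons, c2$carbons)) <= 0)) {
    abort("Zero-carbon acyl chains are not a valid species.")
  }
  total <- c1$carbons + c2$carbons
  if (!is.null(total_carbons)) total[is.na(total)] <- total_carbons[is.na(total)]
  ifelse(is.na(total), NA_character_, sprintf("C-%d", total))
}

#' Classify acyl-chain asymmetry and saturation
#'
#' A species is called asymmetric when its two chains differ in length by at
#' least `delta_min` carbons (default 6, covering 10:0/16:0 and 10:0/18:0-1
#' style pairings while excluding common 16/18 combinations). The
#' saturation profile distinguishes species with two saturated chains from
#' those whose long chain carries a single double bond. Species with a
#' missing chain are `unknown` throughout. Symmetric under chain swap.
#'
#' @param chain1,chain2 Chain descriptors (`"C:D"`), possibly `NA`.
#' @param delta_min Minimum carbon difference for an asymmetric call.
#' @return Tibble: `delta_carbons`, `call` (`asymmetric` / `symmetric` /
#'   `unknown`), `saturation_profile` (`both_saturated` /
#'   `long_chain_monounsaturated` / `other` / `unknown`).
#' @export
classify_asymmetry <- function(chain1, chain2, delta_min = 6L) {
  c1 <- parse_chain(chain1)
  c2 <- parse_chain(chain2)
  delta <- abs(c1$carbons - c2$carbons)
  known <- !is.na(c1$carbons) & !is.na(c2$carbons)
  long_db <- ifelse(c1$carbons >= c2$carbons, c1$double_bonds, c2$double_bonds)
  short_db <- ifelse(c1$carbons >= c2$carbons, c2$double_bonds, c1$double_bonds)
  tibble(
    delta_carbons = ifelse(known, delta, NA_integer_),
    call = case_when(!known ~ "unknown",
                     delta >= delta_min ~ "asymmetric",
                     TRUE ~ "symmetric"),
    saturation_profile = case_when(
      !known ~ "unknown",
      c1$double_bonds == 0L & c2$double_bonds == 0L ~ "both_saturated",
      long_db == 1L & short_db == 0L ~ "long_chain_monounsaturated",
      TRUE ~ "other"))
}

#' Per-species group comparison with two-stage FDR
#'
#' For each species, an unpaired two-sample t-test with pooled variance
#' (equal variances assumed, i.e. not Welch) between the two groups, then
#' discovery flags from the two-stage Benjamini-Krieger-Yekutieli step-up
#' at rate `q` applied within each statistical family. The family defaults
#' to one lipid class's species set (mirroring per-class panels); set
#' `family = "global"` to correct across all species at once. Species that
#' are constant in both groups get p = 1 with a warning.
#'
#' @param table Lipid table (`class`, `chain1`, `chain2`, `sample`, `group`,
#'   `mol_percent`), typically from [normalize_per_class()].
#' @param groups Length-2 character vector: the two group labels to compare
#'   (difference reported as first minus second).
#' @param q Target FDR (default 0.01).
#' @param family `"class"` or `"global"`.
#' @return Tibble per species: group means and SDs, `t_statistic`,
#'   `p_value`, `discovery`.
#' @export
compare_groups <- function(table, groups, q = 0.01,
                           family = c("class", "global")) {
  family <- match.arg(family)
  stopifnot(length(groups) == 2L)
  tab <- filter(table, .data$group %in% groups)
  if (!nrow(tab)) abort("Neither group is present in the table.")
  per_species <- summarise(
    group_by(tab, .data$class, .data$chain1, .data$chain2),
    n_1 = sum(.data$group == groups[1]),
    n_2 = sum(.data$group == groups[2]),
    mean_1 = mean(.data$mol_percent[.data$group == groups[1]]),
    mean_2 = mean(.data$mol_percent[.data$group == groups[2]]),
    sd_1 = sd(.data$mol_percent[.data$group == groups[1]]),
    sd_2 = sd(.data$mol_percent[.data$group == groups[2]]),
    values = list(list(a = .data$mol_percent[.data$group == groups[1]],
                       b = .data$mol_percent[.data$group == groups[2]])),
    .groups = "drop")
  if (any(per_species$n_1 < 2L | per_species$n_2 < 2L)) {
    abort("Every species needs >= 2 replicates in each group.")
  }
  tp <- lapply(per_species$values, function(v) {
    if (sd(c(v$a, v$b)) == 0) return(list(t = 0, p = 1, constant = TRUE))
    tt <- t.test(v$a, v$b, var.equal = TRUE)
    list(t = unname(tt$statistic), p = tt$p.value, constant = FALSE)
  })
  if (any(vapply(tp, `[[`, TRUE, "constant"))) {
    warn("Species constant in both groups; assigned p = 1.")
  }
  per_species$t_statistic <- vapply(tp, `[[`, 0, "t")
  per_species$p_value <- pmax(vapply(tp, `[[`, 0, "p"), .Machine$double.xmin)
  per_species$values <- NULL
  per_species$discovery <- if (family == "global") {
    as.logical(two_stage_bky(per_species$p_value, q))
  } else {
    flags <- logical(nrow(per_species))
    for (cl in unique(per_species$class)) {
      i <- per_species$class == cl
      flags[i] <- as.logical(two_stage_bky(per_species$p_value[i], q))
    }
    flags
  }
  rename(per_species,
         !!paste0("mean_", groups[1]) := "mean_1",
         !!paste0("mean_", groups[2]) := "mean_2",
         !!paste0("sd_", groups[1]) := "sd_1",
         !!paste0("sd_", groups[2]) := "sd_2",
         !!paste0("n_", groups[1]) := "n_1",
         !!paste0("n_", groups[2]) := "n_2")
}
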