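#' Aggregate peptide-level H/L ratios to protein-level quantifications
#'
#' Reduces a long peptide table to one log2(H/L) value per protein and
#' replicate (median by default; the median resists single aberrant
#' peptides), and records the evidence behind each protein: peptide counts
#' per replicate, distinct peptides overall, and the number of replicates
#' with any quantification.
#'
#' @param records Tibble with columns `protein_id`, `replicate`,
#'   `peptide_id`, `log2_hl`.
#' @param method `"median"` (default) or `"mean"`.
#' @return Tibble with one row per protein x quantified replicate:
#'   `protein_id`, `replicate`, `log2_hl`, `n_peptides`,
#'   `n_distinct_peptides`, `n_replicates_quantified`.
#' @export
aggregate_peptides <- function(records, method = c("median", "mean")) {
  method <- match.arg(method)
  if (!nrow(records)) {
    return(tibble(protein_id = character(0), replicate = integer(0),
                  log2_hl = numeric(0), n_peptides = integer(0),
                  n_distinct_peptides = integer(0),
                  n_replicates_quantified = integer(0)))
  }
  if (any(!is.finite(records$log2_hl))) abort("Non-finite log2 H/L ratios in input.")
  agg_fun <- if (method == "median") median else mean
  per_rep <- summarise(group_by(records, .data$protein_id, .data$replicate),
                       log2_hl = agg_fun(.data$log2_hl),
                       n_peptides = n(), .groups = "drop")
  evidence <- summarise(group_by(records, .data$protein_id),
                        n_distinct_peptides = n_distinct(.data$peptide_id),
                        .groups = "drop")
  per_rep <- left_join(per_rep, evidence, by = "protein_id")
  per_rep <- mutate(group_by(per_rep, .data$protein_id),
                    n_replicates_quantified = n())
  ungroup(per_rep)
}

#' Filter proteins by quantification evidence
#'
#' Retains proteins with at least `min_peptides` distinct H/L peptides that
#' were quantified in at least `min_replicates` of the biological
#' replicates.
#'
#' @param quants Output of [aggregate_peptides()].
#' @param min_peptides Minimum distinct peptides per protein (default 2).
#' @param min_replicates Minimum replicates with quantification (default 2).
#' @return Filtered tibble of the same shape.
#' @export
filter_quantified <- function(quants, min_peptides = 2L, min_replicates = 2L) {
  if (min_peptides < 1L || min_replicates < 1L) abort("Thresholds must be >= 1.")
  filter(quants,
         .data$n_distinct_peptides >= min_peptides,
         .data$n_replicates_quantified >= min_replicates)
}

#' Background-based t-test for one protein against the unregulated bulk
#'
#' Tests whether a protein's replicate-level log2 ratios deviate from the
#' background (all quantified proteins' replicate-level values), which
#' under a label-swap design estimates the unregulated expectation. The
#' statistic is a one-sample t of the target mean against the background
#' mean with df = n_target - 1. Under the default `"pooled"` policy the
#' scale is the larger of the target and background standard deviations — a
#' deliberately conservative guard against understated per-protein
#' variance; `"target_only"` uses the target SD alone (the calibrated
#' one-sample t).
#'
#' @param target Numeric vector of the protein's per-replicate log2 values
#'   (>= 2 values).
#' @param background Numeric vector of background values (>= 30 values).
#' @param policy `"pooled"` (max of the two SDs) or `"target_only"`.
#' @return Two-sided p-value in (0, 1].
#' @export
background_t_test <- function(target, background,
                              policy = c("pooled", "target_only")) {
  policy <- match.arg(policy)
  if (length(target) < 2L) abort("Need >= 2 target replicate values.")
  if (length(background) < 30L) abort("Need >= 30 background values.")
  v_bg <- var(background)
  if (v_bg == 0) abort("Degenerate background: zero variance.")
  n <- length(target)
  v <- switch(policy,
              pooled = max(var(target), v_bg),
              target_only = var(target))
  if (v == 0) return(if (mean(target) == mean(background)) 1 else .Machine$double.xmin)
  t_stat <- (mean(target) - mean(background)) / sqrt(v / n)
  max(2 * pt(-abs(t_stat), df = n - 1L), .Machine$double.xmin)
}

#' Flag significantly regulated proteins
#'
#' Applies the printed significance rule — mean -log2(H/L) at or above
#' `ratio_min` and raw p at or below `p_max`, both boundaries inclusive —
#' and joins the membrane annotation. BH-adjusted p-values are reported
#' alongside but the flag follows the raw p, as the rule states.
#'
#' @param stats Tibble with `protein_id`, `neg_log2`, `p_value`.
#' @param membrane_ids Character vector of membrane-protein identifiers.
#' @param ratio_min Minimum mean -log2(H/L) (default 0.3).
#' @param p_max Maximum raw p (default 0.05).
#' @return Tibble adding `adj_p`, `significant`, `is_membrane`.
#' @export
call_significant <- function(stats, membrane_ids = character(0),
                             ratio_min = 0.3, p_max = 0.05) {
  out <- mutate(stats,
                adj_p = adjust_bh(.data$p_value),
                significant = .data$neg_log2 >= ratio_min & .data$p_value <= p_max,
                is_membrane = .data$protein_id %in% membrane_ids)
  if (length(membrane_ids) && !any(out$is_membrane)) {
    warn("No quantified protein matched the membrane annotation; all `is_membrane` set FALSE.")
  }
  out
}

#' Run one SILAC contrast end to end
#'
#' Convenience wrapper: aggregate peptides, apply the evidence filter,
#' compute per-protein mean -log2(H/L), test each protein against the
#' background of all quantified proteins, adjust, and flag.
#'
#' @param records Peptide table (`protein_id`, `replicate`, `peptide_id`,
#'   `log2_hl`).
#' @param membrane_ids Membrane-protein identifiers.
#' @param min_peptides,min_replicates Evidence filter thresholds.
#' @param ratio_min,p_max Significance thresholds.
#' @param aggregate `"median"` or `"mean"` peptide reduction.
#' @param background_policy Passed to [background_t_test()].
#' @return Volcano-style tibble: `protein_id`, `neg_log2`,
#'   `n_replicates_quantified`, `n_distinct_peptides`, `p_value`, `adj_p`,
#'   `significant`, `is_membrane`.
#' @export
run_silac_contrast <- function(records, membrane_ids = character(0),
                               min_peptides = 2L, min_replicates = 2L,
                               ratio_min = 0.3, p_max = 0.05,
                               aggregate = c("median", "mean"),
                               background_policy = c("pooled", "target_only")) {
  aggregate <- match.arg(aggregate)
  background_policy <- match.arg(background_policy)
  quants <- filter_quantified(aggregate_peptides(records, aggregate),
                              min_peptides, min_replicates)
  if (!nrow(quants)) abort("No protein passed the quantification filter.")
  background <- -quants$log2_hl
  per_prot <- summarise(group_by(quants, .data$protein_id),
                        neg_log2 = mean(-.data$log2_hl),
                        n_replicates_quantified = .data$n_replicates_quantified[1],
                        n_distinct_peptides = .data$n_distinct_peptides[1],
                        values = list(-.data$log2_hl), .groups = "drop")
  per_prot$p_value <- vapply(per_prot$values, background_t_test, 0,
                             background = background, policy = background_policy)
  per_prot$values <- NULL
  call_significant(per_prot, membrane_ids, ratio_min, p_max)
}

#' Classify the overlap between two contrasts
#'
#' Intersects the proteins quantified in both contrasts (membrane proteins
#' by default) and assigns each to `both`, `a_only`, `b_only`, or `neither`
#' by its significance flags. The `-log2 > display_floor` rule affects only
#' the emitted scatter table (`display` attribute), never the
#' classification.
#'
#' @param res_a,res_b Results from [run_silac_contrast()].
#' @param display_floor Scatter display floor on -log2 (default -1).
#' @param membrane_only Restrict to proteins annotated as membrane in both
#'   contrasts (default TRUE).
#' @return Tibble `protein_id`, `neg_log2_a`, `neg_log2_b`, `class`, with a
#'   `display` attribute holding the floored scatter table.
#' @export
overlap_contrasts <- function(res_a, res_b, display_floor = -1,
                              membrane_only = TRUE) {
  shared <- dplyr::inner_join(
    select(res_a, "protein_id", neg_log2_a = "neg_log2",
           sig_a = "significant", mem_a = "is_membrane"),
    select(res_b, "protein_id", neg_log2_b = "neg_log2",
           sig_b = "significant", mem_b = "is_membrane"),
    by = "protein_id")
  if (membrane_only) shared <- filter(shared, .data$mem_a & .data$mem_b)
  if (!nrow(shared)) abort("No shared quantified proteins between the two contrasts.")
  out <- mutate(shared,
                class = case_when(.data$sig_a & .data$sig_b ~ "both",
                                  .data$sig_a ~ "a_only",
                                  .data$sig_b ~ "b_only",
                                  TRUE ~ "neither"))
  out <- select(out, "protein_id", "neg_log2_a", "neg_log2_b", "class")
  attr(out, "display") <- filter(out, .data$neg_log2_a > display_floor,
                                 .data$neg_log2_b > display_floor)
  out
}

#' GO-component frequency and enrichment table for a protein set
#'
#' Tallies slim component terms over a protein set, optionally fusing terms
#' first (e.g. reassigning generic vesicle hits to plasma membrane or
#' endosome on a per-protein basis), removes terms with a single hit, and
#' reports dataset frequency, genome frequency and their ratio (enrichment
#' over genome).
#'
#' @param protein_set Character vector of protein identifiers.
#' @param slim_map Tibble `protein_id`, `term` for the dataset annotation.
#' @param genome_map Tibble `protein_id`, `term` for the genome background.
#' @param fusion_rules Optional tibble `protein_id`, `term`, `new_term`;
#'   matching (protein, term) annotations are relabelled before counting.
#'   Rules that match nothing trigger a warning, not an error.
#' @param min_hits Minimum dataset hits for a term to be emitted (default 2).
#' @return Tibble `term`, `dataset_hits`, `dataset_frequency`,
#'   `genome_frequency`, `enrichment`, sorted by hits.
#' @export
go_component_frequency <- function(protein_set, slim_map, genome_map,
                                   fusion_rules = NULL, min_hits = 2L) {
  if (!nrow(slim_map) || !nrow(genome_map)) abort("GO maps must be non-empty.")
  any_rule_used <- FALSE
  apply_fusion <- function(map) {
    if (is.null(fusion_rules) || !nrow(fusion_rules)) return(map)
    key <- paste(map$protein_id, map$term, sep = "\r")
    rkey <- paste(fusion_rules$protein_id, fusion_rules$term, sep = "\r")
    hit <- match(key, rkey)
    if (any(!is.na(hit))) any_rule_used <<- TRUE
    map$term[!is.na(hit)] <- fusion_rules$new_term[hit[!is.na(hit)]]
    map
  }
  slim_map <- apply_fusion(distinct(slim_map))
  genome_map <- apply_fusion(distinct(genome_map))
  if (!is.null(fusion_rules) && nrow(fusion_rules) && !any_rule_used) {
    warn("No fusion rule matched any annotation.")
  }
  in_set <- distinct(filter(slim_map, .data$protein_id %in% protein_set))
  n_set <- length(unique(protein_set))
  n_genome <- n_distinct(genome_map$protein_id)
  counts <- summarise(group_by(in_set, .data$term),
                      dataset_hits = n_distinct(.data$protein_id), .groups = "drop")
  genome_counts <- summarise(group_by(genome_map, .data$term),
                             genome_hits = n_distinct(.data$protein_id),
                             .groups = "drop")
  out <- left_join(counts, genome_counts, by = "term")
  out <- mutate(out,
                dataset_frequency = .data$dataset_hits / n_set,
                genome_frequency = .data$genome_hits / n_genome,
                enrichment = .data$dataset_frequency / .data$genome_frequency)
  out <- filter(out, .data$dataset_hits >= min_hits)
  arrange(select(out, "term", "dataset_hits", "dataset_frequency",
                 "genome_frequency", "enrichment"),
          dplyr::desc(.data$dataset_hits))
}
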