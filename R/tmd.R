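#' Extract oriented transmembrane domains from a topology annotation
#'
#' One segment is emitted per predicted membrane helix. Orientation follows
#' the flanking compartment labels: a TMD preceded by a cytosolic (`inside`)
#' segment runs in-to-out; one preceded by a luminal (`outside`) or signal
#' segment runs out-to-in. The `oriented_seq` is always written from the
#' cytosolic side to the luminal side, i.e. it is reversed for out-to-in
#' helices, so that TMDs from proteins of either polarity can be aligned.
#'
#' @param topology Annotation tibble as returned by [parse_topology()].
#' @param sequences Named character vector of protein sequences (optional;
#'   without it `oriented_seq` is `NA`).
#' @return Tibble: `protein_id`, `index`, `start`, `end`, `length`,
#'   `orientation` (`"in_out"` / `"out_in"`), `oriented_seq`.
#' @export
extract_tmds <- function(topology, sequences = NULL) {
  if (is.null(sequences)) sequences <- attr(topology, "sequences")
  lens <- attr(topology, "seq_length")
  if (!is.null(sequences) && !is.null(lens)) {
    known <- intersect(names(sequences), names(lens))
    bad <- known[nchar(sequences[known]) != lens[known]]
    if (length(bad)) {
      abort(sprintf("Sequence length mismatch with annotation for: %s",
                    paste(bad, collapse = ", ")))
    }
  }
  out <- vector("list", 0L)
  for (id in unique(topology$protein_id)) {
    seg <- arrange(filter(topology, .data$protein_id == id), .data$start)
    tm_idx <- which(seg$label == "TMhelix")
    if (!length(tm_idx)) next
    rows <- vector("list", length(tm_idx))
    for (j in seq_along(tm_idx)) {
      i <- tm_idx[j]
      prev_lab <- if (i > 1L) seg$label[i - 1L] else NA_character_
      next_lab <- if (i < nrow(seg)) seg$label[i + 1L] else NA_character_
      orientation <- if (!is.na(prev_lab)) {
        if (prev_lab == "inside") "in_out" else "out_in"
      } else if (!is.na(next_lab)) {
        # helix at the N-terminus: infer from where it ends up
        if (next_lab == "inside") "out_in" else "in_out"
      } else {
        abort(sprintf("Protein %s: membrane helix with no flanking segment.", id))
      }
      oseq <- NA_character_
      if (!is.null(sequences) && !is.na(sequences[id])) {
        oseq <- substr(sequences[[id]], seg$start[i], seg$end[i])
        if (orientation == "out_in") oseq <- reverse_residues(oseq)
      }
      rows[[j]] <- tibble(protein_id = id, index = j,
                          start = seg$start[i], end = seg$end[i],
                          length = seg$end[i] - seg$start[i] + 1L,
                          orientation = orientation, oriented_seq = oseq)
    }
    out <- c(out, rows)
  }
  if (!length(out)) {
    return(tibble(protein_id = character(0), index = integer(0),
                  start = integer(0), end = integer(0), length = integer(0),
                  orientation = character(0), oriented_seq = character(0)))
  }
  bind_rows(out)
}

#' @rdname extract_tmds
#' @param x A string.
#' @export
reverse_residues <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")
}

#' Hydrophobic-length signature of a transmembrane-protein set
#'
#' Summarizes a set of proteins' TMDs the way substrate sets are compared:
#' the distribution of TMD lengths (median and quartiles), the per-protein
#' shortest TMD, per-protein TMD counts, and the headline fractions — the
#' fraction of TMDs at or below each length threshold, the fraction of
#' proteins whose shortest TMD is at or below each threshold, and the
#' fraction of proteins with at most / more than `count_threshold` TMDs.
#' Proteins with zero predicted TMDs are tallied separately (via
#' `all_protein_ids`) and excluded from the length statistics.
#'
#' @param tmds TMD tibble from [extract_tmds()] (needs `protein_id`, `length`).
#' @param l_thresholds Length thresholds in residues (default 16 and 18).
#' @param count_threshold TMD-count threshold K (default 10).
#' @param all_protein_ids Optional character vector of the full submitted set,
#'   used to report proteins for which no TMD was predicted.
#' @return A `tmd_signature` object (list) with fields `n_tmds`, `n_proteins`,
#'   `n_proteins_no_tmd`, `lengths`, `median`, `q1`, `q3`, `shortest_per_protein`,
#'   `count_per_protein`, `frac_tmds_le`, `frac_proteins_shortest_le`,
#'   `frac_proteins_count_le`, `frac_proteins_count_gt`.
#' @export
signature_stats <- function(tmds, l_thresholds = c(16L, 18L),
                            count_threshold = 10L, all_protein_ids = NULL) {
  if (!nrow(tmds)) abort("No TMDs supplied; cannot compute a signature.")
  lengths <- tmds$length
  per_prot <- summarise(group_by(tmds, .data$protein_id),
                        shortest = min(.data$length), n_tmds = n(),
                        .groups = "drop")
  qs <- quantile(lengths, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  frac_le <- vapply(l_thresholds, function(L) mean(lengths <= L), 0)
  frac_shortest_le <- vapply(l_thresholds, function(L) mean(per_prot$shortest <= L), 0)
  n_no_tmd <- if (is.null(all_protein_ids)) 0L else
    length(setdiff(all_protein_ids, per_prot$protein_id))
  structure(list(
    n_tmds = length(lengths),
    n_proteins = nrow(per_prot),
    n_proteins_no_tmd = n_no_tmd,
    lengths = lengths,
    median = qs[2], q1 = qs[1], q3 = qs[3],
    shortest_per_protein = setNames(per_prot$shortest, per_prot$protein_id),
    count_per_protein = setNames(per_prot$n_tmds, per_prot$protein_id),
    l_thresholds = l_thresholds,
    count_threshold = count_threshold,
    frac_tmds_le = setNames(frac_le, paste0("le_", l_thresholds)),
    frac_proteins_shortest_le = setNames(frac_shortest_le, paste0("le_", l_thresholds)),
    frac_proteins_count_le = mean(per_prot$n_tmds <= count_threshold),
    frac_proteins_count_gt = mean(per_prot$n_tmds > count_threshold)
  ), class = "tmd_signature")
}

#' @export
print.tmd_signature <- function(x, ...) {
  cat(sprintf("TMD signature: %d TMDs across %d proteins (%d proteins without TMDs)\n",
              x$n_tmds, x$n_proteins, x$n_proteins_no_tmd))
  cat(sprintf("  length median [Q1, Q3]: %.1f [%.1f, %.1f] residues\n",
              x$median, x$q1, x$q3))
  for (i in seq_along(x$l_thresholds)) {
    L <- x$l_thresholds[i]
    cat(sprintf("  TMDs with length <= %d: %.0f%%; proteins with shortest TMD <= %d: %.0f%%\n",
                L, 100 * x$frac_tmds_le[i], L, 100 * x$frac_proteins_shortest_le[i]))
  }
  cat(sprintf("  proteins with > %d TMDs: %.0f%%\n",
              x$count_threshold, 100 * x$frac_proteins_count_gt))
  invisible(x)
}

#' Compare two TMD signatures
#'
#' Reports per-statistic differences (A minus B) together with a Wilcoxon
#' rank-sum test on the raw length distributions. The rank-sum test is a
#' convenience extension for synthetic benchmarking, not a statistic the
#' signature itself defines.
#'
#' @param sig_a,sig_b `tmd_signature` objects.
#' @return List with `delta_median`, `delta_q1`, `delta_q3`,
#'   `delta_frac_tmds_le`, `delta_frac_proteins_shortest_le`,
#'   `delta_frac_proteins_count_gt`, and `length_rank_sum_p`.
#' @export
compare_signatures <- function(sig_a, sig_b) {
  stopifnot(inherits(sig_a, "tmd_signature"), inherits(sig_b, "tmd_signature"))
  p <- if (identical(sig_a$lengths, sig_b$lengths)) 1 else
    suppressWarnings(wilcox.test(sig_a$lengths, sig_b$lengths)$p.value)
  list(delta_median = unname(sig_a$median - sig_b$median),
       delta_q1 = unname(sig_a$q1 - sig_b$q1),
       delta_q3 = unname(sig_a$q3 - sig_b$q3),
       delta_frac_tmds_le = sig_a$frac_tmds_le - sig_b$frac_tmds_le,
       delta_frac_proteins_shortest_le =
         sig_a$frac_proteins_shortest_le - sig_b$frac_proteins_shortest_le,
       delta_frac_proteins_count_gt =
         sig_a$frac_proteins_count_gt - sig_b$frac_proteins_count_gt,
       length_rank_sum_p = p)
}

#' Added helical rise from extending a TMD
#'
#' An ideal alpha-helix rises ~1.5 angstrom per residue along its axis, so
#' extending a TMD's hydrophobic stretch by n residues adds n x 1.5 angstrom
#' of spanning length (e.g. +3 residues -> 4.5 angstrom, +6 -> 9 angstrom).
#'
#' @param n_residues Number of residues added (>= 0).
#' @param rise_per_residue Helical rise per residue in angstrom.
#' @return Added rise in angstrom.
#' @export
helix_extension_rise <- function(n_residues, rise_per_residue = 1.5) {
  if (any(n_residues < 0)) abort("`n_residues` must be non-negative.")
  n_residues * rise_per_residue
}
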