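make_records <- function(protein_id, replicate, log2_hl, peptide_id = NULL) {
  tibble::tibble(protein_id = protein_id, replicate = replicate,
                 peptide_id = peptide_id %||%
                   paste0(protein_id, "_", seq_along(protein_id)),
                 log2_hl = log2_hl)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("peptide aggregation takes the per-replicate median with counts", {
  r <- make_records(rep("A", 3), rep(1L, 3), c(0, 0, 0))
  q <- aggregate_peptides(r)
  expect_equal(q$log2_hl, 0)
  expect_equal(q$n_peptides, 3L)

  r2 <- make_records(rep("A", 3), rep(1L, 3), c(-1.0, -1.2, -0.8))
  expect_equal(aggregate_peptides(r2)$log2_hl, -1.0)

  # 50 random peptides against the sort-and-pick oracle
  set.seed(11)
  vals <- rnorm(50)
  r3 <- make_records(rep("A", 50), rep(1L, 50), vals)
  expect_equal(aggregate_peptides(r3)$log2_hl, oracle_median(vals))
  expect_equal(aggregate_peptides(r3, method = "mean")$log2_hl, mean(vals))
})

test_that("quantification filter enforces peptide and replicate evidence", {
  # protein with peptides only in replicate 1 is dropped
  r <- make_records(rep("A", 3), rep(1L, 3), rnorm(3))
  expect_equal(nrow(filter_quantified(aggregate_peptides(r))), 0L)

  # 2 peptides in each of 2 replicates: the boundary case is kept
  r2 <- make_records(rep("B", 4), c(1L, 1L, 2L, 2L), rnorm(4),
                     peptide_id = c("p1", "p2", "p1", "p2"))
  expect_equal(nrow(filter_quantified(aggregate_peptides(r2))), 2L)

  # random table against a brute-force reimplementation of the rule
  set.seed(12)
  big <- tibble::tibble(
    protein_id = sample(sprintf("P%02d", 1:30), 300, replace = TRUE),
    replicate = sample(1:3, 300, replace = TRUE),
    peptide_id = sample(sprintf("pep%02d", 1:5), 300, replace = TRUE),
    log2_hl = rnorm(300))
  big <- dplyr::distinct(big, protein_id, replicate, peptide_id, .keep_all = TRUE)
  kept <- unique(filter_quantified(aggregate_peptides(big))$protein_id)
  brute <- Filter(function(id) {
    sub <- big[big$protein_id == id, ]
    length(unique(sub$peptide_id)) >= 2 && length(unique(sub$replicate)) >= 2
  }, unique(big$protein_id))
  expect_setequal(kept, brute)
})

test_that("background t-test matches its closed form and degenerate cases", {
  set.seed(13)
  bg <- rnorm(500, 0, 0.3)
  # target centered on the background mean: t = 0, p = 1
  tgt <- mean(bg) + c(-0.2, 0, 0.2)
  v <- max(var(tgt), var(bg))
  expect_equal(background_t_test(tgt, bg),
               2 * pt(-abs((mean(tgt) - mean(bg)) / sqrt(v / 3)), df = 2))
  expect_equal(background_t_test(c(mean(bg), mean(bg)), bg, "target_only"), 1)

  # strongly shifted, zero-variance target
  bg2 <- rnorm(100, 0, 0.1)
  expect_lt(background_t_test(c(-1, -1, -1), bg2, "target_only"), 0.001)
  # under the max-variance policy the scale falls back to the background SD
  expect_equal(background_t_test(c(-1, -1, -1), bg2, "pooled"),
               2 * pt(-abs((-1 - mean(bg2)) / sqrt(var(bg2) / 3)), df = 2))

  expect_error(background_t_test(c(0, 1), rep(0.5, 50)), "variance")
  expect_error(background_t_test(1, bg), ">= 2")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  set.seed(14)
  p <- runif(100)
  expect_equal(adjust_bh(p), oracle_bh(p))
  expect_true(all(adjust_bh(p) >= p))
  expect_error(adjust_bh(c(0.1, NaN)), "NaN")
  expect_error(adjust_bh(c(0.1, 0)), "0, 1")
})

test_that("significance calling applies inclusive thresholds and membrane join", {
  stats <- tibble::tibble(protein_id = c("A", "B", "C"),
                          neg_log2 = c(0.29, 0.30, 2.0),
                          p_value = c(0.01, 0.05, 0.2))
  res <- call_significant(stats, membrane_ids = c("A", "B"))
  expect_equal(res$significant, c(FALSE, TRUE, FALSE))
  expect_equal(res$is_membrane, c(TRUE, TRUE, FALSE))
  expect_true(all(res$adj_p >= res$p_value))
})

test_that("significance calling is monotone in effect size at fixed p", {
  p_fix <- 0.01
  effects <- seq(-1, 2, by = 0.1)
  flags <- vapply(effects, function(e) {
    call_significant(tibble::tibble(protein_id = "X", neg_log2 = e,
                                    p_value = p_fix))$significant
  }, TRUE)
  expect_true(all(diff(flags) >= 0))  # once flagged, stays flagged
})

test_that("planted effects are recovered exactly at favourable noise", {
  planted <- c(P0003 = 1.2, P0010 = 1.0, P0017 = 1.5)
  tab <- generate_silac_table(silac_spec(60, effect_map = planted,
                                         peptide_noise_sd = 0.1,
                                         peptides_per_protein_sampler = 5,
                                         seed = 15))
  res <- run_silac_contrast(tab, membrane_ids = sprintf("P%04d", 1:60))
  expect_setequal(res$protein_id[res$significant], names(planted))
})

test_that("full-chain type-I error is calibrated (and conservative when pooled)", {
  tab <- generate_silac_table(silac_spec(2000, peptide_noise_sd = 0.2,
                                         peptides_per_protein_sampler = 4,
                                         seed = 16))
  res_cal <- run_silac_contrast(tab, aggregate = "mean",
                                background_policy = "target_only")
  expect_lt(abs(mean(res_cal$p_value <= 0.05) - 0.05), 0.01)

  res_pool <- run_silac_contrast(tab, aggregate = "mean",
                                 background_policy = "pooled")
  expect_lte(mean(res_pool$p_value <= 0.05), 0.05 + 0.01)

  # with all true shifts below the ratio threshold and vanishing noise,
  # nothing is called significant
  small <- generate_silac_table(silac_spec(50, effect_map = c(P0001 = 0.2),
                                           peptide_noise_sd = 0.001,
                                           peptides_per_protein_sampler = 3,
                                           seed = 17))
  res_small <- run_silac_contrast(small)
  expect_equal(sum(res_small$significant), 0L)
})

test_that("overlap classification partitions the shared membrane set", {
  mk <- function(ids, sig, neg) tibble::tibble(
    protein_id = ids, neg_log2 = neg, p_value = 0.01, adj_p = 0.02,
    significant = sig, is_membrane = TRUE)
  res_a <- mk(c("A", "B", "C", "D"), c(TRUE, TRUE, FALSE, FALSE), c(1, 1, 0, -2))
  res_b <- mk(c("A", "B", "C", "D"), c(TRUE, FALSE, TRUE, FALSE), c(1, 0, 1, -2))
  ov <- overlap_contrasts(res_a, res_b)
  expect_equal(setNames(ov$class, ov$protein_id),
               c(A = "both", B = "a_only", C = "b_only", D = "neither"))
  expect_equal(sum(table(ov$class)), nrow(ov))
  # the display floor trims the scatter table only
  expect_equal(attr(ov, "display")$protein_id, c("A", "B", "C"))
  expect_error(overlap_contrasts(mk("X", TRUE, 1), mk("Y", TRUE, 1)), "shared")
})

test_that("GO component frequencies match a brute-force tally", {
  slim <- tibble::tibble(protein_id = c("A", "B", "C", "C"),
                         term = c("ER", "ER", "ER", "vacuole"))
  genome <- tibble::tibble(protein_id = c("A", "B", "C", "D", "E"),
                           term = c("ER", "ER", "ER", "vacuole", "vacuole"))
  out <- go_component_frequency(c("A", "B"), slim, genome)
  expect_equal(out$term, "ER")
  expect_equal(out$dataset_hits, 2L)
  expect_equal(out$dataset_frequency, 1.0)
  expect_equal(out$enrichment, 1.0 / (3 / 5))
  # a single-hit term never appears
  out2 <- go_component_frequency(c("A", "B", "C"), slim, genome)
  expect_false("vacuole" %in% out2$term)

  # random maps against an independent tally
  set.seed(18)
  prots <- sprintf("P%02d", 1:20)
  terms <- c("ER", "Golgi", "vacuole", "PM")
  rs <- tibble::tibble(protein_id = sample(prots, 60, replace = TRUE),
                       term = sample(terms, 60, replace = TRUE))
  rs <- dplyr::distinct(rs)
  pick <- prots[1:10]
  got <- go_component_frequency(pick, rs, rs, min_hits = 1)
  for (tm in got$term) {
    brute <- length(unique(rs$protein_id[rs$term == tm &
                                         rs$protein_id %in% pick]))
    expect_equal(got$dataset_hits[got$term == tm], brute)
  }
})

test_that("GO fusion rules reassign annotations before counting", {
  slim <- tibble::tibble(protein_id = c("A", "B"),
                         term = c("cytoplasmic vesicles", "cytoplasmic vesicles"))
  rules <- tibble::tibble(protein_id = c("A", "B"),
                          term = "cytoplasmic vesicles",
                          new_term = c("plasma membrane", "endosome"))
  out <- go_component_frequency(c("A", "B"), slim, slim, fusion_rules = rules,
                                min_hits = 1)
  expect_setequal(out$term, c("plasma membrane", "endosome"))
  bad_rule <- tibble::tibble(protein_id = "Z", term = "nope", new_term = "x")
  expect_warning(go_component_frequency(c("A", "B"), slim, slim,
                                        fusion_rules = bad_rule, min_hits = 1),
                 "fusion")
})
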