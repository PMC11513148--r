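hmx1_text <- paste("HMX1\tinside\t1\t292",
                   "HMX1\tTMhelix\t293\t310",
                   "HMX1\toutside\t311\t317", sep = "\n")

test_that("topology parsing handles both dialects and the worked example", {
  ann <- parse_topology(hmx1_text)
  expect_equal(nrow(ann), 3L)
  tm <- ann[ann$label == "TMhelix", ]
  expect_equal(c(tm$start, tm$end), c(293L, 310L))

  # all-inside protein: zero TMDs
  flat <- parse_topology("SOL1\tinside\t1\t100")
  expect_equal(nrow(extract_tmds(flat)), 0L)

  # three-line dialect
  three <- paste(">TP1 | TM=1",
                 paste(rep("A", 12), collapse = ""),
                 "IIIMMMMMMOOO", sep = "\n")
  ann3 <- parse_topology(three)
  expect_equal(ann3$label, c("inside", "TMhelix", "outside"))
  expect_equal(ann3$start, c(1L, 4L, 10L))
})

test_that("write/parse round-trips preserve annotations in both dialects", {
  p <- generate_proteome(proteome_spec(10, tmd_count_sampler = 0:3, seed = 41))
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_topology(p$topology, gff, "gff3")
  back <- parse_topology(gff)
  expect_equal(as.data.frame(back),
               as.data.frame(dplyr::select(p$topology, protein_id, label, start, end)),
               ignore_attr = TRUE)

  tl <- withr::local_tempfile(fileext = ".txt")
  write_topology(p$topology, tl, "three_line", sequences = p$sequences)
  back3 <- parse_topology(tl)
  expect_equal(as.data.frame(back3),
               as.data.frame(dplyr::select(p$topology, protein_id, label, start, end)),
               ignore_attr = TRUE)
  expect_equal(attr(back3, "sequences"), p$sequences)
})

test_that("corrupt topologies are rejected with located errors", {
  expect_error(parse_topology("A\tinside\t2\t10"), "residue 1")
  expect_error(parse_topology(paste("A\tinside\t1\t10",
                                    "A\tTMhelix\t12\t20", sep = "\n")),
               "gap or overlap")
  expect_error(parse_topology(paste("A\tinside\t1\t10",
                                    "A\tTMhelix\t8\t20", sep = "\n")),
               "gap or overlap")
  expect_error(parse_topology(paste("# A Length: 30",
                                    "A\tinside\t1\t10", sep = "\n")),
               "length is 30")
  expect_error(parse_topology("A\tnonsense\t1\t10"), "Unknown topology label")
  # fuzz: random single-field corruptions of a valid file all fail loudly
  p <- generate_proteome(proteome_spec(5, tmd_count_sampler = 2, seed = 42))
  lines <- strsplit(paste(sprintf("%s\t%s\t%d\t%d", p$topology$protein_id,
                                  p$topology$label, p$topology$start,
                                  p$topology$end), collapse = "\n"), "\n")[[1]]
  set.seed(43)
  for (i in sample(seq_along(lines), 5)) {
    corrupt <- lines
    f <- strsplit(corrupt[i], "\t")[[1]]
    f[3] <- as.integer(f[3]) + sample(c(-2L, 2L), 1)  # shift a start coordinate
    corrupt[i] <- paste(f, collapse = "\t")
    expect_error(parse_topology(paste(corrupt, collapse = "\n")))
  }
})

test_that("TMD extraction orients segments cytosolic-to-luminal", {
  seqs <- c(HMX1 = paste(rep("A", 292), collapse = ""))
  seqs["HMX1"] <- paste0(seqs["HMX1"], "LIVLIVLIVLIVLIVLIV", "KRSDEHK")
  ann <- parse_topology(hmx1_text)
  tm <- extract_tmds(ann, seqs)
  expect_equal(tm$length, 18L)          # the 293-310 helix spans 18 residues
  expect_equal(tm$orientation, "in_out")
  expect_equal(tm$oriented_seq, "LIVLIVLIVLIVLIVLIV")

  # helix preceded by a luminal segment is reversed on orientation
  txt <- paste("REV1\toutside\t1\t5",
               "REV1\tTMhelix\t6\t10",
               "REV1\tinside\t11\t15", sep = "\n")
  seq2 <- c(REV1 = "KKKKKLIVFAKKKKK")
  tm2 <- extract_tmds(parse_topology(txt), seq2)
  expect_equal(tm2$orientation, "out_in")
  expect_equal(tm2$oriented_seq, "AFVIL")
  # re-orienting twice is the identity
  expect_equal(reverse_residues(reverse_residues(tm2$oriented_seq)), tm2$oriented_seq)

  # degenerate single-residue helix
  tm3 <- extract_tmds(parse_topology(paste("D1\tinside\t1\t4",
                                           "D1\tTMhelix\t5\t5",
                                           "D1\toutside\t6\t10", sep = "\n")),
                      c(D1 = "KKKKLKKKKK"))
  expect_equal(tm3$length, 1L)
  expect_equal(tm3$oriented_seq, "L")
})

test_that("TMD lengths equal brute-force interval arithmetic on random topologies", {
  p <- generate_proteome(proteome_spec(30, tmd_count_sampler = 1:5, seed = 44))
  tm <- extract_tmds(p$topology, p$sequences)
  expect_equal(tm$length, tm$end - tm$start + 1L)
  expect_equal(dplyr::arrange(dplyr::select(tm, protein_id, start, end, length),
                              protein_id, start),
               dplyr::arrange(dplyr::select(p$tmds, protein_id, start, end, length),
                              protein_id, start))
  # alternating orientation down each protein
  for (id in unique(tm$protein_id)) {
    ori <- tm$orientation[tm$protein_id == id]
    if (length(ori) > 1) expect_true(all(ori[-1] != ori[-length(ori)]))
  }
})

test_that("signature statistics summarize lengths, shortest TMDs and counts", {
  tmds <- tibble::tibble(protein_id = c("A", "A"), length = c(14L, 18L))
  sig <- signature_stats(tmds)
  expect_equal(unname(sig$shortest_per_protein["A"]), 14L)
  expect_equal(unname(sig$count_per_protein["A"]), 2L)
  expect_equal(unname(sig$frac_tmds_le["le_18"]), 1.0)
  expect_equal(sig$n_proteins_no_tmd, 0L)

  # conservation: per-protein counts sum to the TMD total; histogram sums to 1
  p <- generate_proteome(proteome_spec(50, tmd_count_sampler = 1:6, seed = 45))
  sig2 <- signature_stats(p$tmds, all_protein_ids = p$proteins$protein_id)
  expect_equal(sum(sig2$count_per_protein), sig2$n_tmds)
  expect_equal(sum(table(sig2$lengths) / sig2$n_tmds), 1)
  expect_true(all(sig2$shortest_per_protein <=
                    tapply(p$tmds$length, p$tmds$protein_id, max)[names(sig2$shortest_per_protein)]))
  expect_equal(c(sig2$q1, sig2$median, sig2$q3),
               unname(quantile(p$tmds$length, c(.25, .5, .75))))
  expect_error(signature_stats(p$tmds[0, ]), "No TMDs")
})

test_that("signature comparison reports deltas and a rank-sum extension", {
  mk <- function(lengths) signature_stats(
    tibble::tibble(protein_id = paste0("P", seq_along(lengths)), length = lengths))
  sig <- mk(rep(14:18, 4))
  same <- compare_signatures(sig, sig)
  expect_equal(same$delta_median, 0)
  expect_equal(same$length_rank_sum_p, 1)
  shifted <- compare_signatures(mk(rep(14:18, 4)), mk(rep(20:24, 4)))
  expect_equal(shifted$delta_median, -6)
  expect_lt(shifted$length_rank_sum_p, 0.001)
})

test_that("hydropathy fallback finds hydrophobic stretches and nothing else", {
  poly_l <- paste(rep("L", 40), collapse = "")
  hit <- hydropathy_fallback_tmds(poly_l)
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$start, hit$end), c(10L, 31L))  # scorable window centres
  expect_equal(nrow(hydropathy_fallback_tmds(paste(rep("D", 40), collapse = ""))), 0L)
  expect_equal(nrow(hydropathy_fallback_tmds("LLLLL")), 0L)  # shorter than window
  expect_error(hydropathy_fallback_tmds("LLXLL LL"), "non-standard")
})

test_that("hydropathy fallback recalls planted TMD midpoints", {
  p <- generate_proteome(proteome_spec(60, tmd_count_sampler = 1:2,
                                       tmd_length_sampler = 19:26,
                                       linker_length_sampler = 25:60, seed = 46))
  hits <- 0L
  total <- 0L
  for (id in unique(p$tmds$protein_id)) {
    pred <- hydropathy_fallback_tmds(p$sequences[[id]])
    planted <- p$tmds[p$tmds$protein_id == id, ]
    for (k in seq_len(nrow(planted))) {
      mid <- (planted$start[k] + planted$end[k]) %/% 2
      total <- total + 1L
      if (nrow(pred) && any(pred$start <= mid & mid <= pred$end)) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("helix extension rise follows the 1.5 A-per-residue pitch", {
  expect_equal(helix_extension_rise(3), 4.5)
  expect_equal(helix_extension_rise(6), 9)
  expect_equal(helix_extension_rise(0), 0)
  expect_error(helix_extension_rise(-1), "non-negative")
})
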