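test_that("generation is byte-deterministic under identical params and seed", {
  p <- sim_params(rng_seed = 1, n_genomes = 2)
  a <- generate_genome(p, genome_id = "g", seed = 1)
  b <- generate_genome(p, genome_id = "g", seed = 1)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$genome$features, b$genome$features)
  expect_identical(a$hits, b$hits)
  ca <- simulate_community(p)
  cb <- simulate_community(p)
  expect_identical(lapply(ca$genomes, `[[`, "sequence"),
                   lapply(cb$genomes, `[[`, "sequence"))
  expect_identical(ca$truth$heg_truth, cb$truth$heg_truth)
})

test_that("forced in-frame deletion shortens every repeat-bearing HEG by the repeat spacing", {
  p <- sim_params(rng_seed = 7, frameshift_prob = 0, inframe_del_prob = 1,
                  absent_prob = 0, n_genomes = 2)
  com <- simulate_community(p)
  tpl <- generate_genome(p, genome_id = "tpl", seed = p$rng_seed)
  lm_t <- tpl$truth$locus_map
  for (gid in names(com$genomes)) {
    lm <- com$truth$locus_map
    tr <- com$truth$heg_truth
    for (locus in unique(lm$locus[lm$genome_id == gid])) {
      li <- lm[lm$genome_id == gid & lm$locus == locus, ]
      ti <- lm_t[lm_t$locus == locus, ]
      state <- tr$allele_state[tr$genome_id == gid & tr$locus == locus]
      len <- li$end - li$start
      tlen <- ti$end - ti$start
      if (state == "inframe_deletion") {
        expect_equal(tlen - len, 228)
        expect_equal(len %% 3, 0)
      } else {
        # loci without a repeat substrate fall back to another state
        expect_true(state %in% c("frameshifted", "intact"))
      }
    }
  }
})

test_that("forced absence removes all HEG CDSs and truth records them absent", {
  p <- sim_params(rng_seed = 8, frameshift_prob = 0, inframe_del_prob = 0,
                  absent_prob = 1, n_genomes = 2)
  com <- simulate_community(p)
  expect_true(all(com$truth$heg_truth$allele_state == "absent"))
  for (gid in names(com$genomes)) {
    f <- com$genomes[[gid]]$features
    expect_false(any(grepl("^heg", f$gene_id)))
  }
  audit_truth_consistency(com)
})

test_that("the truth self-audit passes at default settings", {
  p <- sim_params(rng_seed = 9)
  com <- simulate_community(p)
  expect_true(audit_truth_consistency(com))
})

test_that("island implant realizes the requested divergence exactly by count", {
  p <- sim_params(rng_seed = 11)
  d <- generate_genome(p, genome_id = "d", seed = 21)
  r <- generate_genome(p, genome_id = "r", seed = 22)
  impl0 <- implant_shared_island(d, r, cargo_len_bp = 6000, divergence = 0,
                                 seed = 23)
  tr0 <- impl0$island_truth
  cd <- get_subseq(impl0$donor$genome, tr0$donor_start, tr0$donor_end)
  cr <- get_subseq(impl0$recipient$genome, tr0$recipient_start,
                   tr0$recipient_end)
  expect_identical(cd, cr)                       # divergence 0 -> identical
  expect_equal(tr0$n_substitutions, 0)

  d2 <- generate_genome(p, genome_id = "d2", seed = 24)
  r2 <- generate_genome(p, genome_id = "r2", seed = 25)
  impl <- implant_shared_island(d2, r2, cargo_len_bp = 12000,
                                divergence = 0.05, seed = 26)
  tr <- impl$island_truth
  cd <- strsplit(get_subseq(impl$donor$genome, tr$donor_start, tr$donor_end),
                 "")[[1]]
  cr <- strsplit(get_subseq(impl$recipient$genome, tr$recipient_start,
                            tr$recipient_end), "")[[1]]
  expect_equal(length(cd), length(cr))
  expect_equal(sum(cd != cr), tr$n_substitutions)
  realized <- 1 - sum(cd != cr) / length(cd)
  expect_equal(realized, 1 - tr$n_substitutions / length(cd))
})

test_that("swap flag records different flanking HEG families in the recipient", {
  p <- sim_params(rng_seed = 12)
  d <- generate_genome(p, genome_id = "d", seed = 31)
  r <- generate_genome(p, genome_id = "r", seed = 32)
  impl <- implant_shared_island(d, r, swap_flank = TRUE, seed = 33)
  tr <- impl$island_truth
  expect_true(tr$swap)
  expect_false(tr$donor_left_family == tr$recipient_left_family)
  expect_false(tr$donor_right_family == tr$recipient_right_family)
  expect_error(implant_shared_island(impl$donor, r, seed = 34),
               "already carries an island")
})

test_that("coverage means match configuration and the Poisson limit holds", {
  p0 <- sim_params(rng_seed = 13, intron_depth_mean = 0)
  sl <- generate_spliced_locus(p0, n_introns = 1, seed = 41)
  tr <- simulate_rnaseq_coverage(sl$genome, sl$splice_truth, p0, seed = 42)
  iv <- sl$splice_truth$introns
  # interior of the intron (outside the 5 bp boundary ramps)
  expect_equal(mean(tr$depth[(iv[1, 1] + 6):(iv[1, 2] - 5)]), 0)

  # sample means within 3 SE of the configured means
  p <- sim_params(rng_seed = 13)
  sl2 <- generate_spliced_locus(p, n_introns = 1, seed = 43)
  tr2 <- simulate_rnaseq_coverage(sl2$genome, sl2$splice_truth, p, seed = 44)
  iv2 <- sl2$splice_truth$introns
  ex_idx <- setdiff(seq_len(sl2$genome$length),
                    (iv2[1, 1] + 1):iv2[1, 2])
  mu <- p$exon_depth_mean; size <- p$depth_dispersion
  se <- sqrt((mu + mu^2 / size) / length(ex_idx))
  expect_lt(abs(mean(tr2$depth[ex_idx]) - mu), 3 * se)
  in_idx <- (iv2[1, 1] + 6):(iv2[1, 2] - 5)
  mu_i <- p$intron_depth_mean
  se_i <- sqrt((mu_i + mu_i^2 / size) / length(in_idx))
  expect_lt(abs(mean(tr2$depth[in_idx]) - mu_i), 3 * se_i)

  # dispersion -> Inf: variance/mean -> 1 (Poisson limit)
  pinf <- sim_params(rng_seed = 13, depth_dispersion = Inf)
  tr3 <- simulate_rnaseq_coverage(sl2$genome, sl2$splice_truth, pinf, seed = 45)
  vm <- stats::var(tr3$depth[ex_idx]) / mean(tr3$depth[ex_idx])
  expect_lt(abs(vm - 1), 0.1)
})

test_that("satellite loci carry matching att repeats and a homologous reference", {
  p <- sim_params(rng_seed = 14)
  sat <- generate_satellite_locus(p, seed = 51)
  tr <- sat$truth
  attL <- get_subseq(sat$contig, tr$attL[1], tr$attL[2])
  attR <- get_subseq(sat$contig, tr$attR[1], tr$attR[2])
  expect_equal(nchar(attL), p$att_len_bp)
  expect_identical(attL, attR)                   # direct orientation

  sat_inv <- generate_satellite_locus(p, att_orientation = "inverted",
                                      seed = 52)
  ti <- sat_inv$truth
  expect_identical(get_subseq(sat_inv$contig, ti$attL[1], ti$attL[2]),
                   revcomp(get_subseq(sat_inv$contig, ti$attR[1], ti$attR[2])))

  # element length near the requested ~13 kb
  expect_lt(abs((tr$bounds[2] - tr$bounds[1]) - 13000), 600)

  # the 95%-identity reference supports >10 kb of block homology
  elem <- get_subseq(sat$contig, tr$bounds[1], tr$bounds[2])
  bl <- find_identity_blocks(elem, sat$reference$sequence)
  expect_gt(max_weight_nonoverlap(bl$q_start, bl$q_end), 10000)
})

test_that("junction support tables cover every true junction with positive reads", {
  p <- sim_params(rng_seed = 15)
  sl <- generate_spliced_locus(p, n_introns = 3, seed = 61)
  jt <- simulate_junction_support(sl$splice_truth, p, seed = 62)
  expect_equal(nrow(jt), 3)
  expect_equal(jt$pos_a, sl$splice_truth$introns[, 1])
  expect_equal(jt$pos_b, sl$splice_truth$introns[, 2])
  expect_true(all(jt$n_reads >= 1))
})

test_that("a genome too short for the requested genes is rejected", {
  p <- sim_params(rng_seed = 16, genome_len_bp = 2000)
  expect_error(generate_genome(p), "too short")
})
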