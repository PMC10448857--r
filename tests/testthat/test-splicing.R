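test_that("ORF validation matches a brute-force codon scan", {
  expect_true(validate_orf("ATGAAATAA")$valid)
  v <- validate_orf("ATGTAAAAATAA")
  expect_false(v$valid)
  expect_match(v$reason, "internal stop")
  expect_false(validate_orf("ATGAAATAAA")$valid)    # length % 3 != 0
  expect_false(validate_orf("CCCAAATAA")$valid)     # no start codon
  expect_false(validate_orf("ATGAAACCC")$valid)     # no terminal stop
  expect_true(validate_orf("GTGAAATGA")$valid)      # alternative start

  set.seed(601)
  for (i in 1:50) {
    s <- rand_seq(999)
    got <- validate_orf(s)$valid
    codons <- substring(s, seq(1, 997, 3), seq(3, 999, 3))
    want <- codons[1] %in% c("ATG", "GTG", "TTG") &&
      codons[333] %in% c("TAA", "TAG", "TGA") &&
      !any(codons[2:332] %in% c("TAA", "TAG", "TGA"))
    expect_identical(got, want)
  }
})

test_that("uniform coverage yields no intron candidates", {
  set.seed(602)
  tr <- coverage_track("g", rnbinom(5000, size = 5, mu = 100))
  expect_equal(nrow(detect_intron_candidates(tr, c(500, 4500))), 0)
})

test_that("a single designed intron is detected within +/-5 bp", {
  p <- sim_params(rng_seed = 603)
  sl <- generate_spliced_locus(p, n_introns = 1, seed = 603)
  tr <- simulate_rnaseq_coverage(sl$genome, sl$splice_truth, p, seed = 604)
  cand <- detect_intron_candidates(tr, sl$splice_truth$gene_span)
  expect_equal(nrow(cand), 1)
  expect_lte(abs(cand$start - sl$splice_truth$introns[1, 1]), 5)
  expect_lte(abs(cand$end - sl$splice_truth$introns[1, 2]), 5)
})

test_that("three designed introns are detected in genomic order", {
  p <- sim_params(rng_seed = 605)
  sl <- generate_spliced_locus(p, n_introns = 3, cds_len_nt = 3000,
                               seed = 605)
  tr <- simulate_rnaseq_coverage(sl$genome, sl$splice_truth, p, seed = 606)
  cand <- detect_intron_candidates(tr, sl$splice_truth$gene_span)
  expect_equal(nrow(cand), 3)
  expect_true(all(diff(cand$start) > 0))
  expect_true(all(cand$end > cand$start))
})

test_that("an unexpressed region raises an insufficient-expression error", {
  tr <- coverage_track("g", rep(0, 2000))
  expect_error(detect_intron_candidates(tr, c(100, 1900)),
               "insufficient expression")
})

test_that("exons and introns tile the gene span in every model", {
  p <- sim_params(rng_seed = 607)
  for (ni in 1:3) {
    sl <- generate_spliced_locus(p, n_introns = ni, seed = 607 + ni)
    tr <- simulate_rnaseq_coverage(sl$genome, sl$splice_truth, p,
                                   seed = 617 + ni)
    cand <- detect_intron_candidates(tr, sl$splice_truth$gene_span)
    frags <- sl$genome$features[grepl("^tmp_f", sl$genome$features$gene_id), ]
    m <- chain_exons(frags, cand, sl$genome)
    pieces <- rbind(m$exons, m$introns)
    pieces <- pieces[order(pieces[, 1]), , drop = FALSE]
    expect_equal(unname(pieces[1, 1]), min(frags$start))
    expect_equal(unname(pieces[nrow(pieces), 2]), max(frags$end))
    expect_true(all(pieces[-1, 1] == pieces[-nrow(pieces), 2]))  # no gap/overlap
  }
})

test_that("exact candidates reconstruct the pre-fragmentation CDS byte for byte", {
  p <- sim_params(rng_seed = 608)
  sl <- generate_spliced_locus(p, n_introns = 2, seed = 608)
  truth_cand <- data.frame(start = sl$splice_truth$introns[, 1],
                           end = sl$splice_truth$introns[, 2],
                           mean_depth = 5)
  frags <- sl$genome$features[grepl("^tmp_f", sl$genome$features$gene_id), ]
  m <- chain_exons(frags, truth_cand, sl$genome)
  expect_true(m$orf_valid)
  expect_identical(m$spliced_cds, sl$splice_truth$full_cds)
})

test_that("the frame search recovers boundaries from a shifted candidate", {
  # constructed perturbation: intron edges are stop-codon-rich so any
  # frame-consistent wrong assignment splices a stop into the CDS
  set.seed(609)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  # upstream exon ends CCC and downstream exon starts CAA: substituting any
  # 1-2 intron edge bases for exon bases at the junction yields a stop
  exon1 <- paste0("ATG", paste(sample(sense, 119, TRUE), collapse = ""),
                  "CCC")
  exon2 <- paste0("CAA", paste(sample(sense, 119, TRUE), collapse = ""),
                  "TAA")
  intron <- paste0(strrep("TAA", 8), rand_seq(352), strrep("TAA", 8))
  full <- paste0(exon1, exon2)
  seqs <- paste0(rand_seq(300), exon1, intron, exon2, rand_seq(300))
  gs <- 300L; ge <- gs + nchar(exon1) + nchar(intron) + nchar(exon2)
  is_ <- gs + nchar(exon1); ie <- is_ + nchar(intron)
  g <- genome_record("t", seqs, features = gene_features(
    c("f1", "f2"), c(gs, is_ + 370L), c(is_ + 30L, ge), c("+", "+")))
  frags <- g$features
  # asymmetric shift: every smaller frame-consistent assignment either
  # splices stop-rich intron edge bases in or shifts the downstream frame
  shifted <- data.frame(start = is_ + 4L, end = ie + 1L, mean_depth = 5)
  m <- chain_exons(frags, shifted, g)
  expect_true(m$orf_valid)
  expect_equal(unname(m$introns[1, ]), c(is_, ie))   # truth offsets recovered
  expect_identical(m$spliced_cds, full)
})

test_that("junction support snaps boundaries and fragments on opposite strands fail", {
  p <- sim_params(rng_seed = 610)
  sl <- generate_spliced_locus(p, n_introns = 2, seed = 610)
  jt <- simulate_junction_support(sl$splice_truth, p, seed = 611)
  frags <- sl$genome$features[grepl("^tmp_f", sl$genome$features$gene_id), ]
  # candidates off by a few bases snap back to the supported junctions
  cand <- data.frame(start = sl$splice_truth$introns[, 1] + c(3, -2),
                     end = sl$splice_truth$introns[, 2] + c(-4, 2),
                     mean_depth = 5)
  m <- chain_exons(frags, cand, sl$genome, junction_table = jt)
  expect_true(m$orf_valid)
  expect_identical(m$spliced_cds, sl$splice_truth$full_cds)
  expect_equal(unname(m$introns[, 1]), unname(sl$splice_truth$introns[, 1]))
  expect_true(all(m$junctions$support >= 1))

  frags_bad <- frags
  frags_bad$strand[2] <- "-"
  expect_error(chain_exons(frags_bad, cand, sl$genome), "opposite strands")
})

test_that("recovery degrades as intron depth approaches exon depth (trend)", {
  means <- c(5, 40, 90)
  hit <- numeric(3)
  for (k in seq_along(means)) {
    p <- sim_params(rng_seed = 612, intron_depth_mean = means[k])
    found <- 0
    for (i in 1:8) {
      sl <- generate_spliced_locus(p, n_introns = 1, seed = 620 + i)
      tr <- simulate_rnaseq_coverage(sl$genome, sl$splice_truth, p,
                                     seed = 640 + 10 * k + i)
      cand <- tryCatch(detect_intron_candidates(tr, sl$splice_truth$gene_span),
                       error = function(e) NULL)
      if (!is.null(cand) && nrow(cand) == 1) found <- found + 1
    }
    hit[k] <- found
  }
  expect_true(hit[1] >= hit[3])
  expect_equal(hit[1], 8)
  expect_lt(hit[3], 8)
})
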