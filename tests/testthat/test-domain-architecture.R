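mk_hit <- function(pid, acc, name, from, to, ev) {
  domain_hits(pid, name, acc, as.integer(from), as.integer(to), ev, 40)
}

test_that("bisection trims the nuclease domain to the nearest terminus", {
  aa <- strrep("M", 300)
  # C-terminal domain
  s1 <- bisect_heg_protein(aa, mk_hit("p", "PF10544", "T5orf172", 210, 290, 1e-12))
  expect_equal(s1$nuclease_fragment, c(210L, 300L))
  expect_equal(s1$dbd_fragment, c(1L, 209L))
  # N-terminal domain
  s2 <- bisect_heg_protein(aa, mk_hit("p", "PF13392", "HNH_3", 10, 90, 1e-12))
  expect_equal(s2$nuclease_fragment, c(1L, 90L))
  expect_equal(s2$dbd_fragment, c(91L, 300L))
  # exact tie (100 residues on each side) resolves to the C-terminal side
  s3 <- bisect_heg_protein(aa, mk_hit("p", "PF10544", "T5orf172", 101, 200, 1e-12))
  expect_equal(s3$nuclease_fragment, c(101L, 300L))
  expect_equal(s3$dbd_fragment, c(1L, 100L))
  # domain covering the whole protein: empty DBD, flagged
  s4 <- bisect_heg_protein(aa, mk_hit("p", "PF10544", "T5orf172", 1, 300, 1e-12))
  expect_true(s4$dbd_empty)
  expect_null(s4$dbd_fragment)
})

test_that("bisection partitions every protein exactly", {
  set.seed(501)
  for (i in 1:200) {
    n <- sample(80:600, 1)
    from <- sample(n, 1); to <- from + sample.int(n - from + 1, 1) - 1L
    s <- bisect_heg_protein(strrep("A", n),
                            mk_hit("p", "PF10544", "T5orf172", from, to, 1e-9))
    if (isTRUE(s$dbd_empty)) {
      expect_equal(s$nuclease_fragment, c(1L, n))
    } else {
      got <- sort(c(seq(s$nuclease_fragment[1], s$nuclease_fragment[2]),
                    seq(s$dbd_fragment[1], s$dbd_fragment[2])))
      expect_identical(got, seq_len(n))   # no residue lost or duplicated
    }
  }
})

test_that("DBD classification follows the CapR > DUF > remote-table decision tree", {
  aa <- strrep("M", 300)
  split <- bisect_heg_protein(aa, mk_hit("p", "PF10544", "T5orf172", 210, 290, 1e-12))

  # two non-overlapping CapR hits below 1e-10: CapR with count 2
  h2 <- rbind(mk_hit("p", "CapR", "CapR", 20, 50, 1e-15),
              mk_hit("p", "CapR", "CapR", 90, 120, 1e-12))
  r <- assign_dbd_class(split, h2)
  expect_equal(r$dbd_class, "CapR")
  expect_equal(r$zn_finger_count, 2L)
  expect_true(r$count_quantified)

  # CapR above its threshold but DUF723 qualifying: DUF723/DUF4397
  h3 <- rbind(mk_hit("p", "CapR", "CapR", 20, 50, 5e-9),
              mk_hit("p", "PF05265", "DUF723", 90, 150, 1e-6))
  r3 <- assign_dbd_class(split, h3)
  expect_equal(r3$dbd_class, "DUF723/DUF4397")

  # CapR exactly at 1e-10 still qualifies (maximum e-value)
  r4 <- assign_dbd_class(split, mk_hit("p", "CapR", "CapR", 20, 50, 1e-10))
  expect_equal(r4$dbd_class, "CapR")

  # no hmm hits; remote-homology table supplies RepA_N, count not quantified
  remote <- data.frame(protein_id = "p", domain = "RepA_N", evalue = 1e-4)
  r5 <- assign_dbd_class(split, h3[0, ], remote)
  expect_equal(r5$dbd_class, "RepA_N")
  expect_false(r5$count_quantified)
  expect_equal(r5$zn_finger_count, 0L)

  # unknown protein in the remote table is skipped with a warning
  bad <- data.frame(protein_id = "p", domain = "whatever", evalue = 1e-4)
  expect_warning(r6 <- assign_dbd_class(split, h3[0, ], bad), "skipped")
  expect_equal(r6$dbd_class, "unassigned")

  # overlapping qualifying hits are counted greedily without overlap
  h7 <- rbind(mk_hit("p", "CapR", "CapR", 20, 60, 1e-15),
              mk_hit("p", "CapR", "CapR", 40, 80, 1e-13),
              mk_hit("p", "CapR", "CapR", 100, 130, 1e-12))
  r7 <- assign_dbd_class(split, h7)
  expect_equal(r7$zn_finger_count, 2L)
})

test_that("designed repeat spacings are recovered exactly and frame status is correct", {
  for (sp in c(90, 228, 501)) {
    pp <- sim_params(rng_seed = 502, repeat_spacing_bp = sp,
                     repeat_divergence = 0.3)
    g <- generate_genome(pp, genome_id = "t", seed = 502 + sp)
    lm <- g$truth$locus_map
    li <- lm[lm$locus == "heg1", ]
    cds <- substr(g$genome$sequence, li$start + 1, li$end)
    rp <- find_repeat_pairs(cds, c(3, 63 + sp + 120))
    expect_gte(nrow(rp), 1)
    expect_equal(rp$spacing_bp[1], sp)
    expect_true(rp$in_frame[1])                     # all three spacings %% 3 == 0
    expect_equal(rp$predicted_product_len[1], nchar(cds) - sp)
  }
  # spacing not divisible by 3 is flagged out of frame
  set.seed(503)
  rep1 <- rand_seq(60)
  cds <- paste0(rand_seq(30), rep1, rand_seq(40), rep1, rand_seq(50))
  rp <- find_repeat_pairs(cds, c(0, nchar(cds)))
  expect_gte(nrow(rp), 1)
  expect_equal(rp$spacing_bp[1], 100)
  expect_false(rp$in_frame[1])
})

test_that("repeat false positives are rare on repeat-free coding sequence", {
  set.seed(504)
  fp <- 0
  for (i in 1:60) {
    cds <- rand_seq(450)
    if (nrow(find_repeat_pairs(cds, c(0, 450))) > 0) fp <- fp + 1
  }
  expect_lt(fp / 60, 0.05)
  # an interval shorter than the minimum repeat length yields nothing
  expect_equal(nrow(find_repeat_pairs(rand_seq(450), c(0, 20))), 0)
})

test_that("domain-swap detection distinguishes shared DBD, nuclease, both, neither", {
  set.seed(505)
  mk_gene <- function(dbd_nt, nuc_nt) {
    cds <- paste0(dbd_nt, nuc_nt)
    n_aa <- nchar(cds) / 3
    dbd_aa <- nchar(dbd_nt) / 3
    split <- structure(list(protein_id = "x",
                            nuclease_fragment = c(dbd_aa + 1L, as.integer(n_aa)),
                            dbd_fragment = c(1L, as.integer(dbd_aa)),
                            dbd_empty = FALSE, dbd_class = "CapR",
                            zn_finger_count = 1L, count_quantified = TRUE),
                       class = "domain_split")
    list(cds = cds, split = split)
  }
  dbd1 <- rand_seq(450); nuc1 <- rand_seq(330)
  dbd2 <- rand_seq(450); nuc2 <- rand_seq(330)
  a <- mk_gene(dbd1, nuc1)
  expect_equal(detect_domain_swap(a, mk_gene(dbd1, nuc1)), "shared_both")
  expect_equal(detect_domain_swap(a, mk_gene(dbd1, nuc2)), "shared_dbd_only")
  expect_equal(detect_domain_swap(a, mk_gene(dbd2, nuc1)), "shared_nuclease_only")
  expect_equal(detect_domain_swap(a, mk_gene(dbd2, nuc2)), "shared_neither")
  expect_error(detect_domain_swap(a, list(cds = "ACGT", split = NULL)),
               "lacks a completed domain split")
})

test_that("the architecture census covers called HEGs with consistent fragments", {
  p <- sim_params(rng_seed = 506, n_genomes = 3)
  com <- simulate_community(p)
  calls <- call_hegs(com$genomes, com$hits)
  arch <- architecture_census(com$genomes, calls, com$hits)
  expect_gt(nrow(arch), 0)
  # fragments partition each protein
  for (i in seq_len(nrow(arch))) {
    if (!is.na(arch$dbd_from[i])) {
      lens <- (arch$nuc_to[i] - arch$nuc_from[i] + 1) +
        (arch$dbd_to[i] - arch$dbd_from[i] + 1)
      expect_equal(lens, max(arch$nuc_to[i], arch$dbd_to[i]))
    }
  }
  # full-length T5orf172 HEGs (wide DBD fragments; frameshift fragments keep
  # only a sliver of the DBD) carry quantified CapR Zn-finger counts from
  # the designed repeats
  t5 <- arch[arch$family == "T5orf172" & !is.na(arch$dbd_from) &
               arch$dbd_to - arch$dbd_from >= 100, ]
  expect_gt(nrow(t5), 0)
  expect_true(all(t5$dbd_class == "CapR"))
  expect_true(all(t5$zn_finger_count >= 1))
})
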