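# one-CDS genome with a supplied protein and hit table
one_gene_genome <- function(hits_df, gene_len = 903, id = "g1") {
  set.seed(42)
  seq <- paste0(rand_seq(500), strrep("ACGTGA", gene_len / 3), rand_seq(500))
  feats <- gene_features("p1", 500L, 500L + gene_len, "+")
  genome_record(id, substr(seq, 1, 500 + gene_len + 500), features = feats)
}

test_that("HEG calling applies the 1e-3 domain e-value cutoff and MUG113 relabeling", {
  g <- one_gene_genome()
  mk <- function(acc, name, ev) {
    domain_hits("g1|p1", name, acc, 182L, 291L, ev, 50)
  }
  # clear T5orf172 hit
  calls <- call_hegs(list(g), mk("PF10544", "T5orf172", 1e-20))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$family, "T5orf172")

  # MUG113 (PF13455) is accepted and relabeled to T5orf172
  calls2 <- call_hegs(list(g), mk("PF13455", "MUG113", 1e-8))
  expect_equal(calls2$family, "T5orf172")
  expect_equal(calls2$nuclease_acc, "PF13455")

  # above-threshold hit is not called (2e-3 > 1e-3)
  calls3 <- call_hegs(list(g), mk("PF10544", "T5orf172", 2e-3))
  expect_equal(nrow(calls3), 0)
  # exactly at the threshold is called (maximum e-value cutoff)
  calls4 <- call_hegs(list(g), mk("PF10544", "T5orf172", 1e-3))
  expect_equal(nrow(calls4), 1)

  expect_error(call_hegs(list(g), mk("PF10544", "T5orf172", 1e-20) |>
                           transform(protein_id = "g1|nope")),
               "unknown protein")
})

test_that("IPA-HNH requires HNH plus AP2 on the same or adjacent CDS", {
  g <- one_gene_genome()
  hnh <- domain_hits("g1|p1", "HNH_3", "PF13392", 10L, 110L, 1e-12, 60)
  both <- rbind(hnh, domain_hits("g1|p1", "AP2", "PF00847", 180L, 280L, 1e-8, 40))
  expect_equal(call_hegs(list(g), hnh)$family, "HNH-3")
  expect_equal(call_hegs(list(g), both)$family, "IPA-HNH")

  # adjacent-CDS AP2: split gene pair
  feats <- gene_features(c("pa", "pb"), c(500L, 960L), c(950L, 1400L),
                         c("+", "+"))
  set.seed(43)
  g2 <- genome_record("g2", rand_seq(2000), features = feats)
  hits2 <- rbind(domain_hits("g2|pa", "HNH_3", "PF13392", 10L, 110L, 1e-12, 60),
                 domain_hits("g2|pb", "AP2", "PF00847", 5L, 100L, 1e-8, 40))
  expect_equal(call_hegs(list(g2), hits2)$family, "IPA-HNH")
})

test_that("calling is monotone in the e-value threshold", {
  p <- sim_params(rng_seed = 21)
  com <- simulate_community(p)
  thresholds <- c(1e-6, 1e-4, 1e-3, 1e-2, 1e-1)
  counts <- vapply(thresholds, function(ev) {
    nrow(call_hegs(com$genomes, com$hits, heg_config(heg_domain_evalue = ev)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("allele-state classification recovers designed states exactly", {
  p <- sim_params(rng_seed = 22, bg_divergence = 0)
  com <- simulate_community(p)
  calls <- call_hegs(com$genomes, com$hits)
  lm <- com$truth$locus_map
  st <- do.call(rbind, lapply(split(lm, lm$locus), function(lg) {
    classify_allele_state(lg, com$genomes, calls, com$hits)
  }))
  st <- st[st$allele_state != "fused", ]
  locus_of <- sub("_[ab].*$", "", sub("[+].*$", "", st$gene_id))
  key <- paste(st$genome_id, locus_of)
  tr <- com$truth$heg_truth
  m <- match(paste(tr$genome_id, tr$locus), key)
  expect_false(anyNA(m))
  # exact agreement at zero background mutation
  expect_identical(st$allele_state[m], tr$allele_state)
})

test_that("a 228 bp in-frame shorter allele among full-length alleles is classified as in-frame deletion", {
  # three homologous loci: 900/900/672 nt (delta = 228, divisible by 3)
  set.seed(44)
  mk_genome <- function(id, glen) {
    feats <- gene_features("h", 1000L, 1000L + glen, "+")
    genome_record(id, rand_seq(3000), features = feats)
  }
  genomes <- list(a = mk_genome("a", 900L), b = mk_genome("b", 900L),
                  c = mk_genome("c", 672L))
  hits <- domain_hits(c("a|h", "b|h", "c|h"), "T5orf172", "PF10544",
                      c(10L, 10L, 10L), c(100L, 100L, 100L), 1e-12, 50)
  calls <- call_hegs(genomes, hits)
  lg <- data.frame(genome_id = c("a", "b", "c"), locus = "h",
                   start = 1000L, end = c(1900L, 1900L, 1672L))
  st <- classify_allele_state(lg, genomes, calls, hits)
  expect_equal(st$allele_state[st$genome_id == "c"], "inframe_deletion")
  expect_equal(st$allele_state[st$genome_id %in% c("a", "b")],
               rep("intact", 2))
})

test_that("a split CDS pair with small net offset yields frameshifted plus a fused call", {
  set.seed(45)
  mk <- function(id, split) {
    if (split) {
      feats <- gene_features(c("h_a", "h_b"), c(1000L, 1451L),
                             c(1451L, 1904L), c("+", "+"))
    } else {
      feats <- gene_features("h", 1000L, 1903L, "+")
    }
    genome_record(id, rand_seq(3000), features = feats)
  }
  genomes <- list(a = mk("a", FALSE), b = mk("b", TRUE))
  hits <- rbind(
    domain_hits("a|h", "HNH_3", "PF13392", 10L, 100L, 1e-12, 50),
    domain_hits("b|h_a", "HNH_3", "PF13392", 10L, 100L, 1e-12, 50),
    domain_hits("b|h_b", "AP2", "PF00847", 20L, 120L, 1e-8, 40))
  calls <- call_hegs(genomes, hits)
  lg <- data.frame(genome_id = c("a", "b"), locus = "h",
                   start = 1000L, end = c(1903L, 1904L))
  st <- classify_allele_state(lg, genomes, calls, hits)
  b_states <- st$allele_state[st$genome_id == "b"]
  expect_setequal(b_states, c("frameshifted", "fused"))
  expect_equal(st$gene_id[st$genome_id == "b" &
                            st$allele_state == "frameshifted"], "h_a+h_b")
  expect_equal(st$allele_state[st$genome_id == "a"], "intact")
})

test_that("flank-anchored locus grouping links homologous loci across genomes", {
  p <- sim_params(rng_seed = 23, n_genomes = 3, bg_divergence = 0.01)
  com <- simulate_community(p)
  calls <- call_hegs(com$genomes, com$hits)
  intact <- calls[calls$allele_state == "intact", ]
  groups <- group_heg_loci(com$genomes, intact)
  # each group should contain at most one call per genome, and calls at the
  # same template locus should co-cluster
  for (grp in groups) {
    expect_lte(max(table(grp$genome_id)), 1)
    base <- sub("_[ab]$", "", grp$locus)
    expect_length(unique(base), 1)
  }
})

test_that("genome filtering drops short records and metagenome assemblies with reasons", {
  set.seed(46)
  mk <- function(id, L, tag = "") genome_record(id, rand_seq(L), source_tag = tag)
  out <- filter_genomes(list(mk("short", 19999), mk("edge", 20000),
                             mk("long", 30000), mk("meta", 50000, "metagenome"),
                             mk("ok", 25000)))
  expect_equal(vapply(out$retained, `[[`, "", "id"), c("edge", "long", "ok"))
  expect_equal(nrow(out$rejected), 2)
  expect_match(out$rejected$reason[out$rejected$genome_id == "short"],
               "19999 bp < 20000")
  expect_match(out$rejected$reason[out$rejected$genome_id == "meta"],
               "metagenome")
})
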