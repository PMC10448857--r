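test_that("neighborhood windows follow the +/-3250 bp rule with single-pass ORF extension", {
  set.seed(301)
  # linear genome, no boundary-crossing CDS: plain arithmetic
  feats <- gene_features("anchor", 10000L, 11000L, "+")
  g <- toy_genome(60000, circular = FALSE, features = feats)
  anchor <- data.frame(genome_id = "toy", gene_id = "anchor",
                       start = 10000L, end = 11000L)
  nb <- extract_neighborhood(anchor, g)
  expect_equal(nb$interval, c(6750, 14250))

  # a CDS overlapping the left window edge extends the interval to its start
  feats2 <- gene_features(c("anchor", "left"), c(10000L, 6500L),
                          c(11000L, 6900L), c("+", "+"))
  g2 <- toy_genome(60000, circular = FALSE, features = feats2)
  nb2 <- extract_neighborhood(anchor, g2)
  expect_equal(nb2$interval[1], 6500)
  expect_equal(nb2$interval[2], 14250)
  expect_true("left" %in% nb2$member_genes$gene_id)

  # extension is single-pass: a second CDS touching only the extended part
  # does not extend further, but is a member
  feats3 <- gene_features(c("anchor", "left", "far"),
                          c(10000L, 6500L, 6000L),
                          c(11000L, 6900L, 6600L), rep("+", 3))
  g3 <- toy_genome(60000, circular = FALSE, features = feats3)
  nb3 <- extract_neighborhood(anchor, g3)
  expect_equal(nb3$interval[1], 6500)
  expect_true("far" %in% nb3$member_genes$gene_id)
})

test_that("circular windows wrap the origin and match the modular construction", {
  set.seed(302)
  g <- toy_genome(10000, circular = TRUE,
                  features = gene_features("a", 100L, 400L, "+"))
  anchor <- data.frame(genome_id = "toy", gene_id = "a",
                       start = 100L, end = 400L)
  nb <- extract_neighborhood(anchor, g)
  # [100-3250, 400+3250) mod 10000 -> starts at 6850, wraps to 3650
  expect_equal(nb$interval[1], 6850)
  expect_equal(nb$interval[2] %% 10000, 3650)
  expect_equal(nb$interval[2] - nb$interval[1], 300 + 6500)
})

test_that("neighborhood extraction equals a brute-force doubled-sequence overlap scan", {
  set.seed(303)
  for (rep in 1:200) {
    L <- sample(8000:15000, 1)
    nf <- sample(5:25, 1)
    fs <- sort(sample(0:(L - 400), nf))
    fe <- pmin(fs + sample(200:2500, nf, TRUE), L + fs - 1)
    wraps <- fe > L
    feats <- gene_features(paste0("g", seq_len(nf)), fs,
                           ifelse(wraps, fe %% L, fe), rep("+", nf), wraps)
    g <- genome_record("t", strrep("A", L), circular = TRUE,
                       features = feats)
    ai <- sample(nf, 1)
    anchor <- data.frame(genome_id = "t", gene_id = paste0("g", ai),
                         start = fs[ai], end = min(fe[ai], fs[ai] + 900))
    nb <- extract_neighborhood(anchor, g)

    # oracle: place every feature on the doubled sequence and test overlap
    s0 <- anchor$start - 3250; e0 <- anchor$end + 3250
    ov_with <- function(s, e) {
      vapply(seq_len(nf), function(i) {
        any(vapply(c(-L, 0, L), function(d) {
          s < fe[i] + d && fs[i] + d < e
        }, logical(1)))
      }, logical(1))
    }
    ov0 <- ov_with(s0, e0)
    s1 <- s0; e1 <- e0
    for (i in which(ov0)) {
      for (d in c(-L, 0, L)) {
        if (s1 < fe[i] + d && fs[i] + d < e1) {
          s1 <- min(s1, fs[i] + d); e1 <- max(e1, fe[i] + d)
        }
      }
    }
    if (e1 - s1 > L) { s1 <- 0; e1 <- L }
    want <- sort(paste0("g", which(ov_with(s1, e1))))
    expect_identical(sort(nb$member_genes$gene_id), want)
    expect_equal(nb$interval[2] - nb$interval[1], e1 - s1)
  }
})

test_that("window property holds: the initial +/-3250 window is always contained", {
  set.seed(304)
  for (rep in 1:50) {
    L <- sample(20000:40000, 1)
    s <- sample(5000:(L - 6000), 1)
    feats <- gene_features(c("a", "x"), c(s, s - 4000L),
                           c(s + 1000L, s - 2000L), c("+", "+"))
    g <- genome_record("t", strrep("A", L), circular = TRUE, features = feats)
    anchor <- data.frame(genome_id = "t", gene_id = "a", start = s,
                         end = s + 1000L)
    nb <- extract_neighborhood(anchor, g)
    # extension never shrinks the initial window
    expect_equal(nb$interval[1], s - 4000)        # extended to the ORF start
    expect_equal(nb$interval[2], s + 1000 + 3250)
    expect_gte(nb$interval[2] - nb$interval[1], 1000 + 6500)
  }
})

test_that("linear and circular extraction agree for interior anchors", {
  set.seed(305)
  L <- 60000
  feats <- gene_features(c("a", "b", "c"), c(25000L, 21000L, 29500L),
                         c(26000L, 22500L, 30500L), rep("+", 3))
  anchor <- data.frame(genome_id = "t", gene_id = "a", start = 25000L,
                       end = 26000L)
  seqs <- strrep("A", L)
  g_lin <- genome_record("t", seqs, circular = FALSE, features = feats)
  g_circ <- genome_record("t", seqs, circular = TRUE, features = feats)
  nb_l <- extract_neighborhood(anchor, g_lin)
  nb_c <- extract_neighborhood(anchor, g_circ)
  expect_equal(nb_l$interval, nb_c$interval)
  expect_identical(nb_l$member_genes$gene_id, nb_c$member_genes$gene_id)
})

test_that("marker classification applies the 0.1 annotation cutoff exactly", {
  set.seed(306)
  feats <- gene_features(c("h", "t"), c(10000L, 12000L), c(10900L, 13200L),
                         c("+", "+"))
  g <- toy_genome(30000, features = feats)
  anchor <- data.frame(genome_id = "toy", gene_id = "h", start = 10000L,
                       end = 10900L)
  nb <- extract_neighborhood(anchor, g)
  hit_at <- function(ev) domain_hits("toy|t", "Terminase_6", "PF03237",
                                     5L, 300L, ev, 20)
  nb1 <- classify_markers(nb, hit_at(0.09))
  expect_true("terminase" %in% nb1$markers)
  nb2 <- classify_markers(nb, hit_at(0.1))
  expect_true("terminase" %in% nb2$markers)     # maximum e-value cutoff
  nb3 <- classify_markers(nb, hit_at(0.11))
  expect_false("terminase" %in% nb3$markers)
})

test_that("a neighborhood with RNR plus a second HEG reports both", {
  set.seed(307)
  feats <- gene_features(c("h", "nrdA", "h2"),
                         c(10000L, 11500L, 13000L),
                         c(10900L, 12900L, 13900L), rep("+", 3))
  g <- toy_genome(30000, features = feats)
  hits <- rbind(
    domain_hits("toy|h", "T5orf172", "PF10544", 10L, 100L, 1e-12, 50),
    domain_hits("toy|nrdA", "Ribonuc_red_lgN", "PF00317", 5L, 400L, 1e-20, 80),
    domain_hits("toy|h2", "HNH_3", "PF13392", 10L, 90L, 1e-9, 45))
  calls <- call_hegs(list(g), hits)
  anchor <- calls[calls$gene_id == "h", ]
  nb <- classify_markers(extract_neighborhood(anchor, g), hits, calls)
  expect_identical(nb$markers, "RNR")
  expect_equal(nrow(nb$other_hegs), 1)
  expect_equal(nb$other_hegs$gene_id, "h2")
})

test_that("enrichment summaries report exact per-marker fractions", {
  set.seed(308)
  mk_nb <- function(markers) {
    structure(list(anchor = data.frame(gene_id = "h"), genome_id = "g1",
                   interval = c(0, 100), member_genes = gene_features(),
                   markers = markers, other_hegs = NULL),
              class = "neighborhood")
  }
  nbs <- list(mk_nb("terminase"), mk_nb(character()), mk_nb(character()),
              mk_nb(character()))
  sm <- summarize_enrichment(nbs)
  expect_equal(sm$per_marker$fraction[sm$per_marker$marker == "terminase"],
               0.25)
  expect_true(all(sm$per_marker$fraction[sm$per_marker$marker != "terminase"]
                  == 0))
  expect_error(summarize_enrichment(list()), "no neighborhoods")

  # fractions on a simulated community equal truth-derived fractions
  p <- sim_params(rng_seed = 31, n_genomes = 3)
  com <- simulate_community(p)
  calls <- call_hegs(com$genomes, com$hits)
  nbhds <- extract_all_neighborhoods(com$genomes, calls, com$hits)
  sm2 <- summarize_enrichment(nbhds)
  # recompute independently from the genomes' marker gene positions
  mk_map <- marker_accessions()
  frac_truth <- vapply(names(mk_map), function(mk) {
    hitset <- com$hits[com$hits$domain_acc %in% mk_map[[mk]] &
                         com$hits$i_evalue <= 0.1, ]
    got <- vapply(nbhds, function(nb) {
      any(paste0(nb$genome_id, "|", nb$member_genes$gene_id) %in%
            hitset$protein_id)
    }, logical(1))
    mean(got)
  }, numeric(1))
  expect_equal(sm2$per_marker$fraction, unname(frac_truth))
})
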