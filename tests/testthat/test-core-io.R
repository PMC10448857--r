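test_that("GenBank CDS locations map to 0-based half-open internal coordinates", {
  set.seed(101)
  seqs <- tolower(rand_seq(10000))
  lines <- vapply(seq(1, 10000, 60), function(i) substr(seqs, i, min(i + 59, 10000)),
                  character(1))
  gb <- c(
    "LOCUS       test1                  10000 bp    DNA     circular PHG 01-JAN-2020",
    "DEFINITION  synthetic fixture.",
    "FEATURES             Location/Qualifiers",
    "     source          1..10000",
    "     CDS             101..403",
    "                     /locus_tag=\"geneA\"",
    "                     /product=\"test product\"",
    "                     /translation=\"MKLV",
    "                     PQRS\"",
    "     CDS             complement(501..802)",
    "                     /locus_tag=\"geneB\"",
    "     CDS             join(9001..10000,1..300)",
    "                     /locus_tag=\"geneC\"",
    "ORIGIN",
    paste0("  ", lines), "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)

  recs <- read_genome_records(path, "genbank")
  expect_length(recs, 1)
  g <- recs[[1]]
  expect_true(g$circular)
  expect_equal(g$length, 10000)
  f <- g$features
  expect_equal(f$start[f$gene_id == "geneA"], 100)
  expect_equal(f$end[f$gene_id == "geneA"], 403)
  expect_equal(f$strand[f$gene_id == "geneB"], "-")
  expect_equal(f$product[f$gene_id == "geneA"], "test product")
  expect_equal(f$protein_seq[f$gene_id == "geneA"], "MKLVPQRS")
  # origin-spanning join: wraps, unwrapped length 1300
  gc <- f[f$gene_id == "geneC", ]
  expect_true(gc$wraps_origin)
  expect_equal(interval_length(gc$start, gc$end, g$length, TRUE), 1300)
})

test_that("FASTA yields feature-less records and GFF3 features attach to them", {
  path <- withr::local_tempfile(fileext = ".fa")
  set.seed(102)
  writeLines(c(">contig1 a 500 bp contig", rand_seq(500)), path)
  recs <- read_genome_records(path, "fasta")
  expect_length(recs, 1)
  expect_equal(recs[[1]]$id, "contig1")
  expect_equal(recs[[1]]$length, 500)
  expect_equal(nrow(recs[[1]]$features), 0)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "contig1\tsim\tCDS\t11\t100\t.\t+\t0\tID=gene1",
               "contig1\tsim\tCDS\t151\t300\t.\t-\t0\tID=gene2"), gff)
  recs2 <- read_genome_records(gff, "gff3", fasta_path = path)
  f <- recs2[[1]]$features
  expect_equal(f$start, c(10, 150))
  expect_equal(f$end, c(100, 300))
  expect_equal(f$strand, c("+", "-"))
})

test_that("missing and empty genome files raise parse errors", {
  expect_error(read_genome_records("/nonexistent/x.fa", "fasta"), "no such file")
  empty <- withr::local_tempfile(fileext = ".gb")
  writeLines(character(0), empty)
  expect_error(read_genome_records(empty, "genbank"), "empty")
})

test_that("domtblout reading maps envelope coordinates and i-Evalue, skipping comments", {
  hits <- domain_hits(
    protein_id = c("g1|p1", "g1|p2"), domain_name = c("T5orf172", "HNH_3"),
    domain_acc = c("PF10544", "PF13392"), aa_from = c(12L, 3L),
    aa_to = c(85L, 60L), i_evalue = c(4.2e-12, 1e-4), bit_score = c(88, 40))
  path <- withr::local_tempfile(fileext = ".domtblout")
  write_domtblout(hits, path)
  back <- read_domain_hits(path)
  expect_equal(nrow(back), 2)
  expect_equal(back$aa_from, hits$aa_from)
  expect_equal(back$aa_to, hits$aa_to)
  expect_equal(back$protein_id, hits$protein_id)
  expect_equal(back$domain_acc, hits$domain_acc)
  expect_equal(back$i_evalue, hits$i_evalue, tolerance = 1e-2)

  bad <- withr::local_tempfile()
  writeLines(c("# comment", "too few fields here"), bad)
  expect_error(read_domain_hits(bad), "line 2")
})

test_that("bedGraph expands per base, fills zeros, and later lines overwrite", {
  g <- genome_record("g1", strrep("A", 20))
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("g1\t0\t10\t5.0"), path)
  tr <- read_coverage_track(path, g)
  expect_equal(tr$depth[1:10], rep(5, 10))
  expect_equal(tr$depth[11:20], rep(0, 10))

  writeLines(c("g1\t0\t10\t5.0", "g1\t5\t12\t2.0"), path)
  tr2 <- read_coverage_track(path, g)
  expect_equal(tr2$depth[6:12], rep(2, 7))
  expect_equal(tr2$depth[1:5], rep(5, 5))

  writeLines(c("g1\t15\t25\t1.0"), path)
  expect_error(read_coverage_track(path, g), "outside genome")
})

test_that("coverage tracks round-trip through bedGraph", {
  set.seed(103)
  p <- sim_params(rng_seed = 103)
  sl <- generate_spliced_locus(p, n_introns = 2, seed = 103)
  tr <- simulate_rnaseq_coverage(sl$genome, sl$splice_truth, p, seed = 104)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, path)
  back <- read_coverage_track(path, sl$genome)
  expect_identical(back$depth, tr$depth)
})

test_that("results tables write deterministically and round-trip per schema", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(NULL, path, "heg_calls")
  ln <- readLines(path)
  expect_length(ln, 1)    # header-only for an empty list
  expect_match(ln, "^genome_id\t")

  calls <- data.frame(genome_id = c("a", "b"), gene_id = c("h1", "h2"),
                      family = "T5orf172", allele_state = "intact",
                      nuclease_acc = "PF10544", evalue = c(1e-10, 2e-8),
                      start = c(10L, 20L), end = c(900L, 950L),
                      strand = "+")
  write_results_table(calls, path, "heg_calls")
  expect_length(readLines(path), 3)
  back <- read_results_table(path, "heg_calls")
  expect_equal(back$gene_id, calls$gene_id)
  expect_equal(back$start, calls$start)

  expect_error(write_results_table(calls, path, "nonsense"), "unknown schema")
})

test_that("FASTA, GFF3 and truth-JSON emitters round-trip a simulated genome", {
  p <- sim_params(rng_seed = 106, n_genomes = 2)
  com <- simulate_community(p)
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  tj <- withr::local_tempfile(fileext = ".json")
  write_genome_fasta(com$genomes, fa)
  g1 <- com$genomes[[1]]
  write_features_gff3(g1, gff)
  back <- read_genome_records(gff, "gff3", fasta_path = fa, circular = TRUE)
  b1 <- back[[which(vapply(back, `[[`, "", "id") == g1$id)]]
  expect_identical(b1$sequence, g1$sequence)
  nw <- !g1$features$wraps_origin
  expect_identical(b1$features$gene_id, g1$features$gene_id[nw])
  expect_identical(b1$features$start[nw], g1$features$start[nw])

  write_truth_json(com$truth, tj)
  tr <- read_truth_json(tj)
  expect_equal(tr$heg_truth$allele_state, com$truth$heg_truth$allele_state)
  expect_equal(tr$locus_map$start, com$truth$locus_map$start)
})

test_that("coordinate conversion 1-based inclusive <-> internal is the identity", {
  set.seed(105)
  for (i in 1:200) {
    L <- sample(1000:100000, 1)
    s1 <- sample(L, 1); e1 <- sample(s1:L, 1)    # 1-based inclusive
    s0 <- s1 - 1L; e0 <- e1                      # internal half-open
    expect_identical(c(s0 + 1L, e0), c(s1, e1))
    expect_equal(e0 - s0, e1 - s1 + 1)
  }
})
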