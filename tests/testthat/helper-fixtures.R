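# shared fixture builders; everything is generated in code, no stored data

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, TRUE), collapse = "")
}

# substitute exactly n_sub positions (never to the same base)
substitute_n <- function(seq, n_sub) {
  ch <- strsplit(seq, "")[[1]]
  idx <- sample(length(ch), n_sub)
  for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# a pair of sequences sharing a diverged core in random flanks
divergent_pair <- function(core_len, divergence, flank_max = 300) {
  core <- rand_seq(core_len)
  core_b <- substitute_n(core, round(divergence * core_len))
  list(a = paste0(rand_seq(sample(50:flank_max, 1)), core,
                  rand_seq(sample(50:flank_max, 1))),
       b = paste0(rand_seq(sample(50:flank_max, 1)), core_b,
                  rand_seq(sample(50:flank_max, 1))),
       core = core, core_b = core_b)
}

# independent Smith-Waterman oracle (Biostrings dynamic programming) under
# the same scoring system as the block engine
sw_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
sw_local <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = sw_mat,
    gapOpening = 5, gapExtension = 2)
  list(score = Biostrings::score(aln),
       q = c(Biostrings::start(Biostrings::pattern(aln)) - 1L,
             Biostrings::end(Biostrings::pattern(aln))),
       s = c(Biostrings::start(Biostrings::subject(aln)) - 1L,
             Biostrings::end(Biostrings::subject(aln))),
       nmatch = Biostrings::nmatch(aln),
       width = Biostrings::nchar(aln))
}

# small genome with explicit features for neighborhood tests
toy_genome <- function(L = 60000, circular = FALSE, features = NULL,
                       id = "toy") {
  genome_record(id, rand_seq(L), circular = circular, features = features)
}

# one island pair fixture (unrelated genomes + implanted shared cargo)
island_fixture <- function(seed, cargo_len = 12000, divergence = 0.02,
                           swap = FALSE) {
  p <- sim_params(rng_seed = seed)
  d <- generate_genome(p, genome_id = "donor", seed = seed * 2 + 1)
  r <- generate_genome(p, genome_id = "recip", seed = seed * 2 + 2)
  impl <- implant_shared_island(d, r, cargo_len_bp = cargo_len,
                                divergence = divergence, swap_flank = swap,
                                seed = seed * 2 + 3)
  genomes <- list(donor = impl$donor$genome, recip = impl$recipient$genome)
  hits <- rbind(impl$donor$hits, impl$recipient$hits)
  calls <- call_hegs(genomes, hits)
  list(genomes = genomes, hits = hits, calls = calls,
       truth = impl$island_truth)
}
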