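#' Simulation parameters
#'
#' Parameters of the synthetic phage-community generator. The generator
#' emulates the statistical structure the analysis assumes: clusters of
#' related genomes sharing gene content at homologous loci, HEG alleles
#' subject to frameshift / in-frame deletion / clean loss, degenerate
#' intragenic repeats inside DNA-binding regions, intron-fragmented genes
#' with depressed intronic read coverage, and integrated satellite elements
#' flanked by attachment-site repeats.
#'
#' @param n_genomes genomes per community.
#' @param genome_len_bp replicon length (default 60000).
#' @param gc_fraction background GC content (default 0.42).
#' @param n_hegs_per_genome HEG loci per genome.
#' @param island_divergence per-base substitution probability applied to
#'   shared island cargo (default 0.02).
#' @param bg_divergence per-base substitution probability applied to
#'   non-HEG sequence when deriving a genome from a community template
#'   (default 0.01; set 0 for mutation-free communities).
#' @param frameshift_prob,inframe_del_prob,absent_prob HEG allele-state
#'   probabilities (remainder = intact).
#' @param repeat_len_bp,repeat_spacing_bp,repeat_divergence designed
#'   degenerate repeats in T5orf172 DNA-binding regions: length, start-to-
#'   start spacing (default 228, in frame) and per-base divergence of the
#'   second copy.
#' @param intron_len_bp intron length for fragmented genes (default 400).
#' @param exon_depth_mean,intron_depth_mean,depth_dispersion negative-
#'   binomial coverage: means over exonic/flanking vs intronic bases, and
#'   the NB size parameter (size -> Inf recovers Poisson; default 0.3,
#'   i.e. strongly overdispersed).
#' @param att_len_bp attachment-site repeat length (default 20).
#' @param circular simulate circular replicons (default TRUE).
#' @param rng_seed mandatory integer seed; identical params + seed give
#'   identical output.
#' @return named list of class `sim_params`.
#' @export
sim_params <- function(n_genomes = 6, genome_len_bp = 60000,
                       gc_fraction = 0.42, n_hegs_per_genome = 4,
                       island_divergence = 0.02, bg_divergence = 0.01,
                       frameshift_prob = 0.15, inframe_del_prob = 0.15,
                       absent_prob = 0.15, repeat_len_bp = 90,
                       repeat_spacing_bp = 228, repeat_divergence = 0.15,
                       intron_len_bp = 400, exon_depth_mean = 100,
                       intron_depth_mean = 5, depth_dispersion = 0.3,
                       att_len_bp = 20, circular = TRUE, rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory")
  p <- as.list(environment())
  probs <- c(p$frameshift_prob, p$inframe_del_prob, p$absent_prob,
             p$island_divergence, p$bg_divergence, p$repeat_divergence)
  stopifnot(all(probs >= 0), all(probs <= 1),
            p$frameshift_prob + p$inframe_del_prob + p$absent_prob <= 1)
  structure(p, class = "sim_params")
}

NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                    c("A","C","G","T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

rand_dna <- function(n, gc = 0.42) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random CDS: ATG + n_codons sense codons + TAA
rand_cds <- function(n_codons) {
  paste0("ATG", paste(sample(NONSTOP_CODONS, n_codons, TRUE), collapse = ""),
         "TAA")
}

rand_evalue <- function(n = 1, lo = -30, hi = -6) 10^stats::runif(n, lo, hi)

# substitute each base independently with probability p; returns seq and count
mutate_seq <- function(seq, p) {
  if (p <= 0 || !nzchar(seq)) return(list(seq = seq, n_sub = 0L))
  ch <- strsplit(seq, "")[[1]]
  idx <- which(stats::runif(length(ch)) < p & ch %in% c("A", "C", "G", "T"))
  for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  list(seq = paste(ch, collapse = ""), n_sub = length(idx))
}

# mutate but repair any premature in-frame stop codon created
mutate_keep_orf <- function(seq, p) {
  s <- mutate_seq(seq, p)$seq
  ch <- strsplit(s, "")[[1]]
  n_codon <- length(ch) %/% 3
  if (n_codon > 2) {
    for (ci in 2:(n_codon - 1)) {
      cd <- paste(ch[(3 * ci - 2):(3 * ci)], collapse = "")
      if (cd %in% c("TAA", "TAG", "TGA")) {
        ch[3 * ci] <- "C"     # TAA->TAC, TAG->TAC(via G->C? keep simple), TGA->TGC
      }
    }
  }
  paste(ch, collapse = "")
}

# ---------------------------------------------------------------------------
# segment-based genome designs
# ---------------------------------------------------------------------------

new_seg <- function(type, name, seq, genes = NULL, hits = NULL, extra = list()) {
  list(type = type, name = name, seq = seq,
       genes = if (is.null(genes)) gene_features() else genes,
       hits = if (is.null(hits)) domain_hits() else hits, extra = extra)
}

seg_gene <- function(name, seq, product = "", strand = "+",
                     accs = character(), names_ = character(),
                     aa_from = integer(), aa_to = integer(),
                     evalues = numeric()) {
  prot <- translate_cds(if (strand == "-") revcomp(seq) else seq)
  genes <- gene_features(name, 0L, nchar(seq), strand, FALSE, product, prot)
  hits <- if (length(accs)) {
    domain_hits(rep(name, length(accs)), names_, accs, aa_from, aa_to,
                evalues, 50 + 10 * abs(log10(evalues)))
  } else domain_hits()
  new_seg("gene", name, seq, genes, hits)
}

marker_domain_table <- function() {
  list(terminase = c("PF03237", "Terminase_6"),
       capsid    = c("PF05065", "Phage_capsid"),
       TMP       = c("PF10145", "TMP_repeat"),
       RNR       = c("PF00317", "Ribonuc_red_lgN"),
       replicase = c("PF00476", "DNA_pol_A"))
}

make_marker_seg <- function(marker, name, n_codons) {
  md <- marker_domain_table()[[marker]]
  seq <- rand_cds(n_codons)
  plen <- n_codons + 1
  seg_gene(name, seq, product = marker, accs = md[1], names_ = md[2],
           aa_from = 5L, aa_to = as.integer(plen - 5L),
           evalues = rand_evalue())
}

make_filler_seg <- function(name, params) {
  n_codons <- sample(180:380, 1)
  seq <- rand_cds(n_codons)
  strand <- sample(c("+", "-"), 1)
  if (strand == "-") seq <- revcomp(seq)
  sg <- seg_gene(name, seq, product = "hypothetical protein", strand = strand)
  # occasional decoy nuclease hit above the calling threshold
  if (stats::runif(1) < 0.3) {
    sg$hits <- domain_hits(name, "HNH_3", "PF13392", 10L, 60L,
                           rand_evalue(1, -2, 0), 8)
  }
  sg
}

spacer_seg <- function(params, len = sample(150:400, 1)) {
  new_seg("spacer", "", rand_dna(len, params$gc_fraction))
}

# family -> nuclease/DBD design of a HEG gene
heg_family_design <- function(family) {
  switch(family,
    "T5orf172" = list(nuc_acc = "PF10544", nuc_name = "T5orf172",
                      nuc_end = "C", dbd = "repeats"),
    "T5orf172-MUG113" = list(nuc_acc = "PF13455", nuc_name = "MUG113",
                             nuc_end = "C", dbd = "repeats"),
    "IPA-HNH" = list(nuc_acc = "PF13392", nuc_name = "HNH_3",
                     nuc_end = "N", dbd = "AP2"),
    "HNH-3" = list(nuc_acc = "PF13392", nuc_name = "HNH_3",
                   nuc_end = "C", dbd = "DUF723"),
    "LAGLIDADG" = list(nuc_acc = "PF00961", nuc_name = "LAGLIDADG_1",
                       nuc_end = "C", dbd = "DUF723"),
    "GIY-YIG" = list(nuc_acc = "PF01541", nuc_name = "GIY-YIG",
                     nuc_end = "C", dbd = "DUF723"),
    "PD-(D/E)XK" = list(nuc_acc = "PF12705", nuc_name = "PDDEXK_1",
                        nuc_end = "C", dbd = "DUF723"),
    stop("unknown HEG family: ", family))
}

# Design an intact HEG gene. Layout for nuc_end == "C" (coordinates are
# CDS-local nt, 0-based):
#   [ATG 0-3)[DBD region 3-453) incl. two degenerate repeats][linker 453-543)
#   [nuclease domain 543-873)[tail 873-900)[TAA 900-903)
# For nuc_end == "N" the nuclease domain occupies the N-terminal region and
# the DBD the C-terminal one.
design_heg_gene <- function(locus, family, params) {
  fd <- heg_family_design(family)
  rep_len <- params$repeat_len_bp
  spacing <- params$repeat_spacing_bp

  n_codons <- 300
  body <- strsplit(rand_cds(n_codons - 1), "")[[1]]  # 903 nt incl ATG/TAA
  cds_len <- length(body)

  repeats <- NULL
  if (fd$dbd == "repeats") {
    # two in-frame degenerate repeats within the DBD region
    r1s <- 63L
    r1 <- rand_cds(rep_len / 3 - 1)
    r1 <- substr(r1, 4, 3 + rep_len)      # sense codons only, length rep_len
    r2 <- mutate_keep_orf(r1, params$repeat_divergence)
    body[(r1s + 1):(r1s + rep_len)] <- strsplit(r1, "")[[1]]
    r2s <- r1s + spacing
    body[(r2s + 1):(r2s + rep_len)] <- strsplit(r2, "")[[1]]
    repeats <- data.frame(r1_start = r1s, r1_end = r1s + rep_len,
                          r2_start = r2s, r2_end = r2s + rep_len,
                          spacing_bp = spacing)
  }
  seq <- paste(body, collapse = "")
  plen <- (cds_len - 3) / 3

  if (fd$nuc_end == "C") {
    nuc_aa <- c(182L, 291L)
    dbd_aa <- c(2L, 151L)
  } else {
    nuc_aa <- c(10L, 110L)
    dbd_aa <- c(180L, as.integer(plen - 5L))
  }
  accs <- fd$nuc_acc; nm <- fd$nuc_name
  aa_f <- nuc_aa[1]; aa_t <- nuc_aa[2]
  ev <- rand_evalue()
  if (fd$dbd == "repeats") {
    # one CapR Zn-finger hit per repeat copy
    for (k in 1:2) {
      rs <- repeats[[paste0("r", k, "_start")]]
      accs <- c(accs, "CapR"); nm <- c(nm, "CapR")
      aa_f <- c(aa_f, as.integer(rs / 3 + 1))
      aa_t <- c(aa_t, as.integer((rs + rep_len) / 3))
      ev <- c(ev, rand_evalue(1, -20, -11))
    }
  } else if (fd$dbd == "AP2") {
    accs <- c(accs, "PF00847"); nm <- c(nm, "AP2")
    aa_f <- c(aa_f, dbd_aa[1]); aa_t <- c(aa_t, dbd_aa[2])
    ev <- c(ev, rand_evalue())
  } else if (fd$dbd == "DUF723") {
    accs <- c(accs, "PF05265"); nm <- c(nm, "DUF723")
    aa_f <- c(aa_f, dbd_aa[1]); aa_t <- c(aa_t, dbd_aa[2])
    ev <- c(ev, rand_evalue(1, -8, -4))
  }
  list(locus = locus, family = family, seq = seq, cds_len = cds_len,
       nuc_end = fd$nuc_end, repeats = repeats,
       hit_tab = data.frame(acc = accs, name = nm, aa_from = aa_f,
                            aa_to = aa_t, evalue = ev,
                            stringsAsFactors = FALSE),
       linker = if (fd$nuc_end == "C") c(453L, 543L) else c(345L, 525L))
}

# realize one allele of a designed HEG gene as a segment
realize_heg_seg <- function(design, state, params) {
  locus <- design$locus
  truth_family <- if (design$family == "T5orf172-MUG113") "T5orf172" else design$family
  if (state == "absent") {
    sg <- new_seg("heg_locus", locus, "",
                  extra = list(locus = locus, family = truth_family,
                               state = "absent"))
    return(sg)
  }
  if (state == "intact") {
    ht <- design$hit_tab
    sg <- seg_gene(locus, design$seq, product = "homing endonuclease",
                   accs = ht$acc, names_ = ht$name, aa_from = ht$aa_from,
                   aa_to = ht$aa_to, evalues = ht$evalue)
    sg$type <- "heg_locus"
    sg$extra <- list(locus = locus, family = truth_family, state = "intact",
                     repeats = design$repeats)
    return(sg)
  }
  if (state == "inframe_deletion") {
    if (is.null(design$repeats)) state <- "frameshifted"  # no repeat substrate
  }
  if (state == "inframe_deletion") {
    r <- design$repeats
    seq <- paste0(substr(design$seq, 1, r$r1_start),
                  substr(design$seq, r$r2_start + 1, design$cds_len))
    ht <- design$hit_tab
    # drop hits inside the deleted interval; shift hits past it by the
    # deleted codons
    del_aa <- r$spacing_bp / 3
    nt_from <- 3 * (ht$aa_from - 1); nt_to <- 3 * ht$aa_to
    drop <- nt_from >= r$r1_start & nt_to <= r$r2_start
    ht <- ht[!drop, , drop = FALSE]
    shift <- 3 * (ht$aa_from - 1) >= r$r2_start
    ht$aa_from[shift] <- ht$aa_from[shift] - del_aa
    ht$aa_to[shift] <- ht$aa_to[shift] - del_aa
    sg <- seg_gene(locus, seq, product = "homing endonuclease",
                   accs = ht$acc, names_ = ht$name, aa_from = ht$aa_from,
                   aa_to = ht$aa_to, evalues = ht$evalue)
    sg$type <- "heg_locus"
    sg$extra <- list(locus = locus, family = truth_family,
                     state = "inframe_deletion", del_bp = r$spacing_bp)
    return(sg)
  }
  # frameshifted: 1-bp insertion in the linker splits the gene into two CDSs
  lk <- design$linker
  fs_at <- sample(seq(lk[1] + 6L, lk[2] - 6L), 1)
  ins <- sample(c("A", "C", "G", "T"), 1)
  seq <- paste0(substr(design$seq, 1, fs_at), ins,
                substr(design$seq, fs_at + 1, design$cds_len))
  end_a <- 3L * (fs_at %/% 3L)          # fragment A ends at the codon boundary
  ht <- design$hit_tab
  in_a <- ht$aa_to <= end_a / 3
  ha <- ht[in_a, , drop = FALSE]
  hb <- ht[!in_a, , drop = FALSE]
  # fragment B protein coordinates are relative to the fragment start
  off_aa <- as.integer(end_a / 3)
  hb$aa_from <- pmax(1L, hb$aa_from - off_aa)
  hb$aa_to <- hb$aa_to - off_aa
  ga <- paste0(locus, "_a"); gb <- paste0(locus, "_b")
  genes <- gene_features(c(ga, gb), c(0L, end_a),
                         c(end_a, nchar(seq)), c("+", "+"), c(FALSE, FALSE),
                         rep("homing endonuclease fragment", 2),
                         c(translate_cds(substr(seq, 1, end_a)), NA))
  hits <- rbind(
    if (nrow(ha)) domain_hits(rep(ga, nrow(ha)), ha$name, ha$acc, ha$aa_from,
                              ha$aa_to, ha$evalue, 40) else domain_hits(),
    if (nrow(hb)) domain_hits(rep(gb, nrow(hb)), hb$name, hb$acc, hb$aa_from,
                              hb$aa_to, hb$evalue, 40) else domain_hits())
  sg <- new_seg("heg_locus", locus, seq, genes, hits,
                extra = list(locus = locus, family = truth_family,
                             state = "frameshifted",
                             repeats = design$repeats))
  sg
}

default_heg_families <- function(n) {
  rep(c("T5orf172", "IPA-HNH", "T5orf172-MUG113", "HNH-3", "LAGLIDADG",
        "GIY-YIG"), length.out = n)
}

# template layout: segment skeleton shared by all genomes of a community
design_template <- function(params) {
  n_heg <- params$n_hegs_per_genome
  markers <- list(c("terminase", 400), c("capsid", 350), c("TMP", 500),
                  c("RNR", 400), c("replicase", 400))
  fams <- default_heg_families(n_heg)
  heg_designs <- lapply(seq_len(n_heg), function(i) {
    design_heg_gene(paste0("heg", i), fams[i], params)
  })
  segs <- list()
  push <- function(x) segs[[length(segs) + 1L]] <<- x
  mi <- 1L; hi <- 1L; fi <- 1L
  while (mi <= length(markers) || hi <= n_heg) {
    push(spacer_seg(params))
    if (mi <= length(markers)) {
      push(make_marker_seg(markers[[mi]][1],
                           paste0("mk_", markers[[mi]][1]),
                           as.integer(markers[[mi]][2])))
      mi <- mi + 1L
    }
    push(spacer_seg(params))
    if (hi <= n_heg) {
      push(new_seg("heg_slot", paste0("heg", hi), "",
                   extra = list(design = heg_designs[[hi]])))
      hi <- hi + 1L
    }
  }
  # filler genes up to ~genome_len - 16 kb, then one flexible background pad
  used <- sum(vapply(segs, function(s) {
    if (s$type == "heg_slot") s$extra$design$cds_len else nchar(s$seq)
  }, numeric(1)))
  target <- params$genome_len_bp - 16000
  while (used < target) {
    push(spacer_seg(params))
    f <- make_filler_seg(paste0("orf", fi), params)
    fi <- fi + 1L
    push(f)
    used <- used + nchar(f$seq) + 300
  }
  pad <- max(params$genome_len_bp - used - 400, 2000)
  push(new_seg("flex", "flex", rand_dna(pad, params$gc_fraction)))
  list(segs = segs, heg_designs = heg_designs, params = params)
}

# draw an allele state from the configured probabilities
draw_allele_state <- function(params) {
  u <- stats::runif(1)
  if (u < params$frameshift_prob) "frameshifted"
  else if (u < params$frameshift_prob + params$inframe_del_prob) "inframe_deletion"
  else if (u < params$frameshift_prob + params$inframe_del_prob +
             params$absent_prob) "absent"
  else "intact"
}

#' Generate one synthetic phage genome
#'
#' Without a template, designs a fresh genome: background sequence at the
#' configured GC fraction, a gene grid of essential markers (terminase,
#' capsid, TMP, RNR, replicase), HEG loci whose DNA-binding regions carry
#' designed degenerate repeats, and filler ORFs (some carrying decoy domain
#' hits above the calling threshold). With a template (a previous result of
#' this function), derives a related genome: shared gene content and
#' near-identical sequence (background substitution rate `bg_divergence`),
#' with each HEG allele independently redrawn as intact / frameshifted
#' (1-bp insertion splitting the CDS) / in-frame deleted (excision between
#' the direct-repeat starts) / absent (clean excision).
#'
#' @param params [sim_params()].
#' @param template optional previous `generate_genome()` result to derive
#'   from.
#' @param genome_id replicon id.
#' @param seed RNG seed for this genome (defaults to `params$rng_seed`).
#' @return list with `genome` ([genome_record()]), `hits` (domain-hits table
#'   with `protein_id = "<genome>|<gene>"`), `truth` (per-locus allele
#'   states, repeat intervals, locus map), and `design` (for deriving
#'   further genomes).
#' @export
generate_genome <- function(params, template = NULL, genome_id = "sim_g1",
                            seed = params$rng_seed) {
  set.seed(seed)
  if (is.null(template)) {
    tpl <- design_template(params)
    all_intact <- TRUE
  } else {
    tpl <- template$design
    all_intact <- FALSE
  }
  min_needed <- 3000 + 903 * params$n_hegs_per_genome
  if (params$genome_len_bp < min_needed) {
    stop("genome_len_bp too short to host the requested genes (need >= ",
         min_needed, ")")
  }

  segs <- list()
  for (s in tpl$segs) {
    if (s$type == "heg_slot") {
      state <- if (all_intact) "intact" else draw_allele_state(params)
      segs[[length(segs) + 1L]] <- realize_heg_seg(s$extra$design, state, params)
    } else if (is.null(template)) {
      segs[[length(segs) + 1L]] <- s
    } else {
      s2 <- s
      s2$seq <- if (nrow(s$genes)) mutate_keep_orf(s$seq, params$bg_divergence)
                else mutate_seq(s$seq, params$bg_divergence)$seq
      if (nrow(s2$genes)) {
        s2$genes$protein_seq <- vapply(seq_len(nrow(s2$genes)), function(i) {
          f <- s2$genes[i, ]
          cds <- substr(s2$seq, f$start + 1, f$end)
          translate_cds(if (f$strand == "-") revcomp(cds) else cds)
        }, character(1))
      }
      segs[[length(segs) + 1L]] <- s2
    }
  }
  materialize_design(segs, tpl, params, genome_id)
}

materialize_design <- function(segs, tpl, params, genome_id) {
  seqs <- character(length(segs))
  feats <- list(); hits <- list()
  heg_truth <- list(); repeat_truth <- list(); locus_map <- list()
  off <- 0L
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    seqs[i] <- s$seq
    if (nrow(s$genes)) {
      g <- s$genes
      g$start <- g$start + off
      g$end <- g$end + off
      feats[[length(feats) + 1L]] <- g
    }
    if (nrow(s$hits)) {
      h <- s$hits
      h$protein_id <- paste0(genome_id, "|", h$protein_id)
      hits[[length(hits) + 1L]] <- h
    }
    if (s$type == "heg_locus") {
      ex <- s$extra
      heg_truth[[length(heg_truth) + 1L]] <- data.frame(
        genome_id = genome_id, locus = ex$locus, family = ex$family,
        allele_state = ex$state, stringsAsFactors = FALSE)
      locus_map[[length(locus_map) + 1L]] <- data.frame(
        genome_id = genome_id, locus = ex$locus, start = off,
        end = off + nchar(s$seq), stringsAsFactors = FALSE)
      if (!is.null(ex$repeats) && ex$state %in% c("intact", "frameshifted")) {
        r <- ex$repeats
        repeat_truth[[length(repeat_truth) + 1L]] <- data.frame(
          genome_id = genome_id, gene_id = ex$locus,
          r1_start = r$r1_start, r1_end = r$r1_end, r2_start = r$r2_start,
          r2_end = r$r2_end, spacing_bp = r$spacing_bp,
          stringsAsFactors = FALSE)
      }
    }
    off <- off + nchar(s$seq)
  }
  features <- if (length(feats)) do.call(rbind, feats) else gene_features()
  genome <- genome_record(genome_id, paste(seqs, collapse = ""),
                          circular = params$circular, features = features,
                          source_tag = "simulated")
  list(genome = genome,
       hits = if (length(hits)) do.call(rbind, hits) else domain_hits(),
       truth = list(
         heg_truth = do.call(rbind, heg_truth),
         repeat_truth = if (length(repeat_truth)) do.call(rbind, repeat_truth)
                        else NULL,
         locus_map = do.call(rbind, locus_map)),
       design = list(segs = tpl$segs, heg_designs = tpl$heg_designs,
                     params = params),
       segs = segs)
}

#' Simulate a community of related phage genomes
#'
#' Designs a template genome, then derives `n_genomes` related genomes from
#' it with independently drawn HEG allele states and background divergence.
#'
#' @param params [sim_params()].
#' @return list of class `heg_community`: `genomes` (named list of genome
#'   records), `hits` (combined domain-hits table), `truth` (combined truth
#'   tables), `params`.
#' @export
simulate_community <- function(params) {
  set.seed(params$rng_seed)
  tpl <- generate_genome(params, genome_id = "template",
                         seed = params$rng_seed)
  genomes <- list(); hits <- list(); ht <- list(); rt <- list(); lm <- list()
  for (i in seq_len(params$n_genomes)) {
    gid <- sprintf("sim_g%d", i)
    gi <- generate_genome(params, template = tpl, genome_id = gid,
                          seed = (params$rng_seed + 7919L * i) %% 2147483647L)
    genomes[[gid]] <- gi$genome
    hits[[gid]] <- gi$hits
    ht[[gid]] <- gi$truth$heg_truth
    if (!is.null(gi$truth$repeat_truth)) rt[[gid]] <- gi$truth$repeat_truth
    lm[[gid]] <- gi$truth$locus_map
  }
  structure(list(
    genomes = genomes,
    hits = do.call(rbind, hits),
    truth = list(heg_truth = do.call(rbind, ht),
                 repeat_truth = if (length(rt)) do.call(rbind, rt) else NULL,
                 locus_map = do.call(rbind, lm)),
    params = params), class = "heg_community")
}

# ---------------------------------------------------------------------------
# shared HEG-islands
# ---------------------------------------------------------------------------

# cargo built from marker genes + fillers to the requested length
build_island_segs <- function(params, cargo_len_bp, flank_families) {
  segs <- list()
  push <- function(x) segs[[length(segs) + 1L]] <<- x
  dl <- design_heg_gene("islL", flank_families[1], params)
  dr <- design_heg_gene("islR", flank_families[2], params)
  push(realize_heg_seg(dl, "intact", params))
  push(spacer_seg(params, 200))
  cargo_used <- 200L
  cargo_markers <- list(c("capsid", 350), c("TMP", 500), c("RNR", 400))
  k <- 1L
  while (cargo_used < cargo_len_bp - 1400) {
    if (k <= length(cargo_markers)) {
      m <- cargo_markers[[k]]
      sg <- make_marker_seg(m[1], paste0("isl_mk_", m[1]),
                            as.integer(m[2]))
    } else {
      sg <- make_filler_seg(paste0("isl_orf", k), params)
    }
    k <- k + 1L
    push(sg)
    cargo_used <- cargo_used + nchar(sg$seq)
    sp <- spacer_seg(params, 200)
    push(sp)
    cargo_used <- cargo_used + 200L
  }
  rem <- cargo_len_bp - cargo_used
  if (rem > 0) push(spacer_seg(params, rem))
  push(realize_heg_seg(dr, "intact", params))
  segs
}

#' Implant a shared HEG-island into a recipient genome
#'
#' Builds (in the donor, if not already present) a cargo region of
#' `cargo_len_bp` containing marker genes, flanked on both ends by intact
#' HEG genes, then copies it into the recipient's flexible background
#' region. Each cargo base is substituted independently with probability
#' `divergence` in the recipient copy; the realized substitution count is
#' recorded in the truth entry. With `swap_flank = TRUE` the recipient's
#' flanking HEGs are replaced by freshly designed HEGs of different
#' families (modelling cognate-HEG turnover).
#'
#' @param donor,recipient results of [generate_genome()] (independent
#'   genomes; islands are meant to be detected between otherwise unrelated
#'   sequences).
#' @param cargo_len_bp cargo length (default 12000).
#' @param divergence per-base substitution probability in `[0, 0.4)`.
#' @param swap_flank replace recipient flanking HEG families.
#' @param seed RNG seed.
#' @return list with updated `donor`, `recipient` and `island_truth`
#'   (one-row data.frame with both cargo intervals, divergence, realized
#'   substitutions, flank families).
#' @export
implant_shared_island <- function(donor, recipient, cargo_len_bp = 12000,
                                  divergence = 0.02, swap_flank = FALSE,
                                  seed = NULL) {
  stopifnot(divergence >= 0, divergence < 0.4)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(donor$island_truth)) stop("donor already carries an island")
  params <- donor$design$params
  fam_d <- c("T5orf172", "HNH-3")
  isl <- build_island_segs(params, cargo_len_bp, fam_d)

  donor2 <- splice_island_into(donor, isl, params, prefix = "d_")
  # recipient copy: mutate cargo (all segments between the flank HEGs)
  isl_r <- isl
  n_sub <- 0L
  for (i in seq_along(isl_r)) {
    s <- isl_r[[i]]
    if (s$type == "heg_locus") next
    mut <- mutate_seq(s$seq, divergence)
    n_sub <- n_sub + mut$n_sub
    isl_r[[i]]$seq <- mut$seq
  }
  fam_r <- fam_d
  if (swap_flank) {
    fam_r <- c("LAGLIDADG", "PD-(D/E)XK")
    dl <- design_heg_gene("islL", fam_r[1], params)
    dr <- design_heg_gene("islR", fam_r[2], params)
    isl_r[[1]] <- realize_heg_seg(dl, "intact", params)
    isl_r[[length(isl_r)]] <- realize_heg_seg(dr, "intact", params)
  }
  recipient2 <- splice_island_into(recipient, isl_r, params, prefix = "r_")

  cargo_d <- attr(donor2, "island_interval")
  cargo_r <- attr(recipient2, "island_interval")
  truth <- data.frame(
    donor_id = donor2$genome$id, recipient_id = recipient2$genome$id,
    donor_start = cargo_d[1], donor_end = cargo_d[2],
    recipient_start = cargo_r[1], recipient_end = cargo_r[2],
    divergence = divergence, n_substitutions = n_sub,
    donor_left_family = fam_d[1], donor_right_family = fam_d[2],
    recipient_left_family = fam_r[1], recipient_right_family = fam_r[2],
    swap = swap_flank, stringsAsFactors = FALSE)
  donor2$island_truth <- truth
  recipient2$island_truth <- truth
  list(donor = donor2, recipient = recipient2, island_truth = truth)
}

# replace the flex segment with island segments; re-materialize
splice_island_into <- function(gres, isl, params, prefix = "") {
  segs <- gres$segs
  flex_at <- which(vapply(segs, function(s) s$type == "flex", logical(1)))
  if (!length(flex_at)) stop("genome has no flexible background region")
  flex_at <- flex_at[1]
  isl <- lapply(isl, function(s) {
    if (nzchar(s$name)) {
      s$name <- paste0(prefix, s$name)
      if (nrow(s$genes)) s$genes$gene_id <- paste0(prefix, s$genes$gene_id)
      if (nrow(s$hits)) s$hits$protein_id <- paste0(prefix, s$hits$protein_id)
      if (s$type == "heg_locus") s$extra$locus <- paste0(prefix, s$extra$locus)
    }
    s
  })
  flex_len <- nchar(segs[[flex_at]]$seq)
  isl_len <- sum(vapply(isl, function(s) nchar(s$seq), numeric(1)))
  rest <- max(flex_len - isl_len, 200)
  new_segs <- c(segs[seq_len(flex_at - 1L)], isl,
                list(new_seg("spacer", "", rand_dna(rest, params$gc_fraction))),
                if (flex_at < length(segs)) segs[(flex_at + 1L):length(segs)])
  res <- materialize_design(new_segs, gres$design, params, gres$genome$id)
  # cargo interval: between the end of the left flank HEG and the start of
  # the right flank HEG (the trimmed island interval)
  lm <- res$truth$locus_map
  li <- lm[lm$locus == paste0(prefix, "islL"), ]
  ri <- lm[lm$locus == paste0(prefix, "islR"), ]
  attr(res, "island_interval") <- c(li$end, ri$start)
  res
}

# ---------------------------------------------------------------------------
# intron-fragmented genes and coverage
# ---------------------------------------------------------------------------

#' Generate a genome carrying one intron-fragmented gene
#'
#' A full-length CDS (default 2400 nt, TMP-like) is interrupted by
#' `n_introns` introns of `intron_len_bp` random sequence. Each annotated
#' CDS fragment runs from its (possibly intronic) start codon to the first
#' in-frame stop inside the following intron, the way an annotation pipeline
#' would call the fragment ORFs; exon/intron truth records the true splice
#' intervals. Flanking filler genes surround the locus.
#'
#' @param params [sim_params()].
#' @param n_introns 1-3.
#' @param cds_len_nt length of the uninterrupted CDS (multiple of 3).
#' @param seed RNG seed.
#' @return list with `genome`, `splice_truth` (gene span, exon and intron
#'   intervals, fragment ids, the pre-fragmentation CDS), and `hits`.
#' @export
generate_spliced_locus <- function(params, n_introns = 1, cds_len_nt = 2400,
                                   seed = params$rng_seed) {
  set.seed(seed)
  stopifnot(n_introns >= 1, n_introns <= 3, cds_len_nt %% 3 == 0)
  full_cds <- rand_cds(cds_len_nt / 3 - 2)
  L <- params$intron_len_bp
  # split points strictly inside the CDS, well separated
  cuts <- sort(sample(seq(300, cds_len_nt - 300, by = 1), n_introns))
  while (n_introns > 1 && min(diff(cuts)) < 250) {
    cuts <- sort(sample(seq(300, cds_len_nt - 300, by = 1), n_introns))
  }
  introns <- replicate(n_introns, rand_dna(L, params$gc_fraction))

  upstream <- rand_dna(600, params$gc_fraction)
  flankA <- rand_cds(150)
  gap1 <- rand_dna(250, params$gc_fraction)
  pre <- paste0(upstream, flankA, gap1)
  gene_start <- nchar(pre)

  pieces <- character(2 * n_introns + 1)
  exon_iv <- matrix(0L, n_introns + 1, 2)
  intron_iv <- matrix(0L, n_introns, 2)
  pos <- gene_start
  prev <- 0L
  for (k in seq_len(n_introns)) {
    ex <- substr(full_cds, prev + 1, cuts[k])
    pieces[2 * k - 1] <- ex
    exon_iv[k, ] <- c(pos, pos + nchar(ex))
    pos <- pos + nchar(ex)
    pieces[2 * k] <- introns[k]
    intron_iv[k, ] <- c(pos, pos + L)
    pos <- pos + L
    prev <- cuts[k]
  }
  ex <- substr(full_cds, prev + 1, cds_len_nt)
  pieces[2 * n_introns + 1] <- ex
  exon_iv[n_introns + 1, ] <- c(pos, pos + nchar(ex))
  pos <- pos + nchar(ex)
  gene_end <- pos

  gap2 <- rand_dna(250, params$gc_fraction)
  flankB <- rand_cds(150)
  downstream <- rand_dna(600, params$gc_fraction)
  seq <- paste0(pre, paste(pieces, collapse = ""), gap2, flankB, downstream)

  # fragment ORFs: fragment k starts at exon k's reading position (exon 1:
  # the true start codon; later fragments: last in-frame ATG inside the
  # upstream intron) and ends at the first in-frame stop in the downstream
  # intron (last fragment: the true stop).
  frag_start <- integer(n_introns + 1)
  frag_end <- integer(n_introns + 1)
  chs <- strsplit(seq, "")[[1]]
  find_stop_after <- function(from, frame_anchor) {
    # first in-frame stop at or after `from`, frame anchored at frame_anchor
    i <- from + ((frame_anchor - from) %% 3)
    while (i + 2 <= length(chs)) {
      cd <- paste(chs[i:(i + 2)], collapse = "")
      if (cd %in% c("TAA", "TAG", "TGA")) return(i + 2L)
      i <- i + 3L
    }
    length(chs)
  }
  for (k in seq_len(n_introns + 1)) {
    es <- exon_iv[k, 1] + 1L   # 1-based
    if (k == 1) {
      frag_start[k] <- es
    } else {
      # scan backward from exon start for an in-frame ATG inside the intron
      is_ <- intron_iv[k - 1, 1] + 1L
      cand <- NA_integer_
      i <- es - 3L
      while (i >= is_) {
        if (paste(chs[i:(i + 2)], collapse = "") == "ATG") {
          # require no stop between candidate and exon start in this frame
          ok <- TRUE
          j <- i + 3L
          while (j < es) {
            if (paste(chs[j:(j + 2)], collapse = "") %in%
                c("TAA", "TAG", "TGA")) { ok <- FALSE; break }
            j <- j + 3L
          }
          if (ok) { cand <- i; break }
        }
        i <- i - 3L
      }
      if (is.na(cand)) {
        # plant one 12 bp before the exon start
        cand <- es - 12L
        chs[cand:(cand + 2)] <- c("A", "T", "G")
        j <- cand + 3L
        while (j < es) {
          if (paste(chs[j:(j + 2)], collapse = "") %in%
              c("TAA", "TAG", "TGA")) chs[j + 2] <- "C"
          j <- j + 3L
        }
      }
      frag_start[k] <- cand
    }
    ee <- exon_iv[k, 2]        # 0-based end == 1-based last base
    if (k == n_introns + 1) {
      frag_end[k] <- ee
    } else {
      frag_end[k] <- find_stop_after(ee + 1L, frag_start[k])
    }
  }
  seq <- paste(chs, collapse = "")

  gids <- paste0("tmp_f", seq_len(n_introns + 1))
  feats <- gene_features(
    c("flankA", gids, "flankB"),
    c(nchar(upstream), frag_start - 1L, gene_end + nchar(gap2)),
    c(nchar(upstream) + nchar(flankA), frag_end,
      gene_end + nchar(gap2) + nchar(flankB)),
    rep("+", n_introns + 3))
  genome <- genome_record("sim_splice", seq, circular = FALSE,
                          features = feats, source_tag = "simulated")
  gid <- genome$id
  md <- marker_domain_table()$TMP
  hits <- domain_hits(paste0(gid, "|", gids), rep(md[2], length(gids)),
                      rep(md[1], length(gids)), 2L,
                      pmax(3L, (frag_end - frag_start) %/% 3L - 1L),
                      rand_evalue(length(gids)), 60)
  list(genome = genome,
       splice_truth = list(
         gene_span = c(gene_start, gene_end),
         exons = exon_iv, introns = intron_iv, fragments = gids,
         full_cds = full_cds),
       hits = hits)
}

#' Simulate RNA-seq coverage over a spliced locus
#'
#' Per-base depth drawn from a negative binomial: mean `exon_depth_mean`
#' over exons and flanking genes (and intergenic background),
#' `intron_depth_mean` over introns, with a linear ramp of 5 bp at each
#' exon/intron boundary. `depth_dispersion` is the NB size parameter
#' (size -> Inf recovers Poisson).
#'
#' @param genome a `genome_record`.
#' @param splice_truth the `splice_truth` of [generate_spliced_locus()]
#'   (needs `introns`).
#' @param params [sim_params()].
#' @param seed RNG seed.
#' @return a `coverage_track`.
#' @export
simulate_rnaseq_coverage <- function(genome, splice_truth, params,
                                     seed = params$rng_seed) {
  set.seed(seed)
  L <- genome$length
  mu <- rep(params$exon_depth_mean, L)
  introns <- splice_truth$introns
  span <- splice_truth$gene_span
  for (k in seq_len(nrow(introns))) {
    s <- introns[k, 1]; e <- introns[k, 2]
    if (s < span[1] || e > span[2]) stop("intron outside gene span")
    mu[(s + 1):e] <- params$intron_depth_mean
    ramp <- seq(params$exon_depth_mean, params$intron_depth_mean, length.out = 5)
    mu[(s + 1):(s + 5)] <- ramp
    mu[(e - 4):e] <- rev(ramp)
  }
  size <- params$depth_dispersion
  depth <- if (is.infinite(size)) stats::rpois(L, mu)
           else stats::rnbinom(L, size = size, mu = mu)
  coverage_track(genome$id, depth)
}

#' Simulate spliced-read junction support
#'
#' Emits the junction-support table a spliced-read aligner would produce
#' over a fragmented gene: one row per true splice junction with a
#' negative-binomial read count (mean half the exonic depth, minimum 1).
#' This is the evidence [chain_exons()] snaps junction boundaries to.
#'
#' @param splice_truth the `splice_truth` of [generate_spliced_locus()].
#' @param params [sim_params()].
#' @param seed RNG seed.
#' @return data.frame with `pos_a` (intron start), `pos_b` (intron end),
#'   `n_reads`.
#' @export
simulate_junction_support <- function(splice_truth, params,
                                      seed = params$rng_seed) {
  set.seed(seed)
  introns <- splice_truth$introns
  n <- nrow(introns)
  size <- params$depth_dispersion
  mu <- params$exon_depth_mean / 2
  reads <- if (is.infinite(size)) stats::rpois(n, mu)
           else stats::rnbinom(n, size = size, mu = mu)
  data.frame(pos_a = introns[, 1], pos_b = introns[, 2],
             n_reads = pmax(reads, 1L))
}

# ---------------------------------------------------------------------------
# satellite loci
# ---------------------------------------------------------------------------

#' Generate a host contig with an integrated satellite element
#'
#' Implants a ~13 kb element into host background: identical attachment-site
#' repeats of `att_len_bp` at both bounds (direct orientation by default,
#' inverted on request), an integrase CDS within 2 kb of the left att site,
#' interior capsid/decoration/TMP-like marker genes and a RepA_N-tagged
#' replication gene. Also emits a homologous reference element contig
#' (element sequence at `ref_identity`) for the non-contiguous-homology
#' filter, and the RepA_N gene interval as the seed the boundary search
#' starts from.
#'
#' @param params [sim_params()].
#' @param element_len_bp target element length (inner-edge to inner-edge).
#' @param att_orientation `"direct"` or `"inverted"`.
#' @param integrase_class `"tyrosine"` or `"serine"`.
#' @param ref_identity per-base identity of the reference element (default
#'   0.95).
#' @param host_len_bp host contig length.
#' @param seed RNG seed.
#' @return list with `contig` (host `genome_record`), `reference`
#'   (reference-element `genome_record`), `hits`, `seed_interval` (RepA_N
#'   gene interval on the contig) and `truth` (element bounds = inner att
#'   edges, att intervals, orientation, integrase class).
#' @export
generate_satellite_locus <- function(params, element_len_bp = 13000,
                                     att_orientation = c("direct", "inverted"),
                                     integrase_class = c("tyrosine", "serine"),
                                     ref_identity = 0.95, host_len_bp = 45000,
                                     seed = params$rng_seed) {
  att_orientation <- match.arg(att_orientation)
  integrase_class <- match.arg(integrase_class)
  set.seed(seed)
  att <- rand_dna(params$att_len_bp, params$gc_fraction)
  attR_seq <- if (att_orientation == "direct") att else revcomp(att)

  int_acc <- if (integrase_class == "tyrosine") c("PF00589", "Phage_integrase")
             else c("PF00239", "Resolvase")
  segs <- list()
  push <- function(x) segs[[length(segs) + 1L]] <<- x
  push(seg_gene("sat_int", rand_cds(380), product = "integrase",
                accs = int_acc[1], names_ = int_acc[2], aa_from = 10L,
                aa_to = 350L, evalues = rand_evalue()))
  push(spacer_seg(params, 250))
  push(seg_gene("sat_repA", rand_cds(320), product = "replication initiator",
                accs = "PF06970", names_ = "RepA_N", aa_from = 5L, aa_to = 120L,
                evalues = rand_evalue()))
  push(spacer_seg(params, 200))
  interior <- list(c("capsid", 350), c("TMP", 450))
  for (m in interior) {
    push(make_marker_seg(m[1], paste0("sat_", m[1]), as.integer(m[2])))
    push(spacer_seg(params, 200))
  }
  push(seg_gene("sat_dec", rand_cds(180), product = "decoration protein"))
  used <- sum(vapply(segs, function(s) nchar(s$seq), numeric(1)))
  if (used < element_len_bp - 300) {
    push(new_seg("spacer", "", rand_dna(element_len_bp - 300 - used,
                                        params$gc_fraction)))
  }
  k <- 1L
  while (sum(vapply(segs, function(s) nchar(s$seq), numeric(1))) <
         element_len_bp) {
    push(spacer_seg(params, min(300, element_len_bp -
      sum(vapply(segs, function(s) nchar(s$seq), numeric(1))))))
    k <- k + 1L
  }
  elem_seq <- paste(vapply(segs, function(s) s$seq, character(1)),
                    collapse = "")
  elem_len <- nchar(elem_seq)

  left_len <- sample(14000:18000, 1)
  left_bg <- rand_dna(left_len, params$gc_fraction)
  right_len <- host_len_bp - left_len - elem_len - 2 * params$att_len_bp
  right_bg <- rand_dna(max(right_len, 13000), params$gc_fraction)
  # junction bases around the two att copies are forced to mismatch under
  # both direct and inverted pairing, so the designed repeat is exactly
  # att_len_bp (truth-consistency). Direct pairing compares before/before
  # and after/after; inverted pairing compares each side with the reverse
  # complement of the opposite side.
  substr(left_bg, left_len, left_len) <- "A"   # before attL
  substr(elem_seq, elem_len, elem_len) <- "C"  # before attR
  substr(elem_seq, 1, 1) <- "C"                # after attL
  substr(right_bg, 1, 1) <- "A"                # after attR
  host_seq <- paste0(left_bg, att, elem_seq, attR_seq, right_bg)

  attL <- c(left_len, left_len + params$att_len_bp)
  bounds <- c(attL[2], attL[2] + elem_len)
  attR <- c(bounds[2], bounds[2] + params$att_len_bp)

  feats <- list(); hits <- list()
  off <- bounds[1]
  for (s in segs) {
    if (nrow(s$genes)) {
      g <- s$genes
      g$start <- g$start + off; g$end <- g$end + off
      feats[[length(feats) + 1L]] <- g
    }
    if (nrow(s$hits)) hits[[length(hits) + 1L]] <- s$hits
    off <- off + nchar(s$seq)
  }
  features <- do.call(rbind, feats)
  contig <- genome_record("sim_host", host_seq, circular = FALSE,
                          features = features, source_tag = "simulated")
  hit_tab <- do.call(rbind, hits)
  hit_tab$protein_id <- paste0(contig$id, "|", hit_tab$protein_id)

  ref_seq <- mutate_seq(elem_seq, 1 - ref_identity)$seq
  reference <- genome_record("ref_element", ref_seq, circular = FALSE,
                             source_tag = "synthetic reference")
  repa <- features[features$gene_id == "sat_repA", ]
  list(contig = contig, reference = reference, hits = hit_tab,
       seed_interval = c(repa$start, repa$end),
       truth = list(bounds = bounds, attL = attL, attR = attR,
                    att_orientation = att_orientation,
                    integrase = integrase_class, att_seq = att))
}

# ---------------------------------------------------------------------------
# truth self-audit
# ---------------------------------------------------------------------------

#' Audit a simulated community against its own truth
#'
#' Asserts that every truth entry, when re-extracted from the emitted
#' sequences, satisfies its defining property: absent HEG loci have no CDS,
#' in-frame deleted alleles are shorter than the intact design by an exact
#' in-frame amount, designed repeats really repeat at the recorded spacing,
#' and frameshifted loci carry exactly two CDS fragments.
#'
#' @param community result of [simulate_community()].
#' @return invisibly `TRUE`; stops with a message on the first violation.
#' @export
audit_truth_consistency <- function(community) {
  tr <- community$truth
  for (i in seq_len(nrow(tr$heg_truth))) {
    row <- tr$heg_truth[i, ]
    g <- community$genomes[[row$genome_id]]
    lm <- tr$locus_map
    li <- lm[lm$genome_id == row$genome_id & lm$locus == row$locus, ]
    f <- g$features
    inside <- f[!f$wraps_origin & f$start >= li$start & f$end <= li$end, ]
    n_cds <- nrow(inside)
    ok <- switch(row$allele_state,
      absent = n_cds == 0 && li$start == li$end,
      intact = n_cds == 1,
      inframe_deletion = n_cds == 1 && (li$end - li$start) %% 3 == 0,
      frameshifted = n_cds == 2,
      FALSE)
    if (!ok) {
      stop("truth audit failed: ", row$genome_id, " ", row$locus, " state ",
           row$allele_state, " has ", n_cds, " CDS at the locus")
    }
  }
  if (!is.null(tr$repeat_truth)) {
    for (i in seq_len(nrow(tr$repeat_truth))) {
      r <- tr$repeat_truth[i, ]
      lm <- tr$locus_map
      li <- lm[lm$genome_id == r$genome_id & lm$locus == r$gene_id, ]
      g <- community$genomes[[r$genome_id]]
      s1 <- get_subseq(g, li$start + r$r1_start, li$start + r$r1_end)
      s2 <- get_subseq(g, li$start + r$r2_start, li$start + r$r2_end)
      ch1 <- strsplit(s1, "")[[1]]; ch2 <- strsplit(s2, "")[[1]]
      ident <- mean(ch1 == ch2)
      if (ident < 0.6) {
        stop("truth audit failed: repeats of ", r$genome_id, " ", r$gene_id,
             " share only ", round(100 * ident), "% identity")
      }
    }
  }
  invisible(TRUE)
}
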