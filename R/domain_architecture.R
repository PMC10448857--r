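#' Bisect a HEG protein at its nuclease domain
#'
#' HEG nuclease domains generally sit at one terminus of the protein; the
#' protein is trimmed from the nuclease domain to the nearest terminus,
#' yielding a nuclease fragment (terminus through the far domain boundary)
#' and a complementary DNA-binding fragment. The nearest terminus is the
#' side with fewer residues outside the domain; an exact tie goes to the
#' C-terminal side. Coordinates are 1-based inclusive amino-acid positions.
#'
#' @param protein_seq amino-acid string.
#' @param nuclease_hit one row of a domain-hits table (`aa_from`, `aa_to`).
#' @return list of class `domain_split`: `protein_id`, `nuclease_fragment`
#'   `c(from, to)`, `dbd_fragment` `c(from, to)` (or `NULL` when the domain
#'   covers the whole protein, with `dbd_empty = TRUE`), `dbd_class`
#'   (`"unassigned"` until [assign_dbd_class()]), `zn_finger_count`,
#'   `count_quantified`.
#' @export
bisect_heg_protein <- function(protein_seq, nuclease_hit) {
  n <- nchar(protein_seq)
  from <- nuclease_hit$aa_from; to <- nuclease_hit$aa_to
  stopifnot(from >= 1, to <= n, from <= to)
  n_left <- from - 1
  n_right <- n - to
  if (n_left == 0 && n_right == 0) {
    return(structure(list(protein_id = nuclease_hit$protein_id,
                          nuclease_fragment = c(1L, n), dbd_fragment = NULL,
                          dbd_empty = TRUE, dbd_class = "unassigned",
                          zn_finger_count = 0L, count_quantified = FALSE),
                     class = "domain_split"))
  }
  if (n_left < n_right) {            # nuclease at the N-terminal side
    nuc <- c(1L, to)
    dbd <- c(to + 1L, n)
  } else {                           # nearer C terminus (ties included)
    nuc <- c(from, n)
    dbd <- c(1L, from - 1L)
  }
  structure(list(protein_id = nuclease_hit$protein_id,
                 nuclease_fragment = as.integer(nuc),
                 dbd_fragment = as.integer(dbd), dbd_empty = FALSE,
                 dbd_class = "unassigned", zn_finger_count = 0L,
                 count_quantified = FALSE),
            class = "domain_split")
}

#' Assign the DNA-binding-domain class of a bisected HEG
#'
#' Decision tree over hits restricted to the DBD fragment: `CapR` if any
#' CapR-profile hit at e-value `<= capr_evalue` (1e-10), with the Zn-finger
#' count equal to the maximal greedy set of non-overlapping qualifying
#' hits; else `DUF723/DUF4397` if either domain hits at `<= duf_evalue`
#' (1e-3), counted likewise; else the optional remote-homology annotation
#' table is consulted (`RepA_N` or `DUF723/DUF4397`, counts not
#' quantified); else `unassigned`.
#'
#' @param split a `domain_split`.
#' @param hits domain-hits table for the protein.
#' @param remote_annotations optional data.frame with columns `protein_id`,
#'   `domain` (values `RepA_N` or `DUF723/DUF4397`), `evalue`.
#' @param config [heg_config()].
#' @return the completed `domain_split`.
#' @export
assign_dbd_class <- function(split, hits, remote_annotations = NULL,
                             config = heg_config()) {
  if (isTRUE(split$dbd_empty)) return(split)
  dbd <- split$dbd_fragment
  h <- hits[hits$protein_id == split$protein_id &
              hits$aa_from >= dbd[1] & hits$aa_to <= dbd[2], , drop = FALSE]
  capr <- h[h$domain_acc == "CapR" & h$i_evalue <= config$capr_evalue, ,
            drop = FALSE]
  if (nrow(capr)) {
    split$dbd_class <- "CapR"
    split$zn_finger_count <- count_nonoverlapping(capr)
    split$count_quantified <- TRUE
    return(split)
  }
  duf <- h[h$domain_acc %in% c("PF05265", "PF14344") &
             h$i_evalue <= config$duf_evalue, , drop = FALSE]
  if (nrow(duf)) {
    split$dbd_class <- "DUF723/DUF4397"
    split$zn_finger_count <- count_nonoverlapping(duf)
    split$count_quantified <- TRUE
    return(split)
  }
  if (!is.null(remote_annotations) && nrow(remote_annotations)) {
    ra <- remote_annotations[remote_annotations$protein_id ==
                               split$protein_id, , drop = FALSE]
    if ("evalue" %in% names(ra)) {
      ra <- ra[ra$evalue <= config$hhpred_annot_evalue, , drop = FALSE]
    }
    bad <- !ra$domain %in% c("RepA_N", "DUF723/DUF4397")
    if (any(bad)) {
      warning("remote annotation with unknown domain class skipped: ",
              paste(unique(ra$domain[bad]), collapse = ", "))
      ra <- ra[!bad, , drop = FALSE]
    }
    if (nrow(ra)) {
      split$dbd_class <- ra$domain[which.min(ra$evalue %||% 1)]
      split$zn_finger_count <- 0L
      split$count_quantified <- FALSE
      return(split)
    }
  }
  split$dbd_class <- "unassigned"
  split
}

# greedy maximal set of non-overlapping hits, best e-value first
count_nonoverlapping <- function(h) {
  h <- h[order(h$i_evalue), , drop = FALSE]
  taken <- matrix(numeric(0), ncol = 2)
  n <- 0L
  for (i in seq_len(nrow(h))) {
    ov <- FALSE
    if (nrow(taken)) {
      ov <- any(h$aa_from[i] <= taken[, 2] & h$aa_to[i] >= taken[, 1])
    }
    if (!ov) {
      taken <- rbind(taken, c(h$aa_from[i], h$aa_to[i]))
      n <- n + 1L
    }
  }
  n
}

#' Find degenerate repeat pairs within a DNA-binding coding region
#'
#' All-vs-all self-comparison of the DBD-coding nucleotide region using the
#' identity-block engine at repeat-specific thresholds (default minimum
#' length 30 bp, minimum identity 60%), excluding the self-diagonal.
#' Maximal non-overlapping pairs are reported with their start-to-start
#' spacing and frame status; a recombination product between a pair is
#' predicted to shorten the CDS by `spacing_bp`.
#'
#' @param gene_cds_nt CDS nucleotide string (frame 0 at position 1).
#' @param dbd_nt_interval 0-based half-open interval of the DBD-coding
#'   region within the CDS.
#' @param config [heg_config()].
#' @return data.frame with `r1_start`, `r1_end`, `r2_start`, `r2_end`
#'   (0-based, CDS coordinates), `repeat_identity_pct`, `spacing_bp`,
#'   `in_frame`, `predicted_product_len`.
#' @export
find_repeat_pairs <- function(gene_cds_nt, dbd_nt_interval,
                              config = heg_config()) {
  s <- dbd_nt_interval[1]; e <- dbd_nt_interval[2]
  stopifnot(s >= 0, e <= nchar(gene_cds_nt))
  if (e - s < config$repeat_min_len_bp) {
    return(repeat_pair_row()[0, ])
  }
  region <- substr(gene_cds_nt, s + 1, e)
  # exhaustive ungapped diagonal scan: degenerate repeats near the 60%
  # identity floor are too noisy for seeded extension, and the region is
  # small enough (<= a few kb) to score every start-to-start offset
  bl <- repeat_diagonal_scan(region, config$repeat_min_len_bp,
                             config$repeat_min_identity_pct)
  # non-overlapping copies only
  bl <- bl[bl$q_end <= bl$s_start, , drop = FALSE]
  if (!nrow(bl)) return(repeat_pair_row()[0, ])
  bl <- bl[order(-bl$score), , drop = FALSE]
  out <- list(); used <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(bl))) {
    iv <- rbind(c(bl$q_start[i], bl$q_end[i]), c(bl$s_start[i], bl$s_end[i]))
    ov <- FALSE
    if (nrow(used)) {
      for (k in 1:2) {
        if (any(iv[k, 1] < used[, 2] & iv[k, 2] > used[, 1])) ov <- TRUE
      }
    }
    if (ov) next
    used <- rbind(used, iv)
    spacing <- bl$s_start[i] - bl$q_start[i]
    out[[length(out) + 1L]] <- repeat_pair_row(
      s + bl$q_start[i], s + bl$q_end[i], s + bl$s_start[i], s + bl$s_end[i],
      bl$identity_pct[i], spacing, spacing %% 3 == 0,
      nchar(gene_cds_nt) - spacing)
  }
  do.call(rbind, out)
}

# best-scoring ungapped segment on every self-comparison diagonal
# (maximum-subarray per offset); returns block-like rows with
# q interval = first copy, s interval = second copy. Scoring puts the
# identity threshold at breakeven (match 1-t, mismatch -t for t =
# min_ident/100), so the optimum is the longest segment whose identity
# exceeds the threshold rather than a short perfect-match run.
repeat_diagonal_scan <- function(region, min_len, min_ident) {
  ch <- strsplit(region, "")[[1]]
  n <- length(ch)
  t <- min_ident / 100
  rows <- list()
  for (d in seq_len(n - min_len)) {
    m <- ch[seq_len(n - d)] == ch[(d + 1):n] & ch[seq_len(n - d)] != "N"
    sc <- ifelse(m, 1 - t, -t)
    # Kadane: maximal scoring segment
    best <- 0; best_s <- 0L; best_e <- 0L
    cur <- 0; cur_s <- 1L
    for (i in seq_along(sc)) {
      if (cur <= 0) { cur <- sc[i]; cur_s <- i }
      else cur <- cur + sc[i]
      if (cur > best) { best <- cur; best_s <- cur_s; best_e <- i }
    }
    if (best <= 0) next
    len <- best_e - best_s + 1L
    if (len < min_len) next
    ident <- 100 * sum(m[best_s:best_e]) / len
    if (ident <= min_ident) next
    rows[[length(rows) + 1L]] <- data.frame(
      q_start = best_s - 1L, q_end = best_e, s_start = best_s - 1L + d,
      s_end = best_e + d, identity_pct = ident, length = len, score = best)
  }
  if (!length(rows)) {
    return(data.frame(q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      identity_pct = numeric(), length = integer(),
                      score = numeric()))
  }
  do.call(rbind, rows)
}

repeat_pair_row <- function(r1_start = integer(), r1_end = integer(),
                            r2_start = integer(), r2_end = integer(),
                            repeat_identity_pct = numeric(),
                            spacing_bp = integer(), in_frame = logical(),
                            predicted_product_len = integer()) {
  data.frame(r1_start = r1_start, r1_end = r1_end, r2_start = r2_start,
             r2_end = r2_end, repeat_identity_pct = repeat_identity_pct,
             spacing_bp = spacing_bp, in_frame = in_frame,
             predicted_product_len = predicted_product_len,
             stringsAsFactors = FALSE)
}

#' Detect domain swaps between two genes with completed splits
#'
#' Computes qualifying identity blocks restricted to (i) the two
#' DBD-coding nucleotide regions and (ii) the two nuclease-domain-coding
#' regions. A region pair is "shared" iff blocks cover at least
#' `swap_min_cov` (default 0.5) of the shorter region. Accepts any gene
#' pair, including a phage HEG versus a satellite-encoded gene.
#'
#' @param heg_a,heg_b lists with `cds` (nucleotide string) and `split`
#'   (a completed `domain_split`).
#' @param config [heg_config()].
#' @return one of `"shared_both"`, `"shared_dbd_only"`,
#'   `"shared_nuclease_only"`, `"shared_neither"`.
#' @export
detect_domain_swap <- function(heg_a, heg_b, config = heg_config()) {
  for (g in list(heg_a, heg_b)) {
    if (is.null(g$split)) stop("gene lacks a completed domain split")
  }
  aa2nt <- function(iv) c(3L * (iv[1] - 1L), 3L * iv[2])
  region <- function(g, what) {
    iv <- if (what == "dbd") g$split$dbd_fragment else g$split$nuclease_fragment
    if (is.null(iv)) return("")
    nt <- aa2nt(iv)
    substr(g$cds, nt[1] + 1, min(nt[2], nchar(g$cds)))
  }
  shared <- function(what) {
    ra <- region(heg_a, what); rb <- region(heg_b, what)
    if (!nzchar(ra) || !nzchar(rb)) return(FALSE)
    cfg <- config
    cfg$block_min_len_bp <- min(config$block_min_len_bp,
                                max(30, floor(min(nchar(ra), nchar(rb)) / 4)))
    bl <- find_identity_blocks(ra, rb, cfg)
    if (!nrow(bl)) return(FALSE)
    cov <- covered_length(bl$q_start, bl$q_end) / min(nchar(ra), nchar(rb))
    cov >= config$swap_min_cov
  }
  d <- shared("dbd"); n <- shared("nuclease")
  if (d && n) "shared_both"
  else if (d) "shared_dbd_only"
  else if (n) "shared_nuclease_only"
  else "shared_neither"
}

# total length covered by a union of intervals
covered_length <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0; cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > cur_e) {
      tot <- tot + cur_e - cur_s
      cur_s <- starts[i]; cur_e <- ends[i]
    } else cur_e <- max(cur_e, ends[i])
  }
  tot + cur_e - cur_s
}

#' Domain-architecture census for HEG proteins
#'
#' Runs bisection and DBD classification for every HEG call with a usable
#' protein sequence and nuclease hit.
#'
#' @param genomes named list of `genome_record`.
#' @param heg_calls output of [call_hegs()].
#' @param hits domain-hits table.
#' @param remote_annotations optional remote-homology table.
#' @param config [heg_config()].
#' @return data.frame in the `architecture` schema.
#' @export
architecture_census <- function(genomes, heg_calls, hits,
                                remote_annotations = NULL,
                                config = heg_config()) {
  rows <- list()
  for (i in seq_len(nrow(heg_calls))) {
    cl <- heg_calls[i, ]
    if (cl$allele_state %in% c("absent")) next
    g <- genomes[[cl$genome_id]]
    f <- g$features[g$features$gene_id == cl$gene_id, ]
    if (!nrow(f)) next
    prot <- f$protein_seq[1]
    if (is.na(prot) || !nzchar(prot)) {
      prot <- translate_cds(feature_cds(g, f[1, ]))
    }
    pid <- paste0(cl$genome_id, "|", cl$gene_id)
    nh <- hits[hits$protein_id == pid & hits$domain_acc == cl$nuclease_acc, ,
               drop = FALSE]
    if (!nrow(nh)) next
    nh <- nh[which.min(nh$i_evalue), ]
    nh$aa_to <- min(nh$aa_to, nchar(prot))
    split <- bisect_heg_protein(prot, nh)
    split <- assign_dbd_class(split, hits, remote_annotations, config)
    dbd <- split$dbd_fragment %||% c(NA_integer_, NA_integer_)
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = pid, family = cl$family, dbd_class = split$dbd_class,
      zn_finger_count = split$zn_finger_count,
      count_quantified = split$count_quantified,
      nuc_from = split$nuclease_fragment[1], nuc_to = split$nuclease_fragment[2],
      dbd_from = dbd[1], dbd_to = dbd[2], stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(protein_id = character(), family = character(),
                      dbd_class = character(), zn_finger_count = integer(),
                      count_quantified = logical(), nuc_from = integer(),
                      nuc_to = integer(), dbd_from = integer(),
                      dbd_to = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
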