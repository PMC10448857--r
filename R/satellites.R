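#' Extract the candidate locus around a satellite seed
#'
#' Takes the surrounding 12 500 bp on either end of the seed homology
#' interval (clipped on a linear contig, wrapped on a circular one), with
#' features carried over and re-based to the locus.
#'
#' @param contig a `genome_record`.
#' @param seed_interval 0-based half-open interval of the seed homology.
#' @param config [heg_config()].
#' @return list with `record` (a `genome_record` of the locus), `offset`
#'   (locus start on the contig), `seed_local` (seed re-based to the
#'   locus).
#' @export
extract_candidate_locus <- function(contig, seed_interval,
                                    config = heg_config()) {
  L <- contig$length
  fl <- config$satellite_flank_bp
  stopifnot(seed_interval[1] >= 0, seed_interval[2] <= L)
  if (contig$circular && seed_interval[2] - seed_interval[1] + 2 * fl < L) {
    s <- (seed_interval[1] - fl) %% L
    e <- s + (seed_interval[2] - seed_interval[1]) + 2 * fl
  } else {
    s <- max(seed_interval[1] - fl, 0)
    e <- min(seed_interval[2] + fl, L)
  }
  seq <- get_subseq(contig, s, e)
  f <- contig$features
  if (nrow(f)) {
    keep <- logical(nrow(f))
    ns <- ne <- integer(nrow(f))
    for (i in seq_len(nrow(f))) {
      uw <- unwrap_interval(f$start[i], f$end[i], L, f$wraps_origin[i])
      for (d in c(-L, 0, L)) {
        if (uw[1] + d >= s && uw[2] + d <= e) {
          keep[i] <- TRUE
          ns[i] <- uw[1] + d - s; ne[i] <- uw[2] + d - s
          break
        }
      }
    }
    feats <- gene_features(f$gene_id[keep], ns[keep], ne[keep],
                           f$strand[keep], rep(FALSE, sum(keep)),
                           f$product[keep], f$protein_seq[keep])
  } else feats <- gene_features()
  rec <- genome_record(paste0(contig$id, ":locus"), seq, circular = FALSE,
                       features = feats, source_tag = contig$source_tag)
  list(record = rec, offset = s,
       seed_local = c(seed_interval[1] - s, seed_interval[2] - s))
}

#' Search for attachment-site repeats flanking a core span
#'
#' Candidate att pairs are repeat matches of at least `att_min_len`
#' (default 15 bp) at `att_min_identity` (default 90%) between the windows
#' of `att_search_bp` (default 3000) outside each end of the core span,
#' tested in both direct and inverted orientation, ranked by
#' length x identity.
#'
#' @param locus locus record from [extract_candidate_locus()].
#' @param core_span 0-based half-open interval to flank (locus
#'   coordinates).
#' @param config [heg_config()].
#' @return data.frame of candidates: `attL_start`, `attL_end`,
#'   `attR_start`, `attR_end`, `orientation`, `identity_pct`, `length`,
#'   `score`, `best` flag; empty when no qualifying repeat exists.
#' @export
find_att_sites <- function(locus, core_span, config = heg_config()) {
  L <- locus$length
  ws <- config$att_search_bp
  lw <- c(max(core_span[1] - ws, 0), core_span[1])
  rw <- c(core_span[2], min(core_span[2] + ws, L))
  empty <- data.frame(attL_start = integer(), attL_end = integer(),
                      attR_start = integer(), attR_end = integer(),
                      orientation = character(), identity_pct = numeric(),
                      length = integer(), score = numeric(), best = logical())
  if (diff(lw) < config$att_min_len || diff(rw) < config$att_min_len) {
    return(empty)
  }
  left_seq <- get_subseq(locus, lw[1], lw[2])
  right_seq <- get_subseq(locus, rw[1], rw[2])
  cfg <- config
  cfg$seed_k <- min(config$seed_k, config$att_min_len)
  cfg$block_min_len_bp <- config$att_min_len
  cfg$block_min_identity_pct <- config$att_min_identity
  cfg$block_max_evalue <- Inf
  bl <- find_identity_blocks(left_seq, right_seq, cfg)
  if (!nrow(bl)) return(empty)
  out <- data.frame(
    attL_start = lw[1] + bl$q_start, attL_end = lw[1] + bl$q_end,
    attR_start = rw[1] + bl$s_start, attR_end = rw[1] + bl$s_end,
    orientation = ifelse(bl$strand == "+", "direct", "inverted"),
    identity_pct = bl$identity_pct, length = bl$length,
    score = bl$length * bl$identity_pct / 100, stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  out$best <- seq_len(nrow(out)) == 1
  rownames(out) <- NULL
  out
}

#' Call a satellite element at a candidate locus
#'
#' Bounds are the inner edges of the best att pair. The homology support
#' (`homology_bp`) is the total length of a maximum-weight set of
#' non-overlapping qualifying identity blocks (60% / 125 bp / 1e-5)
#' between the bounded element and the best-matching reference element,
#' computed exactly by dynamic programming ("non-contiguous": blocks need
#' not chain). The call passes iff `homology_bp >=
#' satellite_min_homology_bp` (default 10 kb). The integrase class is
#' taken from any integrase-annotated gene within `integrase_att_bp`
#' (default 2000) of either att site.
#'
#' @param locus locus record from [extract_candidate_locus()].
#' @param att_candidates data.frame from [find_att_sites()] (may be
#'   empty).
#' @param reference_elements list of `genome_record` reference elements.
#' @param hits domain-hits table (protein ids `"<contig>|<gene>"` for the
#'   parent contig or the locus record id).
#' @param config [heg_config()].
#' @param integrase_accs [integrase_accessions()].
#' @return list of class `satellite_call`: `contig_id`, `bounds`, `attL`,
#'   `attR`, `att_orientation`, `integrase`, `integrase_gene`,
#'   `homology_bp`, `passed_filter`, `reason`.
#' @export
call_satellite <- function(locus, att_candidates, reference_elements, hits,
                           config = heg_config(),
                           integrase_accs = integrase_accessions()) {
  fail <- function(reason) {
    structure(list(contig_id = locus$id, bounds = c(NA_integer_, NA_integer_),
                   attL = NULL, attR = NULL, att_orientation = NA_character_,
                   integrase = "none", integrase_gene = NA_character_,
                   homology_bp = 0L, passed_filter = FALSE, reason = reason),
              class = "satellite_call")
  }
  if (is.null(att_candidates) || !nrow(att_candidates)) {
    return(fail("no attachment-site pair found"))
  }
  best <- att_candidates[which(att_candidates$best)[1], ]
  bounds <- c(best$attL_end, best$attR_start)
  elem <- get_subseq(locus, bounds[1], bounds[2])

  homology <- 0L
  for (ref in reference_elements) {
    bl <- find_identity_blocks(elem, ref$sequence, config)
    if (!nrow(bl)) next
    h <- max_weight_nonoverlap(bl$q_start, bl$q_end)
    homology <- max(homology, h)
  }

  integ <- "none"; integ_gene <- NA_character_
  f <- locus$features
  if (nrow(f)) {
    near <- f$end >= best$attL_start - config$integrase_att_bp &
            f$start <= best$attL_end + config$integrase_att_bp |
            f$end >= best$attR_start - config$integrase_att_bp &
            f$start <= best$attR_end + config$integrase_att_bp
    for (i in which(near)) {
      for (pid in c(paste0(locus$id, "|", f$gene_id[i]),
                    paste0(sub(":locus$", "", locus$id), "|", f$gene_id[i]))) {
        hh <- hits[hits$protein_id == pid &
                     hits$i_evalue <= config$hhpred_annot_evalue, ,
                   drop = FALSE]
        if (any(hh$domain_acc %in% integrase_accs$tyrosine)) {
          integ <- "tyrosine"; integ_gene <- f$gene_id[i]
        } else if (any(hh$domain_acc %in% integrase_accs$serine)) {
          integ <- "serine"; integ_gene <- f$gene_id[i]
        }
      }
      if (integ != "none") break
    }
  }
  structure(list(
    contig_id = locus$id, bounds = bounds,
    attL = c(best$attL_start, best$attL_end),
    attR = c(best$attR_start, best$attR_end),
    att_orientation = best$orientation, integrase = integ,
    integrase_gene = integ_gene, homology_bp = as.integer(homology),
    passed_filter = homology >= config$satellite_min_homology_bp,
    reason = "ok"), class = "satellite_call")
}

#' Maximum-weight non-overlapping interval coverage
#'
#' Exact dynamic-programming selection of non-overlapping intervals
#' maximizing total length (weight = interval length). Used for the
#' non-contiguous homology support of satellite calls.
#'
#' @param starts,ends parallel 0-based half-open intervals.
#' @return total selected length (numeric).
#' @export
max_weight_nonoverlap <- function(starts, ends) {
  n <- length(starts)
  if (!n) return(0)
  o <- order(ends)
  starts <- starts[o]; ends <- ends[o]
  w <- ends - starts
  # p[i]: last interval ending at or before starts[i]
  p <- findInterval(starts, ends)
  opt <- numeric(n + 1)
  for (i in seq_len(n)) {
    opt[i + 1] <- max(opt[i], opt[p[i] + 1] + w[i])
  }
  opt[n + 1]
}

#' Greedy non-overlapping interval coverage (reference variant)
#'
#' Greedy-by-length selection of non-overlapping intervals; kept as a
#' comparison baseline for the exact DP.
#' @inheritParams max_weight_nonoverlap
#' @return total selected length.
#' @export
greedy_nonoverlap <- function(starts, ends) {
  n <- length(starts)
  if (!n) return(0)
  o <- order(-(ends - starts))
  starts <- starts[o]; ends <- ends[o]
  tot <- 0; taken_s <- numeric(0); taken_e <- numeric(0)
  for (i in seq_len(n)) {
    if (!any(starts[i] < taken_e & ends[i] > taken_s)) {
      tot <- tot + ends[i] - starts[i]
      taken_s <- c(taken_s, starts[i]); taken_e <- c(taken_e, ends[i])
    }
  }
  tot
}

#' Satellite calls as a results table
#' @param calls list of `satellite_call` objects.
#' @return data.frame in the `satellites` schema.
#' @export
satellites_table <- function(calls) {
  do.call(rbind, lapply(calls, function(cl) {
    data.frame(contig_id = cl$contig_id,
               start = cl$bounds[1], end = cl$bounds[2],
               attL_start = if (is.null(cl$attL)) NA_integer_ else cl$attL[1],
               attL_end = if (is.null(cl$attL)) NA_integer_ else cl$attL[2],
               attR_start = if (is.null(cl$attR)) NA_integer_ else cl$attR[1],
               attR_end = if (is.null(cl$attR)) NA_integer_ else cl$attR[2],
               att_orientation = cl$att_orientation,
               integrase = cl$integrase, homology_bp = cl$homology_bp,
               passed_filter = cl$passed_filter, stringsAsFactors = FALSE)
  }))
}
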