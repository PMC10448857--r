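#' Detect candidate introns from a coverage dip
#'
#' Intronic sequence of a fragmented gene shows a distinct drop in RNA-seq
#' read coverage relative to the exons. The detector smooths the per-base
#' depth with a centered running mean (`smooth_bp`, default 51, to tame
#' negative-binomial overdispersion), estimates the exonic reference level
#' as the median depth outside candidate dips (iterated once), and accepts
#' a dip iff its mean raw depth is below `dip_ratio` (default 0.3) times
#' the reference level and its run length is at least `min_intron_bp`
#' (default 100). Adjacent dips separated by fewer than 10 bp are merged.
#' Boundaries are then refined at base resolution by a two-level
#' changepoint fit against the raw counts.
#'
#' @param track a `coverage_track`.
#' @param region 0-based half-open interval to scan.
#' @param config [heg_config()].
#' @return data.frame with `start`, `end` (0-based half-open, genome
#'   coordinates), `mean_depth`, ordered by position.
#' @export
detect_intron_candidates <- function(track, region, config = heg_config()) {
  s <- region[1]; e <- region[2]
  stopifnot(s >= 0, e <= length(track$depth), e > s)
  x <- track$depth[(s + 1):e]
  sm <- running_mean(x, config$smooth_bp)
  # overdispersed counts put the raw median far below the mean; the
  # expression check and reference level work on the smoothed track
  med <- stats::median(sm)
  if (med <= 0) stop("insufficient expression: region median depth is 0")
  if (med <= config$min_region_depth) {
    stop("insufficient expression: region median depth ", round(med, 1),
         " <= min_region_depth ", config$min_region_depth)
  }

  ref <- med
  dips <- NULL
  for (iter in 1:2) {
    thr <- config$dip_ratio * ref
    below <- sm < thr
    dips <- runs_of(below)
    dips <- merge_close_runs(dips, config$dip_merge_bp)
    if (nrow(dips)) {
      dips <- dips[dips$end - dips$start >= config$min_intron_bp, ,
                   drop = FALSE]
    }
    # reference level = median outside current dips
    out_mask <- rep(TRUE, length(x))
    for (i in seq_len(nrow(dips))) {
      out_mask[(dips$start[i] + 1):dips$end[i]] <- FALSE
    }
    if (!any(out_mask)) break
    ref <- stats::median(sm[out_mask])
  }
  if (!nrow(dips)) {
    return(data.frame(start = integer(), end = integer(),
                      mean_depth = numeric()))
  }
  # qualify on mean raw depth and refine boundaries on raw counts
  keep <- logical(nrow(dips))
  for (i in seq_len(nrow(dips))) {
    mu <- mean(x[(dips$start[i] + 1):dips$end[i]])
    keep[i] <- mu < config$dip_ratio * ref
  }
  dips <- dips[keep, , drop = FALSE]
  if (!nrow(dips)) {
    return(data.frame(start = integer(), end = integer(),
                      mean_depth = numeric()))
  }
  dip_idx <- unlist(mapply(function(a, b) (a + 1):b, dips$start, dips$end))
  dip_mu <- max(mean(x[dip_idx]), 0.1)
  # NB dispersion of the exonic background by method of moments
  bg <- x[-dip_idx]
  size_hat <- if (stats::var(bg) > mean(bg)) {
    mean(bg)^2 / (stats::var(bg) - mean(bg))
  } else Inf
  w <- config$smooth_bp
  for (i in seq_len(nrow(dips))) {
    dips$start[i] <- refine_boundary(x, dips$start[i], w, ref, dip_mu,
                                     size_hat, falling = TRUE)
    dips$end[i] <- refine_boundary(x, dips$end[i], w, ref, dip_mu,
                                   size_hat, falling = FALSE)
  }
  dips <- dips[dips$end - dips$start >= config$min_intron_bp, , drop = FALSE]
  mean_depth <- vapply(seq_len(nrow(dips)), function(i) {
    mean(x[(dips$start[i] + 1):dips$end[i]])
  }, numeric(1))
  out <- data.frame(start = s + dips$start, end = s + dips$end,
                    mean_depth = mean_depth)
  out[order(out$start), , drop = FALSE]
}

running_mean <- function(x, w) {
  if (w <= 1) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  h <- w %/% 2
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# runs of TRUE as 0-based half-open intervals (local coordinates)
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  data.frame(start = starts[r$values], end = ends[r$values])
}

merge_close_runs <- function(runs, gap) {
  if (nrow(runs) < 2) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    if (runs$start[i] - out$end[nrow(out)] < gap) {
      out$end[nrow(out)] <- runs$end[i]
    } else out <- rbind(out, runs[i, ])
  }
  out
}

# maximum-likelihood changepoint between exon level mu_hi and dip level
# mu_lo within +/- w of a coarse boundary, scored per base under the
# negative binomial with the data-estimated dispersion (Poisson limit for
# size = Inf). The fitted mean profile includes a short linear ramp
# (ramp_bp, matching the boundary transition the coverage model assumes)
# on the intronic side of the cut.
refine_boundary <- function(x, b, w, mu_hi, mu_lo, size, falling,
                            ramp_bp = 5L) {
  lo <- max(b - w, 0L); hi <- min(b + w, length(x))
  n <- hi - lo
  if (n < 2) return(b)
  seg <- x[(lo + 1):hi]
  ld <- function(v, mu) {
    if (is.finite(size)) stats::dnbinom(v, size = size, mu = mu, log = TRUE)
    else stats::dpois(v, lambda = mu, log = TRUE)
  }
  l_hi <- ld(seg, mu_hi); l_lo <- ld(seg, mu_lo)
  cum_hi <- c(0, cumsum(l_hi)); cum_lo <- c(0, cumsum(l_lo))
  ramp <- seq(mu_hi, mu_lo, length.out = ramp_bp)
  best_ll <- -Inf; best_cut <- b - lo
  for (cut in 0:n) {
    if (falling) {
      # exon [1, cut], ramp on seg[cut+1 .. cut+ramp], dip beyond
      re <- min(cut + ramp_bp, n)
      ll <- (cum_hi[cut + 1] - cum_hi[1]) + (cum_lo[n + 1] - cum_lo[re + 1])
      if (re > cut) {
        ll <- ll + sum(ld(seg[(cut + 1):re], ramp[seq_len(re - cut)]))
      }
    } else {
      # dip [1, cut - ramp], ramp up to the cut, exon beyond
      rs <- max(cut - ramp_bp, 0)
      ll <- (cum_lo[rs + 1] - cum_lo[1]) + (cum_hi[n + 1] - cum_hi[cut + 1])
      if (cut > rs) {
        ll <- ll + sum(ld(seg[(rs + 1):cut], rev(ramp)[seq_len(cut - rs)]))
      }
    }
    if (ll > best_ll) { best_ll <- ll; best_cut <- cut }
  }
  lo + best_cut
}

#' Chain exons across intron candidates into a spliced CDS
#'
#' Exons are the gene span minus the introns. Junction boundaries are
#' refined in one of two ways: when a junction-support table is supplied,
#' each boundary snaps to the maximum-support junction within `snap_bp`
#' (default 10); otherwise boundary offsets within `frame_search_bp`
#' (default 10) are searched for the assignment that makes the spliced CDS
#' a valid ORF (start codon, terminal stop, no internal stop, length
#' divisible by 3 — so that the fragment-internal start/stop codons land
#' inside the introns and are removed). The offset search is exhaustive for
#' up to three introns and per-junction greedy beyond that; among valid
#' assignments the one with the smallest total offset is chosen.
#'
#' @param fragments feature rows of the annotated CDS fragments, collinear
#'   on one strand, in genomic order.
#' @param intron_candidates data.frame from [detect_intron_candidates()].
#' @param genome the `genome_record`.
#' @param junction_table optional data.frame `pos_a`, `pos_b`, `n_reads`
#'   (0-based donor/acceptor positions, i.e. intron start and end).
#' @param config [heg_config()].
#' @return list of class `splice_model`: `gene_group`, `exons`, `introns`
#'   (matrices of 0-based half-open intervals), `junctions`, `spliced_cds`,
#'   `orf_valid`.
#' @export
chain_exons <- function(fragments, intron_candidates, genome,
                        junction_table = NULL, config = heg_config()) {
  if (length(unique(fragments$strand)) != 1) {
    stop("fragments lie on opposite strands")
  }
  span <- c(min(fragments$start), max(fragments$end))
  ic <- intron_candidates[intron_candidates$start >= span[1] &
                            intron_candidates$end <= span[2], , drop = FALSE]
  n_j <- nrow(ic)
  if (!n_j) {
    cds <- get_subseq(genome, span[1], span[2])
    v <- validate_orf(cds)
    return(splice_model(fragments$gene_id, matrix(span, 1), ic[0, ],
                        NULL, cds, v$valid))
  }
  if (!is.null(junction_table) && nrow(junction_table)) {
    starts <- ic$start; ends <- ic$end
    support <- numeric(n_j)
    # coverage boundary uncertainty scales with the smoothing window, so a
    # junction whose intron interval overlaps the detected dip may snap
    # from a correspondingly wider radius
    wide <- config$snap_bp + config$smooth_bp %/% 2
    for (i in seq_len(n_j)) {
      ov <- junction_table$pos_a < ic$end[i] & junction_table$pos_b > ic$start[i]
      ca <- junction_table[abs(junction_table$pos_a - ic$start[i]) <=
                             config$snap_bp |
                           (ov & abs(junction_table$pos_a - ic$start[i]) <=
                              wide), , drop = FALSE]
      cb <- junction_table[abs(junction_table$pos_b - ic$end[i]) <=
                             config$snap_bp |
                           (ov & abs(junction_table$pos_b - ic$end[i]) <=
                              wide), , drop = FALSE]
      if (nrow(ca)) {
        ba <- ca[which.max(ca$n_reads), ]
        starts[i] <- ba$pos_a
        support[i] <- ba$n_reads
      }
      if (nrow(cb)) {
        bb <- cb[which.max(cb$n_reads), ]
        ends[i] <- bb$pos_b
        support[i] <- max(support[i], bb$n_reads)
      }
    }
    model <- build_splice_model(fragments, genome, span, starts, ends, support)
    return(model)
  }
  # frame search over boundary offsets
  fs <- config$frame_search_bp
  offsets <- -fs:fs
  best <- NULL
  try_assignment <- function(ds, de) {
    starts <- ic$start + ds; ends <- ic$end + de
    if (any(starts >= ends) || any(starts < span[1]) || any(ends > span[2])) {
      return(NULL)
    }
    if (n_j > 1 && any(ends[-n_j] > starts[-1])) return(NULL)
    m <- build_splice_model(fragments, genome, span, starts, ends,
                            rep(0, n_j))
    if (!m$orf_valid) return(NULL)
    m$total_offset <- sum(abs(ds)) + sum(abs(de))
    m
  }
  if (n_j <= 3) {
    # iterative deepening on the total offset: smallest-total assignments
    # first, stopping at the first valid spliced ORF
    span_len <- span[2] - span[1]
    intron_len0 <- sum(ic$end - ic$start)
    cap <- c(2 * fs, 10, 7)[n_j]
    for (grid in offset_grids(2 * n_j, fs, cap = cap)) {
      if (!nrow(grid)) next
      for (r in seq_len(nrow(grid))) {
        ds <- grid[r, seq_len(n_j)]
        de <- grid[r, n_j + seq_len(n_j)]
        # cheap frame prefilter before rebuilding the CDS
        if ((span_len - (intron_len0 + sum(de) - sum(ds))) %% 3 != 0) next
        m <- try_assignment(ds, de)
        if (!is.null(m)) { best <- m; break }
      }
      if (!is.null(best)) break
    }
  } else {
    # per-junction greedy in genomic order: minimize offsets junction by
    # junction, requiring the cumulative exonic length to keep frame
    ds <- rep(0, n_j); de <- rep(0, n_j)
    ord2 <- order(abs(offsets), offsets)
    for (jn in seq_len(n_j)) {
      found <- FALSE
      for (a in offsets[ord2]) for (b in offsets[ord2]) {
        ds2 <- ds; de2 <- de; ds2[jn] <- a; de2[jn] <- b
        m <- try_assignment(ds2, de2)
        if (jn < n_j) {
          ok <- ((ic$end[jn] + b) - (ic$start[jn] + a)) %% 3 ==
            (ic$end[jn] - ic$start[jn]) %% 3
          if (ok) { ds <- ds2; de <- de2; found <- TRUE; break }
        } else if (!is.null(m)) {
          ds <- ds2; de <- de2; best <- m; found <- TRUE; break
        }
      }
      if (!found) break
    }
  }
  if (is.null(best)) {
    best <- build_splice_model(fragments, genome, span, ic$start, ic$end,
                               rep(0, n_j))
    best$orf_valid <- FALSE
  }
  best
}

# offset vectors of dimension k with entries in [-fs, fs], grouped by L1
# norm ascending (list of matrices, one per total); enumeration capped at
# total <= cap
offset_grids <- function(k, fs, cap) {
  lapply(0:cap, function(total) {
    rows <- compositions_signed(k, total, fs)
    if (!length(rows)) matrix(numeric(0), 0, k)
    else do.call(rbind, rows)
  })
}

compositions_signed <- function(k, total, fs) {
  out <- list()
  rec <- function(prefix, slots_left, rem) {
    if (slots_left == 0) {
      if (rem == 0) out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in 0:min(rem, fs)) {
      vals <- if (v == 0) 0 else c(v, -v)
      for (sv in vals) rec(c(prefix, sv), slots_left - 1, rem - v)
    }
  }
  rec(numeric(0), k, total)
  out
}

build_splice_model <- function(fragments, genome, span, starts, ends,
                               support) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; support <- support[o]
  n_j <- length(starts)
  ex_start <- c(span[1], ends)
  ex_end <- c(starts, span[2])
  exons <- cbind(ex_start, ex_end)
  introns <- cbind(starts, ends)
  cds <- paste(vapply(seq_len(nrow(exons)), function(i) {
    get_subseq(genome, exons[i, 1], exons[i, 2])
  }, character(1)), collapse = "")
  v <- validate_orf(cds)
  splice_model(fragments$gene_id, exons, introns,
               data.frame(donor = starts, acceptor = ends,
                          support = support), cds, v$valid)
}

splice_model <- function(gene_group, exons, introns, junctions, cds, valid) {
  colnames(exons) <- c("start", "end")
  if (is.data.frame(introns)) introns <- as.matrix(introns[, c("start", "end")])
  if (length(introns)) colnames(introns) <- c("start", "end")
  structure(list(gene_group = gene_group, exons = exons, introns = introns,
                 junctions = junctions, spliced_cds = cds,
                 orf_valid = valid), class = "splice_model")
}

#' Validate a spliced CDS as a single ORF
#'
#' True iff the sequence starts with ATG/GTG/TTG, ends with TAA/TAG/TGA,
#' has length divisible by 3, and contains no internal stop codon in frame
#' 0. Diagnostics name the first violation.
#'
#' @param spliced_cds nucleotide string.
#' @return list `valid` (logical), `reason` (character).
#' @export
validate_orf <- function(spliced_cds) {
  if (!nzchar(spliced_cds)) stop("empty CDS")
  n <- nchar(spliced_cds)
  if (n %% 3 != 0) {
    return(list(valid = FALSE, reason = sprintf("length %d not divisible by 3", n)))
  }
  start <- substr(spliced_cds, 1, 3)
  if (!start %in% c("ATG", "GTG", "TTG")) {
    return(list(valid = FALSE, reason = paste0("no start codon (", start, ")")))
  }
  stop_c <- substr(spliced_cds, n - 2, n)
  if (!stop_c %in% c("TAA", "TAG", "TGA")) {
    return(list(valid = FALSE, reason = paste0("no terminal stop (", stop_c, ")")))
  }
  codons <- substring(spliced_cds, seq(1, n - 3, 3), seq(3, n, 3))
  internal <- codons[-length(codons)]
  hit <- which(internal %in% c("TAA", "TAG", "TGA"))
  if (length(hit)) {
    return(list(valid = FALSE,
                reason = sprintf("internal stop at codon %d", hit[1])))
  }
  list(valid = TRUE, reason = "ok")
}
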