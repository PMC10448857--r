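#' Extract the gene neighborhood around a HEG
#'
#' The neighborhood is the 3250 bp flanking the start and stop position of
#' the anchor HEG, extended once to the bounds of any open reading frame
#' that begins or terminates beyond the initial window (a single,
#' non-transitive pass). On circular genomes the window wraps the origin;
#' on linear genomes it is clipped to `[0, length)`. Overlap means at least
#' one shared base; strand is ignored for membership.
#'
#' @param anchor one row of a HEG-calls data.frame (needs `genome_id`,
#'   `gene_id`, `start`, `end`).
#' @param genome the `genome_record` carrying the anchor.
#' @param config [heg_config()].
#' @return list of class `neighborhood`: `anchor`, `interval` (unwrapped
#'   0-based half-open; end may exceed the genome length when the window
#'   wraps), `member_genes` (feature rows in genomic order from the
#'   interval start), `markers` (set later by [classify_markers()]),
#'   `other_hegs`.
#' @export
extract_neighborhood <- function(anchor, genome, config = heg_config()) {
  L <- genome$length
  fl <- config$neighborhood_flank_bp
  a_len <- anchor$end - anchor$start
  if (a_len > L) stop("anchor longer than genome")
  if (a_len + 2 * fl >= L) {
    s <- 0; e <- L                      # window covers the whole replicon
  } else if (genome$circular) {
    s <- (anchor$start - fl) %% L
    e <- s + a_len + 2 * fl
  } else {
    s <- max(anchor$start - fl, 0)
    e <- min(anchor$end + fl, L)
  }
  f <- genome$features
  if (nrow(f)) {
    uw <- t(vapply(seq_len(nrow(f)), function(i) {
      unwrap_interval(f$start[i], f$end[i], L, f$wraps_origin[i])
    }, numeric(2)))
    ov <- vapply(seq_len(nrow(f)), function(i) {
      intervals_overlap_mod(s, e, uw[i, 1], uw[i, 2],
                            if (genome$circular) L else Inf)
    }, logical(1))
    # single extension pass: cover the full extent of every overlapping ORF
    if (any(ov)) {
      for (i in which(ov)) {
        ext <- extend_to_cover(s, e, uw[i, 1], uw[i, 2],
                               if (genome$circular) L else Inf)
        s <- ext[1]; e <- ext[2]
      }
      if (e - s > L) { s <- 0; e <- L }
      if (!genome$circular) { s <- max(s, 0); e <- min(e, L) }
      # membership against the extended interval
      ov <- vapply(seq_len(nrow(f)), function(i) {
        intervals_overlap_mod(s, e, uw[i, 1], uw[i, 2],
                              if (genome$circular) L else Inf)
      }, logical(1))
    }
    members <- f[ov, , drop = FALSE]
    if (nrow(members)) {
      # genomic order from the interval start
      pos <- vapply(which(ov), function(i) {
        (uw[i, 1] - s) %% if (genome$circular) L else .Machine$integer.max
      }, numeric(1))
      members <- members[order(pos), , drop = FALSE]
    }
  } else members <- f
  structure(list(anchor = anchor, genome_id = genome$id,
                 interval = c(s, e), member_genes = members,
                 markers = character(), other_hegs = empty_heg_calls()),
            class = "neighborhood")
}

# grow [s,e) minimally (modularly) so that it covers [fs,fe)
extend_to_cover <- function(s, e, fs, fe, L) {
  if (!is.finite(L)) {
    return(c(min(s, fs), max(e, fe)))
  }
  # place the feature on the copy of the circle where it overlaps the window
  for (d in c(-L, 0, L)) {
    if (s < fe + d && fs + d < e) {
      return(c(min(s, fs + d), max(e, fe + d)))
    }
  }
  c(s, e)
}

#' Classify essential markers in a neighborhood
#'
#' A marker flag (terminase, capsid, TMP, RNR, replicase) is set iff some
#' member gene carries a domain hit with e-value `<=
#' neighborhood_annot_evalue` (default 0.1) whose accession belongs to that
#' marker's configured accession list. `other_hegs` collects the HEG calls
#' among members other than the anchor.
#'
#' @param nbhd a `neighborhood`.
#' @param hits domain-hits table.
#' @param heg_calls HEG calls for the genome (for `other_hegs`).
#' @param config [heg_config()].
#' @param markers marker accession lists ([marker_accessions()] default).
#' @return the neighborhood with `markers` and `other_hegs` filled in.
#' @export
classify_markers <- function(nbhd, hits, heg_calls = empty_heg_calls(),
                             config = heg_config(),
                             markers = marker_accessions()) {
  if (nrow(nbhd$member_genes)) {
    pids <- paste0(nbhd$genome_id, "|", nbhd$member_genes$gene_id)
    mh <- hits[hits$protein_id %in% pids &
                 hits$i_evalue <= config$neighborhood_annot_evalue, ,
               drop = FALSE]
    flags <- names(markers)[vapply(markers, function(accs) {
      any(mh$domain_acc %in% accs)
    }, logical(1))]
  } else flags <- character()
  nbhd$markers <- flags
  oh <- heg_calls[heg_calls$genome_id == nbhd$genome_id &
                    heg_calls$gene_id %in% nbhd$member_genes$gene_id &
                    heg_calls$gene_id != nbhd$anchor$gene_id, , drop = FALSE]
  nbhd$other_hegs <- oh
  nbhd
}

#' Neighborhoods for all HEG calls of a genome set
#'
#' @param genomes named list of `genome_record`.
#' @param heg_calls output of [call_hegs()].
#' @param hits domain-hits table.
#' @param config [heg_config()].
#' @return list of classified `neighborhood` objects.
#' @export
extract_all_neighborhoods <- function(genomes, heg_calls, hits,
                                      config = heg_config()) {
  lapply(seq_len(nrow(heg_calls)), function(i) {
    anchor <- heg_calls[i, ]
    nb <- extract_neighborhood(anchor, genomes[[anchor$genome_id]], config)
    classify_markers(nb, hits, heg_calls, config)
  })
}

#' Summarize marker enrichment over neighborhoods
#'
#' Per-marker counts and fractions of neighborhoods with the flag set
#' (presence/absence per neighborhood, regardless of how many marker genes
#' co-occur), plus per-genome HEG counts and the number of HEGs in
#' marker-positive neighborhoods. Ordering is deterministic.
#'
#' @param nbhds list of classified `neighborhood` objects.
#' @return list with `per_marker` and `per_genome` data.frames.
#' @export
summarize_enrichment <- function(nbhds) {
  if (!length(nbhds)) stop("no neighborhoods to summarize")
  mk <- names(marker_accessions())
  n <- length(nbhds)
  counts <- vapply(mk, function(m) {
    sum(vapply(nbhds, function(nb) m %in% nb$markers, logical(1)))
  }, integer(1))
  per_marker <- data.frame(marker = mk, count = counts,
                           fraction = counts / n, stringsAsFactors = FALSE)
  gids <- vapply(nbhds, function(nb) nb$genome_id, character(1))
  pos <- vapply(nbhds, function(nb) length(nb$markers) > 0, logical(1))
  per_genome <- do.call(rbind, lapply(sort(unique(gids)), function(g) {
    data.frame(genome_id = g, n_hegs = sum(gids == g),
               n_in_marker_neighborhoods = sum(pos[gids == g]),
               stringsAsFactors = FALSE)
  }))
  list(per_marker = per_marker, per_genome = per_genome)
}

#' Neighborhoods as a results table
#' @param nbhds list of classified neighborhoods.
#' @return data.frame in the `neighborhoods` schema.
#' @export
neighborhoods_table <- function(nbhds) {
  do.call(rbind, lapply(nbhds, function(nb) {
    data.frame(genome_id = nb$genome_id, anchor_gene = nb$anchor$gene_id,
               start = nb$interval[1], end = nb$interval[2],
               n_genes = nrow(nb$member_genes),
               terminase = "terminase" %in% nb$markers,
               capsid = "capsid" %in% nb$markers,
               TMP = "TMP" %in% nb$markers, RNR = "RNR" %in% nb$markers,
               replicase = "replicase" %in% nb$markers,
               n_other_hegs = nrow(nb$other_hegs), stringsAsFactors = FALSE)
  }))
}
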