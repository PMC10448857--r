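#' Call HEG-islands between a genome pair
#'
#' A HEG-island is a large conserved cargo region bracketed by HEGs:
#' qualifying identity blocks (60% identity / 125 bp / 1e-5) are chained
#' when collinear within `chain_gap_bp` (default 2000) into conserved
#' regions; a region becomes an island iff its genomic span is at least
#' `island_min_span_bp` (default 10 kb), it contains at least one
#' essential-marker gene, and a HEG CDS lies within `heg_bracket_bp`
#' (default 1000) of each end (overlap counts). The island interval is then
#' trimmed to exclude the flanking HEG CDSs. Regions failing only the
#' bracket test are returned separately as unbracketed conserved regions.
#'
#' @param ga,gb `genome_record` pair (islands are reported on `ga`).
#' @param heg_calls HEG calls covering both genomes.
#' @param blocks qualifying identity blocks from [genome_blocks()] for
#'   (`ga`, `gb`).
#' @param hits domain-hits table (for marker genes in cargo).
#' @param config [heg_config()].
#' @param markers marker accession lists.
#' @return list with `islands` and `unbracketed`, both data.frames with
#'   interval, flanking HEGs, partner interval, block coverage fraction and
#'   length-weighted mean identity.
#' @export
call_heg_islands <- function(ga, gb, heg_calls, blocks, hits,
                             config = heg_config(),
                             markers = marker_accessions()) {
  for (g in list(ga, gb)) {
    if (!any(heg_calls$genome_id == g$id)) {
      stop("no HEG calls for genome '", g$id, "'")
    }
  }
  # re-filter: island support must derive only from qualifying blocks
  blocks <- blocks[blocks$identity_pct > config$block_min_identity_pct &
                     blocks$length >= config$block_min_len_bp &
                     blocks$evalue <= config$block_max_evalue, , drop = FALSE]
  empty <- island_row()[0, ]
  if (!nrow(blocks)) return(list(islands = empty, unbracketed = empty))

  chains <- chain_blocks(blocks, config$chain_gap_bp)
  hc <- heg_calls[heg_calls$genome_id == ga$id, , drop = FALSE]
  mk_genes <- marker_gene_ids(ga, hits, config, markers)

  islands <- list(); unbr <- list()
  for (ch in chains) {
    qs <- min(ch$q_start); qe <- max(ch$q_end)
    span <- qe - qs
    if (span < config$island_min_span_bp) next
    f <- ga$features
    cargo <- f[!f$wraps_origin & f$start < qe & f$end > qs, , drop = FALSE]
    has_marker <- any(cargo$gene_id %in% mk_genes)
    # bracket test: a HEG CDS within heg_bracket_bp of each end
    near_l <- hc[hc$end >= qs - config$heg_bracket_bp &
                   hc$start <= qs + config$heg_bracket_bp, , drop = FALSE]
    near_r <- hc[hc$end >= qe - config$heg_bracket_bp &
                   hc$start <= qe + config$heg_bracket_bp, , drop = FALSE]
    bracketed <- nrow(near_l) > 0 && nrow(near_r) > 0
    if (!has_marker) next
    ss <- min(ch$s_start); se <- max(ch$s_end)
    if (bracketed) {
      lh <- near_l[which.max(near_l$end), ]    # innermost flank
      rh <- near_r[which.min(near_r$start), ]
      iv <- c(max(qs, lh$end), min(qe, rh$start))
      # support statistics over the trimmed interval only, so the flanking
      # HEGs' own identity does not inflate the cargo identity; identity is
      # recomputed on the clipped segment where the block is collinear
      cs <- pmax(ch$q_start, iv[1]); ce <- pmin(ch$q_end, iv[2])
      cl_len <- ce - cs
      keep_b <- which(cl_len > 0)
      ident_cl <- vapply(keep_b, function(bi) {
        if (ch$strand[bi] == "+" &&
            (ch$q_end[bi] - ch$q_start[bi]) ==
              (ch$s_end[bi] - ch$s_start[bi])) {
          off <- ch$s_start[bi] - ch$q_start[bi]
          qa <- strsplit(get_subseq(ga, cs[bi], ce[bi]), "")[[1]]
          sb <- strsplit(get_subseq(gb, cs[bi] + off, ce[bi] + off), "")[[1]]
          100 * sum(qa == sb & qa != "N") / length(qa)
        } else ch$identity_pct[bi]
      }, numeric(1))
      cov <- sum(cl_len[keep_b]) / (iv[2] - iv[1])
      wid <- sum(ident_cl * cl_len[keep_b]) / sum(cl_len[keep_b])
      islands[[length(islands) + 1L]] <- island_row(
        ga$id, iv[1], iv[2], lh$gene_id, rh$gene_id, gb$id, ss, se,
        min(cov, 1), wid,
        paste(sort(unique(cargo$product[cargo$gene_id %in% mk_genes])),
              collapse = ","))
    } else {
      cov <- sum(pmin(ch$q_end, qe) - pmax(ch$q_start, qs)) / span
      wid <- sum(ch$identity_pct * ch$length) / sum(ch$length)
      unbr[[length(unbr) + 1L]] <- island_row(
        ga$id, qs, qe, NA_character_, NA_character_, gb$id, ss, se,
        min(cov, 1), wid, "")
    }
  }
  list(islands = dedup_islands(rbindf(islands, empty),
                               config$island_dedup_overlap),
       unbracketed = rbindf(unbr, empty))
}

island_row <- function(genome_id = character(), start = integer(),
                       end = integer(), left_heg = character(),
                       right_heg = character(), partner = character(),
                       partner_start = integer(), partner_end = integer(),
                       coverage = numeric(), weighted_identity = numeric(),
                       markers = character()) {
  data.frame(genome_id = genome_id, start = start, end = end,
             left_heg = left_heg, right_heg = right_heg, partner = partner,
             partner_start = partner_start, partner_end = partner_end,
             coverage = coverage, weighted_identity = weighted_identity,
             markers = markers, stringsAsFactors = FALSE)
}

rbindf <- function(lst, empty) if (length(lst)) do.call(rbind, lst) else empty

# collinear chaining of blocks within a maximum gap, per strand
chain_blocks <- function(blocks, gap_bp) {
  out <- list()
  for (str in unique(blocks$strand)) {
    b <- blocks[blocks$strand == str, , drop = FALSE]
    b <- b[order(b$q_start), , drop = FALSE]
    cur <- b[1, , drop = FALSE]
    for (i in seq_len(nrow(b))[-1]) {
      qgap <- b$q_start[i] - max(cur$q_end)
      if (str == "+") {
        sgap <- b$s_start[i] - max(cur$s_end)
      } else {
        sgap <- min(cur$s_start) - b$s_end[i]
      }
      if (qgap <= gap_bp && sgap <= gap_bp && sgap > -gap_bp) {
        cur <- rbind(cur, b[i, ])
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- b[i, , drop = FALSE]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  out
}

marker_gene_ids <- function(g, hits, config, markers = marker_accessions()) {
  accs <- unlist(markers, use.names = FALSE)
  mh <- hits[hits$domain_acc %in% accs &
               hits$i_evalue <= config$neighborhood_annot_evalue, , drop = FALSE]
  pref <- paste0(g$id, "|")
  sub("^.*\\|", "", mh$protein_id[startsWith(mh$protein_id, pref)])
}

# deduplicate islands overlapping by >= frac of the smaller interval
dedup_islands <- function(isl, frac) {
  if (nrow(isl) < 2) return(isl)
  isl <- isl[order(-(isl$end - isl$start)), , drop = FALSE]
  keep <- rep(TRUE, nrow(isl))
  for (i in 2:nrow(isl)) {
    for (j in seq_len(i - 1)) {
      if (!keep[j]) next
      if (isl$genome_id[i] != isl$genome_id[j]) next
      ov <- min(isl$end[i], isl$end[j]) - max(isl$start[i], isl$start[j])
      if (ov >= frac * (isl$end[i] - isl$start[i])) { keep[i] <- FALSE; break }
    }
  }
  out <- isl[keep, , drop = FALSE]
  out[order(out$genome_id, out$start), , drop = FALSE]
}

#' Classify cognate flanking HEGs between matched islands
#'
#' For each flank of a matched island pair: `homologous` iff the two
#' flanking HEG CDS intervals share a qualifying identity block; else
#' `same_class_no_homology` iff the families are equal; else
#' `different_class`; `absent` iff the partner flank lacks a HEG.
#'
#' @param island,partner_island single island rows matched as partners
#'   (the partner island called on the other genome of the pair).
#' @param heg_calls HEG calls covering both genomes.
#' @param genomes named list with both genome records.
#' @param config [heg_config()].
#' @return named character vector `c(left = ..., right = ...)`.
#' @export
classify_cognate_hegs <- function(island, partner_island, heg_calls, genomes,
                                  config = heg_config()) {
  if (island$partner != partner_island$genome_id) {
    stop("islands are not matched as partners")
  }
  ga <- genomes[[island$genome_id]]
  gb <- genomes[[partner_island$genome_id]]
  res <- c(left = "absent", right = "absent")
  for (side in c("left", "right")) {
    a_gene <- island[[paste0(side, "_heg")]]
    b_gene <- partner_island[[paste0(side, "_heg")]]
    if (is.na(b_gene) || is.na(a_gene)) { res[side] <- "absent"; next }
    ca <- heg_calls[heg_calls$genome_id == ga$id &
                      heg_calls$gene_id == a_gene, ][1, ]
    cb <- heg_calls[heg_calls$genome_id == gb$id &
                      heg_calls$gene_id == b_gene, ][1, ]
    sa <- get_subseq(ga, ca$start, ca$end)
    sb <- get_subseq(gb, cb$start, cb$end)
    bl <- find_identity_blocks(sa, sb, config)
    res[side] <- if (nrow(bl)) "homologous"
      else if (identical(ca$family, cb$family)) "same_class_no_homology"
      else "different_class"
  }
  res
}
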