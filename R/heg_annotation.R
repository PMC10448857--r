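#' Call HEGs from domain evidence
#'
#' A CDS is called a HEG iff it carries at least one nuclease-class domain
#' hit with independent e-value `<= heg_domain_evalue` (default 1e-3).
#' MUG113 hits are relabeled to the T5orf172 family (the two profiles are
#' closely related). The family is taken from the lowest-e-value nuclease
#' hit; a protein (or immediately adjacent CDS) combining an HNH-class hit
#' with an AP2-class hit is assigned the composite IPA-HNH family.
#'
#' @param genomes list of `genome_record` (or a single record).
#' @param hits domain-hits table; `protein_id` must be
#'   `"<genome_id>|<gene_id>"`.
#' @param config [heg_config()].
#' @param family_map [domain_family_map()] or a user-edited copy.
#' @return data.frame of HEG calls: `genome_id`, `gene_id`, `family`,
#'   `allele_state` (initially `"intact"`), `nuclease_acc`, `evalue`,
#'   `start`, `end`, `strand`.
#' @export
call_hegs <- function(genomes, hits, config = heg_config(),
                      family_map = domain_family_map()) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  names(genomes) <- vapply(genomes, `[[`, "", "id")
  known <- unlist(lapply(genomes, function(g) {
    if (nrow(g$features)) paste0(g$id, "|", g$features$gene_id) else character()
  }), use.names = FALSE)
  unknown <- setdiff(unique(hits$protein_id), known)
  if (length(unknown)) {
    stop("domain hits reference unknown protein(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  nuc <- family_map[family_map$role == "nuclease", ]
  h <- hits[hits$domain_acc %in% nuc$acc &
              hits$i_evalue <= config$heg_domain_evalue, , drop = FALSE]
  if (!nrow(h)) return(empty_heg_calls())
  h$family <- nuc$family[match(h$domain_acc, nuc$acc)]
  ap2 <- hits[hits$domain_acc == "PF00847" &
                hits$i_evalue <= config$heg_domain_evalue, , drop = FALSE]

  calls <- list()
  for (pid in unique(h$protein_id)) {
    hp <- h[h$protein_id == pid, , drop = FALSE]
    best <- hp[which.min(hp$i_evalue), ]
    parts <- strsplit(pid, "|", fixed = TRUE)[[1]]
    gid <- parts[1]; gene <- parts[2]
    fam <- best$family
    if (fam == "HNH-3" && has_ap2_context(pid, gid, gene, ap2, genomes[[gid]])) {
      fam <- "IPA-HNH"
    }
    g <- genomes[[gid]]
    f <- g$features[g$features$gene_id == gene, ][1, ]
    calls[[length(calls) + 1L]] <- data.frame(
      genome_id = gid, gene_id = gene, family = fam,
      allele_state = "intact", nuclease_acc = best$domain_acc,
      evalue = best$i_evalue, start = f$start, end = f$end,
      strand = f$strand, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, calls)
  out[order(out$genome_id, out$start), ]
}

empty_heg_calls <- function() {
  data.frame(genome_id = character(), gene_id = character(),
             family = character(), allele_state = character(),
             nuclease_acc = character(), evalue = numeric(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

# AP2 hit on the same protein or an immediately adjacent CDS
has_ap2_context <- function(pid, gid, gene, ap2, genome) {
  if (!nrow(ap2)) return(FALSE)
  if (pid %in% ap2$protein_id) return(TRUE)
  f <- genome$features
  ord <- order(f$start)
  f <- f[ord, ]
  at <- which(f$gene_id == gene)
  if (!length(at)) return(FALSE)
  nbr <- f$gene_id[c(at - 1, at + 1)]
  nbr <- nbr[!is.na(nbr)]
  any(paste0(gid, "|", nbr) %in% ap2$protein_id)
}

#' Classify HEG allele states across homologous loci
#'
#' Given a group of homologous HEG loci across related genomes (from a
#' user-supplied locus map or from [group_heg_loci()]), classifies each
#' genome's allele:
#' * `absent` — no CDS with a nuclease hit at the locus;
#' * `frameshifted` — the locus is covered by two or more CDSs whose
#'   concatenated length matches the group's modal length within
#'   `frameshift_offset_bp` (2 bp) and whose combined hits restore one
#'   domain architecture; such split pairs are also emitted as a single
#'   `fused` call for downstream analyses;
#' * `inframe_deletion` — the CDS length differs from the group modal
#'   length by a multiple of 3 of at least `min_inframe_del_bp` (30 bp);
#' * `intact` — otherwise.
#'
#' @param locus_group data.frame with columns `genome_id`, `locus`,
#'   `start`, `end` (one row per genome; `start == end` marks a clean
#'   excision point). All rows describe homologous positions of one locus.
#' @param genomes named list of `genome_record`.
#' @param heg_calls output of [call_hegs()] over the same genomes.
#' @param hits the domain-hits table.
#' @param config [heg_config()].
#' @return data.frame of per-genome calls at this locus, including fused
#'   calls (gene_id `"<a>+<b>"`) for reconstituted split pairs.
#' @export
classify_allele_state <- function(locus_group, genomes, heg_calls, hits,
                                  config = heg_config()) {
  if (!nrow(locus_group)) stop("empty locus group")
  rows <- list()
  # CDSs at each genome's locus interval
  per_genome <- lapply(seq_len(nrow(locus_group)), function(i) {
    li <- locus_group[i, ]
    g <- genomes[[li$genome_id]]
    f <- g$features
    sel <- !f$wraps_origin & f$start < li$end & f$end > li$start
    f[sel, , drop = FALSE]
  })
  lens <- vapply(per_genome, function(f) {
    if (nrow(f)) sum(f$end - f$start) else NA_integer_
  }, numeric(1))
  # reference = the full-length allele of the group. Frameshifts and
  # in-frame deletions only shorten a locus, so the longest observed allele
  # is the intact form; a modal length would flip whenever deleted alleles
  # happen to dominate a small group. A reconstituted split pair also
  # anchors the reference: its summed length carries the 1-2 bp frameshift
  # indel, which is removed by rounding to the codon grid (a complete CDS
  # length is always divisible by 3).
  single <- vapply(per_genome, nrow, integer(1)) == 1
  cand <- c(lens[single], 3 * round(lens[!single] / 3))
  modal_len <- suppressWarnings(max(cand, na.rm = TRUE))
  if (!is.finite(modal_len)) modal_len <- 0L

  for (i in seq_len(nrow(locus_group))) {
    li <- locus_group[i, ]
    f <- per_genome[[i]]
    gid <- li$genome_id
    pid <- function(gene) paste0(gid, "|", gene)
    nuc_hits <- function(gene) {
      hh <- hits[hits$protein_id == pid(gene), , drop = FALSE]
      fm <- domain_family_map()
      hh[hh$domain_acc %in% fm$acc[fm$role == "nuclease"] &
           hh$i_evalue <= config$heg_domain_evalue, , drop = FALSE]
    }
    has_nuc <- vapply(f$gene_id, function(g) nrow(nuc_hits(g)) > 0, logical(1))
    if (!nrow(f) || !any(has_nuc)) {
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = gid, gene_id = li$locus, family = group_family(heg_calls),
        allele_state = "absent", nuclease_acc = NA_character_,
        evalue = NA_real_, start = li$start, end = li$end, strand = "+",
        evidence = "no CDS with nuclease hit at locus",
        stringsAsFactors = FALSE)
      next
    }
    if (nrow(f) >= 2) {
      tot <- sum(f$end - f$start)
      # split pair restores one domain architecture: nuclease class on one
      # fragment, DNA-binding class on another
      fm <- domain_family_map()
      frag_hits <- lapply(f$gene_id, function(gn) {
        hh <- hits[hits$protein_id == pid(gn) &
                     hits$i_evalue <= config$heg_domain_evalue, , drop = FALSE]
        fm$role[match(hh$domain_acc, fm$acc)]
      })
      has_nuc_frag <- vapply(frag_hits, function(r) "nuclease" %in% r, logical(1))
      has_dbd_frag <- vapply(frag_hits, function(r) "dbd" %in% r, logical(1))
      arch_restored <- any(has_nuc_frag) && any(has_dbd_frag & !has_nuc_frag)
      if (arch_restored || abs(tot - modal_len) <= config$frameshift_offset_bp) {
        # concatenation restores the modal length: frameshift split
        genes <- f$gene_id[order(f$start)]
        cl <- heg_calls[heg_calls$genome_id == gid &
                          heg_calls$gene_id %in% genes, , drop = FALSE]
        fam <- if (nrow(cl)) cl$family[1] else group_family(heg_calls)
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = gid, gene_id = paste(genes, collapse = "+"),
          family = fam, allele_state = "frameshifted",
          nuclease_acc = if (nrow(cl)) cl$nuclease_acc[1] else NA_character_,
          evalue = if (nrow(cl)) cl$evalue[1] else NA_real_,
          start = min(f$start), end = max(f$end), strand = f$strand[1],
          evidence = sprintf(
            "split CDS pair, concatenated length %d vs modal %d (offset %d bp); includes variable-stop alleles",
            tot, modal_len, tot - modal_len),
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- within(rows[[length(rows)]], {
          allele_state <- "fused"
          evidence <- "reconstituted split pair emitted for architecture analyses"
        })
        next
      }
    }
    # single (or dominant) CDS
    fmain <- f[which(has_nuc)[1], ]
    len <- fmain$end - fmain$start
    d <- modal_len - len
    cl <- heg_calls[heg_calls$genome_id == gid &
                      heg_calls$gene_id == fmain$gene_id, , drop = FALSE]
    state <- if (d != 0 && d %% 3 == 0 && abs(d) >= config$min_inframe_del_bp) {
      "inframe_deletion"
    } else "intact"
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = gid, gene_id = fmain$gene_id,
      family = if (nrow(cl)) cl$family[1] else group_family(heg_calls),
      allele_state = state,
      nuclease_acc = if (nrow(cl)) cl$nuclease_acc[1] else NA_character_,
      evalue = if (nrow(cl)) cl$evalue[1] else NA_real_,
      start = fmain$start, end = fmain$end, strand = fmain$strand,
      evidence = if (state == "inframe_deletion") {
        sprintf("CDS %d bp shorter than modal %d (in frame)", d, modal_len)
      } else "single full-length CDS",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

group_family <- function(heg_calls) {
  if (nrow(heg_calls)) names(which.max(table(heg_calls$family))) else "other"
}

#' Group HEG loci across genomes by flank anchoring
#'
#' Default locus grouping when no locus map is supplied: loci are anchored
#' by orthology of their flanking sequence (2 kb on each side), because the
#' HEG sequences themselves diverge. HEG calls in different genomes are
#' connected when their flanks share a qualifying identity block; connected
#' components define the locus groups. Ties are broken by highest flank
#' coverage.
#'
#' @param genomes named list of `genome_record`.
#' @param heg_calls output of [call_hegs()].
#' @param config [heg_config()].
#' @return list of data.frames, each a locus group with columns
#'   `genome_id`, `locus`, `start`, `end`.
#' @export
group_heg_loci <- function(genomes, heg_calls, config = heg_config()) {
  n <- nrow(heg_calls)
  if (!n) return(list())
  fl <- config$locus_flank_bp
  flank_seq <- function(i) {
    cl <- heg_calls[i, ]
    g <- genomes[[cl$genome_id]]
    left <- get_subseq(g, max(cl$start - fl, 0), cl$start)
    right <- get_subseq(g, cl$end, min(cl$end + fl, g$length))
    c(left, right)
  }
  flanks <- lapply(seq_len(n), flank_seq)
  # union-find over calls
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  # a locus is the same locus only when BOTH flanks are orthologous; a
  # single shared flank arises spuriously whenever an intervening HEG is
  # absent in one genome and the window reaches the next gene over. Flanks
  # truncated by a contig end are treated as uninformative.
  flank_linked <- function(fa, fb) {
    if (nchar(fa) < 200 || nchar(fb) < 200) return(TRUE)
    nrow(find_identity_blocks(fa, fb, config)) > 0
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (heg_calls$genome_id[i] == heg_calls$genome_id[j]) next
      if (flank_linked(flanks[[i]][1], flanks[[j]][1]) &&
          flank_linked(flanks[[i]][2], flanks[[j]][2])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(split(seq_len(n), roots), function(idx) {
    data.frame(genome_id = heg_calls$genome_id[idx],
               locus = heg_calls$gene_id[idx],
               start = heg_calls$start[idx], end = heg_calls$end[idx],
               stringsAsFactors = FALSE)
  })
}

#' Filter genome records by length and provenance
#'
#' Drops records shorter than `min_genome_bp` (default 20 kb) and records
#' whose `source_tag` marks them as metagenome assemblies.
#'
#' @param genomes list of `genome_record`.
#' @param config [heg_config()].
#' @return list with `retained` (list of records) and `rejected`
#'   (data.frame `genome_id`, `reason`).
#' @export
filter_genomes <- function(genomes, config = heg_config()) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  keep <- logical(length(genomes))
  reasons <- character(0); ids <- character(0)
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    if (g$length < config$min_genome_bp) {
      ids <- c(ids, g$id)
      reasons <- c(reasons, sprintf("length %d bp < %d bp minimum",
                                    g$length, config$min_genome_bp))
    } else if (grepl("metagenome", g$source_tag, ignore.case = TRUE)) {
      ids <- c(ids, g$id)
      reasons <- c(reasons, "metagenome assembly")
    } else keep[i] <- TRUE
  }
  list(retained = genomes[keep],
       rejected = data.frame(genome_id = ids, reason = reasons,
                             stringsAsFactors = FALSE))
}
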