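#' Find pairwise nucleotide identity blocks
#'
#' Seed-and-extend local similarity search between two DNA sequences: exact
#' k-mer seeds on both strands, ungapped X-drop extension (match +1,
#' mismatch -2 by default), and banded stitching of collinear extensions
#' across small indels. Returned blocks satisfy the acceptance thresholds
#' used throughout the analysis: identity > `block_min_identity_pct`
#' (default 60), length >= `block_min_len_bp` (default 125), and e-value <=
#' `block_max_evalue` (default 1e-5). Identity is `matches / alignment
#' columns` (gap columns included in the denominator, matching BLAST's
#' `pident` convention); columns containing N never count as matches.
#'
#' Reverse-strand blocks report `s_start`/`s_end` on the forward strand of
#' the subject with `strand = "-"`. Blocks are sorted by score descending,
#' ties broken by (`q_start`, `s_start`) ascending.
#'
#' @param a,b DNA strings (query, subject).
#' @param config [heg_config()].
#' @param query_id,subject_id ids recorded in the output.
#' @param filter apply the identity/length/e-value thresholds (set `FALSE`
#'   to obtain all raw extensions).
#' @return data.frame with columns `query_id`, `subject_id`, `q_start`,
#'   `q_end`, `s_start`, `s_end` (0-based half-open, forward strand),
#'   `strand`, `identity_pct`, `length` (alignment columns), `score`,
#'   `evalue`.
#' @export
find_identity_blocks <- function(a, b, config = heg_config(),
                                 query_id = "query", subject_id = "subject",
                                 filter = TRUE) {
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  n <- nchar(b)
  res <- list()
  for (str in c("+", "-")) {
    bb <- if (str == "-") revcomp(b) else b
    raw <- cpp_find_blocks(a, bb, config$seed_k, config$match_score,
                           config$mismatch_score, config$xdrop,
                           config$gap_open, config$gap_extend,
                           config$stitch_band, TRUE)
    if (!nrow(raw)) next
    if (str == "-") {
      s_start <- n - raw$se
      s_end <- n - raw$ss
    } else {
      s_start <- raw$ss
      s_end <- raw$se
    }
    res[[str]] <- data.frame(
      query_id = query_id, subject_id = subject_id,
      q_start = raw$qs, q_end = raw$qe, s_start = s_start, s_end = s_end,
      strand = str, identity_pct = 100 * raw$matches / pmax(raw$cols, 1L),
      length = raw$cols, score = raw$score, stringsAsFactors = FALSE)
  }
  if (!length(res)) return(empty_blocks(query_id, subject_id))
  out <- do.call(rbind, res)
  out$evalue <- block_evalue(out$score, nchar(a), n, config)
  if (filter) {
    out <- out[out$identity_pct > config$block_min_identity_pct &
                 out$length >= config$block_min_len_bp &
                 out$evalue <= config$block_max_evalue, , drop = FALSE]
  }
  out <- out[order(-out$score, out$q_start, out$s_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_blocks <- function(query_id = character(), subject_id = character()) {
  data.frame(query_id = character(), subject_id = character(),
             q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), strand = character(),
             identity_pct = numeric(), length = integer(), score = numeric(),
             evalue = numeric(), stringsAsFactors = FALSE)
}

#' Karlin-Altschul e-value for an ungapped block score
#'
#' `E = K * m * n * exp(-lambda * S)` with the fixed ungapped parameters for
#' the +1/-2 scoring system (`lambda = 1.33271`, `K = 0.620991`, recorded in
#' the config). The same parameters are used for stitched (gapped) blocks as
#' a documented approximation; the e-value serves only as an acceptance
#' filter at 1e-5, not as a reported statistic.
#'
#' @param score block score(s), `>= 0`.
#' @param m,n query and subject lengths.
#' @param config [heg_config()] supplying `ka_lambda`, `ka_k`.
#' @return numeric e-value(s).
#' @export
block_evalue <- function(score, m, n, config = heg_config()) {
  stopifnot(all(score >= 0))
  config$ka_k * as.numeric(m) * as.numeric(n) * exp(-config$ka_lambda * score)
}

#' Greedy identity clustering of sequences
#'
#' Longest-first greedy clustering in the style of CD-HIT: each sequence
#' joins the first existing cluster whose representative shares at least
#' `identity_pct` identity over the shorter sequence's length (identity from
#' a global-local alignment of the shorter sequence into the longer);
#' otherwise it founds a new cluster. Representatives are the founding
#' (longest) members. Works on DNA or protein strings.
#'
#' @param seqs named character vector (names = ids) or list of sequences.
#' @param identity_pct clustering threshold in (0, 100].
#' @return list with `clusters` (list of character id vectors) and
#'   `representatives` (character vector of founding ids).
#' @export
cluster_sequences <- function(seqs, identity_pct = 90) {
  seqs <- unlist(seqs)
  if (!length(seqs)) stop("no sequences to cluster")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character()
  clusters <- list()
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (pair_identity_over_shorter(seqs[[i]], seqs[[reps[ci]]]) >= identity_pct) {
        clusters[[ci]] <- c(clusters[[ci]], names(seqs)[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, names(seqs)[i])
      clusters[[length(clusters) + 1L]] <- names(seqs)[i]
      names(clusters)[length(clusters)] <- names(seqs)[i]
    }
  }
  list(clusters = clusters, representatives = reps)
}

# identity of the shorter sequence aligned globally into the longer,
# as matches / shorter length
pair_identity_over_shorter <- function(x, y) {
  if (nchar(x) > nchar(y)) { tmp <- x; x <- y; y <- tmp }
  is_dna <- !grepl("[^ACGTNacgtn]", paste0(x, y))
  if (is_dna) {
    p <- Biostrings::DNAString(toupper(x)); s <- Biostrings::DNAString(toupper(y))
  } else {
    p <- Biostrings::AAString(toupper(x)); s <- Biostrings::AAString(toupper(y))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- if (is_dna) {
    Biostrings::pairwiseAlignment(p, s, type = "global-local",
                                  substitutionMatrix = mat,
                                  gapOpening = 5, gapExtension = 2)
  } else {
    Biostrings::pairwiseAlignment(p, s, type = "global-local",
                                  substitutionMatrix =
                                    identity_substitution_matrix(),
                                  gapOpening = 5, gapExtension = 2)
  }
  100 * Biostrings::nmatch(aln) / nchar(x)
}

identity_substitution_matrix <- function() {
  letters_aa <- strsplit("ARNDCQEGHILKMFPSTWYVBZX*", "")[[1]]
  m <- matrix(-1, length(letters_aa), length(letters_aa),
              dimnames = list(letters_aa, letters_aa))
  diag(m) <- 1
  m
}

#' Blocks between two genome records
#'
#' Convenience wrapper running [find_identity_blocks()] on the sequences of
#' two genome records, recording their ids.
#'
#' @param ga,gb `genome_record` objects.
#' @param config [heg_config()].
#' @return blocks data.frame (see [find_identity_blocks()]).
#' @export
genome_blocks <- function(ga, gb, config = heg_config()) {
  find_identity_blocks(ga$sequence, gb$sequence, config,
                       query_id = ga$id, subject_id = gb$id)
}

#' Export blocks in BLAST outfmt-6 column semantics
#'
#' Writes 1-based inclusive coordinates; minus-strand blocks have
#' `sstart > send`, as in BLAST tabular output.
#'
#' @param blocks blocks data.frame.
#' @param path output TSV.
#' @export
write_blocks_outfmt6 <- function(blocks, path) {
  df <- data.frame(
    qseqid = blocks$query_id, sseqid = blocks$subject_id,
    pident = blocks$identity_pct, length = blocks$length,
    qstart = blocks$q_start + 1L, qend = blocks$q_end,
    sstart = ifelse(blocks$strand == "+", blocks$s_start + 1L, blocks$s_end),
    send = ifelse(blocks$strand == "+", blocks$s_end, blocks$s_start + 1L),
    evalue = blocks$evalue, bitscore = blocks$score)
  write_results_table(df, path, "blocks")
}
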