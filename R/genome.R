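#' Genome record constructor
#'
#' A `genome_record` is one replicon: its sequence (over A/C/G/T/N),
#' circularity flag, CDS features and a free-text provenance tag. All
#' internal coordinates are 0-based half-open on the forward strand; strand
#' is a feature attribute, never a coordinate transform. A feature crossing
#' the origin of a circular replicon keeps `wraps_origin = TRUE` and is
#' interpreted modulo the genome length (see [unwrap_interval()]).
#'
#' @param id replicon identifier, unique within a collection.
#' @param sequence DNA string over `{A,C,G,T,N}` (case-insensitive).
#' @param circular logical; circular replicon.
#' @param features data.frame as built by [gene_features()]; may be empty.
#' @param source_tag free-text provenance (e.g. isolate name); the token
#'   `"metagenome"` marks metagenome assemblies for [filter_genomes()].
#' @return object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, circular = FALSE, features = NULL,
                          source_tag = "") {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence for genome '", id, "'")
  if (grepl("[^ACGTN]", sequence)) {
    stop("genome '", id, "' contains characters outside {A,C,G,T,N}")
  }
  if (is.null(features)) features <- gene_features()
  L <- nchar(sequence)
  if (nrow(features)) {
    bad <- !features$wraps_origin &
      (features$start < 0 | features$end > L | features$start >= features$end)
    if (any(bad)) {
      stop("feature(s) outside [0, length) in genome '", id, "': ",
           paste(features$gene_id[bad], collapse = ", "))
    }
  }
  structure(list(id = id, sequence = sequence, circular = circular,
                 length = L, features = features, source_tag = source_tag),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %s, %d features%s\n", x$id, x$length,
              if (x$circular) "circular" else "linear", nrow(x$features),
              if (nzchar(x$source_tag)) paste0(" [", x$source_tag, "]") else ""))
  invisible(x)
}

#' Build a gene-feature table
#'
#' @param gene_id,start,end,strand,wraps_origin,product,protein_seq parallel
#'   vectors; intervals 0-based half-open on the forward strand. For a
#'   feature with `wraps_origin = TRUE`, `end < start` and the feature covers
#'   `[start, L) U [0, end)`.
#' @return data.frame with one row per feature.
#' @export
gene_features <- function(gene_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          wraps_origin = logical(), product = character(),
                          protein_seq = character()) {
  n <- length(gene_id)
  if (!length(wraps_origin)) wraps_origin <- rep(FALSE, n)
  if (!length(product)) product <- rep("", n)
  if (!length(protein_seq)) protein_seq <- rep(NA_character_, n)
  data.frame(gene_id = as.character(gene_id), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand),
             wraps_origin = as.logical(wraps_origin),
             product = as.character(product),
             protein_seq = as.character(protein_seq),
             stringsAsFactors = FALSE)
}

#' Unwrap a (possibly origin-crossing) interval
#'
#' Converts a stored interval to unwrapped coordinates `[start, start + len)`
#' where `len = (end - start) mod L` for wrapping intervals. The unwrapped
#' end may exceed the genome length; positions are then taken modulo `L`.
#'
#' @param start,end stored 0-based half-open interval.
#' @param L genome length.
#' @param wraps logical, interval crosses the origin.
#' @return numeric vector `c(start, end_unwrapped)`.
#' @export
unwrap_interval <- function(start, end, L, wraps = end <= start) {
  len <- if (wraps) ((end - start) %% L) else (end - start)
  c(start, start + len)
}

#' Length of a stored feature interval
#' @inheritParams unwrap_interval
#' @return integer length in bp.
#' @export
interval_length <- function(start, end, L, wraps = end <= start) {
  as.integer(if (wraps) ((end - start) %% L) else (end - start))
}

#' Extract a (modular) subsequence
#'
#' `start`/`end` are unwrapped 0-based half-open coordinates; `end` may
#' exceed the genome length on a circular replicon, in which case the
#' sequence wraps past the origin.
#'
#' @param genome a `genome_record`.
#' @param start,end unwrapped interval, `0 <= start < L`, `end <= start + L`.
#' @return character DNA string of length `end - start`.
#' @export
get_subseq <- function(genome, start, end) {
  L <- genome$length
  stopifnot(start >= 0, end >= start, end - start <= L)
  if (end <= L) return(substr(genome$sequence, start + 1, end))
  if (!genome$circular) stop("interval [", start, ",", end,
                             ") extends past the end of linear genome ", genome$id)
  paste0(substr(genome$sequence, start + 1, L),
         substr(genome$sequence, 1, end - L))
}

#' Do two modular intervals overlap?
#'
#' Intervals are given in unwrapped coordinates (`end` may exceed `L`).
#' Overlap means at least one shared base on the circle.
#'
#' @param s1,e1,s2,e2 unwrapped 0-based half-open intervals.
#' @param L genome length (use `Inf` for linear comparison).
#' @return logical.
#' @export
intervals_overlap_mod <- function(s1, e1, s2, e2, L = Inf) {
  if (!is.finite(L)) return(s1 < e2 & s2 < e1)
  # compare on the doubled circle: shift each interval by -L, 0, +L
  for (d in c(-L, 0, L)) {
    if (s1 < e2 + d && s2 + d < e1) return(TRUE)
  }
  FALSE
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA strings.
#' @return character vector.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# codon -> amino acid lookup (standard code), built once
codon_table <- local({
  code <- Biostrings::GENETIC_CODE
  tab <- as.character(code)
  names(tab) <- names(code)
  tab
})

#' Translate a CDS nucleotide string to protein
#'
#' Truncates any trailing partial codon and drops the terminal stop;
#' codons containing N translate to X.
#' @param nt character DNA string (forward-strand CDS sequence).
#' @return character amino-acid string.
#' @export
translate_cds <- function(nt) {
  n <- 3 * (nchar(nt) %/% 3)
  if (n == 0) return("")
  codons <- substring(nt, seq(1, n - 2, 3), seq(3, n, 3))
  aa <- unname(codon_table[codons])
  aa[is.na(aa)] <- "X"
  sub("\\*$", "", paste(aa, collapse = ""))
}

#' Forward-strand CDS sequence of a feature
#'
#' Returns the coding sequence of a feature reading 5'->3' on its own strand
#' (i.e. reverse-complemented for minus-strand features).
#'
#' @param genome a `genome_record`.
#' @param feature one-row slice of the feature table.
#' @return character DNA string.
#' @export
feature_cds <- function(genome, feature) {
  uw <- unwrap_interval(feature$start, feature$end, genome$length,
                        feature$wraps_origin)
  s <- get_subseq(genome, uw[1], uw[2])
  if (feature$strand == "-") revcomp(s) else s
}
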