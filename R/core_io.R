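#' Read genome records
#'
#' Reads one or more replicons from FASTA, GenBank flat file, or GFF3 with an
#' accompanying FASTA. GenBank CDS features become gene features with
#' translations when present; FASTA yields feature-less records. All
#' coordinates are converted to 0-based half-open at the boundary; a GenBank
#' compound (`join`) location running past the origin sets `wraps_origin`.
#'
#' @param path input file.
#' @param format one of `"fasta"`, `"genbank"`, `"gff3"`.
#' @param fasta_path for `format = "gff3"`, the FASTA with the sequences.
#' @param circular default circularity for formats that do not record
#'   topology (FASTA, GFF3).
#' @param source_tag provenance tag applied to all records read.
#' @return list of [genome_record()] objects.
#' @export
read_genome_records <- function(path, format = c("fasta", "genbank", "gff3"),
                                fasta_path = NULL, circular = FALSE,
                                source_tag = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
    fasta = {
      seqs <- Biostrings::readDNAStringSet(path)
      if (!length(seqs)) stop("empty FASTA file: ", path)
      ids <- sub("\\s.*$", "", names(seqs))
      lapply(seq_along(seqs), function(i) {
        genome_record(ids[i], as.character(seqs[[i]]), circular = circular,
                      source_tag = source_tag)
      })
    },
    genbank = read_genbank(path, source_tag = source_tag),
    gff3 = {
      if (is.null(fasta_path)) stop("format 'gff3' requires fasta_path")
      recs <- read_genome_records(fasta_path, "fasta", circular = circular,
                                  source_tag = source_tag)
      names(recs) <- vapply(recs, `[[`, "", "id")
      feats <- read_gff3_features(path)
      for (sid in unique(feats$seqid)) {
        if (!sid %in% names(recs)) {
          stop("GFF3 references unknown sequence '", sid, "'")
        }
        f <- feats[feats$seqid == sid, , drop = FALSE]
        recs[[sid]] <- genome_record(
          recs[[sid]]$id, recs[[sid]]$sequence, circular = circular,
          features = gene_features(f$gene_id, f$start, f$end, f$strand),
          source_tag = source_tag)
      }
      unname(recs)
    })
}

# GFF3 CDS features -> data.frame (0-based half-open)
read_gff3_features <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (length(ln) && any(ln == "##FASTA")) ln <- ln[seq_len(which(ln == "##FASTA")[1] - 1)]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  keep <- vapply(parts, function(p) length(p) >= 9 && p[3] == "CDS", logical(1))
  parts <- parts[keep]
  if (!length(parts)) {
    return(data.frame(seqid = character(), gene_id = character(),
                      start = integer(), end = integer(), strand = character()))
  }
  ids <- vapply(parts, function(p) {
    m <- regmatches(p[9], regexec("ID=([^;]+)", p[9]))[[1]]
    if (length(m) == 2) m[2] else paste0(p[1], ":", p[4])
  }, character(1))
  data.frame(
    seqid = vapply(parts, `[[`, "", 1),
    gene_id = ids,
    start = vapply(parts, function(p) as.integer(p[4]) - 1L, integer(1)),
    end = vapply(parts, function(p) as.integer(p[5]), integer(1)),
    strand = vapply(parts, `[[`, "", 7))
}

# Minimal GenBank flat-file reader: LOCUS topology, CDS features with
# location/translation qualifiers, ORIGIN sequence. Coordinates converted
# from 1-based inclusive to 0-based half-open; a join() whose later segment
# restarts below an earlier one is stored as an origin-wrapping interval.
read_genbank <- function(path, source_tag = "") {
  ln <- readLines(path)
  if (!length(ln)) stop("empty GenBank file: ", path)
  starts <- grep("^LOCUS", ln)
  if (!length(starts)) stop("no LOCUS line in ", path)
  ends <- c(starts[-1] - 1L, length(ln))
  lapply(seq_along(starts), function(i) {
    parse_genbank_locus(ln[starts[i]:ends[i]], path, source_tag)
  })
}

parse_genbank_locus <- function(ln, path, source_tag) {
  locus <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  if (length(locus) < 2) stop("malformed LOCUS line in ", path)
  id <- locus[2]
  circular <- any(grepl("\\bcircular\\b", ln[1], ignore.case = TRUE))

  ori <- grep("^ORIGIN", ln)
  if (!length(ori)) stop("no ORIGIN section for locus '", id, "' in ", path)
  seq_ln <- ln[(ori[1] + 1):length(ln)]
  seq_ln <- seq_ln[!grepl("^//", seq_ln)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_ln, collapse = "")))
  if (!nzchar(sequence)) stop("empty sequence for locus '", id, "' in ", path)
  L <- nchar(sequence)

  fstart <- grep("^FEATURES", ln)
  feats <- gene_features()
  if (length(fstart)) {
    fln <- ln[(fstart[1] + 1):(ori[1] - 1)]
    # feature entries start at column 6; continuation/qualifier lines at 22
    entry_idx <- grep("^ {5}\\S", fln)
    if (length(entry_idx)) {
      entry_end <- c(entry_idx[-1] - 1L, length(fln))
      rows <- list()
      for (k in seq_along(entry_idx)) {
        block <- fln[entry_idx[k]:entry_end[k]]
        key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
        if (!identical(key, "CDS")) next
        rows[[length(rows) + 1L]] <- parse_genbank_cds(block, id, L, path)
      }
      if (length(rows)) feats <- do.call(rbind, rows)
    }
  }
  genome_record(id, sequence, circular = circular, features = feats,
                source_tag = source_tag)
}

parse_genbank_cds <- function(block, locus_id, L, path) {
  # location may continue over lines until the first qualifier line
  qual_at <- grep("^\\s{10,}/", block)
  loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(block)
  loc <- paste(trimws(sub("^\\s*CDS\\s*", "", block[1:loc_end])), collapse = "")
  strand <- if (grepl("complement", loc)) "-" else "+"
  inner <- gsub("complement\\(|join\\(|order\\(|\\)", "", loc)
  inner <- gsub("[<>]", "", inner)
  segs <- strsplit(inner, ",")[[1]]
  m <- regmatches(segs, regexec("^(\\d+)\\.\\.(\\d+)$", segs))
  single <- regmatches(segs, regexec("^(\\d+)$", segs))
  a <- b <- integer(length(segs))
  for (j in seq_along(segs)) {
    if (length(m[[j]]) == 3) {
      a[j] <- as.integer(m[[j]][2]); b[j] <- as.integer(m[[j]][3])
    } else if (length(single[[j]]) == 2) {
      a[j] <- b[j] <- as.integer(single[[j]][2])
    } else {
      stop("cannot parse CDS location '", loc, "' at locus '", locus_id,
           "' in ", path)
    }
  }
  wraps <- length(segs) > 1 && any(diff(a) < 0)
  if (wraps) {
    start <- a[1] - 1L
    end <- b[length(b)]
  } else {
    start <- min(a) - 1L
    end <- max(b)
  }
  quals <- parse_genbank_qualifiers(block)
  gene_id <- quals[["locus_tag"]] %||% quals[["gene"]] %||%
    paste0(locus_id, ":", start + 1L)
  gene_features(gene_id, start, if (wraps) end else end, strand,
                wraps_origin = wraps,
                product = quals[["product"]] %||% "",
                protein_seq = quals[["translation"]] %||% NA_character_)
}

parse_genbank_qualifiers <- function(block) {
  qual_at <- grep("^\\s{10,}/", block)
  out <- list()
  if (!length(qual_at)) return(out)
  bounds <- c(qual_at, length(block) + 1L)
  for (k in seq_along(qual_at)) {
    txt <- paste(trimws(block[qual_at[k]:(bounds[k + 1] - 1L)]), collapse = " ")
    m <- regmatches(txt, regexec("^/([A-Za-z_]+)(=\"?(.*?)\"?)?$", txt))[[1]]
    if (length(m) >= 2) {
      val <- if (length(m) >= 4 && nzchar(m[4])) m[4] else ""
      if (m[2] == "translation") val <- gsub(" ", "", val)
      out[[m[2]]] <- val
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Read domain hits from a HMMER3 per-domain table (domtblout)
#'
#' One row per domain hit, using envelope coordinates and the independent
#' e-value. No filtering is applied at read time; thresholds are applied by
#' the consuming modules.
#'
#' @param path domtblout file (whitespace-delimited, `#` comments).
#' @return data.frame with columns `protein_id`, `domain_name`, `domain_acc`,
#'   `aa_from`, `aa_to`, `i_evalue`, `bit_score` (a "domain_hits" table).
#' @export
read_domain_hits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  keep <- which(!startsWith(ln, "#") & nzchar(trimws(ln)))
  if (!length(keep)) return(domain_hits())
  parts <- strsplit(trimws(ln[keep]), "\\s+")
  nf <- lengths(parts)
  if (any(nf < 22)) {
    stop("malformed domtblout row at line ", keep[which(nf < 22)[1]],
         " of ", path, " (", nf[which(nf < 22)[1]], " fields, expected >= 22)")
  }
  domain_hits(
    protein_id  = vapply(parts, `[[`, "", 1),
    domain_name = vapply(parts, `[[`, "", 4),
    domain_acc  = sub("\\.\\d+$", "", vapply(parts, `[[`, "", 5)),
    aa_from     = as.integer(vapply(parts, `[[`, "", 20)),
    aa_to       = as.integer(vapply(parts, `[[`, "", 21)),
    i_evalue    = as.numeric(vapply(parts, `[[`, "", 13)),
    bit_score   = as.numeric(vapply(parts, `[[`, "", 14)))
}

#' Construct a domain-hits table
#' @param protein_id,domain_name,domain_acc,aa_from,aa_to,i_evalue,bit_score
#'   parallel vectors; `aa_from`/`aa_to` are 1-based inclusive envelope
#'   coordinates on the protein.
#' @return data.frame.
#' @export
domain_hits <- function(protein_id = character(), domain_name = character(),
                        domain_acc = character(), aa_from = integer(),
                        aa_to = integer(), i_evalue = numeric(),
                        bit_score = numeric()) {
  stopifnot(all(aa_from >= 1), all(aa_to >= aa_from), all(is.finite(i_evalue)))
  data.frame(protein_id = as.character(protein_id),
             domain_name = as.character(domain_name),
             domain_acc = as.character(domain_acc),
             aa_from = as.integer(aa_from), aa_to = as.integer(aa_to),
             i_evalue = as.numeric(i_evalue),
             bit_score = as.numeric(bit_score), stringsAsFactors = FALSE)
}

#' Write a domain-hits table as HMMER3 domtblout
#'
#' Emits the whitespace-delimited per-domain table dialect so that
#' [read_domain_hits()] round-trips the fields this package consumes.
#'
#' @param hits a domain-hits table.
#' @param path output file.
#' @export
write_domtblout <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# target name accession tlen query name accession qlen E-value score bias # of c-Evalue i-Evalue score bias from to from to from to acc description",
               "#---"), con)
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      writeLines(sprintf(
        "%s - %d %s %s %d %.2g %.1f 0.0 1 1 %.2g %.3g %.1f 0.0 1 %d %d %d %d %d 0.99 -",
        h$protein_id, h$aa_to + 10L, h$domain_name, h$domain_acc,
        h$aa_to - h$aa_from + 1L, h$i_evalue, h$bit_score, h$i_evalue,
        h$i_evalue, h$bit_score, h$aa_to - h$aa_from + 1L,
        h$aa_from, h$aa_to, h$aa_from, h$aa_to), con)
    }
  }
  invisible(path)
}

#' Read a per-base coverage track from bedGraph
#'
#' Expands interval coverage to one value per base; uncovered bases are 0.
#' When intervals overlap, later lines overwrite earlier ones (dialect rule).
#'
#' @param path bedGraph file (0-based half-open intervals).
#' @param genome the `genome_record` the track belongs to.
#' @return list with `genome_id` and numeric `depth` of length
#'   `genome$length` (a "coverage_track").
#' @export
read_coverage_track <- function(path, genome) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("chrom", "start", "end", "value"),
                           colClasses = c("character", "integer", "integer",
                                          "numeric"))
  depth <- numeric(genome$length)
  tab <- tab[tab$chrom == genome$id, , drop = FALSE]
  for (i in seq_len(nrow(tab))) {
    if (tab$end[i] > genome$length || tab$start[i] < 0) {
      stop("bedGraph interval [", tab$start[i], ",", tab$end[i],
           ") outside genome ", genome$id, " (length ", genome$length, ")")
    }
    depth[(tab$start[i] + 1):tab$end[i]] <- tab$value[i]
  }
  coverage_track(genome$id, depth)
}

#' Construct a coverage track
#' @param genome_id replicon id.
#' @param depth non-negative numeric vector, one value per base.
#' @return list of class `coverage_track`.
#' @export
coverage_track <- function(genome_id, depth) {
  stopifnot(all(depth >= 0))
  structure(list(genome_id = genome_id, depth = as.numeric(depth)),
            class = "coverage_track")
}

#' Write a coverage track as bedGraph
#' @param track a `coverage_track`.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  d <- track$depth
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  keep <- r$values != 0
  utils::write.table(
    data.frame(track$genome_id, starts[keep], ends[keep],
               formatC(r$values[keep], format = "g", digits = 10)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Registered result schemas: fixed column order for deterministic output.
result_schemas <- function() {
  list(
    heg_calls = c("genome_id", "gene_id", "family", "allele_state",
                  "nuclease_acc", "evalue", "start", "end", "strand"),
    neighborhoods = c("genome_id", "anchor_gene", "start", "end", "n_genes",
                      "terminase", "capsid", "TMP", "RNR", "replicase",
                      "n_other_hegs"),
    blocks = c("qseqid", "sseqid", "pident", "length", "qstart", "qend",
               "sstart", "send", "evalue", "bitscore"),
    islands = c("genome_id", "start", "end", "left_heg", "right_heg",
                "partner", "partner_start", "partner_end", "coverage",
                "weighted_identity", "markers"),
    splice_models = c("gene_group", "genome_id", "n_exons", "n_introns",
                      "exons", "introns", "orf_valid"),
    satellites = c("contig_id", "start", "end", "attL_start", "attL_end",
                   "attR_start", "attR_end", "att_orientation", "integrase",
                   "homology_bp", "passed_filter"),
    architecture = c("protein_id", "family", "dbd_class", "zn_finger_count",
                     "count_quantified", "nuc_from", "nuc_to", "dbd_from",
                     "dbd_to")
  )
}

#' Write a results table in a registered schema
#'
#' Deterministic column order, TSV with header, floats at fixed precision;
#' optionally mirrors the table to JSON alongside.
#'
#' @param records data.frame whose columns include the schema's columns.
#' @param path output TSV path.
#' @param schema_name one of `heg_calls`, `neighborhoods`, `blocks`,
#'   `islands`, `splice_models`, `satellites`, `architecture`.
#' @param json also write `<path>.json` mirror.
#' @export
write_results_table <- function(records, path, schema_name, json = FALSE) {
  schemas <- result_schemas()
  if (!schema_name %in% names(schemas)) {
    stop("unknown schema '", schema_name, "'; registered: ",
         paste(names(schemas), collapse = ", "))
  }
  cols <- schemas[[schema_name]]
  if (is.null(records) || !nrow(as.data.frame(records))) {
    records <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                      cols))
  }
  records <- as.data.frame(records)
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop("records lack schema column(s): ", paste(missing, collapse = ", "))
  }
  out <- records[, cols, drop = FALSE]
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], format = "g", digits = 6)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (json) {
    jsonlite::write_json(records[, cols, drop = FALSE],
                         paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path TSV path.
#' @param schema_name registered schema name.
#' @return data.frame.
#' @export
read_results_table <- function(path, schema_name) {
  schemas <- result_schemas()
  if (!schema_name %in% names(schemas)) stop("unknown schema '", schema_name, "'")
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}

#' Write genome records as FASTA
#' @param genomes list of `genome_record` (or a single record).
#' @param path output FASTA.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(seqs) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a genome's CDS features as GFF3
#' @param genome a `genome_record`.
#' @param path output GFF3 (features only; sequence goes to FASTA).
#' @export
write_features_gff3 <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("%s\thegscape\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                       genome$id, f$start[i] + 1L,
                       if (f$wraps_origin[i]) genome$length else f$end[i],
                       f$strand[i], f$gene_id[i]), con)
  }
  invisible(path)
}

#' Serialize / restore a simulation truth set as JSON
#' @param truth the `truth` element of a simulated community.
#' @param path JSON file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(out, function(x) if (is.data.frame(x)) x else x)
}

#' Write intervals as BED6
#' @param df data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` (0-based half-open).
#' @param path output file.
#' @export
write_bed6 <- function(df, path) {
  utils::write.table(df[, c("chrom", "start", "end", "name", "score", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
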