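#' Run the HEG landscape pipeline over a simulated or loaded community
#'
#' Orchestrates the analysis stages in order — HEG calling, allele-state
#' classification, neighborhoods, pairwise identity blocks, HEG-islands,
#' and domain architecture — writing one TSV per stage plus a JSON run
#' manifest (config snapshot, input digests, seed, output paths).
#' Re-running with an identical manifest reproduces identical outputs
#' byte for byte.
#'
#' @param community a `heg_community` (see [simulate_community()]) or a
#'   compatible list with `genomes`, `hits`, and optionally `truth`.
#' @param out_dir output directory (created if needed).
#' @param config [heg_config()].
#' @param seed integer seed recorded in the manifest (the analysis stages
#'   are deterministic; the seed governs any simulation upstream).
#' @param stages character subset of
#'   `c("call-hegs", "neighborhoods", "blocks", "islands", "architecture")`.
#' @return invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(community, out_dir, config = heg_config(),
                         seed = NA_integer_,
                         stages = c("call-hegs", "neighborhoods", "blocks",
                                    "islands", "architecture")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- community$genomes
  hits <- community$hits
  res <- list()
  paths <- character()

  flt <- filter_genomes(genomes, config)
  genomes <- flt$retained
  names(genomes) <- vapply(genomes, `[[`, "", "id")

  if ("call-hegs" %in% stages) {
    calls <- call_hegs(genomes, hits, config)
    if (!is.null(community$truth$locus_map)) {
      lm <- community$truth$locus_map
      grouped <- lapply(split(lm, lm$locus), function(lg) {
        classify_allele_state(lg, genomes, calls, hits, config)
      })
      calls <- do.call(rbind, c(grouped, list(make.row.names = FALSE)))
      calls <- calls[order(calls$genome_id, calls$start), ]
    }
    res$heg_calls <- calls
    p <- file.path(out_dir, "heg_calls.tsv")
    write_results_table(calls, p, "heg_calls")
    paths <- c(paths, p)
  }
  if ("neighborhoods" %in% stages) {
    if (is.null(res$heg_calls)) stop("stage 'neighborhoods' requires prior stage 'call-hegs'")
    anchors <- res$heg_calls[!res$heg_calls$allele_state %in%
                               c("absent", "fused"), , drop = FALSE]
    nb <- extract_all_neighborhoods(genomes, anchors, hits, config)
    res$neighborhoods <- nb
    res$enrichment <- summarize_enrichment(nb)
    p <- file.path(out_dir, "neighborhoods.tsv")
    write_results_table(neighborhoods_table(nb), p, "neighborhoods")
    utils::write.table(res$enrichment$per_marker,
                       file.path(out_dir, "marker_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if ("blocks" %in% stages) {
    ids <- names(genomes)
    blocks <- list()
    if (length(ids) >= 2) {
      for (i in seq_along(ids)[-length(ids)]) {
        for (j in (i + 1):length(ids)) {
          blocks[[paste(ids[i], ids[j], sep = "~")]] <-
            genome_blocks(genomes[[ids[i]]], genomes[[ids[j]]], config)
        }
      }
    }
    res$blocks <- blocks
    p <- file.path(out_dir, "blocks.tsv")
    all_blocks <- if (length(blocks)) {
      do.call(rbind, c(blocks, list(make.row.names = FALSE)))
    } else empty_blocks()
    write_blocks_outfmt6(all_blocks, p)
    paths <- c(paths, p)
  }
  if ("islands" %in% stages) {
    if (is.null(res$blocks)) stop("stage 'islands' requires prior stage 'blocks'")
    if (is.null(res$heg_calls)) stop("stage 'islands' requires prior stage 'call-hegs'")
    isl <- list()
    for (key in names(res$blocks)) {
      pr <- strsplit(key, "~", fixed = TRUE)[[1]]
      got <- call_heg_islands(genomes[[pr[1]]], genomes[[pr[2]]],
                              res$heg_calls, res$blocks[[key]], hits, config)
      isl[[key]] <- got$islands
    }
    res$islands <- if (length(isl)) {
      do.call(rbind, c(isl, list(make.row.names = FALSE)))
    } else island_row()[0, ]
    p <- file.path(out_dir, "islands.tsv")
    write_results_table(res$islands, p, "islands")
    paths <- c(paths, p)
  }
  if ("architecture" %in% stages) {
    if (is.null(res$heg_calls)) stop("stage 'architecture' requires prior stage 'call-hegs'")
    arch <- architecture_census(genomes, res$heg_calls, hits, NULL, config)
    res$architecture <- arch
    p <- file.path(out_dir, "architecture.tsv")
    write_results_table(arch, p, "architecture")
    paths <- c(paths, p)
  }

  manifest <- list(
    config = unclass(config), seed = seed, stages = stages,
    genomes = vapply(genomes, function(g) {
      unname(substr(digest_string(g$sequence), 1, 16))
    }, character(1)),
    outputs = basename(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(res, list(manifest = manifest)))
}

# small stable content digest (sum of char codes by position class)
digest_string <- function(x) {
  v <- utf8ToInt(x)
  paste0(sprintf("%08x", sum(v * (seq_along(v) %% 97)) %% 4294967291),
         sprintf("%08x", length(v)))
}
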