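#' Analysis configuration
#'
#' All numeric thresholds used across the pipeline live in a single flat
#' configuration list so that every published cutoff is visible and
#' overridable in one place. Defaults correspond to the thresholds used
#' throughout the analysis; each is documented at its consuming function.
#'
#' Key thresholds:
#' * `heg_domain_evalue` (1e-3): maximum independent e-value for a nuclease
#'   domain hit to call a HEG.
#' * `neighborhood_flank_bp` (3250): flank on each side of a HEG defining its
#'   gene neighborhood.
#' * `neighborhood_annot_evalue` (0.1): maximum e-value for marker-domain
#'   annotation inside neighborhoods.
#' * `min_genome_bp` (20000): genomes shorter than this are dropped.
#' * `block_min_identity_pct` (60), `block_min_len_bp` (125),
#'   `block_max_evalue` (1e-5): identity-block acceptance thresholds.
#' * `capr_evalue` (1e-10): CapR DNA-binding-domain annotation cutoff.
#' * `cluster_identity_pct` (90): greedy clustering identity threshold.
#' * `satellite_flank_bp` (12500): flank extracted around a satellite seed.
#' * `satellite_min_homology_bp` (10000): minimum non-contiguous homology to a
#'   reference element for a satellite call to pass.
#' * `island_min_span_bp` (10000): minimum genomic span of a HEG-island.
#' * `hhpred_annot_evalue` (0.01): cutoff for annotations taken from
#'   remote-homology tables.
#'
#' @param ... named overrides of any default listed below.
#' @return A named list of class `heg_config`.
#' @examples
#' cfg <- heg_config(block_min_len_bp = 100)
#' cfg$block_min_len_bp
#' @export
heg_config <- function(...) {
  cfg <- list(
    # HEG calling
    heg_domain_evalue       = 1e-3,
    min_inframe_del_bp      = 30,
    frameshift_offset_bp    = 2,
    locus_flank_bp          = 2000,
    # genome filtering
    min_genome_bp           = 20000,
    # neighborhoods
    neighborhood_flank_bp   = 3250,
    neighborhood_annot_evalue = 0.1,
    # identity blocks (seed-and-extend)
    seed_k                  = 11,
    xdrop                   = 20,
    match_score             = 1,
    mismatch_score          = -2,
    gap_open                = -5,
    gap_extend              = -2,
    stitch_band             = 32,
    block_min_identity_pct  = 60,
    block_min_len_bp        = 125,
    block_max_evalue        = 1e-5,
    # ungapped Karlin-Altschul parameters for the +1/-2 system
    ka_lambda               = 1.33271,
    ka_k                    = 0.620991,
    # clustering
    cluster_identity_pct    = 90,
    # islands
    chain_gap_bp            = 2000,
    heg_bracket_bp          = 1000,
    island_min_span_bp      = 10000,
    island_dedup_overlap    = 0.5,
    # domain architecture
    capr_evalue             = 1e-10,
    duf_evalue              = 1e-3,
    repeat_min_len_bp       = 30,
    repeat_min_identity_pct = 60,
    swap_min_cov            = 0.5,
    # splicing
    min_region_depth        = 10,
    dip_ratio               = 0.3,
    min_intron_bp           = 100,
    dip_merge_bp            = 10,
    smooth_bp               = 51,
    snap_bp                 = 10,
    frame_search_bp         = 10,
    # satellites
    satellite_flank_bp      = 12500,
    satellite_min_homology_bp = 10000,
    att_search_bp           = 3000,
    att_min_len             = 15,
    att_min_identity        = 90,
    integrase_att_bp        = 2000,
    hhpred_annot_evalue     = 0.01
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           "; valid keys: ", paste(names(cfg), collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  stopifnot(all(vapply(
    cfg[c("heg_domain_evalue", "neighborhood_flank_bp", "min_genome_bp",
          "block_min_identity_pct", "block_min_len_bp", "block_max_evalue",
          "capr_evalue", "cluster_identity_pct", "satellite_flank_bp",
          "satellite_min_homology_bp", "island_min_span_bp")],
    function(x) is.numeric(x) && x > 0, logical(1))))
  stopifnot(cfg$block_min_identity_pct > 0, cfg$block_min_identity_pct <= 100,
            cfg$cluster_identity_pct > 0, cfg$cluster_identity_pct <= 100)
  structure(cfg, class = "heg_config")
}

#' Nuclease and DNA-binding domain family map
#'
#' Maps Pfam-style domain accessions to the nuclease families used for HEG
#' calling, plus the DNA-binding (DBD) and auxiliary classes consumed by the
#' neighborhood and architecture modules. MUG113 (PF13455) is mapped to the
#' T5orf172 family because the two profiles are closely related. The table is
#' plain data so users can extend it with their own accessions.
#'
#' @return data.frame with columns `acc`, `name`, `family`, `role`
#'   (`nuclease`, `dbd`, or `marker`).
#' @export
domain_family_map <- function() {
  rbind(
    data.frame(acc = "PF10544", name = "T5orf172",   family = "T5orf172",   role = "nuclease"),
    data.frame(acc = "PF13455", name = "MUG113",     family = "T5orf172",   role = "nuclease"),
    data.frame(acc = "PF13392", name = "HNH_3",      family = "HNH-3",      role = "nuclease"),
    data.frame(acc = "PF01844", name = "HNH",        family = "HNH-3",      role = "nuclease"),
    data.frame(acc = "PF00961", name = "LAGLIDADG_1", family = "LAGLIDADG", role = "nuclease"),
    data.frame(acc = "PF03161", name = "LAGLIDADG_2", family = "LAGLIDADG", role = "nuclease"),
    data.frame(acc = "PF01541", name = "GIY-YIG",    family = "GIY-YIG",    role = "nuclease"),
    data.frame(acc = "PF12705", name = "PDDEXK_1",   family = "PD-(D/E)XK", role = "nuclease"),
    data.frame(acc = "PF00847", name = "AP2",        family = "AP2",        role = "dbd"),
    data.frame(acc = "CapR",    name = "CapR",       family = "CapR",       role = "dbd"),
    data.frame(acc = "PF05265", name = "DUF723",     family = "DUF723/DUF4397", role = "dbd"),
    data.frame(acc = "PF14344", name = "DUF4397",    family = "DUF723/DUF4397", role = "dbd"),
    data.frame(acc = "PF06970", name = "RepA_N",     family = "RepA_N",     role = "dbd")
  )
}

#' Essential-marker accession lists
#'
#' Accession lists defining the five essential-marker categories scored in
#' gene neighborhoods: terminase, capsid, tape measure protein (TMP),
#' ribonucleotide reductase (RNR) and replicase components. The categories
#' are fixed; the accessions are defaults a user can extend.
#'
#' @return named list of character vectors of accessions.
#' @export
marker_accessions <- function() {
  list(
    terminase = c("PF03237", "PF04466", "PF05876"),          # Terminase_6, Terminase_3, Terminase_GpA
    capsid    = c("PF05065", "PF05125", "PF07068"),          # Phage_capsid (HK97 fold), major capsid
    TMP       = c("PF10145", "PF06791"),                      # tape measure / TMP repeat
    RNR       = c("PF00317", "PF02867", "PF13597"),          # Ribonuc_red_lgN/lgC, class II/III
    replicase = c("PF00476", "PF00136", "PF01896", "PF00580", "PF03796")
      # DNA_pol_A, DNA_pol_B, DNA_primase_S, UvrD-helicase, DnaB_C
  )
}

#' Integrase accession lists
#'
#' Accessions classifying satellite-encoded integrases as tyrosine or serine
#' recombinases.
#'
#' @return named list with elements `tyrosine` and `serine`.
#' @export
integrase_accessions <- function() {
  list(
    tyrosine = c("PF00589", "PF02899"),   # Phage_integrase, Phage_int_SAM_1
    serine   = c("PF00239", "PF07508")    # Resolvase, Recombinase
  )
}
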