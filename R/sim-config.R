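#' Simulation configuration
#'
#' Bundles every parameter of the synthetic genome/methylome/ChIP generator.
#' Defaults describe the study conditions the package is exercised under:
#' a compact genome carrying a few VANDAL-like TE families whose non-coding
#' regions hold same-orientation tandem arrays of a family-specific degenerate
#' motif; one family is "targeted" by an anti-silencing protein, losing CG
#' methylation locally around its motif arrays and non-CG methylation across
#' whole elements.
#'
#' @param seed Integer RNG seed; fixing it makes every output byte-identical.
#' @param genome_length Genome size in bp (single chromosome `chr1`).
#' @param n_te_families,copies_per_family TE family structure.
#' @param te_length_range Length range (bp) TE copies are drawn from.
#' @param motif_per_family Character vector of IUPAC motifs, one per family
#'   (recycled if shorter than `n_te_families`).
#' @param target_family Index of the family hit by the anti-silencing effect.
#' @param repeat_unit_length Tandem repeat unit length (bp); each unit carries
#'   one concrete motif instance.
#' @param repeat_copies_range Range of tandem copies per array (drawn per TE).
#' @param unit_divergence Per-site substitution probability applied to the
#'   non-motif positions of the family repeat unit in each TE copy: units
#'   within one copy's array evolve together, while the embedded motif stays
#'   intact (its concrete instance is drawn per copy).
#' @param mean_coverage Mean per-cytosine read depth (Poisson).
#' @param wt_meth_levels Named proportions `c(CG=, CHG=, CHH=)`: wild-type
#'   methylation inside TEs.
#' @param bg_meth_levels Same, outside TEs (background genome).
#' @param hypo_local_radius Half-width (bp) of the local CG hypomethylation
#'   around each motif array in the targeted family.
#' @param hypo_cg_drop,hypo_chg_drop,hypo_chh_drop Methylation-level drops
#'   (proportions) in the transgenic condition; CG applies locally around
#'   arrays, CHG/CHH across the entire targeted TE.
#' @param chip_enrichment_factor IP/input coverage ratio over motif arrays of
#'   the targeted family.
#' @param chip_input_depth Mean input coverage depth per position.
#' @param chip_bin Resolution (bp) of the simulated coverage tracks.
#' @param tree Newick string used by [simulate_family_evolution()].
#' @param substitution_rate Per-site substitution scale multiplying branch
#'   lengths in the protein-family simulation.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 200000L,
                       n_te_families = 4L,
                       copies_per_family = 5L,
                       te_length_range = c(2000L, 3500L),
                       motif_per_family = c("YAGTATTAY", "AGTTGTCC",
                                            "AGTTGTAC", "CAGTTAGGY"),
                       target_family = 1L,
                       repeat_unit_length = 30L,
                       repeat_copies_range = c(4L, 8L),
                       unit_divergence = 0.1,
                       mean_coverage = 30,
                       wt_meth_levels = c(CG = 0.85, CHG = 0.40, CHH = 0.15),
                       bg_meth_levels = c(CG = 0.05, CHG = 0.03, CHH = 0.02),
                       hypo_local_radius = 250L,
                       hypo_cg_drop = 0.6,
                       hypo_chg_drop = 0.2,
                       hypo_chh_drop = 0.1,
                       chip_enrichment_factor = 8,
                       chip_input_depth = 50,
                       chip_bin = 20L,
                       tree = "((A:0.15,B:0.15):0.10,(C:0.15,D:0.15):0.10);",
                       substitution_rate = 1) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_te_families = as.integer(n_te_families),
              copies_per_family = as.integer(copies_per_family),
              te_length_range = as.integer(te_length_range),
              motif_per_family = rep_len(toupper(motif_per_family),
                                         as.integer(n_te_families)),
              target_family = as.integer(target_family),
              repeat_unit_length = as.integer(repeat_unit_length),
              repeat_copies_range = as.integer(repeat_copies_range),
              unit_divergence = unit_divergence,
              mean_coverage = mean_coverage,
              wt_meth_levels = wt_meth_levels,
              bg_meth_levels = bg_meth_levels,
              hypo_local_radius = as.integer(hypo_local_radius),
              hypo_cg_drop = hypo_cg_drop, hypo_chg_drop = hypo_chg_drop,
              hypo_chh_drop = hypo_chh_drop,
              chip_enrichment_factor = chip_enrichment_factor,
              chip_input_depth = chip_input_depth,
              chip_bin = as.integer(chip_bin),
              tree = tree, substitution_rate = substitution_rate)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  props <- c(cfg$wt_meth_levels, cfg$bg_meth_levels,
             cfg$hypo_cg_drop, cfg$hypo_chg_drop, cfg$hypo_chh_drop,
             cfg$unit_divergence)
  if (any(is.na(props)) || any(props < 0) || any(props > 1))
    stop("all methylation proportions/drops must lie in [0, 1]")
  if (!all(c("CG", "CHG", "CHH") %in% names(cfg$wt_meth_levels)))
    stop("wt_meth_levels must be named CG/CHG/CHH")
  if (cfg$mean_coverage <= 0) stop("mean_coverage must be > 0")
  if (cfg$genome_length < 1000) stop("genome_length too small")
  if (length(cfg$te_length_range) != 2L ||
      cfg$te_length_range[1] > cfg$te_length_range[2])
    stop("te_length_range must be an increasing pair")
  if (length(cfg$repeat_copies_range) != 2L ||
      cfg$repeat_copies_range[1] > cfg$repeat_copies_range[2] ||
      cfg$repeat_copies_range[1] < 1L)
    stop("repeat_copies_range must be an increasing pair >= 1")
  if (cfg$target_family < 1L || cfg$target_family > cfg$n_te_families)
    stop("target_family out of range")
  for (m in cfg$motif_per_family) iupac_to_regex(m)  # validates symbols
  invisible(cfg)
}
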