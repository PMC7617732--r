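#' Bundled two-stage Fab discovery campaign profile
#'
#' The packaged demonstration profile of a two-stage cross-reactivity
#' discovery campaign against a family of long-chain neurotoxin variants
#' (primary antigen `L2`; parallel readout antigens `L1`, `L2`, `L3`, `L5`,
#' `L6`): two rounds of pooled-bait MACS (`L2` + `L3`), four FACS rounds
#' alternating positive selection with `L2` and depletion with a
#' polyspecificity reagent (`PSR`), then five parallel final sorts.
#'
#' The planted ground truth reproduces the published summary structure of
#' such a campaign: 3873 primary-reactive clones, of which 52 bind all five
#' variants (1.3%); per-bait cross-reactivity of 42% (`L1`, the variant
#' closest to the primary), 3.3% (`L3`), 6.2% (`L5`) and 6.6% (`L6`); and
#' 37 of the 52 pan-reactive clones (71%) carrying a 20-residue CDRH3 with
#' the `[WY]YxxGxY` motif (the remaining 15 use 19 residues). Overlaps
#' between the partial cross-reactive sets beyond the pan-reactive core are
#' not identifiable from summary counts and are set to zero. The naive
#' library holds 400,000 clones: the planted binders, 200 polyspecific
#' primary binders (removed by the PSR depletions), and a nonbinding
#' background of which 5% is polyspecific. Planted binder affinities are
#' log-uniform on 1-5 nM; positive sorts run at 10 nM then 5 nM bait
#' (decreasing concentration for affinity stringency), depletions at 1 uM
#' reagent.
#'
#' @param seed Integer seed (mandatory; drives clone generation and, for
#'   multinomial mode, sequencing noise).
#' @param sampling `"lossless"` (exact expected counts, used for planted
#'   ground-truth recovery) or `"multinomial"` (sequencing noise at
#'   `sequencing_depth`).
#' @param sequencing_depth Reads per count table (default 1e6).
#'
#' @return A list of class `"fab_campaign_profile"` with elements
#'   `library_spec` (a [library_spec()]), `rounds` (schedule for
#'   [simulate_campaign()]), `primary_bait` (`"L2"`), `parallel_baits`, and
#'   `planted` (tibble of the planted marginal counts above).
#' @examples
#' \donttest{
#' prof <- fab_campaign_profile(seed = 1)
#' lib <- generate_library(prof$library_spec)
#' cmp <- simulate_campaign(lib, prof$rounds, seed = 1)
#' }
#' @export
fab_campaign_profile <- function(seed,
                                 sampling = c("lossless", "multinomial"),
                                 sequencing_depth = 1e6) {
  sampling <- match.arg(sampling)
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory for fab_campaign_profile().")
  }
  pan_baits <- list(c("L1", "L2", "L3", "L5", "L6"))
  planted <- tibble(
    profile = c("pan_20", "pan_19", "cross_L1", "cross_L3", "cross_L5",
                "cross_L6", "primary_only", "poly_binder"),
    antigens = c(pan_baits, pan_baits,
                 list(c("L2", "L1")), list(c("L2", "L3")),
                 list(c("L2", "L5")), list(c("L2", "L6")),
                 list("L2"), list(c("L2", "PSR"))),
    n = c(37L, 15L, 1575L, 76L, 188L, 204L, 1778L, 200L),
    kd_min = 1e-9, kd_max = 5e-9,
    cdrh3_length = c(20L, 19L, NA, NA, NA, NA, NA, NA),
    motif = c("[WY]YxxGxY", "[WY]YxxGxY", NA, NA, NA, NA, NA, NA)
  )
  lib_spec <- library_spec(
    n_clones = 400000L,
    planted_profiles = planted,
    polyspecific_fraction = 0.05,
    seed = seed
  )
  pos <- function(ag, conc, mode = "FACS_positive", label = NULL) {
    round_spec(mode = mode, baits = tibble(antigen = ag, conc = conc),
               sequencing_depth = sequencing_depth, sampling = sampling,
               label = label)
  }
  depl <- function(label) {
    round_spec(mode = "FACS_depletion",
               baits = tibble(antigen = "PSR", conc = 1e-6),
               sequencing_depth = sequencing_depth, sampling = sampling,
               label = label)
  }
  rounds <- list(
    round_spec(mode = "MACS",
               baits = tibble(antigen = c("L2", "L3"), conc = 1e-8),
               sequencing_depth = sequencing_depth, sampling = sampling,
               label = "macs1"),
    round_spec(mode = "MACS",
               baits = tibble(antigen = c("L2", "L3"), conc = 1e-8),
               sequencing_depth = sequencing_depth, sampling = sampling,
               label = "macs2"),
    pos("L2", 1e-8, label = "facs1"),
    depl("facs2"),
    pos("L2", 5e-9, label = "facs3"),
    depl("facs4"),
    lapply(c("L1", "L2", "L3", "L5", "L6"), function(b)
      pos(b, 5e-9, label = paste0("final_", b)))
  )
  structure(
    list(library_spec = lib_spec, rounds = rounds,
         primary_bait = "L2",
         parallel_baits = c("L1", "L2", "L3", "L5", "L6"),
         planted = planted,
         sampling = sampling, sequencing_depth = sequencing_depth),
    class = "fab_campaign_profile"
  )
}

#' Bundled toxin-panel breadth screen profile
#'
#' The packaged demonstration profile of an antigen-side breadth screen: an
#' 828-variant displayed toxin panel containing 149 long-chain neurotoxin
#' variants with a conserved receptor-binding loop II, sorted through three
#' sequential positive FACS rounds in parallel against the antibody bait
#' and the two human receptor subtypes (`nAChRa1`, `nAChRa7`).
#'
#' The planted ground truth over the 149 long-chain variants is 99
#' antibody-binding (66%), 42 dysfunctional (28%, binding neither human
#' receptor) and 8 escape variants (5%, receptor-binding but
#' antibody-evading, each carrying the planted loop II Asp-to-Ala
#' substitution). Thirteen non-long-chain variants bind the antibody weakly
#' and appear in its final sort, so the final antibody sort holds 112
#' present variants in total. Published screens of this design additionally
#' arbitrated borderline sequencing calls by ELISA; that mechanism is
#' available via [apply_category_overrides()] but the bundled profile
#' plants the post-arbitration categories directly.
#'
#' @param seed Integer seed (mandatory).
#'
#' @return A [toxin_panel_spec()] carrying the counts above.
#' @examples
#' \donttest{
#' panel <- generate_toxin_panel(toxin_screen_profile(seed = 1))
#' screen <- simulate_toxin_screen(panel, seed = 1)
#' }
#' @export
toxin_screen_profile <- function(seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory for toxin_screen_profile().")
  }
  toxin_panel_spec(
    n_variants = 828,
    n_long_chain = 149,
    category_counts = c(binding = 99, dysfunctional = 42, escape = 8),
    n_other_mab_binding = 13,
    seed = seed
  )
}
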