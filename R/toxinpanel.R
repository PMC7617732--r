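# Synthetic family consensus sequences for the displayed toxin panel. These
# are invented three-finger-toxin-like scaffolds (cysteine-anchored, with a
# conserved receptor-binding loop II in the long-chain family); they are not
# natural sequences.
LONG_CHAIN_CONSENSUS <-
  "RICFNQHSSQPQTTKSCSPGESSCYTKTWCDAFCSIRGKVDLGCAATCPKVKPGVDIKCCSTDNCNPFPTR"
LONG_CHAIN_LOOPII <- c(26L, 39L) # inclusive bounds of loop II
SHORT_CHAIN_CONSENSUS <-
  "MECYRMSHSATTQTCEEGQCYKKTWSDHRGTRIERGCGCPSVKKGIELHCCQSDKCNY"
OTHER_3FTX_CONSENSUS <-
  "LTCVTSKSIFGITTEDCPDGQNLCFKRWHYVVPRYSDITWGCAATCPKPTNVRETIHCCETDKCNE"

#' Specify a synthetic displayed toxin variant panel
#'
#' Describes a yeast-displayable panel of toxin variants with planted ground
#' truth for breadth mapping: a long-chain neurotoxin family with a
#' conserved receptor-binding loop II, short-chain and other-family
#' background variants, per-category counts (antibody-binding, dysfunctional,
#' escape) over the long-chain set, and a planted escape mutation (by
#' default the loop II Asp replaced by Ala) that distinguishes escape
#' variants from binders.
#'
#' @param n_variants Total panel size (default 828).
#' @param n_long_chain Number of long-chain variants (default 149;
#'   `<= n_variants`).
#' @param category_counts Named integer vector over the long-chain family
#'   with entries `binding`, `dysfunctional`, `escape`, summing to
#'   `n_long_chain`.
#' @param n_other_mab_binding Number of non-long-chain variants that weakly
#'   bind the antibody bait (cross-class binders that show up in the final
#'   antibody sort).
#' @param loopII_consensus Loop II consensus string (its location in the
#'   long-chain consensus is fixed; supplying a different string of the same
#'   length replaces it).
#' @param escape_mutation List with `position` (1-based within loop II) and
#'   `to` (replacement residue). Default: the loop II aspartate to alanine.
#' @param mutation_rate,loopII_mutation_rate Per-site substitution
#'   probabilities outside and inside loop II (cysteines never mutate).
#' @param mab_bait,receptor_baits Bait ids for the antibody and the two
#'   human receptor subtypes.
#' @param mab_kd_range,receptor_kd_range,weak_mab_kd Molar affinity ranges
#'   for planted binders (log-uniform draws) and the fixed weak Kd of
#'   cross-class antibody binders.
#' @param seed Integer seed (mandatory).
#'
#' @return A list of class `"toxin_panel_spec"`.
#' @seealso [generate_toxin_panel()], [toxin_screen_profile()]
#' @export
toxin_panel_spec <- function(n_variants = 828,
                             n_long_chain = 149,
                             category_counts = c(binding = 99,
                                                 dysfunctional = 42,
                                                 escape = 8),
                             n_other_mab_binding = 0,
                             loopII_consensus = NULL,
                             escape_mutation = NULL,
                             mutation_rate = 0.12,
                             loopII_mutation_rate = 0.02,
                             mab_bait = "mAb",
                             receptor_baits = c("nAChRa1", "nAChRa7"),
                             mab_kd_range = c(1e-10, 5e-9),
                             receptor_kd_range = c(1e-9, 1e-8),
                             weak_mab_kd = 1e-8,
                             seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory in a toxin_panel_spec.")
  }
  if (n_long_chain > n_variants) {
    abort("`n_long_chain` must not exceed `n_variants`.")
  }
  needed <- c("binding", "dysfunctional", "escape")
  if (!all(needed %in% names(category_counts))) {
    abort("`category_counts` needs entries binding, dysfunctional, escape.")
  }
  category_counts <- category_counts[needed]
  if (any(category_counts < 0) || sum(category_counts) != n_long_chain) {
    abort(sprintf(
      "long-chain category counts must be nonnegative and sum to n_long_chain = %d (got %d).",
      n_long_chain, sum(category_counts)
    ))
  }
  if (n_other_mab_binding > n_variants - n_long_chain) {
    abort("`n_other_mab_binding` exceeds the number of non-long-chain variants.")
  }
  loop_len <- LONG_CHAIN_LOOPII[2] - LONG_CHAIN_LOOPII[1] + 1L
  loopII_consensus <- loopII_consensus %||%
    substr(LONG_CHAIN_CONSENSUS, LONG_CHAIN_LOOPII[1], LONG_CHAIN_LOOPII[2])
  if (nchar(loopII_consensus) != loop_len) {
    abort(sprintf("`loopII_consensus` must be %d residues long.", loop_len))
  }
  if (is.null(escape_mutation)) {
    dpos <- regexpr("D", loopII_consensus, fixed = TRUE)[1]
    if (dpos == -1) abort("default escape mutation needs an Asp (D) in loop II.")
    escape_mutation <- list(position = dpos, to = "A")
  }
  if (escape_mutation$position < 1 || escape_mutation$position > loop_len) {
    abort("escape mutation position lies outside loop II.")
  }
  structure(
    list(
      n_variants = as.integer(n_variants),
      n_long_chain = as.integer(n_long_chain),
      category_counts = category_counts,
      n_other_mab_binding = as.integer(n_other_mab_binding),
      loopII_consensus = loopII_consensus,
      loopII_bounds = LONG_CHAIN_LOOPII,
      escape_mutation = escape_mutation,
      mutation_rate = mutation_rate,
      loopII_mutation_rate = loopII_mutation_rate,
      mab_bait = mab_bait,
      receptor_baits = receptor_baits,
      mab_kd_range = mab_kd_range,
      receptor_kd_range = receptor_kd_range,
      weak_mab_kd = weak_mab_kd,
      seed = as.integer(seed)
    ),
    class = "toxin_panel_spec"
  )
}

mutate_from_consensus <- function(consensus, n, rate_vec) {
  L <- nchar(consensus)
  base <- strsplit(consensus, "", fixed = TRUE)[[1]]
  mat <- matrix(rep(base, each = n), nrow = n, ncol = L)
  mut <- matrix(stats::runif(n * L) <
                  matrix(rep(rate_vec, each = n), nrow = n), nrow = n)
  k <- sum(mut)
  if (k > 0) {
    # replacement drawn uniformly from the 19 non-identical residues
    repl <- sample(AA_ALPHABET, k, replace = TRUE)
    same <- repl == mat[mut]
    while (any(same)) {
      repl[same] <- sample(AA_ALPHABET, sum(same), replace = TRUE)
      same <- repl == mat[mut]
    }
    mat[mut] <- repl
  }
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

log_uniform <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Generate a toxin variant panel with planted ground truth
#'
#' Instantiates the panel described by a [toxin_panel_spec()]: exactly
#' `n_variants` variants with family labels (`long_chain`, `short_chain`,
#' `other`), true category labels over the long-chain family (`binding`,
#' `dysfunctional`, `escape`), synthetic sequences diversified from family
#' consensus scaffolds (cysteines fixed, loop II near-conserved), and latent
#' affinities for the antibody and receptor baits. Escape variants carry the
#' configured loop II substitution and differ from their binder-like
#' background only at that position.
#'
#' @param spec A [toxin_panel_spec()].
#'
#' @return An object of class `"toxin_panel"`: list with
#'   \describe{
#'     \item{clones}{tibble `id`, `family`, `true_category`, `sequence`
#'       (named `clones` so the panel plugs directly into
#'       [simulate_campaign()]).}
#'     \item{affinities}{tibble `id`, `antigen`, `kd`.}
#'     \item{spec}{the input spec.}
#'   }
#' @export
generate_toxin_panel <- function(spec) {
  stopifnot(inherits(spec, "toxin_panel_spec"))
  withr::with_seed(spec$seed, generate_toxin_panel_impl(spec))
}

generate_toxin_panel_impl <- function(spec) {
  n <- spec$n_variants
  nL <- spec$n_long_chain
  cc <- spec$category_counts

  consensus <- paste0(
    substr(LONG_CHAIN_CONSENSUS, 1, spec$loopII_bounds[1] - 1L),
    spec$loopII_consensus,
    substr(LONG_CHAIN_CONSENSUS, spec$loopII_bounds[2] + 1L,
           nchar(LONG_CHAIN_CONSENSUS))
  )
  L <- nchar(consensus)
  rate <- rep(spec$mutation_rate, L)
  rate[seq(spec$loopII_bounds[1], spec$loopII_bounds[2])] <-
    spec$loopII_mutation_rate
  base <- strsplit(consensus, "", fixed = TRUE)[[1]]
  rate[base == "C"] <- 0 # disulfide scaffold is invariant

  ids <- sprintf("tox%04d", seq_len(n))
  family <- c(rep("long_chain", nL),
              rep("short_chain", floor((n - nL) * 0.55)),
              rep("other", n - nL - floor((n - nL) * 0.55)))
  category <- rep(NA_character_, n)
  category[seq_len(nL)] <- rep(names(cc), times = cc)

  seqs <- character(n)
  if (nL > 0) seqs[seq_len(nL)] <- mutate_from_consensus(consensus, nL, rate)
  n_short <- sum(family == "short_chain")
  if (n_short > 0) {
    Ls <- nchar(SHORT_CHAIN_CONSENSUS)
    rs <- rep(spec$mutation_rate, Ls)
    rs[strsplit(SHORT_CHAIN_CONSENSUS, "")[[1]] == "C"] <- 0
    seqs[family == "short_chain"] <-
      mutate_from_consensus(SHORT_CHAIN_CONSENSUS, n_short, rs)
  }
  n_other <- sum(family == "other")
  if (n_other > 0) {
    Lo <- nchar(OTHER_3FTX_CONSENSUS)
    ro <- rep(spec$mutation_rate, Lo)
    ro[strsplit(OTHER_3FTX_CONSENSUS, "")[[1]] == "C"] <- 0
    seqs[family == "other"] <- mutate_from_consensus(OTHER_3FTX_CONSENSUS,
                                                     n_other, ro)
  }
  # planted escape substitution, applied after diversification so escape
  # variants differ from their binder-like background only at this site
  esc_abs <- spec$loopII_bounds[1] + spec$escape_mutation$position - 1L
  esc_idx <- which(category == "escape")
  if (length(esc_idx) > 0) {
    substr(seqs[esc_idx], esc_abs, esc_abs) <- spec$escape_mutation$to
  }
  # cross-class weak antibody binders among the non-long-chain variants
  other_idx <- which(is.na(category))
  mab_weak <- integer(0)
  if (spec$n_other_mab_binding > 0) {
    mab_weak <- other_idx[seq_len(spec$n_other_mab_binding)]
  }

  aff <- list()
  bind_idx <- which(category == "binding")
  if (length(bind_idx) > 0) {
    aff[[length(aff) + 1L]] <- tibble(
      id = ids[bind_idx], antigen = spec$mab_bait,
      kd = log_uniform(length(bind_idx), spec$mab_kd_range)
    )
  }
  functional_idx <- which(category %in% c("binding", "escape"))
  for (rb in spec$receptor_baits) {
    aff[[length(aff) + 1L]] <- tibble(
      id = ids[functional_idx], antigen = rb,
      kd = log_uniform(length(functional_idx), spec$receptor_kd_range)
    )
  }
  if (length(mab_weak) > 0) {
    aff[[length(aff) + 1L]] <- tibble(
      id = ids[mab_weak], antigen = spec$mab_bait,
      kd = rep(spec$weak_mab_kd, length(mab_weak))
    )
  }
  variants <- tibble(
    id = ids, family = family, true_category = category, sequence = seqs
  )
  structure(
    list(clones = variants,
         affinities = if (length(aff)) dplyr::bind_rows(aff)
                      else tibble(id = character(), antigen = character(),
                                  kd = double()),
         spec = spec),
    class = "toxin_panel"
  )
}

#' @export
print.toxin_panel <- function(x, ...) {
  cat(sprintf(
    "<toxin_panel> %d variants (%d long-chain: %s)\n",
    nrow(x$clones), sum(x$clones$family == "long_chain"),
    paste(sprintf("%s %d", names(x$spec$category_counts),
                  x$spec$category_counts), collapse = ", ")
  ))
  invisible(x)
}

#' @rdname generate_toxin_panel
#' @param x A `toxin_panel`.
#' @param ... Unused.
#' @method tidy toxin_panel
#' @export
tidy.toxin_panel <- function(x, ...) x$clones

#' Simulate the multi-bait breadth screen of a toxin panel
#'
#' Runs, for each bait (antibody and receptor subtypes), a short campaign of
#' sequential positive FACS sorts starting from the same unsorted panel --
#' the design used to map the breadth of an antibody across a displayed
#' toxin variant library while receptor sorts flag which variants remain
#' functional.
#'
#' @param panel A [generate_toxin_panel()] result.
#' @param n_rounds Sequential sorts per bait (default 3).
#' @param conc Named bait concentrations (molar); defaults: antibody 1 nM,
#'   receptors 10 nM.
#' @param sequencing_depth Reads per table (default 1e6).
#' @param sampling `"lossless"` or `"multinomial"`.
#' @param seed Integer seed (mandatory).
#'
#' @return An object of class `"toxin_screen"`: list with
#'   \describe{
#'     \item{campaigns}{named list of `sort_campaign`, one per bait.}
#'     \item{panel}{the input panel.}
#'     \item{baits}{bait ids (antibody first).}
#'   }
#' @export
simulate_toxin_screen <- function(panel, n_rounds = 3, conc = NULL,
                                  sequencing_depth = 1e6,
                                  sampling = c("lossless", "multinomial"),
                                  seed) {
  stopifnot(inherits(panel, "toxin_panel"))
  sampling <- match.arg(sampling)
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory for simulate_toxin_screen().")
  }
  spec <- panel$spec
  baits <- c(spec$mab_bait, spec$receptor_baits)
  conc <- conc %||% setNames(
    c(1e-9, rep(1e-8, length(spec$receptor_baits))), baits
  )
  campaigns <- list()
  for (i in seq_along(baits)) {
    b <- baits[i]
    rounds <- lapply(seq_len(n_rounds), function(j) {
      round_spec(
        mode = "FACS_positive",
        baits = tibble(antigen = b, conc = conc[[b]]),
        sequencing_depth = sequencing_depth,
        sampling = sampling,
        label = sprintf("sort%d_%s", j, b)
      )
    })
    campaigns[[b]] <- simulate_campaign(panel, rounds,
                                        seed = as.integer(seed) + i - 1L)
  }
  structure(list(campaigns = campaigns, panel = panel, baits = baits),
            class = "toxin_screen")
}

#' @export
print.toxin_screen <- function(x, ...) {
  cat(sprintf("<toxin_screen> %d baits (%s), %d variants\n",
              length(x$baits), paste(x$baits, collapse = ", "),
              nrow(x$panel$clones)))
  invisible(x)
}
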