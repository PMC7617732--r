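#' Specify one selection round
#'
#' Describes a single round of a display-selection campaign: bulk magnetic
#' capture (`"MACS"`), a gated positive fluorescence sort
#' (`"FACS_positive"`), or a depletion sort (`"FACS_depletion"`) that retains
#' the cells *not* bound by the depletion reagent. Under the simulator's
#' Langmuir binding law a clone's retention probability is
#' `retention_efficiency * occupancy` for positive modes (occupancy combined
#' over pooled baits as the chance of being captured by at least one) and
#' `1 - occupancy` of the depletion reagent for depletion rounds.
#'
#' @param mode One of `"MACS"`, `"FACS_positive"`, `"FACS_depletion"`.
#' @param baits Data frame with columns `antigen` (id) and `conc` (molar,
#'   positive), one row per bait used in this round; several rows model
#'   pooled baits.
#' @param retention_efficiency Fraction of truly bound cells recovered by the
#'   sort, in `[0, 1]`. Defaults to 0.8 for MACS (bulk capture) and 0.5 for
#'   FACS. Ignored for depletion rounds.
#' @param gate_occupancy_min Minimum occupancy required to fall inside the
#'   sort gate for positive modes; clones below it are not retained at all.
#'   Default 0 (no gate).
#' @param sequencing_depth Reads sequenced from the post-sort population.
#' @param sampling `"multinomial"` (reads drawn at `sequencing_depth`) or
#'   `"lossless"` (expected read counts reported exactly, possibly
#'   fractional).
#' @param label Optional round label; campaigns assign `round1`, `round2`,
#'   ... when omitted.
#'
#' @return A list of class `"round_spec"`.
#' @seealso [simulate_round()], [simulate_campaign()]
#' @export
round_spec <- function(mode = c("FACS_positive", "FACS_depletion", "MACS"),
                       baits,
                       retention_efficiency = NULL,
                       gate_occupancy_min = 0,
                       sequencing_depth = 1e6,
                       sampling = c("multinomial", "lossless"),
                       label = NULL) {
  mode <- match.arg(mode)
  sampling <- match.arg(sampling)
  baits <- as_tibble(baits)
  if (!all(c("antigen", "conc") %in% names(baits)) || nrow(baits) < 1) {
    abort("`baits` must be a data frame with columns antigen, conc (>=1 row).")
  }
  if (any(baits$conc <= 0 & !is.infinite(baits$conc))) {
    abort("bait concentrations must be positive.")
  }
  retention_efficiency <- retention_efficiency %||%
    if (mode == "MACS") 0.8 else 0.5
  if (retention_efficiency < 0 || retention_efficiency > 1) {
    abort("`retention_efficiency` must lie in [0, 1].")
  }
  if (gate_occupancy_min < 0 || gate_occupancy_min > 1) {
    abort("`gate_occupancy_min` must lie in [0, 1].")
  }
  if (sequencing_depth < 1) abort("`sequencing_depth` must be positive.")
  structure(
    list(mode = mode, baits = baits,
         retention_efficiency = retention_efficiency,
         gate_occupancy_min = gate_occupancy_min,
         sequencing_depth = sequencing_depth,
         sampling = sampling, label = label),
    class = "round_spec"
  )
}

# Per-clone retention probability for one round, given the long affinity
# table (id, antigen, kd). Clones without an affinity entry for a bait are
# nonbinders for it: occupancy exactly 0.
retention_probability <- function(ids, round, affinities) {
  surv <- if (round$mode == "FACS_depletion") {
    rep(1, length(ids)) # start from the fully unbound fraction
  } else {
    rep(1, length(ids)) # probability of escaping *all* baits, inverted below
  }
  for (b in seq_len(nrow(round$baits))) {
    ag <- round$baits$antigen[b]
    conc <- round$baits$conc[b]
    aff <- affinities[affinities$antigen == ag, , drop = FALSE]
    theta <- numeric(length(ids))
    hit <- match(ids, aff$id)
    found <- !is.na(hit)
    if (any(found)) theta[found] <- occupancy(aff$kd[hit[found]], conc)
    surv <- surv * (1 - theta)
  }
  if (round$mode == "FACS_depletion") {
    surv # retained iff unbound by every depletion reagent
  } else {
    captured <- 1 - surv
    if (round$gate_occupancy_min > 0) {
      captured[captured < round$gate_occupancy_min] <- 0
    }
    round$retention_efficiency * captured
  }
}

counts_from_frequencies <- function(freq, depth, sampling) {
  if (sampling == "lossless") {
    freq * depth
  } else {
    as.numeric(rmultinom(1, size = depth, prob = freq))
  }
}

#' Simulate one selection round
#'
#' Applies a [round_spec()] to an input population: computes each clone's
#' retention probability from its Langmuir occupancies, renormalises the
#' surviving frequencies, and reports a sequencing count table drawn per the
#' round's sampling mode. Multinomial counts sum exactly to
#' `sequencing_depth`; lossless counts are the exact expectations
#' `frequency * depth`.
#'
#' @param population Data frame with columns `id` and `freq` (frequencies
#'   summing to 1 within `1e-6`).
#' @param round A [round_spec()].
#' @param library A `fab_library` (or any object with an `affinities` tibble
#'   of `id`, `antigen`, `kd`), or such a tibble directly.
#'
#' @return A tibble count table with columns `id`, `count` (rows with zero
#'   count omitted), and attributes `round` (label), `bait`, `total`, and
#'   `frequencies` -- the exact post-sort population (id, freq) that a
#'   subsequent round should take as input.
#' @export
simulate_round <- function(population, round, library) {
  stopifnot(inherits(round, "round_spec"))
  affinities <- if (is.data.frame(library)) library else library$affinities
  population <- as_tibble(population)
  if (!all(c("id", "freq") %in% names(population))) {
    abort("`population` must have columns id, freq.")
  }
  if (abs(sum(population$freq) - 1) > 1e-6) {
    abort("population frequencies must sum to 1.")
  }
  r <- retention_probability(population$id, round, affinities)
  w <- population$freq * r
  total_mass <- sum(w)
  if (total_mass <= 0) {
    abort(sprintf(
      "extinction: no clone survives round '%s' (%s).",
      round$label %||% round$mode, round$mode
    ))
  }
  post <- tibble(id = population$id, freq = w / total_mass)
  post <- post[post$freq > 0, , drop = FALSE]
  count <- counts_from_frequencies(post$freq, round$sequencing_depth,
                                   round$sampling)
  tab <- tibble(id = post$id, count = count)
  tab <- tab[tab$count > 0, , drop = FALSE]
  attr(tab, "round") <- round$label %||% round$mode
  attr(tab, "bait") <- paste(round$baits$antigen, collapse = "+")
  attr(tab, "total") <- sum(tab$count)
  attr(tab, "frequencies") <- post
  tab
}

#' Simulate a multi-round selection campaign
#'
#' Runs an ordered schedule of [round_spec()]s from a naive library, emitting
#' one sequencing count table per (round, bait) cell, including the naive
#' round 0. The last schedule element may be an (unnamed) list of round
#' specs: a parallel fan-out in which every final sort starts from the same
#' penultimate population, the design used to read out cross-reactivity
#' across antigen variants.
#'
#' @param library A `fab_library` from [generate_library()] (or any list
#'   with `clones` and `affinities` tibbles).
#' @param rounds List of [round_spec()]s; the final element may itself be a
#'   list of round specs (the parallel final sorts).
#' @param seed Integer seed for sequencing sampling (mandatory).
#' @param naive_depth,naive_sampling Sequencing depth and sampling mode for
#'   the naive round 0 table; default to those of the first round (or
#'   `1e6` / `"lossless"` for an empty schedule).
#'
#' @return An object of class `"sort_campaign"`: a list with
#'   \describe{
#'     \item{counts}{long tibble `round`, `bait`, `id`, `count`.}
#'     \item{rounds}{tibble describing the schedule (round, mode, bait,
#'       depth, sampling, serial flag).}
#'     \item{seed}{the seed used.}
#'   }
#' @export
simulate_campaign <- function(library, rounds, seed,
                              naive_depth = NULL, naive_sampling = NULL) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory for simulate_campaign().")
  }
  withr::with_seed(
    as.integer(seed),
    simulate_campaign_impl(library, rounds, as.integer(seed),
                           naive_depth, naive_sampling)
  )
}

simulate_campaign_impl <- function(library, rounds, seed,
                                   naive_depth, naive_sampling) {
  clones <- library$clones
  if (nrow(clones) == 0) abort("cannot simulate a campaign on an empty library.")
  is_fanout <- vapply(rounds, function(r) !inherits(r, "round_spec"),
                      logical(1))
  if (any(is_fanout) && (sum(is_fanout) > 1 || !is_fanout[length(rounds)])) {
    abort("only the final schedule element may be a parallel fan-out list.")
  }
  serial <- if (length(rounds)) rounds[!is_fanout] else list()
  fanout <- if (any(is_fanout)) rounds[[which(is_fanout)]] else list()

  first <- if (length(serial)) serial[[1]] else if (length(fanout)) fanout[[1]] else NULL
  naive_depth <- naive_depth %||% (if (is.null(first)) 1e6 else first$sequencing_depth)
  naive_sampling <- naive_sampling %||% (if (is.null(first)) "lossless" else first$sampling)

  population <- tibble(id = clones$id,
                       freq = rep(1 / nrow(clones), nrow(clones)))
  naive_counts <- counts_from_frequencies(population$freq, naive_depth,
                                          naive_sampling)
  tables <- list(tibble(round = "round0", bait = "naive",
                        id = population$id, count = naive_counts))
  meta <- list(tibble(round = "round0", mode = "naive", bait = "naive",
                      depth = naive_depth, sampling = naive_sampling,
                      serial = TRUE))

  for (i in seq_along(serial)) {
    rs <- serial[[i]]
    rs$label <- rs$label %||% sprintf("round%d", i)
    tab <- simulate_round(population, rs, library)
    population <- attr(tab, "frequencies")
    tables[[length(tables) + 1L]] <- tibble(
      round = attr(tab, "round"), bait = attr(tab, "bait"),
      id = tab$id, count = tab$count
    )
    meta[[length(meta) + 1L]] <- tibble(
      round = attr(tab, "round"), mode = rs$mode, bait = attr(tab, "bait"),
      depth = rs$sequencing_depth, sampling = rs$sampling, serial = TRUE
    )
  }
  for (rs in fanout) {
    rs$label <- rs$label %||%
      sprintf("final_%s", paste(rs$baits$antigen, collapse = "+"))
    tab <- simulate_round(population, rs, library)
    tables[[length(tables) + 1L]] <- tibble(
      round = attr(tab, "round"), bait = attr(tab, "bait"),
      id = tab$id, count = tab$count
    )
    meta[[length(meta) + 1L]] <- tibble(
      round = attr(tab, "round"), mode = rs$mode, bait = attr(tab, "bait"),
      depth = rs$sequencing_depth, sampling = rs$sampling, serial = FALSE
    )
  }
  structure(
    list(counts = dplyr::bind_rows(tables),
         rounds = dplyr::bind_rows(meta),
         seed = seed),
    class = "sort_campaign"
  )
}

#' @export
print.sort_campaign <- function(x, ...) {
  cat(sprintf(
    "<sort_campaign> %d count tables (%d serial rounds + %d parallel finals), seed %d\n",
    nrow(x$rounds), sum(x$rounds$serial) - 1L, sum(!x$rounds$serial), x$seed
  ))
  invisible(x)
}

#' @rdname simulate_campaign
#' @param x A `sort_campaign`.
#' @param ... Unused.
#' @method tidy sort_campaign
#' @export
tidy.sort_campaign <- function(x, ...) x$counts

#' @rdname simulate_campaign
#' @method glance sort_campaign
#' @export
glance.sort_campaign <- function(x, ...) {
  tibble(
    n_tables = nrow(x$rounds),
    n_serial = sum(x$rounds$serial) - 1L,
    n_parallel = sum(!x$rounds$serial),
    total_reads = sum(x$counts$count),
    seed = x$seed
  )
}

#' Extract one count table from a campaign
#'
#' @param campaign A `sort_campaign`.
#' @param round Round label (e.g. `"round0"`, `"final_L2"`).
#'
#' @return A tibble `id`, `count` for that table.
#' @export
campaign_table <- function(campaign, round) {
  stopifnot(inherits(campaign, "sort_campaign"))
  tab <- campaign$counts[campaign$counts$round == round, c("id", "count")]
  if (nrow(tab) == 0) abort(sprintf("no count table for round '%s'.", round))
  tab
}

#' Count-table trajectory for one bait lineage
#'
#' Assembles the ordered per-round count tables relevant to enrichment
#' calling against one final-sort bait: the naive round 0 table, every
#' serial round (the shared population lineage), and the parallel final sort
#' of the requested bait.
#'
#' @param campaign A `sort_campaign`.
#' @param bait Bait id of the parallel final sort (e.g. `"L2"`).
#'
#' @return Long tibble `round`, `id`, `count` with `round` an ordered factor.
#' @export
bait_trajectory <- function(campaign, bait) {
  stopifnot(inherits(campaign, "sort_campaign"))
  serial_rounds <- campaign$rounds$round[campaign$rounds$serial]
  final_round <- campaign$rounds$round[!campaign$rounds$serial &
                                         campaign$rounds$bait == bait]
  if (length(final_round) != 1) {
    abort(sprintf("campaign has no unique parallel final sort for bait '%s'.", bait))
  }
  keep <- c(serial_rounds, final_round)
  out <- campaign$counts[campaign$counts$round %in% keep,
                         c("round", "id", "count")]
  out$round <- factor(out$round, levels = keep, ordered = TRUE)
  out[order(out$round), , drop = FALSE]
}
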