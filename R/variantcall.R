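#' Presence matrix of variants across bait sorts
#'
#' Converts final-sort count tables into a per-variant, per-bait presence
#' matrix: a variant is present for a bait iff its final-sort frequency is
#' at or above the threshold (closed lower bound). Every variant of the
#' library appears as a row, including those never sequenced.
#'
#' @param x A `toxin_screen` (finals and the unsorted round 0 are taken from
#'   it), or a long data frame `bait`, `id`, `count` of final-sort tables.
#' @param threshold Presence threshold on final-sort frequency
#'   (default `1e-5`).
#' @param variant_ids All library variant ids (required for data-frame
#'   input; taken from the panel for a `toxin_screen`).
#' @param detected_ids Ids detected in the unsorted library (round 0); used
#'   downstream to separate dysfunctional (detected, binding nothing) from
#'   absent variants. Taken from round 0 for a `toxin_screen`.
#'
#' @return A tibble with one row per variant: `id`, one logical column per
#'   bait, and `detected`. Attributes `baits`, `threshold`, and `freqs`
#'   (the underlying long frequency table) are attached.
#' @export
presence_call <- function(x, threshold = 1e-5, variant_ids = NULL,
                          detected_ids = NULL) {
  if (threshold <= 0) abort("`threshold` must be positive.")
  if (inherits(x, "toxin_screen")) {
    finals <- purrr::imap_dfr(x$campaigns, function(cmp, bait) {
      final_round <- utils::tail(cmp$rounds$round, 1)
      tab <- campaign_table(cmp, final_round)
      tibble(bait = bait, id = tab$id, count = tab$count)
    })
    variant_ids <- x$panel$clones$id
    r0 <- campaign_table(x$campaigns[[1]], "round0")
    detected_ids <- r0$id[r0$count > 0]
    x <- finals
  }
  x <- as_tibble(x)
  if (!all(c("bait", "id", "count") %in% names(x))) {
    abort("`x` must have columns bait, id, count.")
  }
  if (is.null(variant_ids)) {
    abort("`variant_ids` is required so every library variant appears as a row.")
  }
  orphans <- setdiff(unique(x$id), variant_ids)
  if (length(orphans) > 0) {
    abort(paste0(
      "count tables contain ids not in the variant library: ",
      paste(utils::head(orphans, 5), collapse = ", "),
      if (length(orphans) > 5) sprintf(" (+%d more)", length(orphans) - 5) else ""
    ))
  }
  baits <- unique(x$bait)
  freqs <- x |>
    dplyr::group_by(.data$bait) |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  out <- tibble(id = variant_ids)
  for (b in baits) {
    fb <- freqs[freqs$bait == b, ]
    present <- fb$id[fb$freq >= threshold]
    out[[b]] <- out$id %in% present
  }
  out$detected <- if (is.null(detected_ids)) TRUE else out$id %in% detected_ids
  attr(out, "baits") <- baits
  attr(out, "threshold") <- threshold
  attr(out, "freqs") <- freqs
  out
}

#' Classify toxin variants by antibody and receptor binding
#'
#' Assigns each variant one of four breadth categories from its presence
#' row: `binding` if present in the antibody sort; `escape` if absent from
#' the antibody sort but present in at least one receptor sort (it evades
#' the antibody yet remains functional); `dysfunctional` if detected in the
#' library but present in no sort (it binds neither human receptor
#' subtype); `absent` if never detected at all. The assignment depends only
#' on presence, never on count magnitudes, and is invariant to bait column
#' order.
#'
#' @param presence A [presence_call()] result.
#' @param mab_bait Antibody bait column name (default the first bait).
#' @param receptor_baits Receptor bait column names (default the remaining
#'   baits).
#'
#' @return Tibble `id`, `category` (factor with levels binding, escape,
#'   dysfunctional, absent).
#' @export
classify_variants <- function(presence, mab_bait = NULL,
                              receptor_baits = NULL) {
  baits <- attr(presence, "baits")
  if (is.null(baits)) baits <- setdiff(names(presence), c("id", "detected"))
  mab_bait <- mab_bait %||% baits[1]
  receptor_baits <- receptor_baits %||% setdiff(baits, mab_bait)
  if (!mab_bait %in% names(presence)) {
    abort(sprintf("no presence column for antibody bait '%s'.", mab_bait))
  }
  mab <- presence[[mab_bait]]
  rec <- if (length(receptor_baits) > 0) {
    Reduce(`|`, lapply(receptor_baits, function(b) presence[[b]]))
  } else {
    rep(FALSE, nrow(presence))
  }
  detected <- presence$detected %||% rep(TRUE, nrow(presence))
  category <- dplyr::case_when(
    mab ~ "binding",
    rec ~ "escape",
    detected ~ "dysfunctional",
    TRUE ~ "absent"
  )
  tibble(
    id = presence$id,
    category = factor(category,
                      levels = c("binding", "escape", "dysfunctional", "absent"))
  )
}

#' Apply arbitration overrides to variant categories
#'
#' Borderline sequencing calls are often re-examined by an orthogonal
#' binding assay (e.g. ELISA); this applies such a per-variant override
#' table so published final categories can be reproduced without the
#' wet-lab data.
#'
#' @param calls [classify_variants()] output.
#' @param overrides Data frame `id`, `category` of forced categories.
#'
#' @return `calls` with the overridden categories.
#' @export
apply_category_overrides <- function(calls, overrides) {
  overrides <- as_tibble(overrides)
  if (!all(c("id", "category") %in% names(overrides))) {
    abort("`overrides` must have columns id, category.")
  }
  bad <- setdiff(overrides$id, calls$id)
  if (length(bad) > 0) {
    abort(paste0("override ids not in calls: ", paste(bad, collapse = ", ")))
  }
  bad_cat <- setdiff(unique(as.character(overrides$category)),
                     levels(calls$category))
  if (length(bad_cat) > 0) {
    abort(paste0("unknown override category: ", paste(bad_cat, collapse = ", ")))
  }
  idx <- match(overrides$id, calls$id)
  calls$category[idx] <- as.character(overrides$category)
  calls
}

#' Per-category counts and percentages
#'
#' Summarises variant calls into counts and integer percentages per
#' category, optionally restricted to one family (the usual readout:
#' the breadth of an antibody over the long-chain family).
#'
#' @param calls [classify_variants()] output.
#' @param families Data frame `id`, `family` labelling each variant (e.g.
#'   `tidy()` of a `toxin_panel`). `NULL` to skip filtering.
#' @param family Family to keep (e.g. `"long_chain"`); `NULL` for all.
#'
#' @return Tibble `category`, `n`, `pct` (half-up integer percent);
#'   categories with zero variants included, counts partition the filtered
#'   set.
#' @export
category_summary <- function(calls, families = NULL, family = NULL) {
  if (nrow(calls) == 0) abort("`calls` must be non-empty.")
  if (!is.null(family)) {
    if (is.null(families)) abort("`families` is required when filtering by family.")
    families <- as_tibble(families)
    if (!family %in% families$family) {
      abort(sprintf("unknown family filter '%s'.", family))
    }
    keep <- families$id[families$family == family]
    calls <- calls[calls$id %in% keep, , drop = FALSE]
  }
  n_total <- nrow(calls)
  out <- calls |>
    dplyr::count(.data$category, name = "n", .drop = FALSE) |>
    dplyr::mutate(pct = report_percentage(.data$n, n_total, decimals = 0))
  as_tibble(out)
}

#' Family composition of sequencing reads by round
#'
#' Fraction of reads attributable to each variant family in every round of
#' a campaign -- the stacked-composition view showing, e.g., a library
#' collapsing onto the long-chain family as antibody sorts progress. Reads
#' whose ids carry no family label are reported as `"unassigned"`, never
#' dropped silently.
#'
#' @param campaign A `sort_campaign` (or long tibble `round`, `id`,
#'   `count`). Needs at least 2 rounds.
#' @param families Data frame `id`, `family`.
#'
#' @return Tibble `round`, `family`, `reads`, `fraction`; fractions sum to 1
#'   within each round.
#' @export
composition_by_round <- function(campaign, families) {
  counts <- if (inherits(campaign, "sort_campaign")) campaign$counts
            else as_tibble(campaign)
  if (!all(c("round", "id", "count") %in% names(counts))) {
    abort("`campaign` must provide columns round, id, count.")
  }
  if (length(unique(counts$round)) < 2) {
    abort("composition_by_round() needs at least two rounds.")
  }
  families <- as_tibble(families)
  lvl <- unique(counts$round)
  out <- counts |>
    dplyr::left_join(families[, c("id", "family")], by = "id") |>
    dplyr::mutate(family = dplyr::coalesce(.data$family, "unassigned")) |>
    dplyr::group_by(round = factor(.data$round, levels = lvl),
                    .data$family) |>
    dplyr::summarise(reads = sum(.data$count), .groups = "drop_last") |>
    dplyr::mutate(fraction = .data$reads / sum(.data$reads)) |>
    dplyr::ungroup()
  out
}

#' Contrast position frequencies of binding versus escape variants
#'
#' Builds paired position-frequency matrices over a sequence region (e.g.
#' loop II) for antibody-binding and escape variant sets, plus the
#' per-position, per-residue frequency difference -- the logo contrast that
#' exposes a planted or natural escape substitution.
#'
#' @param binding_seqs,escape_seqs Character vectors of equal-length
#'   sequences; both non-empty.
#' @param region Integer `c(start, end)` (1-based, inclusive) within the
#'   sequences.
#'
#' @return An object of class `"logo_contrast"`: list with `binding` and
#'   `escape` long frequency tibbles (positions numbered within the region)
#'   and `delta` (`position`, `residue`, `freq_binding`, `freq_escape`,
#'   `delta = freq_escape - freq_binding`).
#' @export
escape_logo_contrast <- function(binding_seqs, escape_seqs, region) {
  if (length(binding_seqs) == 0) abort("`binding_seqs` must be non-empty.")
  if (length(escape_seqs) == 0) abort("`escape_seqs` must be non-empty.")
  L_b <- check_equal_length(binding_seqs, "escape_logo_contrast()")
  L_e <- check_equal_length(escape_seqs, "escape_logo_contrast()")
  if (length(region) != 2 || region[1] < 1 || region[2] < region[1] ||
      region[2] > min(L_b, L_e)) {
    abort("`region` must be c(start, end) within all sequences.")
  }
  sub_b <- substr(binding_seqs, region[1], region[2])
  sub_e <- substr(escape_seqs, region[1], region[2])
  prof_b <- frequency_logo_matrix(sub_b)
  prof_e <- frequency_logo_matrix(sub_e)
  delta <- dplyr::full_join(
    dplyr::rename(prof_b, freq_binding = "freq"),
    dplyr::rename(prof_e, freq_escape = "freq"),
    by = c("position", "residue")
  ) |>
    dplyr::mutate(
      freq_binding = dplyr::coalesce(.data$freq_binding, 0),
      freq_escape = dplyr::coalesce(.data$freq_escape, 0),
      delta = .data$freq_escape - .data$freq_binding
    ) |>
    dplyr::arrange(.data$position, .data$residue)
  structure(
    list(binding = prof_b, escape = prof_e, delta = delta, region = region),
    class = "logo_contrast"
  )
}

#' @export
print.logo_contrast <- function(x, ...) {
  cat(sprintf("<logo_contrast> region %d-%d; largest |delta| = %.3f\n",
              x$region[1], x$region[2], max(abs(x$delta$delta))))
  invisible(x)
}

#' @rdname escape_logo_contrast
#' @param x A `logo_contrast`.
#' @param ... Unused.
#' @method tidy logo_contrast
#' @export
tidy.logo_contrast <- function(x, ...) x$delta
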