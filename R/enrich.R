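#' Clone frequencies from a count table
#'
#' @param table Data frame with columns `id` and `count` (nonnegative, at
#'   least one positive).
#'
#' @return Tibble `id`, `freq` with frequencies summing to 1.
#' @examples
#' frequencies(data.frame(id = c("a", "b"), count = c(3, 1)))
#' @export
frequencies <- function(table) {
  table <- as_tibble(table)
  if (!all(c("id", "count") %in% names(table)) || nrow(table) == 0) {
    abort("count table must be non-empty with columns id, count.")
  }
  if (any(table$count < 0)) abort("counts must be nonnegative.")
  total <- sum(table$count)
  if (total <= 0) abort("count table total must be positive.")
  tibble(id = table$id, freq = table$count / total)
}

#' Call clones enriched along a selection trajectory
#'
#' Compares each clone's frequency in the final sort against a reference
#' round (by default the naive round 0 table) and calls it enriched when it
#' clears both a minimum final frequency and a minimum fold enrichment.
#' Clones unobserved in the reference are assigned a pseudo-frequency of
#' `0.5 / total_reference_reads`, so new appearances get a finite, large
#' fold value rather than infinity.
#'
#' @param trajectory Long data frame `round`, `id`, `count` with `round` an
#'   ordered factor or in first-to-last order of appearance (as produced by
#'   [bait_trajectory()]). At least two rounds (reference + final) required.
#' @param min_freq Minimum final-sort frequency (default `1e-5`).
#' @param min_fold Minimum fold enrichment versus the reference
#'   (default 10).
#' @param reference Label of the reference round; default the first round in
#'   the trajectory (the naive library).
#'
#' @return Tibble with one row per clone observed in the final sort:
#'   `id`, `freq_reference`, `freq_final`, `enrichment`, `enriched`, plus
#'   one `freq_<round>` column per intermediate round. Thresholds are
#'   attached as attributes `min_freq` / `min_fold`.
#' @export
call_enriched <- function(trajectory, min_freq = 1e-5, min_fold = 10,
                          reference = NULL) {
  if (min_freq <= 0 || min_fold <= 0) {
    abort("`min_freq` and `min_fold` must be positive.")
  }
  trajectory <- as_tibble(trajectory)
  if (!all(c("round", "id", "count") %in% names(trajectory))) {
    abort("`trajectory` must have columns round, id, count.")
  }
  lev <- if (is.factor(trajectory$round)) levels(trajectory$round)
         else unique(as.character(trajectory$round))
  lev <- lev[lev %in% as.character(trajectory$round)]
  if (length(lev) < 2) {
    abort("trajectory needs at least two rounds (reference + final).")
  }
  reference <- reference %||% lev[1]
  if (!reference %in% lev) abort(sprintf("no round '%s' in trajectory.", reference))
  final <- lev[length(lev)]

  per_round <- lapply(lev, function(r) {
    tab <- trajectory[trajectory$round == r, c("id", "count")]
    fr <- frequencies(tab)
    names(fr)[2] <- paste0("freq_", r)
    fr
  })
  names(per_round) <- lev

  ref_tab <- trajectory[trajectory$round == reference, c("id", "count")]
  pseudo <- 0.5 / sum(ref_tab$count)
  fin <- per_round[[final]]
  names(fin)[2] <- "freq_final"
  ref <- per_round[[reference]]
  names(ref)[2] <- "freq_reference"
  out <- dplyr::left_join(fin, ref, by = "id")
  out$freq_reference[is.na(out$freq_reference)] <- 0
  out$enrichment <- out$freq_final / pmax(out$freq_reference, pseudo)
  out$enriched <- out$freq_final >= min_freq & out$enrichment >= min_fold
  mid <- setdiff(lev, c(reference, final))
  for (r in mid) {
    out <- dplyr::left_join(out, per_round[[r]], by = "id")
  }
  mid_cols <- if (length(mid)) paste0("freq_", mid) else character(0)
  out <- out[, c("id", "freq_reference", mid_cols,
                 "freq_final", "enrichment", "enriched")]
  attr(out, "min_freq") <- min_freq
  attr(out, "min_fold") <- min_fold
  attr(out, "reference") <- reference
  attr(out, "final") <- final
  as_tibble(out)
}

#' Round-half-up percentage as printed in reports
#'
#' `100 * k / n` rounded half away from zero to the requested number of
#' decimals -- the convention used for printed summary percentages (e.g.
#' 52 of 3873 clones is reported as 1.3%).
#'
#' @param k,n Counts with `0 <= k <= n`, `n > 0`.
#' @param decimals Decimal places (default 0).
#'
#' @return The rounded percentage.
#' @examples
#' report_percentage(52, 3873, decimals = 1) # 1.3
#' report_percentage(99, 149)                # 66
#' @export
report_percentage <- function(k, n, decimals = 0) {
  if (any(n <= 0)) abort("`n` must be positive.")
  if (any(k < 0) || any(k > n)) abort("`k` must satisfy 0 <= k <= n.")
  round_half_up(100 * k / n, decimals)
}

#' Cross-reactivity deconvolution over parallel final sorts
#'
#' Given the final count tables of the parallel antigen sorts and the set of
#' clones enriched against the primary antigen, determines which baits each
#' primary-reactive clone is present in, the per-bait retained percentage
#' (the fraction of primary-reactive clones also present in each parallel
#' final sort), and the Venn decomposition over bait combinations.
#' Pan-reactive clones are those present in every parallel final sort.
#'
#' @param final_tables Long data frame `bait`, `id`, `count` with one count
#'   table per parallel final sort, or a `sort_campaign` (its parallel
#'   finals are used).
#' @param primary_set Character vector of primary-reactive clone ids
#'   (typically `enriched` ids from [call_enriched()]). Must be non-empty.
#' @param presence_threshold Minimum final-sort frequency for a clone to
#'   count as present in a bait (closed lower bound; default `1e-5`).
#'
#' @return An object of class `"cross_profiles"` with components
#'   \describe{
#'     \item{profiles}{tibble `id`, `baits` (list-column), `n_baits`,
#'       `pattern` (e.g. `"L1+L2"`), `pan_reactive`.}
#'     \item{per_bait}{tibble `bait`, `n_present`, `pct_retained` (one
#'       decimal, half-up).}
#'     \item{venn}{tibble `pattern`, `n`, `pct` over bait combinations.}
#'     \item{n_primary, baits, presence_threshold}{scalars.}
#'   }
#' @export
cross_profiles <- function(final_tables, primary_set,
                           presence_threshold = 1e-5) {
  if (length(primary_set) == 0) abort("`primary_set` must be non-empty.")
  if (presence_threshold <= 0) abort("`presence_threshold` must be positive.")
  if (inherits(final_tables, "sort_campaign")) {
    finals <- final_tables$rounds$round[!final_tables$rounds$serial]
    if (length(finals) == 0) abort("campaign has no parallel final sorts.")
    final_tables <- final_tables$counts[
      final_tables$counts$round %in% finals, c("round", "bait", "id", "count")
    ]
    final_tables$bait <- final_tables$bait # already the bait id
  }
  final_tables <- as_tibble(final_tables)
  if (!all(c("bait", "id", "count") %in% names(final_tables))) {
    abort("`final_tables` must have columns bait, id, count.")
  }
  baits <- unique(final_tables$bait)
  present_sets <- lapply(baits, function(b) {
    tab <- final_tables[final_tables$bait == b, c("id", "count")]
    if (nrow(tab) == 0) abort(sprintf("bait '%s' is missing its final table.", b))
    fr <- frequencies(tab)
    intersect(fr$id[fr$freq >= presence_threshold], primary_set)
  })
  names(present_sets) <- baits

  membership <- vapply(present_sets, function(s) primary_set %in% s,
                       logical(length(primary_set)))
  if (is.null(dim(membership))) membership <- matrix(membership, nrow = 1)
  baits_per_clone <- apply(membership, 1, function(m) baits[m],
                           simplify = FALSE)
  pattern <- vapply(baits_per_clone, function(b)
    if (length(b) == 0) "(none)" else paste(sort(b), collapse = "+"),
    character(1))
  n_baits_total <- length(baits)
  profiles <- tibble(
    id = primary_set,
    baits = baits_per_clone,
    n_baits = lengths(baits_per_clone),
    pattern = pattern,
    pan_reactive = lengths(baits_per_clone) == n_baits_total
  )
  per_bait <- tibble(
    bait = baits,
    n_present = unname(lengths(present_sets)),
    pct_retained = unname(report_percentage(lengths(present_sets),
                                            length(primary_set),
                                            decimals = 1))
  )
  venn <- profiles |>
    dplyr::count(.data$pattern, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n)) |>
    dplyr::mutate(pct = report_percentage(.data$n, length(primary_set),
                                          decimals = 1))
  structure(
    list(profiles = profiles, per_bait = per_bait, venn = venn,
         n_primary = length(primary_set), baits = baits,
         presence_threshold = presence_threshold),
    class = "cross_profiles"
  )
}

#' @export
print.cross_profiles <- function(x, ...) {
  cat(sprintf(
    "<cross_profiles> %d primary-reactive clones over %d baits; %d pan-reactive (%.1f%%)\n",
    x$n_primary, length(x$baits), sum(x$profiles$pan_reactive),
    100 * sum(x$profiles$pan_reactive) / x$n_primary
  ))
  print(x$per_bait)
  invisible(x)
}

#' @rdname cross_profiles
#' @param x A `cross_profiles` object.
#' @param ... Unused.
#' @method tidy cross_profiles
#' @export
tidy.cross_profiles <- function(x, ...) x$profiles

#' @rdname cross_profiles
#' @method glance cross_profiles
#' @export
glance.cross_profiles <- function(x, ...) {
  tibble(
    n_primary = x$n_primary,
    n_baits = length(x$baits),
    n_pan_reactive = sum(x$profiles$pan_reactive),
    pct_pan_reactive = report_percentage(sum(x$profiles$pan_reactive),
                                         x$n_primary, decimals = 1),
    presence_threshold = x$presence_threshold
  )
}

#' Rank pan-reactive clones for synthesis
#'
#' Orders pan-reactive clones by their weakest link: the minimum final-sort
#' frequency across all parallel baits, descending (ties broken by clone
#' id), and returns the top `k` -- the shortlist one would reformat and
#' express for validation.
#'
#' @param calls [call_enriched()] output (used to restrict to enriched
#'   clones; pass `NULL` to rank all pan-reactive clones).
#' @param profiles A `cross_profiles` object.
#' @param final_tables Long data frame `bait`, `id`, `count` of the parallel
#'   final sorts (or a `sort_campaign`).
#' @param k Number of candidates requested (`>= 1`).
#'
#' @return Tibble `rank`, `id`, `min_final_freq`, one row per candidate. If
#'   fewer than `k` pan-reactive clones exist, all are returned, a warning
#'   is raised, and the attribute `short` is `TRUE`.
#' @export
rank_candidates <- function(calls = NULL, profiles, final_tables, k) {
  stopifnot(inherits(profiles, "cross_profiles"))
  if (k < 1) abort("`k` must be >= 1.")
  if (inherits(final_tables, "sort_campaign")) {
    finals <- final_tables$rounds$round[!final_tables$rounds$serial]
    final_tables <- final_tables$counts[
      final_tables$counts$round %in% finals, c("bait", "id", "count")
    ]
  }
  pan <- profiles$profiles$id[profiles$profiles$pan_reactive]
  if (!is.null(calls)) pan <- intersect(pan, calls$id[calls$enriched])
  freq_long <- final_tables |>
    dplyr::group_by(.data$bait) |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$id %in% pan)
  ranked <- freq_long |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(min_final_freq = min(.data$freq), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$min_final_freq), .data$id)
  short <- nrow(ranked) < k
  if (short) {
    warn(sprintf("only %d pan-reactive clones available for k = %d.",
                 nrow(ranked), k))
  }
  out <- utils::head(ranked, k)
  out <- dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
  attr(out, "short") <- short
  out
}
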