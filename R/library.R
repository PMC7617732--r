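# Background amino-acid usage for synthetic CDRH3 loops. Loosely follows the
# composition of nontemplated human CDRH3 (tyrosine/glycine/serine rich);
# exact values only shape cosmetic sequence content, never counts.
CDRH3_AA_FREQ <- c(
  A = 0.05, C = 0.01, D = 0.06, E = 0.03, F = 0.04, G = 0.12, H = 0.02,
  I = 0.03, K = 0.03, L = 0.05, M = 0.01, N = 0.03, P = 0.04, Q = 0.02,
  R = 0.06, S = 0.09, T = 0.05, V = 0.05, W = 0.04, Y = 0.17
)

random_aa_strings <- function(n, len, freq = CDRH3_AA_FREQ) {
  if (n == 0) return(character())
  mat <- matrix(
    sample(names(freq), n * len, replace = TRUE, prob = freq),
    nrow = n, ncol = len
  )
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

# One random realisation of a motif pattern such as "[WY]YxxGxY":
# alternatives are sampled, wildcards drawn from the background frequencies.
realise_motif <- function(tokens, n, freq = CDRH3_AA_FREQ) {
  cols <- lapply(tokens, function(tok) {
    if (identical(tok, "x")) {
      sample(names(freq), n, replace = TRUE, prob = freq)
    } else if (length(tok) == 1L) {
      rep(tok, n)
    } else {
      sample(tok, n, replace = TRUE)
    }
  })
  do.call(paste0, cols)
}

#' Specify a synthetic naive Fab display library
#'
#' Describes a naive antibody (Fab) display library for the selection
#' simulator: the germline-gene sets and their usage weights, the CDRH3
#' length distribution, and "planted" clone profiles -- groups of clones with
#' configured antigen-binding sets, affinity ranges, CDRH3 lengths and motif
#' templates -- that constitute the recoverable ground truth of a simulated
#' campaign. Clones outside the planted groups are nonbinders (a fraction of
#' which may be polyspecific, i.e. bind the depletion reagent).
#'
#' @param n_clones Total number of clones in the library (nonnegative).
#' @param vh_genes,vl_genes Character vectors naming the heavy- and
#'   light-chain variable gene sets (defaults: 8 VH and 4 VL genes, the 32
#'   pairings of a typical synthetic library design).
#' @param vh_weights,vl_weights Gene usage probabilities, summing to 1.
#' @param cdrh3_lengths Integer vector of allowed CDRH3 lengths
#'   (default 10-20 amino acids).
#' @param cdrh3_length_weights Probabilities over `cdrh3_lengths`, summing
#'   to 1.
#' @param planted_profiles Data frame with one row per planted clone group:
#'   columns `profile` (label), `antigens` (list-column of antigen ids the
#'   group binds), `n` (clone count), `kd_min`, `kd_max` (molar bounds of the
#'   log-uniform Kd draw), and optionally `cdrh3_length` (fixed length, NA to
#'   sample) and `motif` (motif template such as `"[WY]YxxGxY"` embedded in
#'   every clone of the group, NA for none). `NULL` for none.
#' @param polyspecific_fraction Fraction of the non-planted background that
#'   binds the depletion reagent, in `[0, 1]`.
#' @param polyspecific_antigen Id of the depletion reagent (default `"PSR"`,
#'   a polyspecificity reagent).
#' @param polyspecific_kd Kd assigned to polyspecific clones for the
#'   depletion reagent (molar; very tight by default so depletion is nearly
#'   certain).
#' @param seed Integer seed. Mandatory: omitting it is an error, never a
#'   silent default, so every simulated campaign is reproducible.
#'
#' @return A list of class `"library_spec"`.
#' @seealso [generate_library()], [fab_campaign_profile()]
#' @export
library_spec <- function(n_clones,
                         vh_genes = paste0("VH", 1:8),
                         vl_genes = paste0("VL", 1:4),
                         vh_weights = NULL,
                         vl_weights = NULL,
                         cdrh3_lengths = 10:20,
                         cdrh3_length_weights = NULL,
                         planted_profiles = NULL,
                         polyspecific_fraction = 0,
                         polyspecific_antigen = "PSR",
                         polyspecific_kd = 1e-12,
                         seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory in a library_spec; supply an integer seed.")
  }
  if (!is.numeric(n_clones) || length(n_clones) != 1L || n_clones < 0 ||
      n_clones != floor(n_clones)) {
    abort("`n_clones` must be a single nonnegative integer.")
  }
  vh_weights <- vh_weights %||% rep(1 / length(vh_genes), length(vh_genes))
  vl_weights <- vl_weights %||% rep(1 / length(vl_genes), length(vl_genes))
  cdrh3_length_weights <- cdrh3_length_weights %||%
    rep(1 / length(cdrh3_lengths), length(cdrh3_lengths))
  check_probability_vector(vh_weights, "vh_weights")
  check_probability_vector(vl_weights, "vl_weights")
  check_probability_vector(cdrh3_length_weights, "cdrh3_length_weights")
  if (length(vh_weights) != length(vh_genes)) {
    abort("`vh_weights` must have one weight per VH gene.")
  }
  if (length(vl_weights) != length(vl_genes)) {
    abort("`vl_weights` must have one weight per VL gene.")
  }
  if (length(cdrh3_length_weights) != length(cdrh3_lengths)) {
    abort("`cdrh3_length_weights` must have one weight per length.")
  }
  if (!is.null(planted_profiles)) {
    planted_profiles <- as_tibble(planted_profiles)
    needed <- c("profile", "antigens", "n", "kd_min", "kd_max")
    missing_cols <- setdiff(needed, names(planted_profiles))
    if (length(missing_cols) > 0) {
      abort(paste0(
        "planted_profiles is missing column(s): ",
        paste(missing_cols, collapse = ", ")
      ))
    }
    if (!"cdrh3_length" %in% names(planted_profiles)) {
      planted_profiles$cdrh3_length <- NA_integer_
    }
    if (!"motif" %in% names(planted_profiles)) {
      planted_profiles$motif <- NA_character_
    }
    if (any(planted_profiles$n < 0)) {
      abort("planted profile counts must be nonnegative.")
    }
    if (sum(planted_profiles$n) > n_clones) {
      abort(sprintf(
        "planted profile counts sum to %d, exceeding n_clones = %d.",
        sum(planted_profiles$n), n_clones
      ))
    }
    if (any(planted_profiles$kd_min <= 0) ||
        any(planted_profiles$kd_max < planted_profiles$kd_min)) {
      abort("planted profile Kd ranges must satisfy 0 < kd_min <= kd_max.")
    }
    bad_len <- !is.na(planted_profiles$cdrh3_length) &
      !(planted_profiles$cdrh3_length %in% cdrh3_lengths)
    if (any(bad_len)) {
      abort("planted profile cdrh3_length outside the configured lengths.")
    }
  }
  if (polyspecific_fraction < 0 || polyspecific_fraction > 1) {
    abort("`polyspecific_fraction` must lie in [0, 1].")
  }
  structure(
    list(
      n_clones = as.integer(n_clones),
      vh_genes = vh_genes, vl_genes = vl_genes,
      vh_weights = vh_weights, vl_weights = vl_weights,
      cdrh3_lengths = as.integer(cdrh3_lengths),
      cdrh3_length_weights = cdrh3_length_weights,
      planted_profiles = planted_profiles,
      polyspecific_fraction = polyspecific_fraction,
      polyspecific_antigen = polyspecific_antigen,
      polyspecific_kd = polyspecific_kd,
      seed = as.integer(seed)
    ),
    class = "library_spec"
  )
}

#' Generate a synthetic Fab library with planted ground truth
#'
#' Instantiates the library described by a [library_spec()]: exactly
#' `n_clones` clones, with every planted profile present at exactly its
#' configured count. Planted clones carry log-uniform Kd draws for the
#' antigens in their binding set; all other clones are nonbinders (occupancy
#' 0 for every bait), a configured fraction of which bind the depletion
#' reagent. Output is deterministic for a fixed spec seed.
#'
#' @param spec A [library_spec()].
#'
#' @return An object of class `"fab_library"`: a list with
#'   \describe{
#'     \item{clones}{tibble with columns `id`, `vh_gene`, `vl_gene`, `cdrh3`,
#'       `cdrh3_length`, `polyspecific`, `true_profile`.}
#'     \item{affinities}{tibble with columns `id`, `antigen`, `kd` (molar);
#'       clones absent from this table are nonbinders for that antigen.}
#'     \item{spec}{the input spec.}
#'   }
#' @examples
#' spec <- library_spec(
#'   n_clones = 100,
#'   planted_profiles = data.frame(
#'     profile = "binder", n = 10, kd_min = 1e-9, kd_max = 1e-8
#'   ) |> transform(antigens = I(list("L2"))),
#'   seed = 1
#' )
#' lib <- generate_library(spec)
#' nrow(lib$clones)
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  withr::with_seed(spec$seed, generate_library_impl(spec))
}

generate_library_impl <- function(spec) {
  n <- spec$n_clones
  empty <- tibble(
    id = character(), vh_gene = character(), vl_gene = character(),
    cdrh3 = character(), cdrh3_length = integer(),
    polyspecific = logical(), true_profile = character()
  )
  if (n == 0L) {
    return(structure(
      list(clones = empty,
           affinities = tibble(id = character(), antigen = character(),
                               kd = double()),
           spec = spec),
      class = "fab_library"
    ))
  }
  ids <- sprintf("fab%06d", seq_len(n))

  profiles <- spec$planted_profiles
  n_planted <- if (is.null(profiles)) 0L else sum(profiles$n)
  true_profile <- rep("background", n)
  len <- integer(n)
  motif <- rep(NA_character_, n)
  if (n_planted > 0) {
    true_profile[seq_len(n_planted)] <-
      rep(profiles$profile, times = profiles$n)
    motif[seq_len(n_planted)] <- rep(profiles$motif, times = profiles$n)
    fixed_len <- rep(profiles$cdrh3_length, times = profiles$n)
    len[seq_len(n_planted)] <- fixed_len
  }
  need_sample <- is.na(len) | len == 0L
  len[need_sample] <- sample(
    spec$cdrh3_lengths, sum(need_sample),
    replace = TRUE, prob = spec$cdrh3_length_weights
  )

  # CDRH3 strings, generated per length group for speed
  cdrh3 <- character(n)
  for (L in sort(unique(len))) {
    idx <- which(len == L)
    cdrh3[idx] <- random_aa_strings(length(idx), L)
  }
  # embed motif instances in planted clones that carry a template
  with_motif <- which(!is.na(motif))
  if (length(with_motif) > 0) {
    for (pat in unique(motif[with_motif])) {
      idx <- with_motif[motif[with_motif] == pat]
      tokens <- parse_motif(pat)
      k <- length(tokens)
      if (any(len[idx] < k)) {
        abort("motif template longer than the clone CDRH3 length.")
      }
      inst <- realise_motif(tokens, length(idx))
      start <- 1L + floor(stats::runif(length(idx)) * (len[idx] - k + 1L))
      substr(cdrh3[idx], start, start + k - 1L) <- inst
    }
  }

  vh <- sample(spec$vh_genes, n, replace = TRUE, prob = spec$vh_weights)
  vl <- sample(spec$vl_genes, n, replace = TRUE, prob = spec$vl_weights)

  # affinities: planted binding sets with log-uniform Kd draws
  aff <- tibble(id = character(), antigen = character(), kd = double())
  if (n_planted > 0) {
    per_profile <- vector("list", nrow(profiles))
    offset <- 0L
    for (i in seq_len(nrow(profiles))) {
      m <- profiles$n[i]
      if (m == 0L) { per_profile[[i]] <- NULL; next }
      ags <- profiles$antigens[[i]]
      rows <- tibble(
        id = rep(ids[offset + seq_len(m)], each = length(ags)),
        antigen = rep(ags, times = m)
      )
      lo <- log(profiles$kd_min[i]); hi <- log(profiles$kd_max[i])
      rows$kd <- exp(stats::runif(nrow(rows), lo, hi))
      per_profile[[i]] <- rows
      offset <- offset + m
    }
    aff <- dplyr::bind_rows(per_profile)
  }
  # polyspecific background clones bind the depletion reagent
  polyspecific <- logical(n)
  bg <- which(true_profile == "background")
  if (spec$polyspecific_fraction > 0 && length(bg) > 0) {
    n_poly <- round(spec$polyspecific_fraction * length(bg))
    poly_idx <- bg[seq_len(n_poly)]
    polyspecific[poly_idx] <- TRUE
    aff <- dplyr::bind_rows(aff, tibble(
      id = ids[poly_idx],
      antigen = spec$polyspecific_antigen,
      kd = spec$polyspecific_kd
    ))
  }
  # planted profiles that include the depletion reagent are polyspecific too
  if (nrow(aff) > 0) {
    poly_ids <- unique(aff$id[aff$antigen == spec$polyspecific_antigen])
    polyspecific[match(poly_ids, ids)] <- TRUE
  }

  clones <- tibble(
    id = ids, vh_gene = vh, vl_gene = vl,
    cdrh3 = cdrh3, cdrh3_length = as.integer(len),
    polyspecific = polyspecific, true_profile = true_profile
  )
  structure(list(clones = clones, affinities = aff, spec = spec),
            class = "fab_library")
}

#' @export
print.fab_library <- function(x, ...) {
  cat(sprintf(
    "<fab_library> %d clones (%d planted across %d profiles), %d affinity entries\n",
    nrow(x$clones),
    sum(x$clones$true_profile != "background"),
    length(setdiff(unique(x$clones$true_profile), "background")),
    nrow(x$affinities)
  ))
  invisible(x)
}

#' @rdname generate_library
#' @param x A `fab_library`.
#' @param ... Unused.
#' @method tidy fab_library
#' @export
tidy.fab_library <- function(x, ...) x$clones
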