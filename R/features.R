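#' Extract the CDRH3 loop from a full protein sequence
#'
#' Returns the substring strictly between a 5' anchor (e.g. the end of the
#' framework-3 `"CAR"` junction) and a 3' anchor (e.g. the `"WGQG"` start of
#' framework 4). Each anchor must occur exactly once; ambiguous or missing
#' anchors are an error rather than a silent first-match, since a wrong CDR
#' boundary corrupts every downstream length and motif statistic.
#'
#' @param protein_seq Single amino-acid sequence string.
#' @param anchor_5p,anchor_3p Anchor substrings flanking the CDR.
#' @param id Optional sequence id used in error messages.
#'
#' @return The CDRH3 string.
#' @examples
#' extract_cdrh3("MQCARDYWGQGTL", "CAR", "WGQG") # "DY"
#' @export
extract_cdrh3 <- function(protein_seq, anchor_5p = "CAR", anchor_3p = "WGQG",
                          id = NULL) {
  stopifnot(is.character(protein_seq), length(protein_seq) == 1L)
  who <- if (is.null(id)) "" else sprintf(" in sequence '%s'", id)
  m5 <- gregexpr(anchor_5p, protein_seq, fixed = TRUE)[[1]]
  m3 <- gregexpr(anchor_3p, protein_seq, fixed = TRUE)[[1]]
  n5 <- if (m5[1] == -1) 0L else length(m5)
  n3 <- if (m3[1] == -1) 0L else length(m3)
  if (n5 != 1L) {
    abort(sprintf("5' anchor '%s' matched %d times%s (need exactly 1).",
                  anchor_5p, n5, who))
  }
  if (n3 != 1L) {
    abort(sprintf("3' anchor '%s' matched %d times%s (need exactly 1).",
                  anchor_3p, n3, who))
  }
  start <- m5[1] + nchar(anchor_5p)
  end <- m3[1] - 1L
  if (end < start) {
    abort(sprintf("anchors overlap or are out of order%s.", who))
  }
  substr(protein_seq, start, end)
}

#' Germline gene usage frequencies
#'
#' Frequencies of heavy- or light-chain variable gene usage over a clone
#' set, reported over the full configured gene set so that unused genes
#' appear with frequency 0 (as in repertoire usage bar plots).
#'
#' @param clones Data frame with `vh_gene` and `vl_gene` columns (e.g. the
#'   `clones` table of a [generate_library()] result).
#' @param axis `"VH"` or `"VL"`.
#' @param gene_set Character vector of allowed genes; defaults to the genes
#'   observed. Clones with labels outside it are an error.
#'
#' @return Tibble `gene`, `n`, `freq` with frequencies summing to 1.
#' @export
gene_usage <- function(clones, axis = c("VH", "VL"), gene_set = NULL) {
  axis <- match.arg(axis)
  col <- if (axis == "VH") "vh_gene" else "vl_gene"
  clones <- as_tibble(clones)
  if (!col %in% names(clones)) abort(sprintf("`clones` must have a `%s` column.", col))
  if (nrow(clones) == 0) abort("`clones` must be non-empty.")
  labels <- clones[[col]]
  if (any(is.na(labels))) abort("every clone must carry a gene label.")
  gene_set <- gene_set %||% sort(unique(labels))
  unknown <- setdiff(unique(labels), gene_set)
  if (length(unknown) > 0) {
    abort(paste0("unknown gene label(s): ", paste(unknown, collapse = ", ")))
  }
  n <- vapply(gene_set, function(g) sum(labels == g), numeric(1))
  tibble(gene = gene_set, n = as.integer(n), freq = n / sum(n))
}

#' CDRH3 length distribution
#'
#' @param clones Data frame with a `cdrh3` or `cdrh3_length` column, or a
#'   character vector of CDRH3 sequences. Must be non-empty.
#' @param lengths Optional integer vector of lengths to report (zero-count
#'   lengths included); defaults to the observed range.
#'
#' @return Tibble `length`, `n`, `freq` with frequencies summing to 1 and a
#'   `pct` column rounded half-up to integers, the convention used when
#'   reporting e.g. "71% of cross-reactive clones use a 20-residue CDRH3".
#' @export
length_distribution <- function(clones, lengths = NULL) {
  if (is.character(clones)) {
    len <- nchar(clones)
  } else {
    clones <- as_tibble(clones)
    if ("cdrh3_length" %in% names(clones)) {
      len <- clones$cdrh3_length
    } else if ("cdrh3" %in% names(clones)) {
      len <- nchar(clones$cdrh3)
    } else {
      abort("`clones` must have a `cdrh3` or `cdrh3_length` column.")
    }
  }
  if (length(len) == 0) abort("cannot compute a length distribution of an empty set.")
  lengths <- lengths %||% seq(min(len), max(len))
  n <- vapply(lengths, function(L) sum(len == L), numeric(1))
  tibble(
    length = as.integer(lengths), n = as.integer(n), freq = n / sum(n),
    pct = report_percentage(n, sum(n), decimals = 0)
  )
}

check_equal_length <- function(seqs, context) {
  if (length(seqs) < 1) abort(sprintf("%s requires at least one sequence.", context))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    abort(sprintf(
      "%s requires equal-length sequences (got lengths %s); align them first.",
      context, paste(sort(unique(lens)), collapse = ", ")
    ))
  }
  invisible(lens[1])
}

seq_matrix <- function(seqs) {
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

#' Position frequency matrix for logo rendering
#'
#' Per-column residue frequencies of an equal-length sequence set -- the
#' matrix behind a frequency logo. Gaps (`-`) are counted as a symbol here;
#' use [shannon_entropy_profile()] for gap-excluded entropies.
#'
#' @param seqs Character vector of equal-length sequences (`>= 1`).
#'
#' @return Long tibble `position`, `residue`, `freq`; each position's
#'   frequencies sum to 1. Use [tidyr::pivot_wider()] or [write_matrix_tsv()]
#'   to export.
#' @export
frequency_logo_matrix <- function(seqs) {
  check_equal_length(seqs, "frequency_logo_matrix()")
  mat <- seq_matrix(seqs)
  purrr::map_dfr(seq_len(ncol(mat)), function(j) {
    tab <- table(mat[, j])
    tibble(position = j, residue = names(tab),
           freq = as.numeric(tab) / nrow(mat))
  })
}

#' Site-specific Shannon entropy profile
#'
#' Per-column Shannon entropy (bits) of an aligned sequence set,
#' `H = -sum(p * log2(p))` over the observed residue frequencies. Gap
#' characters are excluded and the column renormalised over residues;
#' columns with fewer than two non-gap symbols are flagged, and all-gap
#' columns get `H = NA` (undefined, never reported as 0). Low-entropy sites
#' mark conserved positions -- e.g. the receptor-binding loop of a toxin
#' family -- while high-entropy sites carry the antigenic diversity.
#'
#' @param alignment Character vector of equal-length aligned sequences, or a
#'   data frame with a `sequence` column.
#' @param gap_chars Characters treated as gaps (default `-` and `.`).
#'
#' @return Tibble `position`, `H` (bits), `n_eff` (non-gap symbols),
#'   `flagged` (fewer than 2 non-gap symbols).
#' @export
shannon_entropy_profile <- function(alignment, gap_chars = c("-", ".")) {
  if (is.data.frame(alignment)) {
    if (!"sequence" %in% names(alignment)) {
      abort("data-frame input must have a `sequence` column.")
    }
    alignment <- alignment$sequence
  }
  check_equal_length(alignment, "shannon_entropy_profile()")
  mat <- seq_matrix(alignment)
  purrr::map_dfr(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[!col %in% gap_chars]
    n_eff <- length(col)
    if (n_eff == 0) {
      return(tibble(position = j, H = NA_real_, n_eff = 0L, flagged = TRUE))
    }
    p <- as.numeric(table(col)) / n_eff
    tibble(position = j, H = -sum(p * log2(p)), n_eff = n_eff,
           flagged = n_eff < 2)
  })
}

#' Substitution enrichment versus a parental sequence
#'
#' Per-position residue frequencies among a set of selected clones aligned
#' to a parental sequence, with the frequency delta versus the parent
#' (parent residue gets `freq - 1`, others `freq - 0`). This is the readout
#' used after affinity maturation to spot convergent substitutions, e.g. a
#' prevalent Asp/Glu replacing a parental Ala in a light-chain CDR.
#'
#' @param parent Parental amino-acid sequence.
#' @param clones Character vector of selected-clone sequences, all the same
#'   length as `parent`. Must be non-empty.
#'
#' @return An object of class `"substitution_table"`: list with
#'   \describe{
#'     \item{table}{long tibble `position`, `parent`, `residue`, `freq`,
#'       `is_parent`, `delta`.}
#'     \item{top}{tibble `position`, `parent`, `top_substitution`,
#'       `top_freq` -- the most frequent non-parental residue per position
#'       (NA where no substitution occurs).}
#'   }
#' @export
substitution_enrichment <- function(parent, clones) {
  stopifnot(is.character(parent), length(parent) == 1L)
  if (length(clones) == 0) abort("`clones` must be non-empty.")
  if (any(nchar(clones) != nchar(parent))) {
    abort("all clone sequences must match the parent length.")
  }
  mat <- seq_matrix(clones)
  pres <- strsplit(parent, "", fixed = TRUE)[[1]]
  tab <- purrr::map_dfr(seq_len(ncol(mat)), function(j) {
    tt <- table(mat[, j])
    tibble(
      position = j, parent = pres[j], residue = names(tt),
      freq = as.numeric(tt) / nrow(mat)
    )
  }) |>
    dplyr::mutate(
      is_parent = .data$residue == .data$parent,
      delta = .data$freq - as.numeric(.data$is_parent)
    )
  top <- tab |>
    dplyr::filter(!.data$is_parent) |>
    dplyr::group_by(.data$position, .data$parent) |>
    dplyr::slice_max(.data$freq, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("position", "parent",
                  top_substitution = "residue", top_freq = "freq")
  structure(list(table = tab, top = top), class = "substitution_table")
}

#' @export
print.substitution_table <- function(x, ...) {
  cat(sprintf("<substitution_table> %d positions, %d with substitutions\n",
              max(x$table$position), nrow(x$top)))
  print(x$top)
  invisible(x)
}

#' @rdname substitution_enrichment
#' @param x A `substitution_table`.
#' @param ... Unused.
#' @method tidy substitution_table
#' @export
tidy.substitution_table <- function(x, ...) x$table
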