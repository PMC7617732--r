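#' Read a FASTA file
#'
#' Reads protein/sequence records through Biostrings, returning an ordered
#' tibble. Sequences are uppercased; duplicate ids, empty files, and
#' residues outside the amino-acid/gap alphabet are specific errors. CRLF
#' and LF files parse identically.
#'
#' @param path FASTA file path.
#' @param alphabet Allowed residue characters (default the 20 amino acids
#'   plus `-`, `.`, `*` and `X`).
#'
#' @return Tibble `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path, alphabet = c(AA_ALPHABET, "-", ".", "*", "X")) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(sprintf("FASTA file is empty: %s", path))
  header <- names(set)
  id <- sub("\\s.*$", "", header)
  description <- ifelse(grepl("\\s", header),
                        sub("^\\S+\\s+", "", header), "")
  dup <- id[duplicated(id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", ")))
  }
  sequence <- toupper(as.character(set))
  bad <- vapply(sequence, function(s) {
    chars <- unique(strsplit(s, "", fixed = TRUE)[[1]])
    any(!chars %in% alphabet)
  }, logical(1))
  if (any(bad)) {
    abort(paste0("illegal residue in sequence(s): ",
                 paste(id[bad], collapse = ", ")))
  }
  tibble(id = id, description = description, sequence = unname(sequence))
}

#' Write sequences to FASTA
#'
#' @param seqs Tibble `id`, `sequence` (optional `description`), or a named
#'   character vector.
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!is.data.frame(seqs)) {
    seqs <- tibble(id = names(seqs), description = "",
                   sequence = unname(seqs))
  }
  header <- if ("description" %in% names(seqs)) {
    ifelse(nzchar(seqs$description),
           paste(seqs$id, seqs$description), seqs$id)
  } else {
    seqs$id
  }
  set <- Biostrings::BStringSet(setNames(seqs$sequence, header))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a count table TSV
#'
#' Expects a UTF-8 TSV with header `id`, `count`; counts must be
#' nonnegative numbers (integers for real sequencing data; fractional
#' values are allowed so lossless simulated tables round-trip). Errors name
#' the offending line.
#'
#' @param path TSV path.
#'
#' @return Tibble `id`, `count` with unique ids.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), count = readr::col_double()
  ), progress = FALSE)
  if (nrow(tab) == 0) abort(sprintf("count table has no data rows: %s", path))
  bad <- which(!is.finite(tab$count) | tab$count < 0)
  if (length(bad) > 0) {
    abort(sprintf("negative or non-numeric count at line %d of %s.",
                  bad[1] + 1L, path))
  }
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate id(s) in count table: ",
                 paste(unique(dup), collapse = ", ")))
  }
  as_tibble(tab)
}

# fixed float formatting (6 significant digits) so seeded reruns are
# byte-identical across platforms
format_num <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15,
         format(x, scientific = FALSE, trim = TRUE),
         formatC(x, format = "g", digits = 6))
}

write_tsv_deterministic <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- format_num(df[[j]])
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], paste, character(1), collapse = ",")
    }
  }
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(unname(df), sep = "\t")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a count table TSV
#'
#' @param table Tibble `id`, `count`.
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_counts <- function(table, path) {
  stopifnot(all(c("id", "count") %in% names(table)))
  write_tsv_deterministic(table[, c("id", "count")], path)
}

#' Write a long matrix/profile tibble as TSV
#'
#' Writes any of the package's long-format matrices (logo position
#' frequency tables, entropy profiles, substitution tables) with stable
#' column order and fixed float formatting.
#'
#' @param df Data frame to write.
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(df, path) {
  write_tsv_deterministic(df, path)
}

#' Read survival records from TSV
#'
#' @param path TSV with columns `group`, `time_h`, `event`.
#'
#' @return Validated tibble of survival records.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    group = readr::col_character(), time_h = readr::col_double(),
    event = readr::col_integer()
  ), progress = FALSE)
  check_survival_records(tab)
}

#' Read and validate a JSON run configuration
#'
#' Parses a JSON configuration with a strict schema: unknown top-level keys
#' are rejected, and a seed is mandatory (never a silent default).
#'
#' @param path JSON file path.
#' @param allowed Allowed top-level keys.
#'
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path,
                            allowed = c("schema_version", "seed", "simlib",
                                        "enrich", "variantcall", "phylo",
                                        "survstats", "outdir")) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$seed)) abort("configuration must set an explicit `seed`.")
  cfg
}

#' Write all campaign outputs to a directory
#'
#' Writes one count TSV per (round, bait) table, the clone annotation TSV
#' (with planted ground-truth profile labels), and a JSON manifest of the
#' schedule, seed and package version. All writers use stable column order
#' and fixed float formatting, so a seeded rerun reproduces the directory
#' byte for byte.
#'
#' @param campaign A `sort_campaign`.
#' @param library The `fab_library` (or `toxin_panel`) it was simulated
#'   from; `NULL` to skip the annotation table.
#' @param dir Output directory (created if needed).
#'
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, library = NULL, dir) {
  stopifnot(inherits(campaign, "sort_campaign"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in campaign$rounds$round) {
    tab <- campaign$counts[campaign$counts$round == r, c("id", "count")]
    write_counts(tab, file.path(dir, paste0("counts_", r, ".tsv")))
  }
  if (!is.null(library)) {
    write_tsv_deterministic(library$clones, file.path(dir, "clones.tsv"))
  }
  manifest <- list(
    tool = "crossreact",
    version = as.character(utils::packageVersion("crossreact")),
    seed = campaign$seed,
    rounds = campaign$rounds
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
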