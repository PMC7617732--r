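# Parse a motif pattern written in the bracket-alternation notation used for
# CDRH3 motifs, e.g. "[WY]YxxGxY": uppercase residues are literals, "x" is a
# wildcard, and "[...]" encloses alternative residues for one position.
# Returns a list with one element per motif position: the character "x" for a
# wildcard, otherwise the vector of allowed residues.
parse_motif <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) < 1L) {
    abort("motif pattern must be a single non-empty string.")
  }
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  tokens <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      alts <- character()
      while (j <= length(chars) && chars[j] != "]") {
        if (!chars[j] %in% AA_ALPHABET) {
          abort(sprintf(
            "malformed motif pattern at position %d: '%s' is not a residue.",
            j, chars[j]
          ))
        }
        alts <- c(alts, chars[j])
        j <- j + 1L
      }
      if (j > length(chars)) {
        abort(sprintf("malformed motif pattern: '[' at position %d is never closed.", i))
      }
      if (length(alts) == 0L) {
        abort(sprintf("malformed motif pattern: empty bracket at position %d.", i))
      }
      tokens <- c(tokens, list(unique(alts)))
      i <- j + 1L
    } else if (ch == "x") {
      tokens <- c(tokens, list("x"))
      i <- i + 1L
    } else if (ch %in% AA_ALPHABET) {
      tokens <- c(tokens, list(ch))
      i <- i + 1L
    } else {
      abort(sprintf(
        "malformed motif pattern at position %d: unexpected character '%s'.",
        i, ch
      ))
    }
  }
  tokens
}

motif_to_regex <- function(tokens) {
  paste0(vapply(tokens, function(tok) {
    if (identical(tok, "x")) "." else if (length(tok) == 1L) tok
    else paste0("[", paste0(tok, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Scan sequences for a bracketed motif pattern
#'
#' Tests each sequence for at least one window matching a motif written in
#' bracket-alternation notation (e.g. `"[WY]YxxGxY"`, the convergent CDRH3
#' motif of broadly cross-reactive anti-toxin Fabs): uppercase letters are
#' literal residues, `x` matches any residue, and `[...]` lists alternatives
#' for one position.
#'
#' @param seqs Character vector of amino-acid sequences, or a data frame with
#'   a `cdrh3` column (e.g. the `clones` table of a [generate_library()]
#'   result).
#' @param pattern Motif pattern string.
#'
#' @return A tibble with columns `seq` (or `id` and `cdrh3` for data-frame
#'   input) and `match` (logical). The aggregate match fraction is attached
#'   as attribute `"fraction"`.
#' @examples
#' motif_scan(c("WYKAGTY", "FYKAGTY", "AAWYKAGTYAA"), "[WY]YxxGxY")
#' @export
motif_scan <- function(seqs, pattern) {
  tokens <- parse_motif(pattern)
  rx <- motif_to_regex(tokens)
  if (is.data.frame(seqs)) {
    if (!"cdrh3" %in% names(seqs)) {
      abort("data-frame input to motif_scan() must have a `cdrh3` column.")
    }
    out <- tibble(
      id = if ("id" %in% names(seqs)) seqs$id else as.character(seq_len(nrow(seqs))),
      cdrh3 = seqs$cdrh3,
      match = grepl(rx, seqs$cdrh3)
    )
  } else {
    out <- tibble(seq = seqs, match = grepl(rx, seqs))
  }
  attr(out, "fraction") <- if (nrow(out) == 0) NA_real_ else mean(out$match)
  attr(out, "pattern") <- pattern
  out
}
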