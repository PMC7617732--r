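#' Pairwise p-distance between aligned sequences
#'
#' Proportion of mismatching sites between two aligned sequences, with
#' gap-containing columns excluded pairwise (a column is skipped if either
#' sequence has a gap there).
#'
#' @param a,b Aligned sequences of equal length.
#' @param gap_chars Characters treated as gaps.
#'
#' @return Mismatch fraction in `[0, 1]`.
#' @examples
#' p_distance("AAAA", "AAAT") # 0.25
#' p_distance("AA-A", "AATA") # 0 over 3 comparable columns
#' @export
p_distance <- function(a, b, gap_chars = c("-", ".")) {
  if (nchar(a) != nchar(b)) abort("sequences must be aligned to equal length.")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  keep <- !(ca %in% gap_chars) & !(cb %in% gap_chars)
  if (!any(keep)) abort("no comparable (non-gap) columns between sequences.")
  mean(ca[keep] != cb[keep])
}

#' Jukes-Cantor corrected distance
#'
#' Converts an observed mismatch proportion into an evolutionary distance
#' under the Jukes-Cantor model of equal substitution rates:
#' `d = -((s-1)/s) * ln(1 - s*p/(s-1))` for alphabet size `s`. The classic
#' nucleotide form (`s = 4`) gives `d = -(3/4) ln(1 - 4p/3)`; `s = 20` is
#' the generalized form for amino-acid alignments. Distances saturate at
#' `p >= (s-1)/s`, which is an explicit error, never a silent clamp.
#'
#' @param p Observed mismatch proportion(s) in `[0, (s-1)/s)`.
#' @param alphabet_size Alphabet size `s` (4 for nucleotides, 20 for amino
#'   acids).
#'
#' @return Corrected distance(s), `>= p`.
#' @examples
#' jc_distance(0.3) # 0.3831192
#' @export
jc_distance <- function(p, alphabet_size = 4) {
  s <- alphabet_size
  if (s < 2) abort("`alphabet_size` must be at least 2.")
  if (any(p < 0)) abort("`p` must be nonnegative.")
  pmax_allowed <- (s - 1) / s
  if (any(p >= pmax_allowed)) {
    abort(sprintf(
      "p >= %.4g: distance saturates under the Jukes-Cantor model (alphabet size %d).",
      pmax_allowed, s
    ))
  }
  -pmax_allowed * log(1 - p / pmax_allowed)
}

#' Pairwise distance matrix of an alignment
#'
#' @param seqs Named character vector (or data frame with `id` and
#'   `sequence` columns) of aligned sequences.
#' @param model `"p"` for raw p-distance or `"jc"` for the Jukes-Cantor
#'   correction.
#' @param alphabet_size Alphabet size for the Jukes-Cantor correction
#'   (4 = nucleotide, 20 = amino acid).
#' @param gap_chars Characters treated as gaps (excluded pairwise).
#'
#' @return Symmetric numeric matrix with zero diagonal and taxon labels as
#'   dimnames.
#' @export
distance_matrix <- function(seqs, model = c("p", "jc"), alphabet_size = 4,
                            gap_chars = c("-", ".")) {
  model <- match.arg(model)
  if (is.data.frame(seqs)) {
    seqs <- setNames(seqs$sequence, seqs$id)
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("t", seq_along(seqs))
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      p <- p_distance(seqs[[i]], seqs[[j]], gap_chars)
      d <- if (model == "jc") jc_distance(p, alphabet_size) else p
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor-joining on a distance matrix: at each step
#' the pair (i, j) minimising
#' `Q(i,j) = (r-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined at a new
#' node, with branch lengths
#' `l_i = d(i,j)/2 + (sum_k d(i,k) - sum_k d(j,k)) / (2(r-2))` and
#' `l_j = d(i,j) - l_i`, and distances to the new node
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Q ties are broken by the
#' lowest (row, column) pair of taxon labels, so the result is independent
#' of input order. Negative branch lengths are clamped to 0 and the total
#' clamped deficit recorded in the `clamped_deficit` attribute.
#'
#' @param D Symmetric distance matrix (labelled, zero diagonal, `>= 3`
#'   taxa).
#'
#' @return An unrooted `ape::phylo` tree whose leaf set equals the taxon
#'   labels.
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D)) D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) abort("neighbor-joining needs at least 3 taxa.")
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  }
  if (max(abs(D - t(D))) > 1e-12) abort("distance matrix must be symmetric.")
  if (any(diag(D) != 0)) abort("distance matrix diagonal must be zero.")

  labels <- rownames(D)
  clamped <- 0
  internal_counter <- n + 1L
  temp_edges <- list()
  active <- labels
  Dw <- D

  new_node <- function() {
    id <- paste0(".internal", internal_counter)
    internal_counter <<- internal_counter + 1L
    id
  }
  add_edge <- function(parent, child, len) {
    if (len < 0) { clamped <<- clamped + (-len); len <- 0 }
    temp_edges[[length(temp_edges) + 1L]] <<- list(parent = parent,
                                                   child = child, len = len)
  }

  while (length(active) > 3) {
    r <- length(active)
    rs <- rowSums(Dw)
    Q <- (r - 2) * Dw - outer(rs, rs, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: lowest (row label, column label) pair
    ord <- order(rownames(Dw)[cand[, 1]], colnames(Dw)[cand[, 2]])
    i <- cand[ord[1], 1]; j <- cand[ord[1], 2]
    dij <- Dw[i, j]
    li <- dij / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- dij - li
    u <- new_node()
    add_edge(u, active[i], li)
    add_edge(u, active[j], lj)
    dnew <- (Dw[i, -c(i, j)] + Dw[j, -c(i, j)] - dij) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    Dw <- Dw[keep, keep, drop = FALSE]
    Dw <- rbind(cbind(Dw, dnew), c(dnew, 0))
    rownames(Dw)[r - 1] <- colnames(Dw)[r - 1] <- u
    active <- c(active[keep], u)
  }
  # final 3-way join at an unresolved central node (unrooted tree)
  u <- new_node()
  d12 <- Dw[1, 2]; d13 <- Dw[1, 3]; d23 <- Dw[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  add_edge(u, active[1], l1)
  add_edge(u, active[2], l2)
  add_edge(u, active[3], l3)

  # serialize the join structure as Newick and let ape build the phylo object
  parents <- vapply(temp_edges, `[[`, character(1), "parent")
  to_newick <- function(node) {
    kids <- which(parents == node)
    if (length(kids) == 0) return(node) # a tip label
    paste0("(", paste(vapply(kids, function(k) {
      e <- temp_edges[[k]]
      sprintf("%s:%.17g", to_newick(e$child), e$len)
    }, character(1)), collapse = ","), ")")
  }
  tree <- ape::read.tree(text = paste0(to_newick(u), ";"))
  attr(tree, "clamped_deficit") <- clamped
  if (clamped > 0) {
    warn(sprintf("negative NJ branch lengths clamped to 0 (total deficit %.3g).",
                 clamped))
  }
  tree
}
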