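# Shared fixtures and independent oracles used across the suite.

# tiny planted-profile library spec: n binders for antigen "Ag" in a
# nonbinding background
tiny_library_spec <- function(n_clones = 50, n_binders = 5, seed = 42,
                              antigens = "Ag", kd = c(1e-9, 1e-9), ...) {
  library_spec(
    n_clones = n_clones,
    planted_profiles = tibble::tibble(
      profile = "binder",
      antigens = list(antigens),
      n = n_binders,
      kd_min = kd[1], kd_max = kd[2]
    ),
    seed = seed,
    ...
  )
}

positive_round <- function(antigen = "Ag", conc = 1e-9, ...) {
  round_spec(
    mode = "FACS_positive",
    baits = tibble::tibble(antigen = antigen, conc = conc),
    sampling = "lossless",
    ...
  )
}

# independent brute-force motif matcher: explicit window loop, no regex
brute_motif_match <- function(seq, pattern) {
  tokens <- crossreact:::parse_motif(pattern)
  k <- length(tokens)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < k) return(FALSE)
  for (start in seq_len(n - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      tok <- tokens[[j]]
      ch <- chars[start + j - 1]
      if (!identical(tok, "x") && !(ch %in% tok)) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# independent Mantel-Cox statistic: explicit 2x2 hypergeometric accumulation
# over distinct event times (used as the oracle for logrank_test)
brute_logrank_chisq <- function(time, event, grp) {
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & grp)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(0)
  (O - E)^2 / V
}

# random unrooted tree with positive branch lengths; its cophenetic matrix
# is additive by construction
random_additive_tree <- function(n_taxa, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_taxa, rooted = FALSE)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
    tr$tip.label <- sort(tr$tip.label)
    tr
  })
}

# quartet-pairing induced by an additive distance matrix: in an additive
# metric the matched pairing has the strictly smallest sum
quartet_pairing <- function(D, q) {
  sums <- c(D[q[1], q[2]] + D[q[3], q[4]],
            D[q[1], q[3]] + D[q[2], q[4]],
            D[q[1], q[4]] + D[q[2], q[3]])
  which.min(sums)
}
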