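test_that("occupancy follows the single-site Langmuir law", {
  expect_equal(occupancy(1e-9, 1e-9), 0.5)
  expect_equal(occupancy(1e-9, 0), 0)
  expect_equal(occupancy(1e-9, 9e-9), 9 / (9 + 1))
  expect_equal(occupancy(1e-9, Inf), 1)
  # monotone increasing in conc, decreasing in kd
  concs <- 10^seq(-12, -6, length.out = 20)
  expect_true(all(diff(occupancy(1e-9, concs)) > 0))
  kds <- 10^seq(-12, -6, length.out = 20)
  expect_true(all(diff(occupancy(kds, 1e-9)) < 0))
  expect_error(occupancy(0, 1e-9), "positive")
  expect_error(occupancy(-1e-9, 1e-9), "positive")
  expect_error(occupancy(1e-9, -1), "nonnegative")
})

test_that("generate_library honours counts, planted profiles and seeds", {
  spec <- tiny_library_spec(n_clones = 200, n_binders = 17, seed = 7)
  lib <- generate_library(spec)
  expect_equal(nrow(lib$clones), 200)
  expect_equal(sum(lib$clones$true_profile == "binder"), 17)
  expect_equal(sort(unique(lib$affinities$id)),
               sort(lib$clones$id[lib$clones$true_profile == "binder"]))
  # seeded determinism
  lib2 <- generate_library(spec)
  expect_identical(lib$clones, lib2$clones)
  expect_identical(lib$affinities, lib2$affinities)
  # empty library
  lib0 <- generate_library(library_spec(n_clones = 0, seed = 1))
  expect_equal(nrow(lib0$clones), 0)
  # CDRH3 lengths inside configured bounds
  expect_true(all(lib$clones$cdrh3_length %in% 10:20))
  expect_equal(nchar(lib$clones$cdrh3), lib$clones$cdrh3_length)
})

test_that("library_spec rejects invalid configurations", {
  expect_error(library_spec(n_clones = 10), "seed")
  expect_error(
    library_spec(n_clones = 10, vh_weights = rep(0.2, 8), seed = 1),
    "sum to 1"
  )
  expect_error(
    library_spec(
      n_clones = 3,
      planted_profiles = tibble::tibble(
        profile = "p", antigens = list("A"), n = 5, kd_min = 1e-9, kd_max = 1e-9
      ),
      seed = 1
    ),
    "exceeding n_clones"
  )
})

test_that("planted motif, gene and length structure is recovered", {
  spec <- library_spec(
    n_clones = 2000,
    planted_profiles = tibble::tibble(
      profile = "pan", antigens = list("Ag"), n = 300,
      kd_min = 1e-9, kd_max = 1e-9, cdrh3_length = 20L,
      motif = "[WY]YxxGxY"
    ),
    seed = 11
  )
  lib <- generate_library(spec)
  pan <- lib$clones[lib$clones$true_profile == "pan", ]
  expect_true(all(pan$cdrh3_length == 20))
  expect_true(all(motif_scan(pan$cdrh3, "[WY]YxxGxY")$match))
  # background gene/length usage within 3 multinomial SE of uniform weights
  bg <- lib$clones[lib$clones$true_profile == "background", ]
  usage <- gene_usage(bg, "VH")
  p <- 1 / 8
  se <- sqrt(p * (1 - p) / nrow(bg))
  expect_true(all(abs(usage$freq - p) < 3 * se))
  ld <- length_distribution(bg, lengths = 10:20)
  p_len <- 1 / 11
  se_len <- sqrt(p_len * (1 - p_len) / nrow(bg))
  expect_true(all(abs(ld$freq - p_len) < 3 * se_len))
})

test_that("simulate_round matches hand-computed retention ratios", {
  lib <- list(affinities = tibble::tibble(
    id = c("hi", "lo"), antigen = "Ag", kd = c(1e-9 / 9, 9e-9)
  ))
  pop <- tibble::tibble(id = c("hi", "lo"), freq = c(0.5, 0.5))
  rd <- positive_round(conc = 1e-9) # occupancies 0.9 and 0.1
  tab <- simulate_round(pop, rd, lib)
  post <- attr(tab, "frequencies")
  expect_equal(post$freq[post$id == "hi"] / post$freq[post$id == "lo"], 9,
               tolerance = 1e-12)
  # symmetry: identical occupancies leave frequencies unchanged
  lib2 <- list(affinities = tibble::tibble(
    id = c("a", "b", "c"), antigen = "Ag", kd = 1e-9
  ))
  pop2 <- tibble::tibble(id = c("a", "b", "c"), freq = c(0.2, 0.3, 0.5))
  tab2 <- simulate_round(pop2, positive_round(), lib2)
  expect_equal(attr(tab2, "frequencies")$freq, c(0.2, 0.3, 0.5))
})

test_that("depletion removes certainly bound clones and extinction errors", {
  lib <- list(affinities = tibble::tibble(id = "sticky", antigen = "PSR",
                                          kd = 1e-12))
  pop <- tibble::tibble(id = c("sticky", "clean"), freq = c(0.5, 0.5))
  depl <- round_spec(
    mode = "FACS_depletion",
    baits = tibble::tibble(antigen = "PSR", conc = Inf), # occupancy 1
    sampling = "lossless"
  )
  tab <- simulate_round(pop, depl, lib)
  expect_false("sticky" %in% tab$id) # post-round count 0
  expect_equal(tab$count[tab$id == "clean"], 1e6)
  # a positive sort where nobody binds is an explicit extinction error
  pop3 <- tibble::tibble(id = "clean", freq = 1)
  expect_error(simulate_round(pop3, positive_round(), lib), "extinction")
})

test_that("campaign output equals hand-computed retention products (<=5 clones)", {
  # 3 clones, 2 lossless positive rounds at different concentrations;
  # oracle: freq proportional to the product of occupancies
  kds <- c(a = 1e-9, b = 5e-9, c = 2e-8)
  lib <- list(
    clones = tibble::tibble(id = names(kds)),
    affinities = tibble::tibble(id = names(kds), antigen = "Ag", kd = unname(kds))
  )
  rounds <- list(positive_round(conc = 1e-8), positive_round(conc = 2e-9))
  cmp <- simulate_campaign(lib, rounds, seed = 1)
  th1 <- 1e-8 / (1e-8 + kds); th2 <- 2e-9 / (2e-9 + kds)
  expected <- th1 * th2 / sum(th1 * th2)
  got <- frequencies(campaign_table(cmp, "round2"))
  expect_equal(got$freq[match(names(kds), got$id)], unname(expected),
               tolerance = 1e-12)
  # table bookkeeping: naive + 2 rounds
  expect_equal(nrow(cmp$rounds), 3)
  # empty schedule: only the naive table
  cmp0 <- simulate_campaign(lib, list(), seed = 1)
  expect_equal(cmp0$rounds$round, "round0")
})

test_that("multinomial counts sum to depth and frequencies stay normalised", {
  spec <- tiny_library_spec(n_clones = 100, n_binders = 20, seed = 3,
                            kd = c(1e-9, 1e-8))
  lib <- generate_library(spec)
  rd <- round_spec(
    mode = "FACS_positive",
    baits = tibble::tibble(antigen = "Ag", conc = 5e-9),
    sampling = "multinomial", sequencing_depth = 12345
  )
  pop <- tibble::tibble(id = lib$clones$id, freq = rep(0.01, 100))
  tab <- withr::with_seed(5, simulate_round(pop, rd, lib))
  expect_equal(sum(tab$count), 12345)
  expect_true(all(tab$count == floor(tab$count)))
  expect_equal(sum(attr(tab, "frequencies")$freq), 1, tolerance = 1e-9)
})

test_that("lossless positive sorts never rank a tighter binder below a weaker one", {
  for (seed in 1:5) {
    n <- 30
    kds <- withr::with_seed(seed, 10^stats::runif(n, -10, -7))
    lib <- list(affinities = tibble::tibble(
      id = sprintf("c%02d", seq_len(n)), antigen = "Ag", kd = kds
    ))
    pop <- tibble::tibble(id = lib$affinities$id, freq = rep(1 / n, n))
    tab <- simulate_round(pop, positive_round(conc = 3e-9), lib)
    post <- attr(tab, "frequencies")
    ord <- order(kds)
    expect_true(all(diff(post$freq[match(lib$affinities$id[ord], post$id)]) <= 1e-15))
  }
})

test_that("seeded campaigns rerun identically and fan-out placement is checked", {
  spec <- tiny_library_spec(n_clones = 200, n_binders = 30, seed = 9,
                            kd = c(1e-9, 1e-8))
  lib <- generate_library(spec)
  rounds <- list(
    round_spec(mode = "FACS_positive",
               baits = tibble::tibble(antigen = "Ag", conc = 5e-9),
               sampling = "multinomial", sequencing_depth = 1e5),
    list(
      round_spec(mode = "FACS_positive",
                 baits = tibble::tibble(antigen = "Ag", conc = 5e-9),
                 sampling = "multinomial", sequencing_depth = 1e5)
    )
  )
  c1 <- simulate_campaign(lib, rounds, seed = 4)
  c2 <- simulate_campaign(lib, rounds, seed = 4)
  expect_identical(c1$counts, c2$counts)
  expect_error(
    simulate_campaign(lib, rev(rounds), seed = 4),
    "final schedule element"
  )
  expect_error(simulate_campaign(lib, rounds), "seed")
})
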