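test_that("frequencies normalise count tables and reject degenerate input", {
  expect_equal(frequencies(tibble::tibble(id = "a", count = 7))$freq, 1)
  fr <- frequencies(tibble::tibble(id = c("a", "b"), count = c(3, 1)))
  expect_equal(fr$freq, c(0.75, 0.25))
  for (seed in 1:10) {
    tab <- withr::with_seed(seed, tibble::tibble(
      id = paste0("c", 1:50), count = stats::rpois(50, 20) + 1
    ))
    expect_equal(sum(frequencies(tab)$freq), 1, tolerance = 1e-12)
  }
  expect_error(frequencies(tibble::tibble(id = character(), count = double())),
               "non-empty")
  expect_error(frequencies(tibble::tibble(id = "a", count = 0)), "positive")
})

test_that("report_percentage uses half-up rounding at the requested decimals", {
  expect_identical(report_percentage(52, 3873, 1), 1.3)
  expect_identical(report_percentage(99, 149, 0), 66)
  expect_identical(report_percentage(42, 149, 0), 28)
  expect_identical(report_percentage(8, 149, 0), 5)
  expect_identical(report_percentage(0, 10), 0)
  expect_identical(report_percentage(1, 16, 1), 6.3) # 6.25 rounds up, not to even
  expect_error(report_percentage(1, 0), "positive")
  expect_error(report_percentage(5, 3), "k")
})

test_that("call_enriched applies both thresholds with a pseudo-frequency", {
  traj <- dplyr::bind_rows(
    tibble::tibble(round = "round0", id = c("flat", "bg"),
                   count = c(10, 999990)),
    tibble::tibble(round = "final", id = c("flat", "bg", "new"),
                   count = c(10, 949990, 50000))
  )
  calls <- call_enriched(traj)
  # absent from naive, 5% in final: enriched via pseudo-frequency
  new <- calls[calls$id == "new", ]
  expect_true(new$enriched)
  expect_equal(new$enrichment, 0.05 / (0.5 / 1e6))
  # flat at 1e-5 with no fold change: not enriched
  expect_false(calls$enriched[calls$id == "flat"])
  expect_error(call_enriched(traj, min_freq = 0), "positive")
  expect_error(
    call_enriched(traj[traj$round == "final", ]),
    "at least two rounds"
  )
})

test_that("enrichment calling recovers exactly the planted set under lossless sampling", {
  spec <- tiny_library_spec(n_clones = 5000, n_binders = 120, seed = 21,
                            kd = c(1e-9, 5e-9))
  lib <- generate_library(spec)
  rounds <- list(positive_round(conc = 1e-8), positive_round(conc = 5e-9))
  cmp <- simulate_campaign(lib, rounds, seed = 1)
  traj <- cmp$counts[, c("round", "id", "count")]
  calls <- call_enriched(traj)
  planted <- lib$clones$id[lib$clones$true_profile == "binder"]
  called <- calls$id[calls$enriched]
  expect_setequal(called, planted) # precision and recall both 1
})

test_that("cross-reactivity profiles follow set algebra over per-bait presence", {
  # hand-built final tables: A on all baits, B on two, C on one
  mk <- function(ids) tibble::tibble(id = ids, count = rep(100, length(ids)))
  ft <- dplyr::bind_rows(
    dplyr::mutate(mk(c("A", "B", "C")), bait = "x"),
    dplyr::mutate(mk(c("A", "B")), bait = "y"),
    dplyr::mutate(mk(c("A")), bait = "z")
  )
  cp <- cross_profiles(ft, primary_set = c("A", "B", "C"))
  expect_equal(cp$profiles$pan_reactive, c(TRUE, FALSE, FALSE))
  expect_equal(cp$per_bait$pct_retained[cp$per_bait$bait == "y"],
               report_percentage(2, 3, 1))
  # identical final tables: everything pan-reactive at 100%
  ft_same <- dplyr::bind_rows(lapply(c("x", "y"), function(b)
    dplyr::mutate(mk(c("A", "B")), bait = b)))
  cp_same <- cross_profiles(ft_same, primary_set = c("A", "B"))
  expect_true(all(cp_same$profiles$pan_reactive))
  expect_true(all(cp_same$per_bait$pct_retained == 100))
  # disjoint final populations: zero retention, zero pan-reactive
  ft_disj <- dplyr::bind_rows(
    dplyr::mutate(mk("A"), bait = "x"),
    dplyr::mutate(mk("B"), bait = "y")
  )
  cp_disj <- cross_profiles(ft_disj, primary_set = c("C", "D"))
  expect_equal(sum(cp_disj$profiles$pan_reactive), 0)
  expect_true(all(cp_disj$per_bait$pct_retained == 0))
  expect_error(cross_profiles(ft, primary_set = character()), "non-empty")
})

test_that("pan-reactive set equals the intersection of per-bait present sets", {
  for (seed in 1:10) {
    dat <- withr::with_seed(seed, {
      ids <- paste0("c", 1:40)
      dplyr::bind_rows(lapply(c("b1", "b2", "b3"), function(b) {
        keep <- sample(ids, sample(5:35, 1))
        tibble::tibble(bait = b, id = keep,
                       count = stats::rpois(length(keep), 50) + 1)
      }))
    })
    cp <- cross_profiles(dat, primary_set = paste0("c", 1:40),
                         presence_threshold = 1e-9)
    oracle <- Reduce(intersect, lapply(split(dat$id, dat$bait), unique))
    expect_setequal(cp$profiles$id[cp$profiles$pan_reactive],
                    intersect(oracle, paste0("c", 1:40)))
  }
})

test_that("per-bait retention is monotone non-increasing in the presence threshold", {
  dat <- withr::with_seed(8, dplyr::bind_rows(lapply(c("b1", "b2"), function(b)
    tibble::tibble(bait = b, id = paste0("c", 1:30),
                   count = stats::rpois(30, 5)))))
  dat <- dat[dat$count > 0, ]
  thresholds <- c(1e-6, 1e-3, 1e-2, 5e-2, 1e-1)
  prev <- rep(Inf, 2)
  for (th in thresholds) {
    cp <- cross_profiles(dat, primary_set = paste0("c", 1:30),
                         presence_threshold = th)
    cur <- cp$per_bait$pct_retained[order(cp$per_bait$bait)]
    expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("candidate ranking matches a brute-force sort and flags short lists", {
  mk <- function(b, counts) tibble::tibble(bait = b, id = names(counts),
                                           count = unname(counts))
  for (seed in 1:5) {
    ft <- withr::with_seed(seed, dplyr::bind_rows(lapply(c("x", "y"), function(b) {
      counts <- setNames(stats::rpois(20, 100) + 1, paste0("c", 1:20))
      mk(b, counts)
    })))
    cp <- cross_profiles(ft, primary_set = paste0("c", 1:20),
                         presence_threshold = 1e-9)
    ranked <- rank_candidates(profiles = cp, final_tables = ft, k = 10)
    # oracle: independent min-frequency computation and order()
    freq <- do.call(rbind, lapply(split(ft, ft$bait), function(d)
      d$count[match(paste0("c", 1:20), d$id)] / sum(d$count)))
    minf <- apply(freq, 2, min)
    oracle <- paste0("c", 1:20)[order(-minf, paste0("c", 1:20))][1:10]
    expect_equal(ranked$id, oracle)
  }
  # fewer pan-reactive clones than requested
  ft1 <- dplyr::bind_rows(mk("x", c(a = 10)), mk("y", c(a = 10)))
  cp1 <- cross_profiles(ft1, primary_set = "a")
  expect_warning(r1 <- rank_candidates(profiles = cp1, final_tables = ft1,
                                       k = 30), "only 1")
  expect_equal(nrow(r1), 1)
  expect_true(attr(r1, "short"))
})
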