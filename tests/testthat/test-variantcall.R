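mk_finals <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(names(rows), function(b)
    tibble::tibble(bait = b, id = names(rows[[b]]), count = unname(rows[[b]]))))
}

test_that("presence_call applies a closed lower bound and lists every variant", {
  ft <- mk_finals(
    mAb = c(v1 = 10, v2 = 999990),           # v1 exactly at 1e-5
    nAChRa1 = c(v2 = 50, v3 = 50),
    nAChRa7 = c(v2 = 100)
  )
  pres <- presence_call(ft, threshold = 1e-5,
                        variant_ids = c("v1", "v2", "v3", "v4"),
                        detected_ids = c("v1", "v2", "v3"))
  expect_equal(nrow(pres), 4)
  expect_true(pres$mAb[pres$id == "v1"]) # boundary frequency counts as present
  expect_false(pres$mAb[pres$id == "v3"])
  expect_false(any(unlist(pres[pres$id == "v4", c("mAb", "nAChRa1", "nAChRa7")])))
  expect_error(
    presence_call(ft, variant_ids = c("v1", "v2")),
    "not in the variant library"
  )
})

test_that("variant categories follow the antibody/receptor decision table", {
  ft <- mk_finals(
    mAb = c(bindr = 100),
    nAChRa1 = c(bindr = 50, esc1 = 50),
    nAChRa7 = c(bindr = 50, esc2 = 50)
  )
  ids <- c("bindr", "esc1", "esc2", "dysf", "gone")
  pres <- presence_call(ft, threshold = 1e-5, variant_ids = ids,
                        detected_ids = c("bindr", "esc1", "esc2", "dysf"))
  calls <- classify_variants(pres, mab_bait = "mAb")
  expect_equal(as.character(calls$category),
               c("binding", "escape", "escape", "dysfunctional", "absent"))
  # invariance to bait column order: permute the final tables
  pres2 <- presence_call(ft[order(ft$bait, decreasing = TRUE), ],
                         threshold = 1e-5, variant_ids = ids,
                         detected_ids = c("bindr", "esc1", "esc2", "dysf"))
  calls2 <- classify_variants(pres2, mab_bait = "mAb")
  expect_equal(calls2$category[match(calls$id, calls2$id)], calls$category)
  # invariance to count magnitude above threshold
  ft_big <- dplyr::mutate(ft, count = count * 1000)
  pres3 <- presence_call(ft_big, threshold = 1e-5, variant_ids = ids,
                         detected_ids = c("bindr", "esc1", "esc2", "dysf"))
  expect_equal(classify_variants(pres3, mab_bait = "mAb")$category,
               calls$category)
})

test_that("categories partition the library exactly", {
  panel <- generate_toxin_panel(toxin_panel_spec(
    n_variants = 120, n_long_chain = 40,
    category_counts = c(binding = 25, dysfunctional = 10, escape = 5),
    n_other_mab_binding = 4, seed = 2
  ))
  screen <- simulate_toxin_screen(panel, seed = 2)
  pres <- presence_call(screen)
  calls <- classify_variants(pres)
  expect_equal(nrow(calls), 120)
  expect_equal(sum(table(calls$category)), 120)
  # lossless simulation: confusion matrix against planted truth is diagonal
  lc <- panel$clones[panel$clones$family == "long_chain", ]
  called <- calls$category[match(lc$id, calls$id)]
  expect_equal(as.character(called), lc$true_category)
})

test_that("category summaries partition and filter by family", {
  calls <- tibble::tibble(
    id = paste0("v", 1:4),
    category = factor(c("binding", "binding", "escape", "dysfunctional"),
                      levels = c("binding", "escape", "dysfunctional", "absent"))
  )
  fam <- tibble::tibble(id = paste0("v", 1:4),
                        family = c("long_chain", "long_chain", "long_chain", "other"))
  cs <- category_summary(calls, fam, family = "long_chain")
  expect_equal(sum(cs$n), 3)
  expect_equal(cs$pct[cs$category == "binding"], 67)
  # single variant: one category at 100%
  cs1 <- category_summary(calls[1, ])
  expect_equal(cs1$pct[cs1$category == "binding"], 100)
  expect_error(category_summary(calls, fam, family = "viper"), "unknown family")
})

test_that("arbitration overrides reproduce externally refined categories", {
  calls <- tibble::tibble(
    id = paste0("v", 1:3),
    category = factor(c("binding", "escape", "escape"),
                      levels = c("binding", "escape", "dysfunctional", "absent"))
  )
  out <- apply_category_overrides(calls, tibble::tibble(
    id = c("v2", "v3"), category = c("binding", "dysfunctional")
  ))
  expect_equal(as.character(out$category), c("binding", "binding", "dysfunctional"))
  expect_error(apply_category_overrides(calls, tibble::tibble(
    id = "nope", category = "binding"
  )), "not in calls")
})

test_that("composition by round tracks family read fractions and flags unassigned", {
  counts <- dplyr::bind_rows(
    tibble::tibble(round = "round0", id = c("a", "b", "x"), count = c(50, 30, 20)),
    tibble::tibble(round = "round1", id = c("a", "b"), count = c(90, 10))
  )
  fam <- tibble::tibble(id = c("a", "b"), family = c("long_chain", "other"))
  comp <- composition_by_round(counts, fam)
  sums <- tapply(comp$fraction, comp$round, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  expect_equal(
    comp$fraction[comp$round == "round0" & comp$family == "unassigned"], 0.2
  )
  lc <- comp[comp$family == "long_chain", ]
  expect_gt(lc$fraction[lc$round == "round1"], lc$fraction[lc$round == "round0"])
  expect_error(composition_by_round(counts[counts$round == "round0", ], fam),
               "at least two rounds")
})

test_that("escape logo contrast isolates the planted loop II substitution", {
  # panel with no background mutation: escape differs from binding only at
  # the planted position
  spec <- toxin_panel_spec(
    n_variants = 20, n_long_chain = 20,
    category_counts = c(binding = 15, dysfunctional = 0, escape = 5),
    mutation_rate = 0, loopII_mutation_rate = 0, seed = 5
  )
  panel <- generate_toxin_panel(spec)
  lc <- panel$clones
  region <- spec$loopII_bounds
  lcst <- escape_logo_contrast(lc$sequence[lc$true_category == "binding"],
                               lc$sequence[lc$true_category == "escape"],
                               region)
  esc_rel <- spec$escape_mutation$position
  hit <- lcst$delta[lcst$delta$position == esc_rel & lcst$delta$residue == "A", ]
  expect_equal(hit$delta, 1) # planted fraction: all escape variants carry Ala
  off <- lcst$delta[lcst$delta$position != esc_rel, ]
  expect_true(all(off$delta == 0))
  # identical sets give zero differences
  same <- escape_logo_contrast(lc$sequence[1:5], lc$sequence[1:5], region)
  expect_true(all(same$delta$delta == 0))
  expect_error(
    escape_logo_contrast(lc$sequence[1:5], character(0), region),
    "non-empty"
  )
  expect_error(
    escape_logo_contrast(lc$sequence[1:5], lc$sequence[6:8], c(1, 999)),
    "region"
  )
})

test_that("toxin panels honour configured counts and escape substitutions", {
  panel <- generate_toxin_panel(toxin_screen_profile(seed = 3))
  expect_equal(nrow(panel$clones), 828)
  expect_equal(sum(panel$clones$family == "long_chain"), 149)
  esc <- panel$clones[!is.na(panel$clones$true_category) &
                        panel$clones$true_category == "escape", ]
  expect_equal(nrow(esc), 8)
  pos <- panel$spec$loopII_bounds[1] + panel$spec$escape_mutation$position - 1L
  expect_true(all(substr(esc$sequence, pos, pos) == "A"))
  # single-variant panel
  p1 <- generate_toxin_panel(toxin_panel_spec(
    n_variants = 1, n_long_chain = 1,
    category_counts = c(binding = 1, dysfunctional = 0, escape = 0), seed = 1
  ))
  expect_equal(nrow(p1$clones), 1)
  # category counts exceeding the long-chain family are rejected
  expect_error(toxin_panel_spec(
    n_variants = 10, n_long_chain = 5,
    category_counts = c(binding = 5, dysfunctional = 2, escape = 0), seed = 1
  ), "sum to n_long_chain")
})
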