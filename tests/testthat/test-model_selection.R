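test_that("equal evidences give a symmetric Dirichlet posterior", {
  E <- matrix(0, 6, 4, dimnames = list(NULL, 0:3))
  post <- rfx_bms(E)
  expect_equal(unname(post$alpha), rep(1 + 6 / 4, 4), tolerance = 1e-5)
  expect_equal(unname(post$expected_freq), rep(0.25, 4), tolerance = 1e-6)
})

test_that("a dominant model captures nearly all expected frequency", {
  # with a flat prior the winner's expected frequency is (1 + S) / (K + S),
  # so near-certainty needs a reasonably sized group
  E <- matrix(0, 60, 3, dimnames = list(NULL, 0:2))
  E[, 2] <- 20  # 20 log-units ahead for every subject
  post <- rfx_bms(E)
  expect_gt(post$expected_freq[2], 0.95)
  expect_equal(unname(post$expected_freq[2]), 61 / 63, tolerance = 1e-3)
})

test_that("the fixed-point update matches a hand-iterated 2x2 oracle", {
  # two models, two subjects; one iteration by hand from the flat prior:
  # u_nk  propto exp(lnE_nk + psi(alpha_k) - psi(sum alpha)) with alpha = (1,1),
  # so the digamma terms cancel and u is the softmax of each row
  E <- matrix(c(1, 0,
                0.5, 1.5), 2, 2, byrow = TRUE, dimnames = list(NULL, 0:1))
  u <- t(apply(E, 1, function(r) exp(r) / sum(exp(r))))
  alpha_hand <- 1 + colSums(u)
  post1 <- rfx_bms(E, max_iter = 1, tol = Inf)
  expect_equal(unname(post1$alpha), unname(alpha_hand), tolerance = 1e-12)
  # duplicating every subject doubles the data mass (alpha - prior)
  post <- rfx_bms(E)
  post_dup <- rfx_bms(rbind(E, E))
  expect_equal(unname(post_dup$alpha - 1), 2 * unname(post$alpha - 1),
               tolerance = 1e-4)
})

test_that("exceedance probabilities respect symmetry and the Beta closed form", {
  xp2 <- exceedance_probabilities(c(a = 2, b = 2), n_samples = 2e5, seed = 7)
  expect_lt(abs(xp2[1] - 0.5), 0.005)
  xpk <- exceedance_probabilities(rep(1.5, 5), n_samples = 2e5, seed = 8)
  expect_true(all(abs(xpk - 0.2) < 0.01))
  # alpha = (3, 1): P(p > 1/2) under Beta(3,1) = 1 - 0.5^3 = 0.875
  xp31 <- exceedance_probabilities(c(3, 1), n_samples = 5e5, seed = 9)
  expect_lt(abs(xp31[1] - 0.875), 0.005)
  # seeded draws are reproducible and leave the global RNG alone
  set.seed(123); before <- rnorm(1)
  a <- exceedance_probabilities(c(3, 2, 1), n_samples = 1e5, seed = 11)
  b <- exceedance_probabilities(c(3, 2, 1), n_samples = 1e5, seed = 11)
  expect_identical(a, b)
  set.seed(123)
  expect_identical(rnorm(1), before)
})

test_that("Monte-Carlo exceedance error shrinks with the sample count", {
  alpha <- c(4, 3, 2, 1)
  x1 <- exceedance_probabilities(alpha, n_samples = 1e5, seed = 3)
  x2 <- exceedance_probabilities(alpha, n_samples = 2e5, seed = 4)
  se <- sqrt(x1 * (1 - x1) / 1e5)
  expect_true(all(abs(x2 - x1) < 4 * se + 1e-4))
})

test_that("family inference is symmetric, covers edge cases, and stays shift-invariant", {
  ms <- enumerate_model_space()
  part <- partition_families(ms)
  expect_error(family_level_bms(matrix(0, 2, 3, dimnames = list(NULL, 0:2)),
                                part), "cover")
  # symmetric two-family toy space
  regions <- region_set()
  con <- modulable_connections(regions)
  toy <- enumerate_model_space(regions, modulable = con[1, , drop = FALSE],
                               free_input_regions = character(0))
  toy_part <- partition_families(toy)
  sizes <- vapply(toy_part, function(f) length(f$member_ids), 0L)
  keep <- sizes > 0
  Etoy <- matrix(0, 6, 2, dimnames = list(NULL,
                                          vapply(toy, `[[`, 0L, "model_id")))
  bms <- family_level_bms(Etoy, toy_part[keep], n_samples = 1e5, seed = 5)
  expect_equal(bms$family$exceedance, c(0.5, 0.5), tolerance = 0.02)
  # single-family partition: probability one without Monte Carlo
  one <- family_level_bms(Etoy[, 1, drop = FALSE],
                          list(structure(list(name = "all", member_ids = 0L),
                                         class = "model_family")))
  expect_identical(one$family$exceedance, 1)
  # per-subject shifts leave family exceedance unchanged (same MC seed)
  cfg <- reduced_cohort_config(seed = 42, n_subjects = 5, trials = 2)
  co <- simulate_cohort(cfg)
  dat <- inversion_data_from_cohort(co)[1:3]
  E <- evidence_table(dat, ms[c(1, 14, 30, 64)], keep_fits = FALSE)
  sub_part <- partition_families(ms[c(1, 14, 30, 64)])
  sub_part <- sub_part[vapply(sub_part,
                              function(f) length(f$member_ids) > 0, NA)]
  b1 <- family_level_bms(E, sub_part, n_samples = 1e5, seed = 2)
  b2 <- family_level_bms(sweep(E, 1, c(100, -5, 30), `+`), sub_part,
                         n_samples = 1e5, seed = 2)
  expect_equal(b1$family$exceedance, b2$family$exceedance, tolerance = 1e-9)
  expect_equal(b1$exceedance, b2$exceedance, tolerance = 1e-9)
})

test_that("a huge prior concentration pulls expected frequencies to uniform", {
  E <- matrix(c(0, 5, 1, 4, 2, 3), 3, 2, dimnames = list(NULL, 0:1))
  post <- rfx_bms(E, prior_alpha = 1e6)
  expect_lt(max(abs(post$expected_freq - 0.5)), 1e-3)
})

test_that("the two-stage winner rule follows family then model", {
  ms <- enumerate_model_space()
  part <- partition_families(ms)
  fam_of <- vapply(ms, classify_family, "")
  ids <- vapply(ms, `[[`, 0L, "model_id")
  # construct evidences where one bottom-up model is globally strongest for
  # a minority, but bidirectional models dominate most subjects
  E <- matrix(0, 10, 64, dimnames = list(NULL, ids))
  star_bu <- which(fam_of == "bottom_up")[1]
  bi <- which(fam_of == "bidirectional")[1:3]
  E[1:2, star_bu] <- 40
  E[3:10, bi[1]] <- 12; E[3:10, bi[2]] <- 11; E[3:10, bi[3]] <- 10
  sel <- select_winning(E, part, n_samples = 1e5, seed = 6)
  expect_identical(sel$winning_family, "bidirectional")
  # the returned model is the best bidirectional one, not the global star
  expect_identical(sel$winning_model, ids[bi[1]])
  # degenerate dominant single model: its family and itself
  E2 <- matrix(0, 6, 64, dimnames = list(NULL, ids))
  E2[, 40] <- 25
  sel2 <- select_winning(E2, part, n_samples = 1e5, seed = 6)
  expect_identical(sel2$winning_model, ids[40])
  expect_identical(sel2$winning_family, fam_of[40])
})

test_that("exact within-family ties break toward the lower model id", {
  ms <- enumerate_model_space()[1:4]  # ids 0..3, all no-modulation
  part <- partition_families(ms)
  part <- part[vapply(part, function(f) length(f$member_ids) > 0, NA)]
  E <- matrix(0, 5, 4, dimnames = list(NULL, 0:3))
  bms <- family_level_bms(E, part, n_samples = 1e4, seed = 1)
  bms$exceedance[] <- 0.25  # inject an exact four-way tie
  expect_warning(sel <- select_winning(E, part, bms = bms), "tie")
  expect_identical(sel$winning_model, 0L)
})
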