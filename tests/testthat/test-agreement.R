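test_that("Cohen's kappa matches hand-computed confusion matrices", {
  # perfect agreement on mixed categories
  r <- paired_ratings(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(cohens_kappa(r)$kappa, 1)

  # independence: counts [[25,25],[25,25]]
  r1 <- rep(c("a", "a", "b", "b"), 25)
  r2 <- rep(c("a", "b", "a", "b"), 25)
  k <- cohens_kappa(paired_ratings(r1, r2))
  expect_equal(k$p_o, 0.5)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$kappa, 0)

  # counts [[20,5],[10,65]]: p_o = 0.85, p_e = 0.25*0.3 + 0.75*0.7 = 0.6
  r1 <- c(rep("a", 25), rep("b", 75))
  r2 <- c(rep("a", 20), rep("b", 5), rep("a", 10), rep("b", 65))
  k <- cohens_kappa(paired_ratings(r1, r2))
  expect_equal(k$p_o, 0.85)
  expect_equal(k$p_e, 0.6)
  expect_equal(k$kappa, 0.25 / 0.4)
})

test_that("kappa agrees with the independent e1071 implementation", {
  set.seed(44)
  for (i in 1:20) {
    r1 <- sample(letters[1:4], 60, replace = TRUE)
    r2 <- ifelse(runif(60) < 0.6, r1, sample(letters[1:4], 60,
                                             replace = TRUE))
    ours <- cohens_kappa(paired_ratings(r1, r2))
    ref <- e1071::classAgreement(table(factor(r1, levels = letters[1:4]),
                                       factor(r2, levels = letters[1:4])))
    expect_equal(ours$kappa, ref$kappa, tolerance = 1e-12)
  }
})

test_that("degenerate single-category ratings are signalled distinctly", {
  r <- paired_ratings(c("a", "a"), c("a", "a"), universe = "a")
  expect_warning(k <- cohens_kappa(r), "degenerate")
  expect_true(k$degenerate)
  expect_equal(k$kappa, 1)  # p_o = p_e = 1
})

test_that("weighted kappa with indicator credit reduces to plain kappa", {
  exact <- function(a, b) as.numeric(a == b)
  set.seed(7)
  for (i in 1:500) {
    n <- sample(5:40, 1)
    u <- letters[1:sample(2:5, 1)]
    r1 <- sample(u, n, replace = TRUE)
    r2 <- sample(u, n, replace = TRUE)
    r <- paired_ratings(r1, r2, universe = u)
    a <- suppressWarnings(cohens_kappa(r))
    b <- suppressWarnings(weighted_kappa(r, exact))
    expect_identical(b$kappa, a$kappa)
    expect_identical(b$p_o, a$p_o)
    expect_identical(b$p_e, a$p_e)
  }
})

test_that("weighted kappa validates the credit function", {
  r <- paired_ratings(c("a", "b"), c("b", "a"))
  expect_error(weighted_kappa(r, function(a, b) 0),  # diagonal not 1
               class = "ecocollate_argument_error")
  asym <- function(a, b) if (a == b) 1 else if (a < b) 0.5 else 0
  expect_error(weighted_kappa(r, asym),
               class = "ecocollate_argument_error")
  big <- function(a, b) if (a == b) 1 else 2
  expect_error(weighted_kappa(r, big),
               class = "ecocollate_argument_error")
})

test_that("near-miss credit gives exactly half credit to near misses", {
  r <- paired_ratings(
    rep("Primary vegetation", 10),
    rep("Secondary vegetation (mature)", 10),
    universe = c("Primary vegetation", "Secondary vegetation (mature)"))
  k <- weighted_kappa(r, land_use_credit())
  expect_equal(k$p_o, 0.5)  # all pairs are near misses at credit 0.5

  cr <- intensity_credit()
  expect_equal(cr("Minimal use", "Light use"), 0.5)
  expect_equal(cr("Minimal use", "Intense use"), 0)
  expect_equal(cr("Cannot decide", "Intense use"), 0.5)
  expect_equal(cr("Light use", "Light use"), 1)
})

test_that("weighted kappa equals an exhaustive double-sum oracle", {
  u <- c("x", "y", "z")
  credit <- function(a, b) {
    if (a == b) return(1)
    if (setequal(c(a, b), c("x", "y"))) return(0.5)  # one near-miss pair
    0
  }
  set.seed(30)
  r1 <- sample(u, 30, replace = TRUE)
  r2 <- sample(u, 30, replace = TRUE)
  r <- paired_ratings(r1, r2, universe = u)
  k <- weighted_kappa(r, credit)
  # brute force: mean credit and full double sum over the universe
  p_o <- mean(mapply(credit, r1, r2))
  p_e <- 0
  for (a in u) {
    for (b in u) {
      p_e <- p_e + credit(a, b) * mean(r1 == a) * mean(r2 == b)
    }
  }
  expect_equal(k$p_o, p_o)
  expect_equal(k$p_e, p_e)
  expect_equal(k$kappa, (p_o - p_e) / (1 - p_e))
})

test_that("kappa is invariant to item order and category relabeling", {
  set.seed(9)
  u <- letters[1:4]
  r1 <- sample(u, 80, replace = TRUE)
  r2 <- sample(u, 80, replace = TRUE)
  k0 <- cohens_kappa(paired_ratings(r1, r2, universe = u))
  perm <- sample(80)
  k1 <- cohens_kappa(paired_ratings(r1[perm], r2[perm], universe = u))
  expect_equal(k1$kappa, k0$kappa)
  relabel <- setNames(c("W", "X", "Y", "Z"), u)
  k2 <- cohens_kappa(paired_ratings(relabel[r1], relabel[r2],
                                    universe = unname(relabel)))
  expect_equal(k2$kappa, k0$kappa)
})

test_that("sampled kappa converges to the analytic value of the generator", {
  u <- c("Minimal use", "Light use", "Intense use")
  conf <- matrix(c(0.28, 0.05, 0.02,
                   0.04, 0.30, 0.03,
                   0.02, 0.04, 0.22), 3, 3, byrow = TRUE,
                 dimnames = list(u, u))
  r <- gen_ratings(fixture_spec(seed = 101), conf, n = 10000)
  analytic <- attr(r, "analytic")
  k <- cohens_kappa(r)
  expect_equal(k$kappa, analytic$kappa, tolerance = 0.02)

  # identity and independence edge cases
  id <- diag(3) / 3
  dimnames(id) <- list(u, u)
  expect_equal(attr(gen_ratings(fixture_spec(seed = 1), id, 10),
                    "analytic")$kappa, 1)
  indep <- outer(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2))
  dimnames(indep) <- list(u, u)
  expect_equal(attr(gen_ratings(fixture_spec(seed = 1), indep, 10),
                    "analytic")$kappa, 0)
})

test_that("the goodness-of-fit test matches hand arithmetic and chisq.test", {
  # observed exactly proportional to expected
  res <- representativeness_chisq(c(a = 10, b = 20, c = 70),
                                  c(a = 0.1, b = 0.2, c = 0.7))
  expect_equal(res$statistic, 0)

  # three equal cells: sum((O - 100/3)^2 / (100/3))
  res <- representativeness_chisq(c(a = 10, b = 20, c = 70),
                                  c(a = 1, b = 1, c = 1) / 3)
  e <- 100 / 3
  expect_equal(res$statistic,
               ((10 - e)^2 + (20 - e)^2 + (70 - e)^2) / e)
  expect_equal(res$degrees_of_freedom, 2)
  ref <- suppressWarnings(stats::chisq.test(c(10, 20, 70),
                                            p = rep(1, 3) / 3))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, unname(ref$p.value))
})

test_that("exclusion renormalizes and sets the degrees of freedom", {
  combos <- as.vector(outer(c("Primary vegetation",
                              "Secondary vegetation", "Cropland",
                              "Pasture", "Urban", "Plantation forest"),
                            c("Minimal use", "Light use", "Intense use"),
                            paste, sep = " / "))
  obs <- setNames(rep(10, 18), combos)
  props <- setNames(rep(1 / 18, 18), combos)
  res <- representativeness_chisq(obs, props, exclude = "Urban / Light use")
  expect_equal(res$degrees_of_freedom, 16)
  expect_equal(sum(res$expected), sum(res$observed))

  props2 <- props
  props2[["Urban / Light use"]] <- 0
  expect_error(representativeness_chisq(obs, props2),
               "Urban / Light use", class = "ecocollate_argument_error")
})

test_that("the statistic is order-invariant and scales with the counts", {
  obs <- c(a = 12, b = 30, c = 58)
  p <- c(a = 0.2, b = 0.3, c = 0.5)
  s1 <- representativeness_chisq(obs, p)$statistic
  s2 <- representativeness_chisq(obs[c(3, 1, 2)], p[c(2, 3, 1)])$statistic
  expect_equal(s1, s2)
  expect_equal(representativeness_chisq(2 * obs, p)$statistic, 2 * s1)
})
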