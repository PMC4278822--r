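#' Paired categorical ratings
#'
#' Two raters' classifications of the same items, e.g. predominant land use
#' rescored blind for a random sample of sites in a repeatability study.
#'
#' @param rater1,rater2 Equal-length vectors of category labels.
#' @param universe Category universe; defaults to the union of observed
#'   labels.  Every rating must lie in the universe.
#' @return A `paired_ratings`.
#' @export
paired_ratings <- function(rater1, rater2, universe = NULL) {
  stopifnot(length(rater1) == length(rater2), length(rater1) >= 1)
  rater1 <- as.character(rater1); rater2 <- as.character(rater2)
  if (is.null(universe)) universe <- sort(unique(c(rater1, rater2)))
  if (any(!c(rater1, rater2) %in% universe)) {
    stop_with("ecocollate_argument_error",
              "ratings outside the category universe")
  }
  structure(list(rater1 = rater1, rater2 = rater2, universe = universe),
            class = "paired_ratings")
}

kappa_result <- function(p_o, p_e, kappa, degenerate = FALSE) {
  structure(list(p_o = p_o, p_e = p_e, kappa = kappa,
                 degenerate = degenerate),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (observed agreement %.3f, expected %.3f)%s\n",
              x$kappa, x$p_o, x$p_e,
              if (x$degenerate) " [degenerate: expected agreement is 1]"
              else ""))
  invisible(x)
}

finish_kappa <- function(p_o, p_e) {
  if (p_e >= 1) {
    # all probability mass on one cell: agreement carries no information
    warning("expected agreement is 1; kappa is degenerate",
            call. = FALSE)
    return(kappa_result(p_o, p_e, if (p_o >= 1) 1 else NA_real_,
                        degenerate = TRUE))
  }
  kappa_result(p_o, p_e, (p_o - p_e) / (1 - p_e))
}

#' Cohen's kappa for inter-rater agreement
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with `p_o`
#' the proportion of identical pairs and `p_e` the agreement expected from
#' the raters' marginal distributions.  Ranges from 0 (agreement no better
#' than chance) to 1 (perfect agreement).
#'
#' @param ratings A [paired_ratings()].
#' @return A `kappa_result` with fields `p_o`, `p_e`, `kappa`.
#' @export
cohens_kappa <- function(ratings) {
  stopifnot(inherits(ratings, "paired_ratings"))
  u <- ratings$universe
  n <- length(ratings$rater1)
  p_o <- mean(ratings$rater1 == ratings$rater2)
  m1 <- table(factor(ratings$rater1, levels = u)) / n
  m2 <- table(factor(ratings$rater2, levels = u)) / n
  p_e <- sum(as.vector(m1) * as.vector(m2))
  finish_kappa(p_o, p_e)
}

#' Weighted kappa with partial credit for near misses
#'
#' Generalises [cohens_kappa()] by a credit function giving each ordered
#' category pair a weight in \[0, 1\]: `p_o` is the mean credit over items
#' and `p_e` the expected credit under independent marginals.  Credit must
#' be symmetric and give full credit on the diagonal; with the exact-match
#' indicator the result equals [cohens_kappa()] exactly.  The conventional
#' weighting scores pre-specified "near misses" as 0.5 (see
#' [near_miss_credit()]).
#'
#' @param ratings A [paired_ratings()].
#' @param credit Function `(a, b) -> weight in [0, 1]`.
#' @return A `kappa_result`.
#' @export
weighted_kappa <- function(ratings, credit) {
  stopifnot(inherits(ratings, "paired_ratings"), is.function(credit))
  u <- ratings$universe
  k <- length(u)
  W <- matrix(NA_real_, k, k, dimnames = list(u, u))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) W[i, j] <- credit(u[i], u[j])
  }
  if (any(W < 0 | W > 1)) {
    stop_with("ecocollate_argument_error", "credit must lie in [0, 1]")
  }
  if (any(abs(diag(W) - 1) > 1e-12)) {
    stop_with("ecocollate_argument_error",
              "credit must give full credit to exact agreement")
  }
  if (any(abs(W - t(W)) > 1e-12)) {
    stop_with("ecocollate_argument_error", "credit must be symmetric")
  }
  n <- length(ratings$rater1)
  p_o <- mean(W[cbind(ratings$rater1, ratings$rater2)])
  m1 <- as.vector(table(factor(ratings$rater1, levels = u))) / n
  m2 <- as.vector(table(factor(ratings$rater2, levels = u))) / n
  p_e <- sum(W * outer(m1, m2))
  finish_kappa(p_o, p_e)
}

#' Credit functions for repeatability scoring
#'
#' `near_miss_credit()` builds a credit function from a near-miss relation:
#' exact agreement scores 1, a near miss scores `weight` (0.5 by
#' convention), anything else 0.  `land_use_credit()` and
#' `intensity_credit()` are ready-made credits over the canonical labels,
#' wired to [near_miss_land_use()] and [near_miss_intensity()] (land-use
#' labels are parsed with [parse_land_use()], so secondary stages written as
#' `"Secondary vegetation (young)"` participate in the stage rules).
#'
#' @param near_miss Symmetric predicate `(a, b) -> logical` over parsed
#'   categories.
#' @param weight Partial credit for a near miss (default 0.5).
#' @param parse Category-label parser applied before `near_miss`.
#' @return A credit function usable with [weighted_kappa()].
#' @export
near_miss_credit <- function(near_miss, weight = 0.5, parse = identity) {
  force(near_miss); force(weight); force(parse)
  function(a, b) {
    if (identical(a, b)) return(1)
    pa <- parse(a); pb <- parse(b)
    if (identical(pa, pb)) return(1)
    if (near_miss(pa, pb)) weight else 0
  }
}

#' @rdname near_miss_credit
#' @export
land_use_credit <- function(weight = 0.5) {
  near_miss_credit(near_miss_land_use, weight = weight,
                   parse = parse_land_use)
}

#' @rdname near_miss_credit
#' @export
intensity_credit <- function(weight = 0.5) {
  near_miss_credit(near_miss_intensity, weight = weight)
}

#' Representativeness goodness-of-fit test
#'
#' Compares observed site counts per land-use x intensity combination with
#' the proportions of total terrestrial area expected for each combination.
#' Combinations without an area estimate (e.g. urban land under light use)
#' are excluded and the remaining proportions renormalized; the Pearson
#' statistic `sum((O - E)^2 / E)` is referred to a chi-square distribution
#' with (included combinations - 1) degrees of freedom.
#'
#' @param observed Named vector of site counts per combination.
#' @param expected_props Named vector of area proportions (same names).
#' @param exclude Combination names to drop before renormalizing.
#' @return A `chisq_result`: `statistic`, `degrees_of_freedom`, `p_value`,
#'   `observed`, `expected`.
#' @export
representativeness_chisq <- function(observed, expected_props,
                                     exclude = NULL) {
  common <- intersect(names(observed), names(expected_props))
  if (!length(common)) {
    stop_with("ecocollate_argument_error",
              "observed and expected share no combinations")
  }
  keep <- setdiff(common, exclude)
  o <- observed[keep]
  p <- expected_props[keep]
  zero <- p <= 0
  if (any(zero)) {
    stop_with("ecocollate_argument_error",
              "expected proportion is zero for '%s'; exclude it explicitly",
              keep[zero][1])
  }
  p <- p / sum(p)
  e <- sum(o) * p
  stat <- sum((o - e)^2 / e)
  df <- length(keep) - 1L
  structure(list(statistic = unname(stat), degrees_of_freedom = df,
                 p_value = pchisq(unname(stat), df, lower.tail = FALSE),
                 observed = o, expected = e),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  p <- if (x$p_value < 2.2e-16) "< 2.2e-16" else
    format(x$p_value, digits = 4)
  cat(sprintf("Chi-squared = %.2f, df = %d, P %s%s\n",
              x$statistic, x$degrees_of_freedom,
              if (startsWith(p, "<")) p else paste("=", p), ""))
  invisible(x)
}
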