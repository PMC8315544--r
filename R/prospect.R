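#' Discrete prospect
#'
#' A finite random variable over real outcomes: the object CPT assigns value
#' to. Construction merges duplicate outcomes (summing their probabilities),
#' drops zero-probability outcomes, sorts the support increasingly, and
#' renormalizes probabilities that are within `1e-12` of summing to one;
#' larger deviations are an error.
#'
#' @param outcomes Numeric vector of outcome values.
#' @param probabilities Numeric vector of nonnegative probabilities, same
#'   length as `outcomes`, summing to 1.
#' @return An object of class `prospect` with sorted, distinct outcomes.
#' @examples
#' prospect(c(1000, 0), c(0.95, 0.05))
#' prospect(c(1, 1, 2), c(0.25, 0.25, 0.5)) # duplicates merged
#' @export
prospect <- function(outcomes, probabilities) {
  stopifnot(is.numeric(outcomes), is.numeric(probabilities),
            length(outcomes) == length(probabilities),
            length(outcomes) >= 1L)
  if (any(!is.finite(outcomes))) stop("outcomes must be finite")
  if (any(!is.finite(probabilities)) || any(probabilities < 0)) {
    stop("probabilities must be finite and nonnegative")
  }
  tot <- sum(probabilities)
  if (abs(tot - 1) > 1e-12) {
    stop(sprintf("probabilities sum to %.15g, not 1 (tolerance 1e-12)", tot))
  }
  probabilities <- probabilities / tot
  ord <- order(outcomes)
  outcomes <- outcomes[ord]
  probabilities <- probabilities[ord]
  # merge outcomes equal within 1e-12 (absolute) and drop zero-probability mass
  grp <- cumsum(c(TRUE, diff(outcomes) > 1e-12))
  o <- as.numeric(tapply(outcomes, grp, `[`, 1L))
  p <- as.numeric(tapply(probabilities, grp, sum))
  keep <- p > 0
  structure(list(outcomes = o[keep], probabilities = p[keep]),
            class = "prospect")
}

#' @export
print.prospect <- function(x, ...) {
  cat("<prospect>", length(x$outcomes), "outcomes\n")
  print(tibble::tibble(outcome = x$outcomes, probability = x$probabilities))
  invisible(x)
}

#' @export
tidy.prospect <- function(x, ...) {
  tibble::tibble(outcome = x$outcomes, probability = x$probabilities)
}

#' Rank-dependent decision weights
#'
#' Splits the support of a prospect into gains (`r >= b`) and losses
#' (`r < b`) and computes the cumulative-prospect decision weights: for a
#' gain, `psi(r) = w(P(R >= r)) - w(P(R > r))`; for a loss,
#' `psi(r) = w(P(R <= r)) - w(P(R < r))`. For an all-gain (or all-loss)
#' prospect the weights telescope to `w(1) = 1`.
#'
#' @param x A [prospect()].
#' @param reference_point Reference point `b` separating gains from losses.
#' @param weighting A [weighting_spec()].
#' @return A tibble with columns `outcome`, `probability`, `sign`
#'   (`"gain"`/`"loss"`), and `weight`.
#' @examples
#' decision_weights(prospect(c(1000, 0), c(0.95, 0.05)), 0,
#'                  weighting_spec("prelec", 1, 0.75))
#' @export
decision_weights <- function(x, reference_point = 0,
                             weighting = weighting_spec()) {
  stopifnot(inherits(x, "prospect"))
  o <- x$outcomes
  p <- x$probabilities
  n <- length(o)
  gain <- o >= reference_point
  # decumulative P(R >= r_j) and cumulative P(R <= r_j), outcomes ascending
  p_ge <- rev(cumsum(rev(p)))
  p_gt <- p_ge - p
  p_le <- cumsum(p)
  p_lt <- p_le - p
  clamp01 <- function(z) pmin(pmax(z, 0), 1)
  w <- function(z) prob_weight(clamp01(z), weighting)
  psi <- ifelse(gain, w(p_ge) - w(p_gt), w(p_le) - w(p_lt))
  tibble::tibble(outcome = o, probability = p,
                 sign = ifelse(gain, "gain", "loss"),
                 weight = psi)
}

#' CPT value of a discrete prospect
#'
#' The cumulative-prospect value: outcomes are framed as gains or losses
#' relative to the reference point, given reference-dependent utilities, and
#' aggregated with rank-dependent decision weights,
#' `V = sum_gains u(r - b) psi(r) + sum_losses u(r - b) psi(r)`.
#' With identity utility, identity weighting, and `b = 0` this is the
#' ordinary expectation (the expected-utility limit).
#'
#' @param x A [prospect()].
#' @param params A [cpt_params()].
#' @return A single numeric value.
#' @examples
#' cpt_value(prospect(c(1000, 0), c(0.95, 0.05)), eut_params()) # 950
#' @export
cpt_value <- function(x, params = eut_params()) {
  stopifnot(inherits(x, "prospect"), inherits(params, "cpt_params"))
  dw <- decision_weights(x, params$reference_point, params$weighting)
  sum(utility(x$outcomes - params$reference_point, params$utility) * dw$weight)
}

#' Value of a certain outcome
#'
#' The CPT value of receiving `r` for sure: `u(r - b)`.
#'
#' @param r Certain outcome (numeric vector allowed).
#' @param params A [cpt_params()].
#' @export
certainty_value <- function(r, params = eut_params()) {
  stopifnot(inherits(params, "cpt_params"))
  utility(r - params$reference_point, params$utility)
}

#' Value of a two-outcome gamble
#'
#' The CPT value of the gamble paying `r_plus` with probability `p` and
#' `r_minus` with probability `1 - p` (`r_plus > r_minus`). Equals
#' [cpt_value()] of the corresponding two-outcome prospect; the decision
#' weight of each branch depends on whether that branch is framed as a gain
#' or a loss.
#'
#' @param r_plus Larger outcome.
#' @param r_minus Smaller outcome.
#' @param p Probability of `r_plus`.
#' @param params A [cpt_params()].
#' @export
gamble_value <- function(r_plus, r_minus, p, params = eut_params()) {
  stopifnot(is.numeric(r_plus), is.numeric(r_minus), length(r_plus) == 1L,
            length(r_minus) == 1L, is.numeric(p), length(p) == 1L,
            p >= 0, p <= 1)
  if (!(r_plus > r_minus)) stop("r_plus must exceed r_minus")
  cpt_value(prospect(c(r_minus, r_plus), c(1 - p, p)), params)
}

#' CPT value via the epsilon-integral form
#'
#' Independent evaluation of the CPT value as the difference of two
#' tail-probability integrals,
#' `int_0^inf w(P(U+ > e)) de - int_0^inf w(P(U- > e)) de`,
#' where `U+` is the gain utility of the positive part of `R - b` and `U-`
#' the magnitude of the loss utility of its negative part. Because the
#' prospect is discrete both integrands are step functions, and the
#' quadrature sums each step exactly. Used as a cross-check oracle for
#' [cpt_value()]; the two agree to near machine precision.
#'
#' @inheritParams cpt_value
#' @return A single numeric value.
#' @export
cpt_value_integral <- function(x, params = eut_params()) {
  stopifnot(inherits(x, "prospect"), inherits(params, "cpt_params"))
  b <- params$reference_point
  off <- x$outcomes - b
  p <- x$probabilities
  u_gain <- ifelse(off >= 0, utility(pmax(off, 0), params$utility), 0)
  u_loss <- ifelse(off < 0, -utility(pmin(off, 0), params$utility), 0)
  step_integral <- function(u) {
    # int_0^inf w(P(U > e)) de for a nonnegative discrete U
    lv <- sort(unique(u[u > 0]))
    if (length(lv) == 0L) return(0)
    lo <- c(0, lv[-length(lv)])
    tail_p <- vapply(lv, function(t) sum(p[u >= t - 1e-15]), numeric(1))
    sum((lv - lo) * prob_weight(pmin(pmax(tail_p, 0), 1), params$weighting))
  }
  step_integral(u_gain) - step_integral(u_loss)
}

# Vectorized CPT backup kernel: row-wise CPT value of many small prospects.
# O and P are n x m matrices of outcomes and probabilities (rows need not be
# sorted or deduplicated: rank-dependent weights are invariant to splitting
# an outcome across tied columns, so ties and zero-probability slots are
# harmless). Used by the Markov planner.
cpt_value_rows <- function(O, P, params) {
  n <- nrow(O)
  m <- ncol(O)
  b <- params$reference_point
  # sort each row ascending with a single order() call
  ridx <- row(O)
  perm <- order(ridx, O)
  Os <- matrix(O[perm], nrow = n, byrow = TRUE)
  Ps <- matrix(P[perm], nrow = n, byrow = TRUE)
  psi <- psi_sorted_rows(Os, Ps, params)
  U <- matrix(utility(as.numeric(Os) - b, params$utility), nrow = n)
  rowSums(U * psi)
}

# decision weights for row-sorted outcome/probability matrices
psi_sorted_rows <- function(Os, Ps, params) {
  m <- ncol(Os)
  b <- params$reference_point
  # decumulative P(R >= r) per row
  Pge <- Ps
  if (m > 1) for (j in (m - 1):1) Pge[, j] <- Pge[, j + 1] + Ps[, j]
  Pgt <- Pge - Ps
  Ple <- 1 - Pgt
  Plt <- 1 - Pge
  cl <- function(z) pmin(pmax(z, 0), 1)
  wspec <- params$weighting
  gain <- Os >= b
  ifelse(gain,
         prob_weight(cl(Pge), wspec) - prob_weight(cl(Pgt), wspec),
         prob_weight(cl(Ple), wspec) - prob_weight(cl(Plt), wspec))
}

# decision weights in the original (unsorted) slot order of O
psi_rows <- function(O, P, params) {
  n <- nrow(O)
  m <- ncol(O)
  ridx <- row(O)
  perm <- order(ridx, O)
  Os <- matrix(O[perm], nrow = n, byrow = TRUE)
  Ps <- matrix(P[perm], nrow = n, byrow = TRUE)
  psi_s <- psi_sorted_rows(Os, Ps, params)
  psi <- numeric(n * m)
  psi[perm] <- as.numeric(t(psi_s))
  matrix(psi, nrow = n)
}
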