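#' Utility specification for CPT agents
#'
#' Reference-dependent utility with diminishing marginal returns and loss
#' aversion. For an offset `x = r - b` from the reference point, the power
#' utility is `x^gamma` for gains (`x >= 0`) and `-lambda * |x|^gamma` for
#' losses (`x < 0`). The identity kind (`u(x) = x`) is the expected-utility
#' special case and behaves as `gamma = 1`, `lambda = 1`.
#'
#' @param kind `"power"` or `"identity"`.
#' @param gamma Positive exponent controlling utility concavity
#'   (dimensionless). `gamma < 1` gives diminishing marginal returns.
#' @param lambda Positive loss-aversion multiplier: losses are scaled by
#'   `lambda` relative to gains of equal magnitude.
#' @return An object of class `utility_spec`.
#' @examples
#' u <- utility_spec("power", gamma = 0.85, lambda = 2)
#' utility(c(-1, 0, 1, 1000), u)
#' @export
utility_spec <- function(kind = c("power", "identity"), gamma = 1, lambda = 1) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma), gamma > 0)
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda), lambda > 0)
  if (kind == "identity") {
    gamma <- 1
    lambda <- 1
  }
  structure(list(kind = kind, gamma = gamma, lambda = lambda),
            class = "utility_spec")
}

#' Probability weighting specification
#'
#' Distortion of cumulative probabilities. The Prelec form is
#' `w(p) = exp(-alpha * (-log p)^delta)`; `alpha` controls whether the
#' possibility effect (overweighting of small probabilities, small `alpha`)
#' or the certainty effect (underweighting of large probabilities, large
#' `alpha`) dominates, while `delta` bends the curve around the fixed point.
#' The original 1992 form is `w(p) = p^g / (p^g + (1-p)^g)^(1/g)`. The
#' identity kind maps `p` to itself (the expected-utility limit).
#'
#' @param kind `"prelec"`, `"kt1992"`, or `"identity"`.
#' @param alpha Positive Prelec parameter.
#' @param delta Positive Prelec exponent.
#' @param gamma_w Positive exponent of the 1992 form.
#' @return An object of class `weighting_spec`.
#' @examples
#' w <- weighting_spec("prelec", alpha = 0.5, delta = 0.9)
#' prob_weight(c(0, 0.5, 1), w)
#' @export
weighting_spec <- function(kind = c("prelec", "kt1992", "identity"),
                           alpha = 1, delta = 0.75, gamma_w = 0.85) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha), alpha > 0)
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta), delta > 0)
  stopifnot(is.numeric(gamma_w), length(gamma_w) == 1L, is.finite(gamma_w),
            gamma_w > 0)
  structure(list(kind = kind, alpha = alpha, delta = delta, gamma_w = gamma_w),
            class = "weighting_spec")
}

#' Full CPT parameter set for one agent
#'
#' Bundles the utility function, probability weighting function, and
#' reference point. Outcomes at or above the reference point `b` are framed
#' as gains, outcomes below it as losses.
#'
#' @param utility A [utility_spec()].
#' @param weighting A [weighting_spec()].
#' @param reference_point Reference point `b`, in outcome units.
#' @return An object of class `cpt_params`.
#' @examples
#' cpt_params(utility_spec("power", 0.85, 2), weighting_spec("prelec", 1, 0.75))
#' eut_params() # the expected-utility special case
#' @export
cpt_params <- function(utility = utility_spec(),
                       weighting = weighting_spec(),
                       reference_point = 0) {
  stopifnot(inherits(utility, "utility_spec"),
            inherits(weighting, "weighting_spec"),
            is.numeric(reference_point), length(reference_point) == 1L,
            is.finite(reference_point))
  structure(list(utility = utility, weighting = weighting,
                 reference_point = reference_point),
            class = "cpt_params")
}

#' @rdname cpt_params
#' @details `eut_params()` is the identity-utility, identity-weighting,
#'   zero-reference parameter set under which CPT value reduces to the
#'   ordinary expectation of the prospect.
#' @export
eut_params <- function(reference_point = 0) {
  cpt_params(utility_spec("identity"), weighting_spec("identity"),
             reference_point)
}

#' @export
print.cpt_params <- function(x, ...) {
  u <- x$utility
  w <- x$weighting
  cat("<cpt_params>\n")
  if (u$kind == "identity") {
    cat("  utility:   u(x) = x\n")
  } else {
    cat(sprintf("  utility:   u(x) = x^%g (gains), -%g|x|^%g (losses)\n",
                u$gamma, u$lambda, u$gamma))
  }
  wtxt <- switch(w$kind,
    identity = "w(p) = p",
    prelec = sprintf("w(p) = exp(-%g(-log p)^%g)", w$alpha, w$delta),
    kt1992 = sprintf("w(p) = p^%g/(p^%g+(1-p)^%g)^(1/%g)",
                     w$gamma_w, w$gamma_w, w$gamma_w, w$gamma_w))
  cat("  weighting:", wtxt, "\n")
  cat("  reference point b =", x$reference_point, "\n")
  invisible(x)
}

#' Reference-dependent utility
#'
#' Evaluates the utility of an offset from the reference point.
#'
#' @param x Numeric vector of offsets `r - b` (outcome units).
#' @param spec A [utility_spec()].
#' @return Numeric vector: `x^gamma` where `x >= 0`,
#'   `-lambda * |x|^gamma` where `x < 0` (identity kind returns `x`).
#' @export
utility <- function(x, spec = utility_spec()) {
  stopifnot(inherits(spec, "utility_spec"), is.numeric(x))
  if (any(!is.finite(x))) stop("non-finite utility argument")
  if (spec$kind == "identity") return(as.numeric(x))
  out <- abs(x)^spec$gamma
  neg <- x < 0
  out[neg] <- -spec$lambda * out[neg]
  out
}

#' Probability weighting
#'
#' Applies the probability weighting function to (cumulative) probabilities.
#' `w(0) = 0` is taken by continuity for the Prelec form, which is otherwise
#' undefined at zero.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @param spec A [weighting_spec()].
#' @return Numeric vector of distorted probabilities in `[0, 1]`.
#' @export
prob_weight <- function(p, spec = weighting_spec()) {
  stopifnot(inherits(spec, "weighting_spec"), is.numeric(p))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  switch(spec$kind,
    identity = as.numeric(p),
    prelec = {
      out <- numeric(length(p))
      pos <- p > 0
      out[pos] <- exp(-spec$alpha * (-log(p[pos]))^spec$delta)
      out
    },
    kt1992 = {
      g <- spec$gamma_w
      pg <- p^g
      qg <- (1 - p)^g
      pg / (pg + qg)^(1 / g)
    })
}
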