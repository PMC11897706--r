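# User-visible handles on the DP's piecewise objective ("envelope").  These
# wrap the same compiled primitives the segmentation loop runs, so grid-oracle
# tests of these operations exercise the production code path.

#' Create an empty objective envelope
#'
#' An envelope represents the forward-pass objective as an ordered list of
#' pieces, each `a * g1(theta) + b * theta + c` on an interval of the natural
#' parameter; pieces tile the domain.  A new envelope is identically zero.
#'
#' @param family loss family; fixes `g1` (theta^2, exp, or log(1+exp)).
#' @param domain length-2 numeric; defaults to the clamped natural-parameter
#'   range for poisson/binomial and must be supplied for gaussian.
#' @return An object of class `envelope`.
#' @export
envelope_new <- function(family = c("gaussian", "poisson", "binomial"),
                         domain = NULL) {
  family <- match.arg(family)
  if (is.null(domain)) {
    if (family == "gaussian")
      stop("supply a finite 'domain' for the gaussian family")
    domain <- c(-THETA_CLAMP, THETA_CLAMP)
  }
  stopifnot(length(domain) == 2, domain[1] < domain[2])
  structure(list(pieces = env_new_cpp(domain[1], domain[2]), family = family),
            class = "envelope")
}

#' Add one datum's loss to an envelope
#'
#' Coefficient-wise addition: every piece's `(a, b, c)` is shifted by the
#' datum's triple; piece intervals are unchanged, so the result equals the old
#' envelope plus the datum loss pointwise.
#'
#' @param env an [envelope_new()] object.
#' @param y observed value (gaussian/poisson) or methylated count (binomial).
#' @param w non-negative weight.
#' @param total total count (binomial only).
#' @return The updated envelope.
#' @export
envelope_add_datum <- function(env, y, w = 1, total = NULL) {
  stopifnot(inherits(env, "envelope"))
  if (env$family == "binomial") {
    if (is.null(total)) stop("binomial datum needs 'total'")
    da <- w * total; db <- -w * y; dc <- 0
  } else if (env$family == "poisson") {
    da <- w; db <- -w * y; dc <- 0
  } else {
    da <- w / 2; db <- -w * y; dc <- w * y^2 / 2
  }
  env$pieces <- env_add_datum_cpp(env$pieces, da, db, dc)
  env
}

#' Apply the L0 restart step to an envelope
#'
#' Replaces the envelope by the pointwise minimum of itself and the constant
#' `min(env) + lambda`.  Intervals where the constant branch is strictly
#' better become "restart" pieces (provenance recorded for the backward
#' pass); exact ties keep the continue branch.  Piece boundaries at the
#' crossings are found by closed-form quadratic roots (gaussian) or
#' safeguarded Newton with bisection fallback (poisson/binomial).
#'
#' @param env an envelope.
#' @param lambda non-negative changepoint penalty.
#' @return A list with `envelope` (the updated envelope), `restart_regions`
#'   (two-column matrix of theta intervals where the restart branch is
#'   active), `min` and `argmin` of the input envelope.
#' @export
envelope_l0_step <- function(env, lambda) {
  stopifnot(inherits(env, "envelope"), lambda >= 0)
  cur <- max(env$pieces$tau)
  out <- env_l0_step_cpp(env$pieces, lambda, family_code(env$family), cur + 1L)
  env$pieces <- out$envelope
  list(envelope = env, restart_regions = out$restart_regions,
       min = out$min, argmin = out$argmin)
}

#' Evaluate an envelope on a grid
#' @param env an envelope.
#' @param theta numeric vector of natural-parameter values inside the domain.
#' @return Envelope values at `theta`.
#' @export
envelope_eval <- function(env, theta) {
  stopifnot(inherits(env, "envelope"))
  env_eval_cpp(env$pieces, as.numeric(theta), family_code(env$family))
}

#' Global minimum of an envelope
#' @param env an envelope.
#' @return List with `min`, `argmin` and the provenance tag at the argmin.
#' @export
envelope_min <- function(env) {
  stopifnot(inherits(env, "envelope"))
  env_min_cpp(env$pieces, family_code(env$family))
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope> %s, %d piece(s) on [%g, %g]\n", x$family,
              length(x$pieces$lo), x$pieces$lo[1], rev(x$pieces$hi)[1]))
  invisible(x)
}
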