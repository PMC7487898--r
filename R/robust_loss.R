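# General adaptive robust loss: a single family that interpolates between L2
# (shape alpha = 2), Charbonnier (alpha = 1) and Cauchy (alpha = 0) losses,
# with the shape alpha and scale c trainable through its negative
# log-likelihood, whose normalizer Z(alpha) is computed by quadrature.

.ALPHA_EPS <- 1e-4   # switch-over window around the singular shapes 0 and 2

#' General robust loss
#'
#' `f(x, alpha, c) = (|alpha-2|/alpha) * (((x/c)^2/|alpha-2| + 1)^(alpha/2) - 1)`
#' with the analytic limits `0.5*(x/c)^2` at `alpha = 2` and
#' `log(0.5*(x/c)^2 + 1)` at `alpha = 0`. Nonnegative, zero at `x = 0`,
#' non-decreasing in `|x|`; larger `alpha` penalizes large residuals more.
#'
#' @param x numeric vector of residuals.
#' @param alpha shape parameter (scalar).
#' @param c scale parameter (scalar, > 0).
#' @return numeric vector of losses, same length as `x`.
#' @export
#' @examples
#' general_loss(1, alpha = 1, c = 1)   # sqrt(2) - 1
general_loss <- function(x, alpha, c) {
  stopifnot(length(alpha) == 1, length(c) == 1)
  if (!is.finite(c) || c <= 0) stop("scale c must be > 0")
  u <- (x / c)^2
  if (abs(alpha - 2) < .ALPHA_EPS) return(0.5 * u)
  if (abs(alpha) < .ALPHA_EPS) return(log1p(0.5 * u))
  b <- abs(alpha - 2)
  (b / alpha) * (exp((alpha / 2) * log1p(u / b)) - 1)
}

# partial derivatives of the loss wrt x and c (analytic; valid in all
# branches because g^(alpha/2 - 1) is continuous through the limits)
.general_loss_dx <- function(x, alpha, c) {
  u <- (x / c)^2
  if (abs(alpha - 2) < .ALPHA_EPS) return(x / c^2)
  if (abs(alpha) < .ALPHA_EPS) return((x / c^2) / (0.5 * u + 1))
  b <- abs(alpha - 2)
  (x / c^2) * exp((alpha / 2 - 1) * log1p(u / b))
}

.general_loss_dc <- function(x, alpha, c) {
  -(x / c) * .general_loss_dx(x, alpha, c)
}

# d f / d alpha by a central difference wide enough to straddle the
# switch-over window, so both evaluation points use the generic formula
.general_loss_dalpha <- function(x, alpha, c, h = 5e-4) {
  (general_loss(x, alpha + h, c) - general_loss(x, alpha - h, c)) / (2 * h)
}

# ---- partition function ----------------------------------------------------

.robust_cache <- new.env(parent = emptyenv())

.quadrature_logZ <- function(alpha) {
  val <- stats::integrate(function(x) exp(-general_loss(x, alpha, 1)),
                          -Inf, Inf, rel.tol = 1e-9, abs.tol = 0)$value
  log(val)
}

.logZ_table <- function() {
  if (is.null(.robust_cache$logZ_fun)) {
    grid <- seq(0, 2, length.out = 256)
    logz <- vapply(grid, .quadrature_logZ, numeric(1))
    .robust_cache$logZ_fun <- stats::splinefun(grid, logz, method = "natural")
  }
  .robust_cache$logZ_fun
}

#' Partition function of the robust-loss density
#'
#' `Z(alpha) = integral of exp(-f(x, alpha, 1)) dx`, finite for
#' `alpha in [0, 2]` (heavy-tailed but integrable as `alpha` approaches 0).
#' Closed forms: `Z(2) = sqrt(2*pi)`, `Z(0) = pi*sqrt(2)`.
#'
#' @param alpha shape value(s) in `[0, 2]`.
#' @param method `"interpolate"` (cached 256-point spline of `log Z`, the
#'   training path) or `"quadrature"` (direct adaptive integration).
#' @return numeric vector `Z(alpha)`.
#' @export
partition_Z <- function(alpha, method = c("interpolate", "quadrature")) {
  method <- match.arg(method)
  if (any(!is.finite(alpha)) || any(alpha < 0)) {
    stop("partition function diverges for alpha < 0")
  }
  if (any(alpha > 2)) stop("alpha above 2 is outside the supported range")
  if (method == "quadrature") {
    return(vapply(alpha, function(a) exp(.quadrature_logZ(a)), numeric(1)))
  }
  exp(.logZ_table()(alpha))
}

.dlogZ_dalpha <- function(alpha) .logZ_table()(pmin(pmax(alpha, 0), 2), deriv = 1)

#' Negative log-likelihood under the robust-loss density
#'
#' `-log p(x | alpha, c) = log(c * Z(alpha)) + f(x, alpha, c)`. Minimizing
#' this over the model weights and `(alpha, c)` jointly is the regression
#' training objective; the `log(c*Z(alpha))` term is what stops the optimizer
#' from cheating by making the loss arbitrarily flat.
#'
#' @inheritParams general_loss
#' @return numeric vector of per-residual negative log-likelihoods.
#' @export
robust_nll <- function(x, alpha, c) {
  log(c) + log(partition_Z(alpha)) + general_loss(x, alpha, c)
}

# ---- trainable parameterization -------------------------------------------

.sigmoid <- function(x) 1 / (1 + exp(-x))
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Trainable robust-loss parameters
#'
#' Latent, unconstrained parameterization used during training:
#' `alpha = 1e-3 + (2 - 1e-3) * sigmoid(alpha_latent)` keeps the shape in
#' (0, 2] (bounded away from 0 so the density stays comfortably normalizable)
#' and `c = scale_lo + softplus(scale_latent)` keeps the scale positive and
#' above a floor. Both maps are smooth and monotone. The floor matters when
#' the scale is trained jointly with a flexible model: without it the
#' likelihood can be driven up by shrinking `c` around memorized residuals,
#' flattening the loss for every genuine point; `scale_lo` = 0.05 (on the
#' standardized-residual scale the trainer uses) encodes that labels are not
#' more precise than a few percent of their spread.
#'
#' @param alpha_latent,scale_latent unconstrained reals.
#' @param scale_lo lower bound for the scale `c`.
#' @return object of class `robust_loss_params` with fields `alpha_latent`,
#'   `scale_latent`, `scale_lo`, `alpha`, `c`.
#' @export
#' @examples
#' p <- robust_loss_params(0, 0)   # alpha = 1.0005, c = 0.05 + log(2)
#' p$alpha
robust_loss_params <- function(alpha_latent = 0, scale_latent = 0.541324,
                               scale_lo = 0.05) {
  structure(list(
    alpha_latent = alpha_latent,
    scale_latent = scale_latent,
    scale_lo = scale_lo,
    alpha = .map_alpha(alpha_latent),
    c = .map_scale(scale_latent, scale_lo)
  ), class = "robust_loss_params")
}

.map_alpha <- function(latent) 1e-3 + (2 - 1e-3) * .sigmoid(latent)
.map_scale <- function(latent, lo = 0.05) lo + .softplus(latent)
.map_alpha_grad <- function(latent) {
  s <- .sigmoid(latent); (2 - 1e-3) * s * (1 - s)
}
.map_scale_grad <- function(latent) .sigmoid(latent)

#' @export
print.robust_loss_params <- function(x, ...) {
  cat(sprintf("<robust_loss_params> alpha = %.4f, c = %.4f\n", x$alpha, x$c))
  invisible(x)
}

# Total NLL over a residual vector plus gradients wrt residuals and the two
# latent parameters; the workhorse called by the regression trainer.
.robust_nll_batch <- function(x, params) {
  a <- params$alpha; cc <- params$c
  n <- length(x)
  nll <- sum(log(cc) + log(partition_Z(a)) + general_loss(x, a, cc))
  dx <- .general_loss_dx(x, a, cc)
  dalpha <- n * .dlogZ_dalpha(a) + sum(.general_loss_dalpha(x, a, cc))
  dc <- n / cc + sum(.general_loss_dc(x, a, cc))
  list(value = nll,
       dx = dx,
       dalpha_latent = dalpha * .map_alpha_grad(params$alpha_latent),
       dscale_latent = dc * .map_scale_grad(params$scale_latent))
}
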