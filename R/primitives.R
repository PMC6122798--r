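#' Protected arithmetic primitives for expression trees
#'
#' Symbolic-regression trees must evaluate to a finite log-odds for every
#' finite input, otherwise the censored-data likelihood is undefined and the
#' evolutionary search stalls on degenerate individuals. The primitive set
#' therefore uses *protected* versions of the partial operators:
#'
#' * `gp_div(a, b)` returns 1 wherever `|b| < 1e-9`, otherwise `a / b`;
#' * `gp_log(a)` returns `log(|a|)` with `gp_log(0) = 0`;
#' * `gp_sqrt(a)` returns `sqrt(|a|)`;
#' * `gp_exp(a)` clamps its argument to `[-50, 50]` before exponentiating;
#' * `gp_tan(a)` clamps its output to `[-1e6, 1e6]` (poles of tan);
#' * `gp_mul(a, b)` is multiplication with the product clamped to
#'   `[-1e150, 1e150]` so that chained products inside a depth-limited tree
#'   can never overflow to `Inf` (and hence never produce `NaN` downstream).
#'
#' All are vectorised and recycle like the base operators. `+`, `-`, `sin`
#' and `cos` are used unprotected: given the multiplication clamp and the
#' depth cap, sums cannot reach `Inf` from finite inputs.
#'
#' @param a,b numeric vectors.
#' @return A numeric vector, finite wherever the inputs are finite.
#' @name gp-primitives
#' @examples
#' gp_div(1, 0)      # 1
#' gp_log(0)         # 0
#' gp_exp(1000)      # exp(50)
NULL

#' @rdname gp-primitives
#' @export
gp_div <- function(a, b) {
  out <- a / b
  small <- rep_len(abs(b) < 1e-9, length(out))
  if (any(small)) out[small] <- 1
  clamp_mag(out)
}

#' @rdname gp-primitives
#' @export
gp_mul <- function(a, b) clamp_mag(a * b)

#' @rdname gp-primitives
#' @export
gp_log <- function(a) {
  out <- log(abs(a))
  zero <- rep_len(a == 0, length(out))
  if (any(zero)) out[zero] <- 0
  out
}

#' @rdname gp-primitives
#' @export
gp_sqrt <- function(a) sqrt(abs(a))

#' @rdname gp-primitives
#' @export
gp_exp <- function(a) exp(pmin(pmax(a, -50), 50))

#' @rdname gp-primitives
#' @export
gp_tan <- function(a) pmin(pmax(tan(a), -1e6), 1e6)

# magnitude clamp shared by gp_mul / gp_div; also absorbs an Inf produced
# by the raw product before it can propagate
clamp_mag <- function(x) pmin(pmax(x, -1e150), 1e150)

# internal operator tables -------------------------------------------------

.gp_binary_ops <- c("+", "-", "gp_mul", "gp_div")
.gp_unary_ops  <- c("sin", "cos", "gp_tan", "gp_sqrt", "gp_exp", "gp_log")

# internal name <-> surface (serialised) name
.gp_surface <- c(
  "+" = "+", "-" = "-", "gp_mul" = "*", "gp_div" = "/",
  "sin" = "sin", "cos" = "cos", "gp_tan" = "tan",
  "gp_sqrt" = "sqrt", "gp_exp" = "exp", "gp_log" = "log"
)
.gp_internal <- stats::setNames(names(.gp_surface), .gp_surface)
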