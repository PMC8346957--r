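# Truncated Grunwald-Letnikov weight tables and discrete fractional
# derivatives of sampled signals.

.gl_cache <- new.env(parent = emptyenv())

#' Truncated Grunwald-Letnikov weights
#'
#' Computes the binomial weights \eqn{w_k = (-1)^k \binom{\nu}{k}} of the
#' truncated Grunwald-Letnikov fractional derivative of order \eqn{\nu},
#' for \eqn{k = 0, \dots, N}. The weights are generated by the
#' multiplicative recurrence
#' \deqn{w_0 = 1, \qquad w_k = w_{k-1}\left(1 - \frac{\nu + 1}{k}\right),}
#' which is exact where the Gamma-function closed form is defined and, unlike
#' direct Gamma evaluation, has no poles at integer order (where the weight
#' sequence truncates to the ordinary finite-difference stencil).
#'
#' Weight tables are memoised per `(order, n_terms)` pair, since a time-domain
#' simulation reuses one table at every step.
#'
#' @param order Fractional order \eqn{\nu \ge 0} (finite real). Integer orders
#'   reproduce ordinary finite-difference coefficients.
#' @param n_terms Truncation length \eqn{N \ge 0}; `n_terms + 1` weights are
#'   returned.
#' @return An object of class `gl_weights`: a list with elements `order`,
#'   `n_terms` and the numeric vector `weights` (`w_0` first).
#' @examples
#' gl_weights(0.5, 4)$weights  # 1, -0.5, -0.125, -0.0625, -0.0390625
#' gl_weights(1, 3)$weights    # 1, -1, 0, 0
#' @export
gl_weights <- function(order, n_terms) {
  if (!is.numeric(order) || length(order) != 1L || !is.finite(order))
    stop("`order` must be a single finite number", call. = FALSE)
  if (!is.numeric(n_terms) || length(n_terms) != 1L || is.na(n_terms) ||
      n_terms < 0 || n_terms != floor(n_terms))
    stop("`n_terms` must be a single non-negative integer", call. = FALSE)
  if (order < 0)
    stop("negative `order` is not supported", call. = FALSE)
  n_terms <- as.integer(n_terms)

  key <- paste(format(order, digits = 17), n_terms, sep = "|")
  hit <- .gl_cache[[key]]
  if (!is.null(hit)) return(hit)

  w <- numeric(n_terms + 1L)
  w[1L] <- 1
  if (n_terms >= 1L) {
    for (k in seq_len(n_terms)) {
      w[k + 1L] <- w[k] * (1 - (order + 1) / k)
    }
  }
  out <- structure(
    list(order = order, n_terms = n_terms, weights = w),
    class = "gl_weights"
  )
  .gl_cache[[key]] <- out
  out
}

#' @export
print.gl_weights <- function(x, ...) {
  cat(sprintf("Grunwald-Letnikov weights: order %g, N = %d\n",
              x$order, x$n_terms))
  print(utils::head(x$weights, 8L))
  if (x$n_terms + 1L > 8L) cat(sprintf("... (%d weights total)\n",
                                       x$n_terms + 1L))
  invisible(x)
}

#' Sampled signal container
#'
#' Bundles a uniformly sampled (real or complex) signal, newest sample last,
#' with its time step. Histories shorter than the weight table are treated as
#' zero before recording started (signal at rest), matching how a time-domain
#' simulation initialises its polarization history.
#'
#' @param values Numeric or complex vector, oldest first, newest last.
#' @param dt Positive finite time step.
#' @return An object of class `sampled_signal`.
#' @export
sampled_signal <- function(values, dt) {
  if (length(values) < 1L)
    stop("signal must contain at least one sample", call. = FALSE)
  if (!is.numeric(values) && !is.complex(values))
    stop("signal values must be numeric or complex", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single finite positive number", call. = FALSE)
  structure(list(values = values, dt = dt), class = "sampled_signal")
}

#' Discrete fractional derivative at the newest sample
#'
#' Evaluates the left-sided truncated Grunwald-Letnikov derivative
#' \deqn{D^\nu f(t) \approx \frac{1}{\Delta t^\nu} \sum_{k=0}^{N} w_k\,
#'   f(t - k\Delta t)}
#' at the newest sample of `signal`. Only past samples enter the sum, so the
#' operator is causal; samples before the start of the record are taken as
#' zero.
#'
#' @param signal A [sampled_signal()], or a plain numeric/complex vector (in
#'   which case `dt` must be given).
#' @param order Fractional order; must match `weights$order` when a weight
#'   table is supplied.
#' @param weights Optional [gl_weights()] table; computed (and cached) from
#'   `order` and `n_terms` when missing.
#' @param n_terms Truncation length used when `weights` is missing; defaults
#'   to the full available history.
#' @param dt Time step, required when `signal` is a bare vector.
#' @return A single real or complex number.
#' @examples
#' gl_derivative(sampled_signal(c(0, 0.1, 0.2, 0.3), dt = 0.1), order = 1)
#' @export
gl_derivative <- function(signal, order, weights = NULL, n_terms = NULL,
                          dt = NULL) {
  if (!inherits(signal, "sampled_signal")) {
    if (is.null(dt))
      stop("`dt` is required when `signal` is not a sampled_signal",
           call. = FALSE)
    signal <- sampled_signal(signal, dt)
  }
  x <- signal$values
  if (is.null(weights)) {
    if (is.null(n_terms)) n_terms <- length(x) - 1L
    weights <- gl_weights(order, n_terms)
  }
  if (!isTRUE(all.equal(weights$order, order)))
    stop("`weights$order` does not match `order`", call. = FALSE)

  n <- length(x)
  N <- weights$n_terms
  k_max <- min(N, n - 1L)                      # older samples are zero
  w <- weights$weights[seq_len(k_max + 1L)]
  # newest sample last: f(t - k dt) = x[n - k]
  past <- x[seq.int(n, n - k_max)]
  sum(w * past) / signal$dt^order
}
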