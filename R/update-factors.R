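# Scalar building blocks of the supervised update rules: range scaling, the
# damping factors of the two modified CPANN algorithms, and the fused
# similarity / adaptive weighting factor of the X-Y fused network.

#' Range scaling to \[0, 1\]
#'
#' `(value - min) / (max - min)`, clamped to \[0, 1\].  When all reference
#' values are equal (`min == max`) the scaled value is defined as 1.
#'
#' @param value Numeric value(s) to scale.
#' @param min,max Range bounds with `min <= max`.
#' @return Scaled value(s) in \[0, 1\].
#' @export
range_scale <- function(value, min, max) {
  if (any(min > max)) abort("`min` must not exceed `max`.")
  n <- max(length(value), length(min), length(max))
  value <- rep_len(value, n)
  mn <- rep_len(min, n)
  mx <- rep_len(max, n)
  out <- ifelse(mx > mn, (value - mn) / (mx - mn), 1)
  pmin(pmax(out, 0), 1)
}

#' Damping factor of the first modified CPANN update
#'
#' `m = 1 - (1 - p) * |scaled_o - scaled_w|`.  At the start of training
#' (`p = 1`) the factor is 1 and the update reduces to the plain CPANN rule;
#' as `p` anneals toward 0 the correction is damped in proportion to the
#' disagreement between the range-scaled object value and the range-scaled
#' weight.  Always in \[0, 1\] for arguments in \[0, 1\].
#'
#' @param scaled_o Range-scaled object value in \[0, 1\].
#' @param scaled_w Range-scaled weight value in \[0, 1\].
#' @param p Annealing parameter in \[0, 1\] (1 at the first epoch, 0 at the last).
#' @return Factor(s) in \[0, 1\].
#' @examples
#' m_factor_v1(0.9, 0.5, p = 0.5) # 0.8
#' @export
m_factor_v1 <- function(scaled_o, scaled_w, p) {
  for (nm in c("scaled_o", "scaled_w", "p")) {
    v <- get(nm)
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
      abort(sprintf("`%s` must lie in [0, 1].", nm))
    }
  }
  1 - (1 - p) * abs(scaled_o - scaled_w)
}

#' Damping factor of the second modified CPANN update
#'
#' The product of the [m_factor_v1()] factor for the descriptor and the
#' analogous factor for the target (endpoint) variable, giving the endpoint a
#' larger role in the weight correction.  In \[0, 1\] for valid arguments.
#'
#' @inheritParams m_factor_v1
#' @param scaled_o_target,scaled_w_target Range-scaled endpoint value and
#'   endpoint-layer weight, each in \[0, 1\].
#' @return Factor(s) in \[0, 1\].
#' @export
m_factor_v2 <- function(scaled_o, scaled_w, scaled_o_target, scaled_w_target, p) {
  m_factor_v1(scaled_o, scaled_w, p) *
    m_factor_v1(scaled_o_target, scaled_w_target, p)
}

#' Fused dissimilarity of the X-Y fused network
#'
#' Convex combination `alpha * S_x + (1 - alpha) * S_y` of the normalized
#' descriptor-map and output-map dissimilarities (0 = perfect match; both are
#' normalized Euclidean distances, `ED / sqrt(n)`).  During X-Y fused training
#' the winner is the neuron minimizing this value.
#'
#' @param s_x Normalized descriptor-map dissimilarity in \[0, 1\].
#' @param s_y Normalized output-map dissimilarity in \[0, 1\].
#' @param alpha Mixing weight in \[0, 1\] (1 = descriptor-only).
#' @return Fused dissimilarity in \[0, 1\].
#' @export
fused_similarity <- function(s_x, s_y, alpha) {
  for (nm in c("s_x", "s_y", "alpha")) {
    v <- get(nm)
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
      abort(sprintf("`%s` must lie in [0, 1].", nm))
    }
  }
  alpha * s_x + (1 - alpha) * s_y
}

#' Adaptive-learning weighting factor of the X-Y fused network
#'
#' `F = 2 - (alpha * S_x + (1 - alpha) * S_y)`.  Because the dissimilarities
#' are normalized, `F` is 2 for a perfectly matched object (doubling the
#' weight correction) and 1 for an object with no match.
#'
#' @inheritParams fused_similarity
#' @return Weighting factor in \[1, 2\].
#' @examples
#' adaptive_weighting_factor(0, 0, 0.5) # perfect match: 2
#' adaptive_weighting_factor(1, 1, 0.5) # no match: 1
#' @export
adaptive_weighting_factor <- function(s_x, s_y, alpha) {
  2 - fused_similarity(s_x, s_y, alpha)
}
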