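#' @include AllClasses.R utils.R
NULL

#' Map unconstrained weights onto a synaptic constraint surface
#'
#' The constrained training modes keep an unconstrained parameter matrix
#' `A_tilde` and expose the actual synaptic weights through a
#' reparameterization `a = g(A_tilde)`:
#' \itemize{
#'   \item `homeo_input`: `a_ij = phi * at_ij / sum_k |at_ik|` — every
#'     projection's incoming absolute weight sums to exactly `phi`.
#'   \item `homeo_output`: the column analogue — every input neuron's
#'     outgoing absolute weight sums to `phi`.
#'   \item `homeo_circuit`: `a = phi * A_tilde / sum_ij |at_ij|` — the whole
#'     circuit's absolute weight equals `phi`.
#'   \item `bounded`: `a_ij = min(max(at_ij, -omega), omega)`.
#'   \item `none`: identity.
#' }
#' Masked-out entries stay exactly zero. A zero row/column/total absolute
#' norm under a homeostatic kind is degenerate (the constraint surface is
#' unreachable) and raises an error.
#'
#' @param A_tilde unconstrained weight matrix (`nProj x nNeurons`).
#' @param mask binary matrix of existing synapses.
#' @param constraint a [ConstraintSpec-class].
#' @return Weight matrix on the constraint surface.
#' @examples
#' applyConstraint(matrix(c(2, -2, 0), 1), matrix(c(1, 1, 0), 1),
#'                 ConstraintSpec("homeo_input", phi = 2))  # (1, -1, 0)
#' @export
applyConstraint <- function(A_tilde, mask, constraint) {
  A <- A_tilde * mask
  switch(constraint@kind,
    none = A,
    bounded = pmin(pmax(A, -constraint@omega), constraint@omega),
    homeo_input = {
      s <- rowSums(abs(A))
      if (any(s == 0))
        stop("degenerate projection: zero incoming absolute weight, cannot normalize")
      A * (constraint@phi / s)
    },
    homeo_output = {
      s <- colSums(abs(A))
      if (any(s == 0))
        stop("degenerate input neuron: zero outgoing absolute weight, cannot normalize")
      sweep(A, 2L, constraint@phi / s, "*")
    },
    homeo_circuit = {
      s <- sum(abs(A))
      if (s == 0) stop("degenerate circuit: zero total absolute weight")
      A * (constraint@phi / s)
    })
}

## Chain rule through the reparameterization: given gradA = dLL/da evaluated
## at a = applyConstraint(A_tilde), return dLL/dA_tilde. The subgradient of
## |.| at 0 is taken as 0. For `bounded` the training loop does projected
## gradient (clip after each step), so inside the box the chain rule is the
## identity; `none` likewise.
constraintChainRule <- function(gradA, A_tilde, mask, constraint) {
  At <- A_tilde * mask
  G <- gradA * mask
  switch(constraint@kind,
    none = G,
    bounded = G,
    homeo_input = {
      s <- rowSums(abs(At))
      inner <- rowSums(G * At)                 # sum_k g_ik at_ik per row
      (constraint@phi / s) * (G - sign(At) * (inner / s)) * mask
    },
    homeo_output = {
      s <- colSums(abs(At))
      inner <- colSums(G * At)
      corr <- sign(At) * matrix(inner / s, nrow(G), ncol(G), byrow = TRUE)
      sweep(G - corr, 2L, constraint@phi / s, "*") * mask
    },
    homeo_circuit = {
      s <- sum(abs(At))
      inner <- sum(G * At)
      (constraint@phi / s) * (G - sign(At) * (inner / s)) * mask
    })
}
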