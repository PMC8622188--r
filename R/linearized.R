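#' Small-angle stiffness matrix of the chain
#'
#' Linearizes the equations of motion around zero (`sin x -> x`) and returns
#' the 2n x 2n matrix `A` such that the vector of elastic torques is
#' `A %*% phi`, with variables ordered strand-1 sites 1..n then strand-2
#' sites 1..n. Under the default symmetric sign convention `A` is negative
#' definite (all equilibrium-restoring); under `"as_printed"` the strand-2
#' single-base term enters with a positive sign.
#'
#' @param system A [build_system()] result.
#' @param strand2_sign See [chain_rhs()].
#' @return A 2n x 2n numeric matrix (units: N m per rad).
#' @export
stiffness_matrix <- function(system,
                             strand2_sign = c("symmetric", "as_printed")) {
  stopifnot(inherits(system, "chain_system"))
  s2 <- sign_factor(strand2_sign)
  n <- system$n
  A <- matrix(0, 2 * n, 2 * n)
  backbone <- function(K) {
    B <- matrix(0, n, n)
    for (i in seq_len(n)) {
      if (i == 1L) {
        B[1, 1] <- -K[1]; B[1, 2] <- K[1]
      } else if (i == n) {
        B[n, n] <- -K[n]; B[n, n - 1] <- K[n]
      } else {
        B[i, i - 1] <- K[i]; B[i, i] <- -2 * K[i]; B[i, i + 1] <- K[i]
      }
    }
    B
  }
  i1 <- seq_len(n); i2 <- n + i1
  A[i1, i1] <- backbone(system$K1)
  A[i2, i2] <- backbone(system$K2)
  Rsum <- system$R1 + system$R2
  cross <- system$k12 * system$R1 * system$R2
  diag(A)[i1] <- diag(A)[i1] - system$k12 * system$R1 * Rsum - cross
  diag(A)[i2] <- diag(A)[i2] + s2 * system$k12 * system$R2 * Rsum - cross
  A[cbind(i1, i2)] <- A[cbind(i1, i2)] + cross
  A[cbind(i2, i1)] <- A[cbind(i2, i1)] + cross
  A
}

#' Static deflection under a constant torque
#'
#' Solves the linear static problem obtained from the equations of motion by
#' dropping all time derivatives and replacing `sin x` with `x`:
#' `A %*% phi + M = 0`, where `M` holds the constant torque on targeted
#' pendulums. This is the profile the damped dynamics relax to under a
#' constant drive, as long as deflections stay in the small-angle regime.
#'
#' @param system A [build_system()] result.
#' @param forcing A [forcing_spec()] in `"constant"` (or `"zero"`) mode.
#' @param strand2_sign See [chain_rhs()].
#' @return A 2 x n matrix of deflection angles (rad), row j = strand j.
#' @export
#' @examples
#' sys <- build_system(strrep("A", 10))
#' linearized_steady_state(sys, forcing_spec("constant", M0 = 1e-22))
linearized_steady_state <- function(system,
                                    forcing = forcing_spec("constant",
                                                           M0 = 1e-22),
                                    strand2_sign = c("symmetric",
                                                     "as_printed")) {
  stopifnot(inherits(system, "chain_system"), inherits(forcing, "forcing_spec"))
  if (!forcing$mode %in% c("constant", "zero"))
    stop("a static deflection is defined only for constant (or zero) forcing",
         call. = FALSE)
  n <- system$n
  A <- stiffness_matrix(system, strand2_sign)
  mask <- target_mask(forcing, n)
  M <- if (forcing$mode == "zero") numeric(2 * n) else
    forcing$M0 * c(mask[1, ], mask[2, ])
  sol <- tryCatch(solve(A, -M), error = function(e)
    stop("singular stiffness matrix: the linearized static system is not ",
         "invertible for these coefficients (", conditionMessage(e), ")",
         call. = FALSE))
  rbind(strand1 = sol[seq_len(n)], strand2 = sol[n + seq_len(n)])
}
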