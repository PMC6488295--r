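#' Model parameter bundles
#'
#' Constructors for the parameter sets of the learning models. All
#' retention factors must lie in (0, 1); update sizes must lie in
#' (0, `e`), where `e` is the clamp size the parameters will be used with
#' (`Inf` when unknown at construction time).
#'
#' @param A,U retention factor and per-trial update (degrees) of the
#'   state-space adaptation process.
#' @param e clamp size bound for update parameters (degrees).
#' @return a named list with class `clamp_params`.
#' @name model_params
NULL

#' @rdname model_params
#' @export
state_space_params <- function(A, U, e = Inf) {
  check_number(A, "A", 0, 1)
  check_number(U, "U", 0, e)
  structure(list(A = A, U = U),
            class = c("state_space_params", "clamp_params"))
}

#' @rdname model_params
#' @param A_prime retention factor of the reinforcement weights.
#' @param s reinforcement increment added to the weight of the reinforced
#'   direction unit on each hit trial.
#' @export
reinforcement_params <- function(A_prime, s) {
  check_number(A_prime, "A_prime", 0, 1)
  check_number(s, "s", 0, Inf)
  structure(list(A_prime = A_prime, s = s),
            class = c("reinforcement_params", "clamp_params"))
}

#' @rdname model_params
#' @param gamma_A,gamma_u strictly positive gains applied to retention and
#'   update on hit trials (1 on miss trials by construction).
#' @export
modulation_params <- function(A, U, gamma_A, gamma_u, e = Inf) {
  check_number(A, "A", 0, 1)
  check_number(U, "U", 0, e)
  check_number(gamma_A, "gamma_A", 0, Inf)
  check_number(gamma_u, "gamma_u", 0, Inf)
  structure(list(A = A, U = U, gamma_A = gamma_A, gamma_u = gamma_u),
            class = c("modulation_params", "clamp_params"))
}

#' @rdname model_params
#' @param A_spe,U_spe retention/update of the process driven by sensory
#'   prediction error (updates on every clamp trial).
#' @param A_te,U_te retention/update of the process driven by target error
#'   (updates only on miss/straddle clamp trials).
#' @export
dual_error_params <- function(A_spe, U_spe, A_te, U_te, e = Inf) {
  check_number(A_spe, "A_spe", 0, 1)
  check_number(U_spe, "U_spe", 0, e)
  check_number(A_te, "A_te", 0, 1)
  check_number(U_te, "U_te", 0, e)
  structure(list(A_spe = A_spe, U_spe = U_spe, A_te = A_te, U_te = U_te),
            class = c("dual_error_params", "clamp_params"))
}
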