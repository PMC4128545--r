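#' Instantaneous derivatives of the delayed-lysis model
#'
#' Evaluates the right-hand side of the seven-equation chemostat model at
#' one time point. Lysis is a delayed event: a cell infected at time
#' \eqn{t - L} bursts at time \eqn{t} if it survived washout, so burst and
#' enzyme-production terms pair the phage and free-bacteria densities of
#' `delayed` (the state `L` minutes in the past) with the washout survival
#' factor \eqn{e^{-wL}}:
#' \deqn{\dot B = v(1-(B+R)/C)B - kP_GB - kP_WB - wB + h(E)R}
#' \deqn{\dot R = v(1-(B+R)/C)R - h(E)R}
#' \deqn{\dot P_G = b_G k P_{GL} B_L e^{-wL} - kP_G(B+I_G+I_W) - wP_G}
#' \deqn{\dot P_W = b_W k P_{WL} B_L e^{-wL} - kP_W(B+I_G+I_W) - wP_W}
#' \deqn{\dot I_G = -k P_{GL} B_L e^{-wL} + kP_GB - wI_G}
#' \deqn{\dot I_W = -k P_{WL} B_L e^{-wL} + kP_WB - wI_W}
#' \deqn{\dot E = Z k P_{GL} B_L e^{-wL} - wE}
#' where the `L` subscript marks delayed values and \eqn{h(E)} is
#' [release_rate()]. Logistic growth applies to the total bacterial density
#' `B + R`; refuge bacteria are not washed out (they are surface-attached)
#' and are lost only by release into the free state. Phages adsorb to free
#' and already-infected cells alike, but only adsorption to free cells
#' founds new infections.
#'
#' @param current State vector ([state_vector()]) at time t.
#' @param delayed State vector at time t - L.
#' @param params A [model_params()] object.
#' @return Named numeric vector of the seven rates (per mL per minute).
#' @examples
#' p <- model_params()
#' s <- state_vector(B = 2.5e9)         # phage-free equilibrium C(1 - w/v)
#' derivative_field(s, s, p)[["B"]]     # ~ 0
#' @export
derivative_field <- function(current, delayed, params) {
  stopifnot(inherits(params, "phage_model_params"))
  validate_state(current, "current")
  validate_state(delayed, "delayed")
  cu <- as.list(current)
  de <- as.list(delayed)
  h <- release_rate(cu$E, params)
  surv <- exp(-params$w * params$L)
  growth <- params$v * (1 - (cu$B + cu$R) / params$C)
  burst_G <- params$k * de$P_G * de$B * surv
  burst_W <- params$k * de$P_W * de$B * surv
  sink <- cu$B + cu$I_G + cu$I_W
  d <- c(
    B   = growth * cu$B - params$k * cu$P_G * cu$B -
          params$k * cu$P_W * cu$B - params$w * cu$B + h * cu$R,
    R   = growth * cu$R - h * cu$R,
    P_G = params$b_G * burst_G - params$k * cu$P_G * sink - params$w * cu$P_G,
    P_W = params$b_W * burst_W - params$k * cu$P_W * sink - params$w * cu$P_W,
    I_G = -burst_G + params$k * cu$P_G * cu$B - params$w * cu$I_G,
    I_W = -burst_W + params$k * cu$P_W * cu$B - params$w * cu$I_W,
    E   = params$Z * burst_G - params$w * cu$E
  )
  if (any(!is.finite(d))) stop("non-finite derivative")
  d
}
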