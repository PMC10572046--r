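#' Classify a virtual patient into H/D/F/R subtypes
#'
#' Subtypes summarize the comorbidity phase portrait implied by a virtual
#' patient's parameters:
#' \describe{
#'   \item{H (healthy)}{a safe immune response for *both* diseases; any
#'     initiated disease is eradicated immediately.}
#'   \item{R (risk)}{two interior stable comorbidity states (bistable); the
#'     patient sits in the dormant state but a perturbation across the
#'     separatrix triggers escape to the fatal state.}
#'   \item{D (dormant)}{a single interior stable state of low burden.}
#'   \item{F (fatal)}{a single interior stable state of high burden.}
#' }
#' The D/F boundary for monostable patients uses the total burden
#' `X + Y < burden_threshold` at the unique interior stable state.
#'
#' @param params A [ric_params] object.
#' @param burden_threshold Total-burden cutoff separating D from F
#'   (default 1).
#' @param states Optional precomputed [find_steady_states()] result for
#'   `cluster_params(params)`.
#' @return A one-character factor with levels `H`, `D`, `F`, `R`.
#' @export
classify_subtype <- function(params, burden_threshold = 1, states = NULL) {
  stopifnot(inherits(params, "ric_params"))
  lv <- c("H", "D", "F", "R")
  if (is_safe_immune(params, "both")) return(factor("H", levels = lv))
  if (is.null(states)) states <- find_steady_states(cluster_params(params))
  int <- dplyr::filter(states, .data$role %in% c("dormant", "fatal"),
                       .data$stability == "stable")
  if (nrow(int) >= 2) return(factor("R", levels = lv))
  if (nrow(int) == 1 && int$X + int$Y < burden_threshold) {
    return(factor("D", levels = lv))
  }
  factor("F", levels = lv)
}
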