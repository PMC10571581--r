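# Utility model U(D) = TCP(D) * (1 - NTCP(D)): probability of risk-free
# local control (RFLC), optimal-dose search.

#' Utility curve from TCP and NTCP vectors
#'
#' The utility of a treatment at dose D is the probability of risk-free local
#' control, `U(D) = TCP(D) * (1 - NTCP(D))`. The predicted optimal dose is
#' the grid dose maximising U, with ties broken toward the lower dose (less
#' irradiation).
#'
#' @param tcp,ntcp Probability vectors on `grid`.
#' @param grid Dose grid in Gy.
#' @return An object of class `utility_curve`: `dose_grid`, `tcp`, `ntcp`,
#'   `utility`, `optimal_dose`, `rflc_at_optimum`.
#' @examples
#' u <- utility_curve(c(0.8, 0.9), c(0.1, 0.3), c(80, 90))
#' u$optimal_dose   # 80: U = 0.72 beats 0.63
#' @export
utility_curve <- function(tcp, ntcp, grid) {
  if (length(tcp) != length(ntcp) || length(tcp) != length(grid))
    stop("utility_curve: tcp, ntcp and grid must have equal length",
         call. = FALSE)
  if (any(tcp < 0 | tcp > 1) || any(ntcp < 0 | ntcp > 1))
    stop("utility_curve: probabilities must lie in [0, 1]", call. = FALSE)
  u <- tcp * (1 - ntcp)
  i <- which.max(u)   # which.max returns the first (lowest-dose) maximum
  structure(list(dose_grid = grid, tcp = tcp, ntcp = ntcp, utility = u,
                 optimal_dose = grid[i], rflc_at_optimum = u[i]),
            class = "utility_curve")
}

#' @export
print.utility_curve <- function(x, ...) {
  cat(sprintf("<utility_curve> optimal dose %.1f Gy, RFLC %.1f%% (grid %g-%g Gy)\n",
              x$optimal_dose, 100 * x$rflc_at_optimum,
              min(x$dose_grid), max(x$dose_grid)))
  invisible(x)
}

#' Reference utility of a TCP curve against the reference NTCP
#'
#' Evaluates U(D) for a named reference TCP curve against the reference NTCP
#' curve on a fine grid over the range of clinical interest (default 0.5 Gy
#' steps over 70-100 Gy total EQD2), without IDV uncertainty.
#'
#' @param tcp_name `"TCP1"`, `"TCP2A"`, `"TCP2B"` or `"TCP2C"`.
#' @param grid Dose grid in Gy EQD2.
#' @param registry Curve registry, default [reference_registry()].
#' @return A [utility_curve()].
#' @examples
#' reference_utility("TCP2A")$optimal_dose   # 80 Gy
#' @export
reference_utility <- function(tcp_name, grid = seq(70, 100, by = 0.5),
                              registry = reference_registry()) {
  if (!tcp_name %in% names(registry))
    stop("reference_utility: unknown curve '", tcp_name, "'", call. = FALSE)
  tcp <- response(grid, registry[[tcp_name]])
  ntcp <- response(grid, registry[["NTCP_ref"]])
  utility_curve(tcp, ntcp, grid)
}

#' Utility of convolved dose-response curves
#'
#' Utility of a convolved (R') TCP curve against the combined convolved OAR
#' NTCP curve (see [combined_oar_curve()]), on their common grid.
#'
#' @param tcp_rprime Convolved TCP probabilities on `grid`.
#' @param oar_rprime Combined convolved OAR NTCP probabilities on `grid`.
#' @param grid Common dose grid in Gy.
#' @return A [utility_curve()].
#' @export
convolved_utility <- function(tcp_rprime, oar_rprime, grid) {
  utility_curve(tcp_rprime, oar_rprime, grid)
}
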