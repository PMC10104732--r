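#' Tidy the threshold-scan objective curve
#'
#' @param x A `threshold_result` from [optimal_threshold()].
#' @param ... Unused.
#' @return Tibble with one row per scanned threshold: `t`, `G`, `optimal`.
#' @export
tidy.threshold_result <- function(x, ...) {
  dplyr::mutate(x$curve, optimal = .data$t == x$t_star)
}

#' One-row summary of a threshold result
#'
#' @inheritParams tidy.threshold_result
#' @return Tibble: `t_star`, `G_star`, class means and counts, overall mean.
#' @export
glance.threshold_result <- function(x, ...) {
  tibble(
    t_star = x$t_star, G_star = x$G_star,
    a1 = x$a1, a2 = x$a2, M1 = x$M1, M2 = x$M2, abar = x$abar
  )
}

#' Tidy a flow solution into its station table
#'
#' @param x A `flow_solution` from [solve_steady_flow()].
#' @param ... Unused.
#' @return Tibble of stations: `s`, `r`, `area`, `pressure_pa`,
#'   `pressure_mmhg`, `velocity`.
#' @export
tidy.flow_solution <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "flow_solution")
  as_tibble(out)
}

#' One-row summary of a flow solution
#'
#' @inheritParams tidy.flow_solution
#' @return Tibble: `q_ml_s`, `dp_pa`, `dp_mmhg`, inlet/outlet pressures
#'   (mmHg) and the pressure ratio outlet/inlet.
#' @export
glance.flow_solution <- function(x, ...) {
  p_in <- x$pressure_mmhg[1]
  p_out <- x$pressure_mmhg[nrow(x)]
  tibble(
    q_ml_s = attr(x, "q_ml_s"),
    dp_pa = attr(x, "dp_pa"),
    dp_mmhg = pa_to_mmhg(attr(x, "dp_pa")),
    p_inlet_mmhg = p_in,
    p_outlet_mmhg = p_out,
    pressure_ratio = p_out / p_in
  )
}

#' Tidy an FFR result
#'
#' @param x An `ffr_result` from [compute_ffr()].
#' @param ... Unused.
#' @return One-row tibble: `ffr`, `ps`, `pr`.
#' @export
tidy.ffr_result <- function(x, ...) {
  tibble(ffr = x$ffr, ps = x$ps, pr = x$pr)
}

#' Tidy ROC points
#'
#' @param x A `roc_result` from [roc_auc()].
#' @param ... Unused.
#' @return Tibble of ROC points: `threshold`, `tpr`, `fpr`.
#' @export
tidy.roc_result <- function(x, ...) x$roc

#' One-row ROC summary
#'
#' @inheritParams tidy.roc_result
#' @return Tibble with `auc` and the operating-point count.
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, n_thresholds = nrow(x$roc) - 1L)
}

#' Tidy a mesh report
#'
#' @param x A list from [mesh_report()].
#' @param ... Unused.
#' @return One-row tibble of the report fields.
#' @export
tidy_mesh_report <- function(x, ...) as_tibble(x)
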