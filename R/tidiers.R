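#' Tidy and glance methods
#'
#' broom-style summaries: `tidy()` turns a `flow_series` into a per-time
#' tibble of field extrema and a `hemoflow_case` into its index table;
#' `glance()` gives one-row overviews (convergence diagnostics for a
#' series, headline numbers for a case).
#'
#' @param x The object to summarize.
#' @param ... Unused.
#' @return A tibble.
#' @name hemoflow-tidiers
NULL

#' @rdname hemoflow-tidiers
#' @export
tidy.flow_series <- function(x, ...) {
  mesh <- x$mesh
  purrr::map_dfr(seq_along(x$states), function(k) {
    s <- x$states[[k]]
    tibble::tibble(time_s = x$times[k],
                   v_max = max(speed_cc(s, mesh)[mesh$fluid]),
                   p_max = max(s$p[mesh$fluid]),
                   p_mean = mean(s$p[mesh$fluid]),
                   residual = s$residual)
  })
}

#' @rdname hemoflow-tidiers
#' @export
glance.flow_series <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(n_states = length(x$states), period = x$period,
                 dt = d$dt %||% NA_real_,
                 cycle_drift = d$cycle_drift %||% NA_real_,
                 max_continuity_residual =
                   if (!is.null(d$residuals) && nrow(d$residuals))
                     max(d$residuals$continuity) else NA_real_)
}

#' @rdname hemoflow-tidiers
#' @export
tidy.hemoflow_case <- function(x, ...) {
  tibble::as_tibble(x$indices)
}

#' @rdname hemoflow-tidiers
#' @export
glance.hemoflow_case <- function(x, ...) {
  s <- x$summary
  tibble::tibble(vessel_kind = s$vessel_kind, mode = s$mode,
                 cells = s$cells, wss_max = s$wss_max,
                 tawss_max = s$indices$tawss_max,
                 osi_max = s$indices$osi_max,
                 rrt_max = s$indices$rrt_max,
                 ecap_max = s$indices$ecap_max,
                 mass_imbalance = s$mass_balance$relative_imbalance)
}
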