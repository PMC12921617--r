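## Plain-text interchange formats: lookup-table and shim-state JSON,
## decay / NMRD / transfer / exchange CSV dialects.

#' Lookup-table JSON
#'
#' `{kind, abscissa[], ordinate[], valid_range, metadata}`.
#'
#' @param table A `lookup_table`.
#' @param path File path.
#' @export
write_lookup_table <- function(table, path) {
  stopifnot(inherits(table, "lookup_table"))
  jsonlite::write_json(unclass(table), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lookup_table
#' @export
read_lookup_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_lookup_table(x$kind, x$abscissa, x$ordinate,
                   metadata = as.list(x$metadata))
}

#' Shim-state JSON
#'
#' `{currents_mA[9], ci95_mA[9], alpha, residual_stats}`.
#'
#' @param state A `shim_state` from [optimize_shims()].
#' @param path File path.
#' @export
write_shim_state <- function(state, path) {
  stopifnot(inherits(state, "shim_state"))
  jsonlite::write_json(
    list(currents_mA = state$currents, ci95_mA = state$ci95,
         alpha = state$alpha,
         residual_stats = state$residual_stats[c("mean", "median", "sd",
                                                 "rel_sd", "median_mean_dev")],
         converged = state$converged, ci_reliable = state$ci_reliable),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Decay-trace CSV
#'
#' Long format `field_T,vd_s,signal,signal_err` (signal_err optional).
#'
#' @param traces List of [decay_trace()]s.
#' @param path File path.
#' @export
write_decay_csv <- function(traces, path) {
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(field_T = tr$field, vd_s = tr$delays, signal = tr$signals,
               signal_err = if (is.null(tr$signal_errors)) NA_real_
               else tr$signal_errors)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decay_csv
#' @export
read_decay_csv <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$field_T), function(g) {
    g <- g[order(g$vd_s), ]
    decay_trace(g$field_T[1], g$vd_s, g$signal,
                signal_errors = if (all(is.finite(g$signal_err)))
                  g$signal_err else NULL)
  })
}

#' Transfer-profile CSV (`time_s,field_T`)
#'
#' @param profile A [transfer_profile()].
#' @param path File path.
#' @export
write_transfer_csv <- function(profile, path) {
  utils::write.csv(data.frame(time_s = profile$time_s,
                              field_T = profile$field_T),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transfer_csv
#' @export
read_transfer_csv <- function(path, label = "profile") {
  d <- utils::read.csv(path)
  transfer_profile(d$time_s, d$field_T, label = label)
}

#' Exchange-kinetics CSV (`tau_e_s,series,integral`)
#'
#' @param data An [exchange_dataset()].
#' @param path File path.
#' @export
write_exchange_csv <- function(data, path) {
  rows <- do.call(rbind, lapply(names(data$series), function(nm)
    data.frame(tau_e_s = data$tau_e, series = nm,
               integral = data$series[[nm]])))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_exchange_csv
#' @export
read_exchange_csv <- function(path) {
  d <- utils::read.csv(path)
  tau <- sort(unique(d$tau_e_s))
  series <- lapply(split(d, d$series), function(g) {
    g <- g[order(g$tau_e_s), ]
    if (!isTRUE(all.equal(g$tau_e_s, tau)))
      stop("all series must share the same delay grid")
    g$integral
  })
  exchange_dataset(tau, series)
}
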