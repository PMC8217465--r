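#' Epileptogenic-zone delineation parameters
#'
#' @param coverage fraction of total events the EZ channel set must cover
#'   (default 0.72, the published threshold for the fast-ripple channel
#'   distribution).
#' @param rule `"event_coverage"` (default): minimal top-ranked channel
#'   prefix whose cumulative event count reaches `coverage` of all events;
#'   `"channel_fraction"`: top `coverage` fraction of event-positive
#'   channels.
#' @return A list of class `ez_params`.
#' @export
ez_params <- function(coverage = 0.72,
                      rule = c("event_coverage", "channel_fraction")) {
  if (coverage <= 0 || coverage > 1)
    stop_hfoloc("hfoloc_invalid_argument", "coverage: must be in (0, 1]")
  structure(list(coverage = coverage, rule = match.arg(rule)),
            class = "ez_params")
}

#' Rank channels by HFO rate
#'
#' Stable descending sort; ties keep the input channel order.
#'
#' @param rates named numeric vector of per-channel rates (or counts), or a
#'   data.frame with `channel` and a rate/count column.
#' @return data.frame of class `channel_ranking`: `channel`, `rate`,
#'   `cum_fraction` (cumulative event fraction; 0 throughout if no events).
#' @export
rank_channels <- function(rates) {
  if (is.data.frame(rates)) {
    col <- intersect(c("rate_per_min", "rate", "n_events", "count"), names(rates))[1]
    v <- rates[[col]]
    names(v) <- rates$channel
    rates <- v
  }
  ord <- order(-rates)               # stable: ties keep input order
  out <- data.frame(channel = names(rates)[ord], rate = unname(rates[ord]),
                    stringsAsFactors = FALSE)
  total <- sum(out$rate)
  out$cum_fraction <- if (total > 0) cumsum(out$rate) / total else 0
  class(out) <- c("channel_ranking", class(out))
  out
}

#' Delineate the putative epileptogenic zone
#'
#' Under the default rule, returns the minimal prefix of the descending
#' ranking whose cumulative event count reaches `coverage` of the total;
#' zero-event channels are never included. The alternative reading of the
#' 72% threshold (top 72% of event-positive channels) is available via
#' `ez_params(rule = "channel_fraction")`.
#'
#' @param ranking a [rank_channels()] result.
#' @param params an [ez_params()].
#' @return Character vector of EZ channel labels (empty, with a warning,
#'   when no channel has events).
#' @export
delineate_ez <- function(ranking, params = ez_params()) {
  pos <- ranking[ranking$rate > 0, , drop = FALSE]
  if (nrow(pos) == 0) {
    warning("no events in any channel; EZ is empty")
    return(character(0))
  }
  if (params$rule == "channel_fraction") {
    k <- max(1L, ceiling(params$coverage * nrow(pos)))
    return(pos$channel[seq_len(k)])
  }
  cum <- cumsum(pos$rate) / sum(pos$rate)
  k <- which(cum >= params$coverage - 1e-12)[1]
  pos$channel[seq_len(k)]
}

#' Choose the analysis band with fast-ripple priority
#'
#' Fast-ripple counts are used whenever any retained fast ripple exists;
#' otherwise the ripple results are referred to (the published fallback,
#' e.g. a patient with no detected FR).
#'
#' @param events event table from [detect_hfos()].
#' @param channels channels to report; defaults to the table's `channels`
#'   attribute.
#' @return data.frame `channel`, `n_events` with attribute `band_used`
#'   (`"fast-ripple"`, `"ripple"`, or `NA` with a warning when no retained
#'   events exist).
#' @export
select_band <- function(events, channels = NULL) {
  channels <- channels %||% attr(events, "channels") %||% unique(events$channel)
  kept <- events[!is.na(events$retained) & events$retained, , drop = FALSE]
  if (nrow(kept) == 0) {
    warning("no retained events in any band")
    out <- data.frame(channel = channels, n_events = 0L)
    attr(out, "band_used") <- NA_character_
    return(out)
  }
  band_used <- if (any(kept$band == "fast-ripple")) "fast-ripple" else "ripple"
  sel <- kept[kept$band == band_used, , drop = FALSE]
  out <- data.frame(channel = channels,
                    n_events = vapply(channels, function(ch)
                      sum(sel$channel == ch), 1L),
                    stringsAsFactors = FALSE)
  attr(out, "band_used") <- band_used
  out
}

#' EZ report for one recording
#'
#' Composes band selection, ranking and delineation into the JSON-ready
#' per-recording report.
#'
#' @param events event table from [detect_hfos()].
#' @param params an [ez_params()].
#' @param duration_s analyzed duration (seconds).
#' @return list `band_used`, `coverage`, `ranked_channels` (data.frame with
#'   `label`, `rate`, `cum_fraction`, `in_ez`).
#' @export
ez_report <- function(events, params = ez_params(), duration_s = NULL) {
  duration_s <- duration_s %||% attr(events, "analyzed_duration_s")
  counts <- select_band(events)
  v <- counts$n_events
  names(v) <- counts$channel
  ranking <- rank_channels(v)
  ez <- if (all(v == 0)) character(0) else delineate_ez(ranking, params)
  rate <- if (!is.null(duration_s)) ranking$rate / (duration_s / 60) else ranking$rate
  list(band_used = attr(counts, "band_used"),
       coverage = params$coverage,
       ez_channels = ez,
       ranked_channels = data.frame(label = ranking$channel, rate = rate,
                                    cum_fraction = ranking$cum_fraction,
                                    in_ez = ranking$channel %in% ez,
                                    stringsAsFactors = FALSE))
}
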