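#' Find stall events in a hemodynamic trace
#'
#' A stall is a maximal run of consecutive zero-flux valid windows whose total
#' span reaches `min_gap_s`. A single invalid (motion-artifact) window inside
#' a zero-flux run does not break it — artifacts should not split a genuine
#' stall — but two or more consecutive invalid windows do, which keeps the
#' rule conservative against artifact-driven false events.
#'
#' @param trace A `hemo_trace` (tiled windows assumed for event timing).
#' @param min_gap_s Minimum event span in s (> 0).
#' @return Data frame of class `stall_events`: `start_s`, `end_s`,
#'   `duration_s`, sorted and non-overlapping. May have zero rows.
#' @export
find_stall_events <- function(trace, min_gap_s) {
  stopifnot(inherits(trace, "hemo_trace"), min_gap_s > 0)
  if (!nrow(trace)) stop("trace has no windows")
  if (!any(trace$valid)) stop("all windows are invalid")
  w <- attr(trace, "window_s")
  # states: Z zero-flux valid, F flowing valid, I invalid
  st <- ifelse(!trace$valid, "I", ifelse(trace$flux_cps == 0, "Z", "F"))
  # bridge single invalid windows flanked by Z on both sides
  n <- length(st)
  for (i in seq_len(n)) {
    if (st[i] == "I" &&
        i > 1 && i < n && st[i - 1] == "Z" && st[i + 1] == "Z")
      st[i] <- "Z"
  }
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  zi <- which(r$values == "Z")
  ev <- data.frame(start_s = trace$t_s[starts[zi]] - w / 2,
                   end_s = trace$t_s[ends[zi]] + w / 2)
  ev$duration_s <- ev$end_s - ev$start_s
  ev <- ev[ev$duration_s >= min_gap_s, , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("stall_events", "data.frame")
  ev
}

#' Call the flow status of a vessel
#'
#' A vessel is BLOCKED when a terminal zero-flux run of at least
#' `min_block_s` reaches the end of the trace — the minimum continuous
#' absence of RBC passage required before treating a cessation as a blockage
#' rather than an intermittent stall — and, when a later verification trace
#' is supplied, that verification also shows zero flux throughout. A trace
#' with stall events that is not BLOCKED is INTERMITTENT; otherwise FLOWING.
#'
#' @param trace A `hemo_trace`.
#' @param min_block_s Minimum terminal no-flow duration in s; default 15.
#' @param verify_trace Optional verification `hemo_trace` recorded after the
#'   main trace (up to minutes later). Verification passes when every valid
#'   window shows zero flux.
#' @param min_stall_s Minimum duration for listing intermittent stall events;
#'   default 2.
#' @return List of class `vessel_call`: `status` in
#'   `{"FLOWING","INTERMITTENT","BLOCKED"}`, `events` (stall events),
#'   `confirmed` (TRUE only when a verification trace was supplied and showed
#'   no flow), `terminal_gap_s`.
#' @export
call_vessel <- function(trace, min_block_s = 15, verify_trace = NULL,
                        min_stall_s = 2) {
  stopifnot(inherits(trace, "hemo_trace"))
  events <- find_stall_events(trace, min_stall_s)
  w <- attr(trace, "window_s")
  duration <- attr(trace, "duration_s")

  terminal_gap <- 0
  if (nrow(events)) {
    last <- events[nrow(events), ]
    if (abs(last$end_s - (trace$t_s[nrow(trace)] + w / 2)) < w / 2)
      terminal_gap <- last$duration_s
  }
  candidate <- is.finite(min_block_s) && terminal_gap >= min_block_s

  confirmed <- FALSE
  if (!is.null(verify_trace)) {
    stopifnot(inherits(verify_trace, "hemo_trace"))
    ok <- verify_trace$valid
    if (!any(ok)) stop("verification trace has no valid windows")
    confirmed <- all(verify_trace$flux_cps[ok] == 0)
  }
  blocked <- candidate && (is.null(verify_trace) || confirmed)
  status <- if (blocked) "BLOCKED"
            else if (nrow(events) || candidate) "INTERMITTENT"
            else "FLOWING"
  structure(list(status = status, events = events, confirmed = confirmed,
                 terminal_gap_s = terminal_gap),
            class = "vessel_call")
}

#' Construct a trial outcome record
#'
#' Maps a vessel call plus trial covariates to the categorical trial outcome.
#' BLOCKAGE requires a BLOCKED call confirmed by a verification scan.
#' Hemorrhage is an observational label supplied by the experimenter (dye
#' spill), never inferred from the trace.
#'
#' @param call A `vessel_call`, or NULL when `hemorrhage = TRUE`.
#' @param excitation_s Excitation duration (s).
#' @param depth_um Depth below the pia (µm).
#' @param group Group label.
#' @param hemorrhage Logical; observed hemorrhage overrides the flow call.
#' @return One-row data frame: `group`, `outcome`, `depth_um`, `excitation_s`.
#' @export
trial_outcome <- function(call, excitation_s, depth_um, group,
                          hemorrhage = FALSE) {
  category <- if (hemorrhage) "HEMORRHAGE"
  else {
    stopifnot(inherits(call, "vessel_call"))
    if (call$status == "BLOCKED" && call$confirmed) "BLOCKAGE" else "NONE"
  }
  data.frame(group = group, outcome = category, depth_um = depth_um,
             excitation_s = excitation_s)
}

#' Summarise excitation times of blockage trials by depth
#'
#' Sample mean and SD of the excitation duration among BLOCKAGE trials,
#' binned by depth below the pia. Bins with no blockage are omitted; bins
#' with a single blockage report `sd = NA` (undefined for n = 1).
#'
#' @param outcomes Trial-outcome data frame (`group`, `outcome`, `depth_um`,
#'   `excitation_s`).
#' @param depth_bins Numeric vector of bin edges in µm (left-closed).
#' @return Data frame: `depth_bin`, `n`, `mean_s`, `sd_s`.
#' @export
summarize_excitation_times <- function(outcomes,
                                       depth_bins = c(75, 125, 175, 225)) {
  if (!nrow(outcomes)) stop("empty outcome list")
  bl <- outcomes[outcomes$outcome == "BLOCKAGE", , drop = FALSE]
  bin <- cut(bl$depth_um, depth_bins, right = FALSE)
  keep <- !is.na(bin)
  bl <- bl[keep, , drop = FALSE]; bin <- bin[keep]
  if (!nrow(bl)) {
    return(data.frame(depth_bin = character(0), n = integer(0),
                      mean_s = numeric(0), sd_s = numeric(0)))
  }
  agg <- lapply(split(bl$excitation_s, droplevels(bin)), function(x)
    c(n = length(x), mean_s = mean(x),
      sd_s = if (length(x) > 1) stats::sd(x) else NA_real_))
  out <- data.frame(depth_bin = names(agg),
                    do.call(rbind, agg), row.names = NULL)
  out$n <- as.integer(out$n)
  out
}
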