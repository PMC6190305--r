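#' Run a simulation case
#'
#' Time-integrates a case from rest (domain filled with continuous
#' phase, prescribed spin-up), records field snapshots at the requested
#' cadence, and maintains a droplet event log: pinch-offs (droplet label
#' count increases), merges (labels coalesce; volume is conserved), and
#' outlet exits (a droplet disappears while touching an outlet), each
#' with time, droplet id, position, and outlet.
#'
#' @param case a `vof_case` from [build_case()].
#' @param t_end end time (s); default from the case.
#' @param snapshot_dt snapshot cadence (s); default from the case.
#' @param dx override cell size (m).
#' @param max_steps hard cap on step count.
#' @param stop_when_steady stop early once the velocity field stops
#'   changing (relative change < `steady_tol` between snapshots);
#'   for single-phase steady problems.
#' @param steady_tol relative steadiness tolerance.
#' @param verbose print progress every snapshot.
#' @param body_forces passed to [init_solver()].
#' @return object of class `vof_run`: `snapshots` (list of
#'   `field_state`), `events` (data.frame), `diagnostics` (one row per
#'   step), `droplets` (final registry), `ctx`.
#' @export
run_case <- function(case, t_end = NULL, snapshot_dt = NULL, dx = NULL,
                     max_steps = 500000L, stop_when_steady = FALSE,
                     steady_tol = 1e-4, verbose = FALSE,
                     body_forces = TRUE) {
  stopifnot(inherits(case, "vof_case"))
  if (is.null(t_end)) t_end <- case$run$t_end
  if (is.null(snapshot_dt)) snapshot_dt <- case$run$snapshot_dt %||% t_end
  ctx <- init_solver(case, dx = dx, body_forces = body_forces)
  state <- init_state(ctx)
  two_phase <- any(state$alpha[ctx$mask] < 1) ||
    any(vapply(ctx$inports, function(p) p$phase == "dp", TRUE))
  diags <- vector("list", 2048L); ndiag <- 0L
  snapshots <- list(state)
  next_snap <- snapshot_dt
  tracker <- new_droplet_tracker()
  if (two_phase) tracker <- track_droplets(tracker, state, ctx, 0)
  events <- list()
  prev_u <- state$u; prev_v <- state$v
  nstep <- 0L
  while (state$t < t_end - 1e-15 && nstep < max_steps) {
    res <- step(state, ctx, two_phase = two_phase)
    state <- res$state
    nstep <- nstep + 1L
    ndiag <- ndiag + 1L
    if (ndiag > length(diags)) diags <- c(diags, vector("list", length(diags)))
    diags[[ndiag]] <- res$diag
    if (state$t >= next_snap - 1e-12 || state$t >= t_end - 1e-15) {
      snapshots[[length(snapshots) + 1L]] <- state
      next_snap <- next_snap + snapshot_dt
      if (two_phase) {
        upd <- track_droplets(tracker, state, ctx, state$t)
        tracker <- upd
        if (length(upd$new_events))
          events <- c(events, upd$new_events)
      }
      if (verbose)
        message(sprintf("t = %.4g s (%d steps, %d droplets)",
                        state$t, nstep, nrow(tracker$registry)))
      if (stop_when_steady) {
        du <- max(abs(state$u - prev_u), abs(state$v - prev_v))
        uref <- max(abs(state$u), abs(state$v), 1e-12)
        if (du / uref < steady_tol) break
        prev_u <- state$u; prev_v <- state$v
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(0), event = character(0),
               droplet_id = integer(0), x = numeric(0), y = numeric(0),
               outlet = character(0), volume = numeric(0),
               parents = character(0), stringsAsFactors = FALSE)
  structure(list(case = case, ctx = ctx, snapshots = snapshots,
                 events = ev,
                 diagnostics = do.call(rbind, diags[seq_len(ndiag)]),
                 droplets = tracker$registry, n_steps = nstep),
            class = "vof_run")
}

new_droplet_tracker <- function() {
  list(prev = NULL, prev_time = 0, next_id = 1L,
       registry = data.frame(id = integer(0), birth_time = numeric(0),
                             last_seen = numeric(0), volume = numeric(0),
                             area = numeric(0), x = numeric(0), y = numeric(0),
                             fate = character(0), stringsAsFactors = FALSE),
       new_events = list())
}

# match droplets between consecutive snapshots by cell overlap and emit
# pinch-off / merge / exit events
track_droplets <- function(tracker, state, ctx, time) {
  cur <- label_droplets(state, ctx)
  cells <- attr(cur, "cells")
  tracker$new_events <- list()
  prev <- tracker$prev
  cur_ids <- integer(nrow(cur))
  if (is.null(prev)) {
    for (k in seq_len(nrow(cur))) {
      cur_ids[k] <- tracker$next_id
      tracker$registry <- rbind(tracker$registry, data.frame(
        id = tracker$next_id, birth_time = time, last_seen = time,
        volume = cur$volume[k], area = cur$area[k],
        x = cur$x[k], y = cur$y[k], fate = "in_domain",
        stringsAsFactors = FALSE))
      tracker$new_events[[length(tracker$new_events) + 1L]] <- data.frame(
        time = time, event = "pinch_off", droplet_id = tracker$next_id,
        x = cur$x[k], y = cur$y[k], outlet = NA_character_,
        volume = cur$volume[k], parents = NA_character_,
        stringsAsFactors = FALSE)
      tracker$next_id <- tracker$next_id + 1L
    }
  } else {
    pcells <- attr(prev$set, "cells")
    matched_prev <- rep(FALSE, nrow(prev$set))
    for (k in seq_len(nrow(cur))) {
      ov <- vapply(seq_along(pcells), function(q)
        length(intersect(cells[[k]], pcells[[q]])), 0L)
      hits <- which(ov > 0)
      if (!length(hits)) {                       # new droplet: pinch-off
        cur_ids[k] <- tracker$next_id
        tracker$registry <- rbind(tracker$registry, data.frame(
          id = tracker$next_id, birth_time = time, last_seen = time,
          volume = cur$volume[k], area = cur$area[k],
          x = cur$x[k], y = cur$y[k], fate = "in_domain",
          stringsAsFactors = FALSE))
        tracker$new_events[[length(tracker$new_events) + 1L]] <- data.frame(
          time = time, event = "pinch_off", droplet_id = tracker$next_id,
          x = cur$x[k], y = cur$y[k], outlet = NA_character_,
          volume = cur$volume[k], parents = NA_character_,
          stringsAsFactors = FALSE)
        tracker$next_id <- tracker$next_id + 1L
      } else if (length(hits) == 1L) {           # continuation
        pid <- prev$ids[hits]
        cur_ids[k] <- pid
        matched_prev[hits] <- TRUE
        r <- tracker$registry$id == pid
        tracker$registry$last_seen[r] <- time
        tracker$registry$volume[r] <- cur$volume[k]
        tracker$registry$area[r] <- cur$area[k]
        tracker$registry$x[r] <- cur$x[k]
        tracker$registry$y[r] <- cur$y[k]
      } else {                                   # merge
        pids <- prev$ids[hits]
        matched_prev[hits] <- TRUE
        keep <- min(pids)
        cur_ids[k] <- keep
        for (pid in setdiff(pids, keep)) {
          r <- tracker$registry$id == pid
          tracker$registry$fate[r] <- "merged"
          tracker$registry$last_seen[r] <- time
        }
        r <- tracker$registry$id == keep
        tracker$registry$last_seen[r] <- time
        tracker$registry$volume[r] <- cur$volume[k]
        tracker$registry$area[r] <- cur$area[k]
        tracker$registry$x[r] <- cur$x[k]
        tracker$registry$y[r] <- cur$y[k]
        tracker$new_events[[length(tracker$new_events) + 1L]] <- data.frame(
          time = time, event = "merge", droplet_id = keep,
          x = cur$x[k], y = cur$y[k], outlet = NA_character_,
          volume = cur$volume[k],
          parents = paste(sort(pids), collapse = "+"),
          stringsAsFactors = FALSE)
      }
    }
    # unmatched previous droplets: exited or vanished
    for (q in which(!matched_prev)) {
      pid <- prev$ids[q]
      out <- nearest_outlet(ctx, prev$set$x[q], prev$set$y[q],
                            pcells[[q]])
      r <- tracker$registry$id == pid
      tracker$registry$fate[r] <- if (is.na(out)) "vanished" else
        paste0("outlet_", out)
      tracker$registry$last_seen[r] <- time
      tracker$new_events[[length(tracker$new_events) + 1L]] <- data.frame(
        time = time, event = "exit", droplet_id = pid,
        x = prev$set$x[q], y = prev$set$y[q], outlet = out,
        volume = prev$set$volume[q], parents = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  tracker$prev <- list(set = cur, ids = cur_ids)
  tracker$prev_time <- time
  tracker
}

# outlet id whose faces lie nearest to the droplet (within 4 cells),
# else NA
nearest_outlet <- function(ctx, x, y, cells) {
  faces <- ctx$grid$faces
  of <- faces[faces$tag == "outlet", , drop = FALSE]
  if (!nrow(of)) return(NA_character_)
  d2 <- (of$fx - x)^2 + (of$fy - y)^2
  k <- which.min(d2)
  if (sqrt(d2[k]) > 6 * ctx$dx * max(1, sqrt(length(cells)))) return(NA_character_)
  of$outlet_id[k]
}

#' @export
print.vof_run <- function(x, ...) {
  cat(sprintf("<vof_run> %s: %d steps to t = %.4g s, %d snapshots\n",
              x$case$case_id, x$n_steps,
              x$snapshots[[length(x$snapshots)]]$t, length(x$snapshots)))
  if (nrow(x$events)) {
    tb <- table(x$events$event)
    cat("  events:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.vof_run <- function(object, ...) {
  dg <- object$diagnostics
  cat(sprintf("Run %s: %d steps, final t = %.4g s\n",
              object$case$case_id, object$n_steps, dg$t[nrow(dg)]))
  cat(sprintf("  max |div| over run: %.3g 1/s; last dispersed volume %.4g m^3\n",
              max(dg$div_max), dg$dispersed_volume[nrow(dg)]))
  if (nrow(object$droplets)) {
    cat(sprintf("  droplets tracked: %d; fates: %s\n", nrow(object$droplets),
                paste(names(table(object$droplets$fate)),
                      table(object$droplets$fate), sep = "=", collapse = ", ")))
  }
  invisible(object)
}

#' Plot a field snapshot
#'
#' Image of the dispersed-phase fraction (1 - alpha_CP) on the solid
#' mask, base graphics.
#'
#' @param x a `vof_run`.
#' @param snapshot snapshot index (default: last).
#' @param ... passed to [graphics::image()].
#' @export
plot.vof_run <- function(x, snapshot = length(x$snapshots), ...) {
  st <- x$snapshots[[snapshot]]
  g <- x$ctx$grid
  z <- 1 - st$alpha
  z[!g$mask] <- NA
  graphics::image(x = g$x0 + (seq_len(g$nx) - 0.5) * g$dx,
                  y = g$y0 + (seq_len(g$ny) - 0.5) * g$dx,
                  z = z, asp = 1, xlab = "x (m)", ylab = "y (m)",
                  main = sprintf("%s, t = %.4g s", x$case$case_id, st$t),
                  useRaster = TRUE, ...)
  invisible(x)
}
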