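#' Label dispersed-phase droplets in a volume-fraction field
#'
#' Connected components (face connectivity) of cells whose
#' continuous-phase fraction is below `threshold`. Components touching a
#' dispersed-phase inlet are excluded: they are the still-attached feed
#' thread, not droplets. In planar-2D mode the droplet volume is its
#' in-plane dispersed area times the channel depth, and the
#' sphere-equivalent diameter is D = (6 V / pi)^(1/3).
#'
#' @param alpha volume-fraction field (nx x ny), or a `field_state`.
#' @param ctx a `solver_ctx` (or `vof_grid` for fields without inlets).
#' @param threshold dispersed-cell threshold on alpha_CP (default 0.5).
#' @return data.frame of class `droplet_set`: one row per droplet with
#'   label, cell count, area (m^2), volume (m^3), diameter (m), centroid
#'   (m); member cells in the `cells` attribute (list of linear index
#'   vectors).
#' @export
label_droplets <- function(alpha, ctx, threshold = 0.5) {
  if (inherits(alpha, "field_state")) alpha <- alpha$alpha
  grid <- if (inherits(ctx, "vof_grid")) ctx else ctx$grid
  dx <- grid$dx
  disp <- grid$mask & alpha < threshold
  empty <- structure(
    data.frame(label = integer(0), n_cells = integer(0), area = numeric(0),
               volume = numeric(0), diameter = numeric(0),
               x = numeric(0), y = numeric(0)),
    cells = list(), class = c("droplet_set", "data.frame"))
  if (!any(disp)) return(empty)
  comp <- label_mask_components(disp)
  # exclude components adjacent to a dispersed inlet face
  excl <- integer(0)
  if (!inherits(ctx, "vof_grid") && !is.null(ctx$face_tag_u)) {
    iu <- which(!is.na(ctx$face_tag_u) & ctx$face_tag_u == "inlet_dp")
    if (length(iu)) {
      ij <- arrayInd(iu, dim(ctx$face_tag_u))
      cells <- adjacent_fluid_cell_idx(ij, ctx$face_sign_u[iu], "x")
      excl <- c(excl, comp[cells])
    }
    iv <- which(!is.na(ctx$face_tag_v) & ctx$face_tag_v == "inlet_dp")
    if (length(iv)) {
      ij <- arrayInd(iv, dim(ctx$face_tag_v))
      cells <- adjacent_fluid_cell_idx(ij, ctx$face_sign_v[iv], "y")
      excl <- c(excl, comp[cells])
    }
    excl <- setdiff(unique(excl), 0L)
  }
  labs <- setdiff(sort(unique(comp[comp > 0])), excl)
  if (!length(labs)) return(empty)
  H <- grid$depth
  xc <- grid$x0 + (seq_len(grid$nx) - 0.5) * dx
  yc <- grid$y0 + (seq_len(grid$ny) - 0.5) * dx
  cells_list <- vector("list", length(labs))
  rows <- vector("list", length(labs))
  for (k in seq_along(labs)) {
    cl <- which(comp == labs[k])
    ij <- arrayInd(cl, dim(comp))
    w <- 1 - alpha[cl]             # sub-cell dispersed content
    area <- sum(w) * dx^2
    vol <- area * H
    rows[[k]] <- data.frame(
      label = labs[k], n_cells = length(cl), area = area, volume = vol,
      diameter = (6 * vol / pi)^(1 / 3),
      x = sum(w * xc[ij[, 1]]) / sum(w),
      y = sum(w * yc[ij[, 2]]) / sum(w))
    cells_list[[k]] <- cl
  }
  out <- do.call(rbind, rows)
  attr(out, "cells") <- cells_list
  class(out) <- c("droplet_set", "data.frame")
  out
}

#' Population statistics of droplet sizes
#'
#' Mean, population (divide-by-n) standard deviation, and coefficient of
#' variation CV = std/mean. The population convention is the one under
#' which the reference droplet-area table reproduces its printed CV.
#'
#' @param x numeric vector (droplet areas or sizes); must be non-empty.
#' @return list with `mean`, `sd`, `cv`.
#' @examples
#' population_stats(c(0.077, 0.078, 0.077, 0.081, 0.080, 0.085, 0.072))
#' @export
population_stats <- function(x) {
  if (!length(x)) stop("population_stats: empty size list", call. = FALSE)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  list(mean = m, sd = s, cv = if (m != 0) s / m else 0)
}

#' Droplet generation rate
#'
#' f = (number of new droplets) / (time interval), counting pinch-off
#' events only: merges reduce the droplet count but do not reduce the
#' number generated.
#'
#' @param events either an event log data.frame (with columns `time` and
#'   `event`, counting rows with `event == "pinch_off"`), or an integer
#'   count of new droplets.
#' @param dt time interval in s (> 0). For an event log, defaults to the
#'   log's time span; required for a plain count.
#' @return rate in 1/s.
#' @export
generation_rate <- function(events, dt = NULL) {
  if (is.data.frame(events)) {
    n <- sum(events$event == "pinch_off")
    if (is.null(dt)) dt <- diff(range(events$time))
  } else {
    n <- as.numeric(events)
  }
  if (is.null(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  n / dt
}

#' Non-dimensionalize a droplet population
#'
#' Dimensionless mean droplet area A~ = A_mean / (W H), dimensionless
#' diameters D~ = D / Dh, and dimensionless generation rate f~ = f /
#' shear-rate, with the mean shear rate taken as gamma = 8 U / Dh (the
#' hydraulic-diameter Poiseuille wall-shear analog; configurable).
#'
#' @param droplets a `droplet_set` (pooled over sub-channels), or a
#'   numeric vector of areas (m^2).
#' @param channel a [rect_channel()].
#' @param U mean continuous-phase channel velocity (m/s); required for
#'   f~ when `f > 0`.
#' @param f droplet generation rate (1/s), or NULL.
#' @param gamma_dot mean shear rate (1/s); default 8 U / Dh.
#' @return object of class `droplet_population`.
#' @export
nondimensionalize_metrics <- function(droplets, channel, U = NULL, f = NULL,
                                      gamma_dot = NULL) {
  stopifnot(inherits(channel, "rect_channel"))
  areas <- if (is.numeric(droplets)) droplets else droplets$area
  diams <- if (is.numeric(droplets)) NULL else droplets$diameter
  st <- population_stats(areas)
  if (is.null(gamma_dot)) {
    if (!is.null(U) && U > 0) gamma_dot <- 8 * U / channel$Dh
    else if (!is.null(f) && f > 0)
      stop("U = 0 with f > 0: dimensionless rate undefined", call. = FALSE)
  }
  structure(list(
    droplets = if (is.numeric(droplets)) NULL else droplets,
    A_average = st$mean, A_sd = st$sd, CV = st$cv,
    A_tilde = st$mean / (channel$width * channel$height),
    D_tilde = if (!is.null(diams)) diams / channel$Dh else NULL,
    D_tilde_mean = if (!is.null(diams)) mean(diams) / channel$Dh else NULL,
    f = f, gamma_dot = gamma_dot,
    f_tilde = if (!is.null(f) && !is.null(gamma_dot)) f / gamma_dot else NULL,
    channel = channel),
    class = "droplet_population")
}

#' @export
print.droplet_population <- function(x, ...) {
  n <- if (!is.null(x$droplets)) nrow(x$droplets) else NA_integer_
  cat(sprintf("<droplet_population> %s droplets\n",
              ifelse(is.na(n), "?", n)))
  cat(sprintf("  A_mean = %.4g mm^2 (A~ = %.3g), CV = %.3g\n",
              x$A_average * 1e6, x$A_tilde, x$CV))
  if (!is.null(x$D_tilde_mean))
    cat(sprintf("  D~ mean = %.3g\n", x$D_tilde_mean))
  if (!is.null(x$f_tilde))
    cat(sprintf("  f = %.4g /s (f~ = %.3g, gamma = %.4g /s)\n",
                x$f, x$f_tilde, x$gamma_dot))
  invisible(x)
}

#' Droplet size histogram with mode detection
#'
#' Bins a list of dimensionless droplet sizes and reports the local
#' maxima of the counts (modes). A population containing both unmerged
#' droplets and pairwise-merged droplets (volume doubled, diameter
#' scaled by 2^(1/3)) shows two peaks.
#'
#' @param d_tilde numeric vector of dimensionless sizes (non-empty).
#' @param bin_width histogram bin width; bins start at the data minimum.
#' @return list: `breaks`, `counts`, `mids`, `peaks` (data.frame of mode
#'   positions and counts, largest first).
#' @export
size_histogram <- function(d_tilde, bin_width = 0.05) {
  if (!length(d_tilde)) stop("empty size list", call. = FALSE)
  check_positive(bin_width, "bin_width")
  lo <- min(d_tilde); hi <- max(d_tilde)
  nb <- max(1L, ceiling((hi - lo) / bin_width - 1e-9))
  breaks <- lo + (0:nb) * bin_width
  cnt <- tabulate(pmin(pmax(floor((d_tilde - lo) / bin_width) + 1L, 1L), nb),
                  nbins = nb)
  mids <- breaks[-1] - bin_width / 2
  # local maxima (plateaus count once, at their first bin)
  ext <- c(-1, cnt, -1)
  ispeak <- vapply(seq_len(nb), function(k)
    cnt[k] > 0 && ext[k] < cnt[k] && cnt[k] >= ext[k + 2], TRUE)
  # suppress trailing bins of equal-count plateaus
  if (nb > 1)
    for (k in 2:nb) if (ispeak[k] && cnt[k - 1] == cnt[k]) ispeak[k] <- FALSE
  peaks <- data.frame(position = mids[ispeak], count = cnt[ispeak])
  peaks <- peaks[order(-peaks$count, peaks$position), , drop = FALSE]
  list(breaks = breaks, counts = cnt, mids = mids, peaks = peaks)
}
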