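#' Write cell fields to a legacy VTK structured-points file
#'
#' ASCII legacy VTK, `DATASET STRUCTURED_POINTS`, one `SCALARS` block of
#' CELL_DATA per field; values carry 9 significant digits (full float
#' precision).
#'
#' @param path output file.
#' @param grid a `vof_grid`.
#' @param fields named list of nx x ny matrices.
#' @param title dataset title line.
#' @return `path`, invisibly.
#' @export
write_vtk_structured <- function(path, grid, fields, title = "spindrop fields") {
  stopifnot(length(names(fields)) == length(fields))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", grid$nx + 1, grid$ny + 1, 2),
               sprintf("ORIGIN %.9g %.9g 0", grid$x0, grid$y0),
               sprintf("SPACING %.9g %.9g %.9g", grid$dx, grid$dx, grid$depth),
               sprintf("CELL_DATA %d", grid$nx * grid$ny)), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    stopifnot(nrow(f) == grid$nx, ncol(f) == grid$ny)
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(formatC(as.numeric(f), format = "g", digits = 9), con)
  }
  invisible(path)
}

#' @rdname write_vtk_structured
#' @return `read_vtk_structured` returns a list: `nx`, `ny`, `origin`,
#'   `spacing`, and `fields` (named list of matrices).
#' @export
read_vtk_structured <- function(path) {
  lines <- readLines(path)
  dims <- as.numeric(strsplit(trimws(sub("DIMENSIONS", "",
                                         grep("^DIMENSIONS", lines, value = TRUE))),
                              "\\s+")[[1]])
  nx <- dims[1] - 1; ny <- dims[2] - 1
  origin <- as.numeric(strsplit(trimws(sub("ORIGIN", "",
                                           grep("^ORIGIN", lines, value = TRUE))),
                                "\\s+")[[1]])
  spacing <- as.numeric(strsplit(trimws(sub("SPACING", "",
                                            grep("^SPACING", lines, value = TRUE))),
                                 "\\s+")[[1]])
  sc <- grep("^SCALARS", lines)
  fields <- list()
  for (k in seq_along(sc)) {
    nm <- strsplit(lines[sc[k]], "\\s+")[[1]][2]
    start <- sc[k] + 2
    vals <- as.numeric(lines[start:(start + nx * ny - 1)])
    fields[[nm]] <- matrix(vals, nx, ny)
  }
  list(nx = nx, ny = ny, origin = origin, spacing = spacing, fields = fields)
}

#' Write all outputs of a run
#'
#' Writes, under `outdir`: a run manifest (JSON, written first and
#' finalized at exit), per-snapshot legacy VTK files (volume fraction,
#' cell-centered velocity, pressure, mixture properties), step
#' diagnostics CSV, the event log CSV, the droplet table CSV (one row
#' per droplet with dimensionless size and fate), and a size-histogram
#' CSV plus PNG when droplets exist. File naming is deterministic
#' (case_index), and repeated runs produce byte-identical CSVs.
#'
#' @param run a `vof_run`.
#' @param outdir output directory (created if missing).
#' @param write_snapshots write VTK snapshot files (default TRUE).
#' @param write_png render the histogram PNG (default TRUE).
#' @param seed reserved random seed recorded in the manifest (the
#'   pipeline itself is deterministic).
#' @return the manifest, invisibly.
#' @export
write_outputs <- function(run, outdir, write_snapshots = TRUE,
                          write_png = TRUE, seed = NA_integer_) {
  stopifnot(inherits(run, "vof_run"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    case_id = run$case$case_id,
    output_dir = outdir,
    snapshot_dt = run$case$run$snapshot_dt,
    seed = seed,
    version = as.character(utils::packageVersion("spindrop")),
    start_time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = list())
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  outputs <- character(0)

  dpath <- file.path(outdir, sprintf("%s_diagnostics.csv", run$case$case_id))
  utils::write.csv(run$diagnostics, dpath, row.names = FALSE)
  outputs <- c(outputs, dpath)
  epath <- file.path(outdir, sprintf("%s_events.csv", run$case$case_id))
  utils::write.csv(run$events, epath, row.names = FALSE)
  outputs <- c(outputs, epath)

  if (nrow(run$droplets)) {
    ch <- run$case$layout$channel
    dr <- run$droplets
    dr$diameter <- (6 * dr$volume / pi)^(1 / 3)
    dr$D_tilde <- dr$diameter / ch$Dh
    tpath <- file.path(outdir, sprintf("%s_droplets.csv", run$case$case_id))
    utils::write.csv(dr, tpath, row.names = FALSE)
    outputs <- c(outputs, tpath)
    hist <- size_histogram(dr$D_tilde, bin_width = 0.05)
    hpath <- file.path(outdir, sprintf("%s_histogram.csv", run$case$case_id))
    utils::write.csv(data.frame(mid = hist$mids, count = hist$counts),
                     hpath, row.names = FALSE)
    outputs <- c(outputs, hpath)
    if (write_png) {
      ppath <- file.path(outdir, sprintf("%s_histogram.png", run$case$case_id))
      grDevices::png(ppath, width = 640, height = 480)
      graphics::barplot(hist$counts, names.arg = sprintf("%.2f", hist$mids),
                        xlab = "D / Dh", ylab = "count",
                        main = sprintf("Droplet size distribution (%s)",
                                       run$case$case_id))
      grDevices::dev.off()
      outputs <- c(outputs, ppath)
    }
  }

  if (write_snapshots) {
    mixl <- lapply(seq_along(run$snapshots), function(k) {
      st <- run$snapshots[[k]]
      g <- run$ctx$grid
      mix <- mixture_properties(st$alpha, run$ctx$fluids)
      uc <- 0.5 * (st$u[1:g$nx, , drop = FALSE] +
                     st$u[2:(g$nx + 1), , drop = FALSE])
      vc <- 0.5 * (st$v[, 1:g$ny, drop = FALSE] +
                     st$v[, 2:(g$ny + 1), drop = FALSE])
      sp <- file.path(outdir, sprintf("%s_%04d.vtk", run$case$case_id, k - 1))
      write_vtk_structured(sp, g, list(alpha_cp = st$alpha, u = uc, v = vc,
                                       p = st$p, rho = mix$rho, eta = mix$eta),
                           title = sprintf("t=%.9g", st$t))
      sp
    })
    outputs <- c(outputs, unlist(mixl))
  }

  manifest$outputs <- basename(outputs)
  manifest$end_time <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  missing <- !file.exists(outputs)
  if (any(missing)) {
    manifest$incomplete <- basename(outputs[missing])
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
    stop(sprintf("output write failed for: %s; partial manifest written",
                 paste(basename(outputs[missing]), collapse = ", ")),
         call. = FALSE)
  }
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
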