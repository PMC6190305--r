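#' Rectangular microchannel cross-section
#'
#' @param width in-plane width W in m (transverse to flow).
#' @param height disc-normal depth H in m.
#' @param length channel length in m.
#' @return object of class `rect_channel` with a `Dh` field,
#'   the hydraulic diameter 2WH/(W+H).
#' @examples
#' ch <- rect_channel(200e-6, 100e-6, 25e-3)
#' ch$Dh  # 133.33 um
#' @export
rect_channel <- function(width, height, length) {
  check_positive(width, "width")
  check_positive(height, "height")
  check_positive(length, "length")
  structure(list(width = width, height = height, length = length,
                 Dh = 2 * width * height / (width + height)),
            class = "rect_channel")
}

#' Hydraulic diameter of a rectangular channel
#'
#' @param width,height cross-section dimensions in m, or a
#'   [rect_channel()] as first argument.
#' @return 2WH/(W+H) in m.
#' @export
hydraulic_diameter <- function(width, height = NULL) {
  if (inherits(width, "rect_channel")) return(width$Dh)
  2 * width * height / (width + height)
}

# A layout is a union of straight channel segments (rectangles of given
# width around a center line, possibly oblique) plus ports (inlets and
# outlets) attached to segment ends. Coordinates are in the disc plane
# with the rotation center at the origin.

segment_df <- function(x0, y0, x1, y1, width) {
  data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1, width = width)
}

make_port <- function(name, kind, center, normal, width, outlet_id = NA_character_) {
  list(name = name, kind = kind, center = center,
       normal = normal / sqrt(sum(normal^2)), width = width,
       outlet_id = outlet_id)
}

new_layout <- function(segments, ports, channel, depth, disc_radius = NA_real_,
                       meta = list(), name = "layout", prefill = NULL) {
  structure(list(segments = segments, ports = ports, channel = channel,
                 depth = depth, disc_radius = disc_radius, meta = meta,
                 name = name, prefill = prefill),
            class = "channel_layout")
}

#' @export
print.channel_layout <- function(x, ...) {
  cat(sprintf("<channel_layout> %s: %d segments, %d ports, depth %g um\n",
              x$name, nrow(x$segments), length(x$ports), x$depth * 1e6))
  for (p in x$ports)
    cat(sprintf("  port %-10s kind %-9s at (%.4g, %.4g) mm\n",
                p$name, p$kind, p$center[1] * 1e3, p$center[2] * 1e3))
  invisible(x)
}

#' Lab-on-a-disc device layout
#'
#' The emulsification/separation device: a radially oriented main channel
#' fed with the continuous phase, splitting at bifurcated junctions into
#' circumferential sub-channels. Each sub-channel carries a T-junction
#' side inlet for the dispersed phase (droplet formation) and ends in a
#' bifurcated separation junction with a radially outward outlet A and a
#' lateral outlet B. The rotation center is at the origin; the main
#' channel runs along +x (radially outward), sub-channels along +y
#' (locally circumferential).
#'
#' @param W,H channel width and depth in m (200 x 100 um by default).
#' @param disc_radius disc radius in m (54 mm: 108 mm diameter disc).
#' @param r_inlet radial position of the continuous-phase inlet (m).
#' @param junction_radii radial positions of the bifurcated junctions /
#'   sub-channels (m), strictly increasing, all < `disc_radius`.
#' @param sub_length length of each circumferential sub-channel (m).
#' @param t_offset distance along the sub-channel of the T-junction
#'   dispersed-phase side inlet (m).
#' @param dp_length length of the dispersed-phase side channel (m).
#' @param dp_width width of the dispersed-phase side channel (m).
#' @param sep_offset distance along the sub-channel of the separation
#'   junction (m).
#' @param outlet_length length of the two outlet arms (m).
#' @param outlet_a_angle,outlet_b_angle arm directions at the separation
#'   junction, degrees from the +x (radial) axis. Defaults: A radially
#'   outward (0), B lateral (90).
#' @return a `channel_layout`.
#' @export
device_layout <- function(W = 200e-6, H = 100e-6,
                          disc_radius = 54e-3,
                          r_inlet = 15e-3,
                          junction_radii = c(24e-3, 28e-3, 32e-3),
                          sub_length = 6e-3,
                          t_offset = 1e-3,
                          dp_length = 1e-3,
                          dp_width = 200e-6,
                          sep_offset = 4e-3,
                          outlet_length = 2e-3,
                          outlet_a_angle = 0,
                          outlet_b_angle = 90) {
  if (is.unsorted(junction_radii, strictly = TRUE))
    stop("field 'junction_radii' must be strictly increasing (junctions ordered downstream)",
         call. = FALSE)
  if (any(junction_radii >= disc_radius) || r_inlet >= disc_radius)
    stop("field 'junction_radii'/'r_inlet': all radial positions must be < disc_radius",
         call. = FALSE)
  r_end <- max(junction_radii)
  segs <- segment_df(r_inlet, 0, r_end, 0, W)     # main radial channel
  ports <- list(make_port("inlet_cp", "inlet_cp",
                          c(r_inlet, 0), c(-1, 0), W))
  prefill <- NULL
  for (k in seq_along(junction_radii)) {
    rk <- junction_radii[k]
    # circumferential sub-channel
    segs <- rbind(segs, segment_df(rk, 0, rk, sep_offset, W))
    # dispersed-phase side channel, fed from radially inward; the feed
    # is primed with dispersed phase up to the T-junction at t = 0
    segs <- rbind(segs, segment_df(rk - W / 2 - dp_length, t_offset,
                                   rk, t_offset, dp_width))
    prefill <- rbind(prefill, segment_df(rk - W / 2 - dp_length, t_offset,
                                         rk - W / 2, t_offset, dp_width))
    ports[[length(ports) + 1L]] <-
      make_port(sprintf("inlet_dp%d", k), "inlet_dp",
                c(rk - W / 2 - dp_length, t_offset), c(-1, 0), dp_width)
    # separation junction arms
    aa <- outlet_a_angle * pi / 180
    ba <- outlet_b_angle * pi / 180
    axy <- c(rk + W / 2, sep_offset)  # A starts at the outer sub-channel wall
    aend <- axy + outlet_length * c(cos(aa), sin(aa))
    segs <- rbind(segs, segment_df(axy[1] - W / 2, axy[2], aend[1], aend[2], W))
    ports[[length(ports) + 1L]] <-
      make_port(sprintf("outlet_a%d", k), "outlet",
                aend, c(cos(aa), sin(aa)), W, outlet_id = "A")
    bend <- c(rk, sep_offset) + (outlet_length + W / 2) * c(cos(ba), sin(ba))
    segs <- rbind(segs, segment_df(rk, sep_offset, bend[1], bend[2], W))
    ports[[length(ports) + 1L]] <-
      make_port(sprintf("outlet_b%d", k), "outlet",
                bend, c(cos(ba), sin(ba)), W, outlet_id = "B")
  }
  new_layout(segs, ports, rect_channel(W, H, r_end - r_inlet), H,
             disc_radius = disc_radius,
             meta = list(junction_radii = junction_radii,
                         t_junction_radii = junction_radii,
                         sep_offset = sep_offset, t_offset = t_offset),
             name = "device", prefill = prefill)
}

#' Rotating flow-focusing validation layout
#'
#' The droplet channel of the rotating flow-focusing benchmark: 25 mm
#' long, 660 um wide, 200 um deep, with a downstream constriction 376 um
#' wide and a dispersed-phase side channel joining at 80 degrees. The
#' radial position of the junction is not fixed by the benchmark
#' geometry; it is exposed as `r_junction` (default 32 mm, the one radial
#' station quoted for this device family).
#'
#' @param length droplet-channel length in m (25 mm as printed; shorten
#'   for desk-scale runs).
#' @param W droplet-channel width (660 um).
#' @param H depth (200 um).
#' @param W_constriction downstream constriction width (376 um).
#' @param constriction_length length of the constriction segment (m).
#' @param junction_angle side-channel approach angle in degrees (80).
#' @param dp_width dispersed-phase side channel width (m).
#' @param dp_length dispersed-phase side channel length (m).
#' @param r_junction radial position of the junction (m).
#' @return a `channel_layout`.
#' @export
validation_layout <- function(length = 25e-3, W = 660e-6, H = 200e-6,
                              W_constriction = 376e-6,
                              constriction_length = 2e-3,
                              junction_angle = 80,
                              dp_width = 376e-6,
                              dp_length = 1.5e-3,
                              r_junction = 32e-3) {
  x0 <- r_junction
  upstream <- 1e-3  # continuous-phase run-in upstream of the junction
  segs <- segment_df(x0 - upstream, 0, x0 + length, 0, W)
  segs <- rbind(segs, segment_df(x0 + length, 0,
                                 x0 + length + constriction_length, 0,
                                 W_constriction))
  # dispersed side channel joining at the junction angle, from +y; the
  # angle is measured between the side channel and the droplet channel
  # axis, approaching from upstream
  th <- junction_angle * pi / 180
  far <- c(x0 - cos(th) * dp_length, sin(th) * dp_length)
  segs <- rbind(segs, segment_df(far[1], far[2], x0, 0, dp_width))
  # side channel primed with dispersed phase down to the junction mouth
  tcut <- (W / 2) / sin(th)
  pf <- c(x0, 0) + (far - c(x0, 0)) / dp_length * tcut
  prefill <- segment_df(far[1], far[2], pf[1], pf[2], dp_width)
  ports <- list(
    make_port("inlet_cp", "inlet_cp", c(x0 - upstream, 0), c(-1, 0), W),
    make_port("inlet_dp", "inlet_dp", far, c(-cos(th), sin(th)), dp_width),
    make_port("outlet_a", "outlet",
              c(x0 + length + constriction_length, 0), c(1, 0),
              W_constriction, outlet_id = "A"))
  new_layout(segs, ports, rect_channel(W, H, length), H,
             meta = list(r_junction = r_junction,
                         junction_angle = junction_angle,
                         W_constriction = W_constriction),
             name = "validation", prefill = prefill)
}

#' Analytic toy layouts
#'
#' Small closed or straight-channel domains used by the built-in solver
#' verification suite: a quiescent box holding a static droplet, a
#' straight channel for patch advection / Poiseuille flow, and a radial
#' rotating channel.
#'
#' @param which one of "box", "channel", "radial_channel",
#'   "radial_expansion".
#' @param size box side or channel length (m).
#' @param W channel width (m).
#' @param H depth (m).
#' @param r_start radial position of the channel start (m), for the
#'   radial layouts.
#' @param W_chamber,chamber_length expansion-chamber dimensions (m), for
#'   "radial_expansion": a radial feed channel opening into a wider
#'   chamber (the planar configuration in which the Coriolis force
#'   visibly deflects the throughflow toward the trailing wall).
#' @return a `channel_layout`.
#' @export
toy_layout <- function(which = c("box", "channel", "radial_channel",
                                 "radial_expansion"),
                       size = 200e-6, W = 200e-6, H = 100e-6,
                       r_start = 30e-3, W_chamber = 600e-6,
                       chamber_length = 800e-6) {
  which <- match.arg(which)
  if (which == "radial_expansion") {
    x0 <- r_start
    segs <- segment_df(x0, 0, x0 + size, 0, W)
    segs <- rbind(segs, segment_df(x0 + size, 0,
                                   x0 + size + chamber_length, 0, W_chamber))
    ports <- list(
      make_port("inlet_cp", "inlet_cp", c(x0, 0), c(-1, 0), W),
      make_port("outlet_a", "outlet", c(x0 + size + chamber_length, 0),
                c(1, 0), W_chamber, outlet_id = "A"))
    return(new_layout(segs, ports, rect_channel(W, H, size), H,
                      meta = list(W_chamber = W_chamber,
                                  chamber_start = x0 + size,
                                  chamber_length = chamber_length),
                      name = which))
  }
  if (which == "box") {
    segs <- segment_df(0, 0, size, 0, size)
    # the segment is centered on y = 0; shift so the box is [0,size]^2
    segs$y0 <- segs$y1 <- size / 2
    return(new_layout(segs, list(), rect_channel(size, H, size), H,
                      name = "box"))
  }
  x0 <- if (which == "radial_channel") r_start else 0
  segs <- segment_df(x0, 0, x0 + size, 0, W)
  ports <- list(
    make_port("inlet_cp", "inlet_cp", c(x0, 0), c(-1, 0), W),
    make_port("outlet_a", "outlet", c(x0 + size, 0), c(1, 0), W,
              outlet_id = "A"))
  new_layout(segs, ports, rect_channel(W, H, size), H,
             name = which)
}

# point-in-segment test, vectorized over points
points_in_segment <- function(px, py, seg) {
  dx <- seg$x1 - seg$x0; dy <- seg$y1 - seg$y0
  L <- sqrt(dx^2 + dy^2)
  if (L == 0) return(rep(FALSE, length(px)))
  ax <- dx / L; ay <- dy / L
  qx <- px - seg$x0; qy <- py - seg$y0
  s <- qx * ax + qy * ay          # along-axis coordinate
  t <- -qx * ay + qy * ax         # transverse coordinate
  # half-open transverse bound: a cell center exactly on one channel
  # edge is counted once (so a 660 um channel at 20 um is 33 cells)
  tie <- seg$width / 2 * 1e-9
  s >= -1e-12 & s <= L + 1e-12 &
    t >= -seg$width / 2 - tie & t < seg$width / 2 - tie
}

#' Rasterize a channel layout onto a uniform grid
#'
#' Builds the cell-centered solid mask and tags the boundary faces of the
#' fluid region (wall, continuous-phase inlet, dispersed-phase inlets,
#' outlets A/B). Oblique segments are rasterized by staircase
#' approximation at cell resolution.
#'
#' @param layout a `channel_layout`.
#' @param dx uniform cell size in m. Every channel must be resolved by at
#'   least 4 cells across; coarser `dx` is refused with the required value.
#' @param mode only "planar2d" is supported: the simulation plane is the
#'   disc plane, the depth `H` enters through the out-of-plane friction
#'   term and through volume reconstruction in the droplet metrics.
#' @return an object of class `vof_grid`: cell size, mask, boundary face
#'   tags, physical origin (rotation center at the coordinate origin).
#' @export
rasterize_geometry <- function(layout, dx, mode = "planar2d") {
  stopifnot(inherits(layout, "channel_layout"))
  check_positive(dx, "dx")
  if (!identical(mode, "planar2d"))
    stop("mode must be 'planar2d' (full-3D rasterization is not provided)",
         call. = FALSE)
  wmin <- min(layout$segments$width)
  if (wmin / dx < 4 - 1e-9)
    stop(sprintf(
      "dx = %g m too coarse: narrowest channel (%g m) would be < 4 cells across; require dx <= %g m",
      dx, wmin, wmin / 4), call. = FALSE)
  pad <- dx
  xmin <- min(layout$segments$x0, layout$segments$x1) - max(layout$segments$width) / 2 - pad
  xmax <- max(layout$segments$x0, layout$segments$x1) + max(layout$segments$width) / 2 + pad
  ymin <- min(layout$segments$y0, layout$segments$y1) - max(layout$segments$width) / 2 - pad
  ymax <- max(layout$segments$y0, layout$segments$y1) + max(layout$segments$width) / 2 + pad
  x0 <- floor(xmin / dx) * dx
  y0 <- floor(ymin / dx) * dx
  nx <- ceiling((xmax - x0) / dx)
  ny <- ceiling((ymax - y0) / dx)
  xc <- x0 + (seq_len(nx) - 0.5) * dx
  yc <- y0 + (seq_len(ny) - 0.5) * dx
  px <- rep(xc, times = ny)
  py <- rep(yc, each = nx)
  inside <- rep(FALSE, nx * ny)
  for (k in seq_len(nrow(layout$segments)))
    inside <- inside | points_in_segment(px, py, layout$segments[k, ])
  mask <- matrix(inside, nx, ny)
  if (!any(mask)) stop("rasterization produced no fluid cells", call. = FALSE)

  grid <- structure(list(dx = dx, nx = nx, ny = ny, x0 = x0, y0 = y0,
                         mask = mask, depth = layout$depth, mode = mode,
                         layout = layout),
                    class = "vof_grid")
  grid$faces <- tag_boundary_faces(grid, layout$ports)
  grid
}

# boundary faces between fluid and non-fluid (or domain edge); returns a
# data.frame with axis ("x"/"y"), face indices, outward sign, tag, port
# name and outlet id.
tag_boundary_faces <- function(grid, ports) {
  mask <- grid$mask; nx <- grid$nx; ny <- grid$ny; dx <- grid$dx
  padx <- rbind(FALSE, mask, FALSE)           # (nx+2) x ny, shifted in i
  # u-faces: face (i,j), i = 1..nx+1 between cells i-1 and i
  fl <- padx[1:(nx + 1), , drop = FALSE]      # cell i-1 fluid
  fr <- padx[2:(nx + 2), , drop = FALSE]      # cell i fluid
  ub <- which(xor(fl, fr), arr.ind = TRUE)
  usign <- ifelse(fl[ub], 1, -1)              # outward normal +x if fluid on left
  ufx <- grid$x0 + (ub[, 1] - 1) * dx
  ufy <- grid$y0 + (ub[, 2] - 0.5) * dx
  pady <- cbind(FALSE, mask, FALSE)
  fb <- pady[, 1:(ny + 1), drop = FALSE]
  ft <- pady[, 2:(ny + 2), drop = FALSE]
  vb <- which(xor(fb, ft), arr.ind = TRUE)
  vsign <- ifelse(fb[vb], 1, -1)
  vfx <- grid$x0 + (vb[, 1] - 0.5) * dx
  vfy <- grid$y0 + (vb[, 2] - 1) * dx
  faces <- data.frame(
    axis = c(rep("x", nrow(ub)), rep("y", nrow(vb))),
    i = c(ub[, 1], vb[, 1]), j = c(ub[, 2], vb[, 2]),
    sign = c(usign, vsign),
    fx = c(ufx, vfx), fy = c(ufy, vfy),
    tag = "wall", port = NA_character_, outlet_id = NA_character_,
    stringsAsFactors = FALSE)
  for (p in ports) {
    # port capture rectangle: width across the port, one cell thick
    tvec <- c(-p$normal[2], p$normal[1])
    rel_x <- faces$fx - p$center[1]
    rel_y <- faces$fy - p$center[2]
    along <- rel_x * p$normal[1] + rel_y * p$normal[2]
    across <- rel_x * tvec[1] + rel_y * tvec[2]
    hit <- abs(along) <= grid$dx * 1.01 & abs(across) <= p$width / 2 + grid$dx / 2
    # only faces whose outward normal is roughly aligned with the port normal
    nface_x <- ifelse(faces$axis == "x", faces$sign, 0)
    nface_y <- ifelse(faces$axis == "y", faces$sign, 0)
    aligned <- (nface_x * p$normal[1] + nface_y * p$normal[2]) > 0.5
    sel <- hit & aligned
    faces$tag[sel] <- p$kind
    faces$port[sel] <- p$name
    faces$outlet_id[sel] <- p$outlet_id
  }
  faces
}

#' @export
print.vof_grid <- function(x, ...) {
  cat(sprintf("<vof_grid> %d x %d cells (dx = %g um), %d fluid cells\n",
              x$nx, x$ny, x$dx * 1e6, sum(x$mask)))
  tg <- table(x$faces$tag)
  cat("  boundary faces:", paste(names(tg), tg, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Check that every fluid cell is reachable from an inlet
#'
#' Flood-fills the fluid mask (face connectivity) from the inlet faces
#' and reports whether all fluid cells and the requested outlets are
#' reached.
#'
#' @param grid a `vof_grid`.
#' @return list with `all_reached` (logical), `n_unreached`, and
#'   `outlets_reached` (named logical per outlet id).
#' @export
grid_connectivity <- function(grid) {
  comp <- label_mask_components(grid$mask)
  faces <- grid$faces
  inlet_faces <- faces[faces$tag %in% c("inlet_cp", "inlet_dp"), , drop = FALSE]
  seed_cells <- adjacent_fluid_cell(grid, inlet_faces)
  seeds <- unique(comp[seed_cells])
  reached <- comp %in% seeds & grid$mask
  outf <- faces[faces$tag == "outlet", , drop = FALSE]
  out_cells <- adjacent_fluid_cell(grid, outf)
  outlets <- tapply(comp[out_cells] %in% seeds, outf$outlet_id, all)
  list(all_reached = all(reached[grid$mask]),
       n_unreached = sum(grid$mask) - sum(reached[grid$mask]),
       outlets_reached = outlets)
}

# linear indices of the fluid cell adjacent to each boundary face
adjacent_fluid_cell <- function(grid, faces) {
  i <- ifelse(faces$axis == "x",
              ifelse(faces$sign > 0, faces$i - 1L, faces$i), faces$i)
  j <- ifelse(faces$axis == "y",
              ifelse(faces$sign > 0, faces$j - 1L, faces$j), faces$j)
  cbind(i, j)
}

# connected components of a logical mask under face connectivity,
# via igraph; returns an integer matrix (0 for non-fluid)
label_mask_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(matrix(0L, nx, ny))
  id <- matrix(0L, nx, ny)
  id[idx] <- seq_along(idx)
  edges <- NULL
  right <- mask[-nx, , drop = FALSE] & mask[-1, , drop = FALSE]
  if (any(right)) {
    w <- which(right, arr.ind = TRUE)
    edges <- rbind(edges, cbind(id[cbind(w[, 1], w[, 2])],
                                id[cbind(w[, 1] + 1L, w[, 2])]))
  }
  up <- mask[, -ny, drop = FALSE] & mask[, -1, drop = FALSE]
  if (any(up)) {
    w <- which(up, arr.ind = TRUE)
    edges <- rbind(edges, cbind(id[cbind(w[, 1], w[, 2])],
                                id[cbind(w[, 1], w[, 2] + 1L)]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  out <- matrix(0L, nx, ny)
  out[idx] <- as.integer(memb)
  out
}
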