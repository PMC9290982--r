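# Channel, cavity and gate phantoms with analytically known geometry.
# These are the oracles for the grid-based cavity machinery: a tube of
# radius R must be detected as a channel with pore radius R, a sealed
# hollow sphere as an enclosed cavity of known volume, and the gate
# phantom's leucine must open/close the bore exactly as constructed.

# Lattice atoms filling a region predicate, as an atom data.frame.
lattice_atoms <- function(xr, yr, zr, spacing, keep, resid = "UNK",
                          chain = "W", elesy = "C") {
  pts <- as.matrix(expand.grid(x = seq(xr[1L], xr[2L], by = spacing),
                               y = seq(yr[1L], yr[2L], by = spacing),
                               z = seq(zr[1L], zr[2L], by = spacing)))
  pts <- pts[keep(pts[, 1L], pts[, 2L], pts[, 3L]), , drop = FALSE]
  if (nrow(pts) == 0) stop("empty lattice region")
  data.frame(chain = chain, resno = seq_len(nrow(pts)), insert = "",
             resid = resid, elety = "C", elesy = elesy, het = TRUE,
             x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
             stringsAsFactors = FALSE)
}

#' Build a tube phantom with a cylindrical channel of known radius
#'
#' The wall is a cylindrical sheet of atoms around an empty axial
#' channel.  The expected number of open voxels for the recommended
#' grid (literal marking mode, spacing `grid_spacing`, the returned
#' `bounds`) is computed from the analytic cylinder geometry, not from
#' the cavity module.
#'
#' @param radius Channel radius in Angstrom (wall atom centers sit at
#'   this radius).
#' @param length Tube length in Angstrom.
#' @param wall_spacing Wall atom spacing (<= 1 Angstrom keeps the wall
#'   voxel-tight).
#' @param center xy position of the tube axis (always along z).
#' @param probe,grid_spacing Probe radius and grid spacing the analytic
#'   count refers to.
#' @return A list: `structure`, `expected_open_voxels`, `bounds` (grid
#'   bounds cropped inside the tube ends so the channel reaches the z
#'   faces), `radius`, `probe`, `spacing`.
#' @export
build_channel_phantom <- function(radius, length = 20, wall_spacing = 0.5,
                                  center = c(0, 0), probe = 1.4,
                                  grid_spacing = 1.0) {
  if (radius <= 0 || length <= 0) stop("radius and length must be positive")
  if (wall_spacing > 1.0) stop("wall atom spacing must be <= 1 Angstrom")
  nz <- ceiling(length / wall_spacing)
  ncirc <- max(8L, ceiling(2 * pi * radius / wall_spacing))
  theta <- (seq_len(ncirc) - 1L) * 2 * pi / ncirc
  ring <- cbind(center[1L] + radius * cos(theta),
                center[2L] + radius * sin(theta))
  zs <- (seq_len(nz + 1L) - 1L) * wall_spacing
  atom <- data.frame(
    chain = "W", resno = rep(seq_along(zs), each = ncirc), insert = "",
    resid = "UNK", elety = "C", elesy = "C", het = TRUE,
    x = rep(ring[, 1L], times = length(zs)),
    y = rep(ring[, 2L], times = length(zs)),
    z = rep(zs, each = ncirc), stringsAsFactors = FALSE)
  s <- hw_structure(atom, id = sprintf("tube_r%.1f", radius))
  # integer-aligned bounds so a grid point sits exactly on the tube axis
  # (keeps the analytic and marked voxel sets identical)
  lim <- ceiling(radius + probe + 2)
  bounds <- list(xlim = c(center[1L] - lim, center[1L] + lim),
                 ylim = c(center[2L] - lim, center[2L] + lim),
                 zlim = c(2, floor(max(zs)) - 2))
  # analytic open count: grid points with axial distance < radius - probe,
  # over the z layers inside the cropped bounds
  xs <- seq(bounds$xlim[1L], bounds$xlim[2L], by = grid_spacing)
  ys <- seq(bounds$ylim[1L], bounds$ylim[2L], by = grid_spacing)
  nzl <- floor((bounds$zlim[2L] - bounds$zlim[1L]) / grid_spacing) + 1L
  r2 <- outer((xs - center[1L])^2, (ys - center[2L])^2, `+`)
  lumen <- if (radius > probe) sum(r2 < (radius - probe)^2) else 0L
  list(structure = s, expected_open_voxels = as.integer(lumen * nzl),
       bounds = bounds, radius = radius, probe = probe,
       spacing = grid_spacing)
}

#' Build a sealed hollow-sphere phantom
#'
#' A solid shell of lattice atoms around an empty sphere; the enclosed
#' cavity volume under literal marking is analytically
#' `4/3 * pi * (radius - probe)^3`.
#'
#' @param radius Inner shell radius (atom centers start here).
#' @param layers Number of concentric shell layers.
#' @param layer_gap Radial gap between layers (Angstrom).
#' @return A list: `structure`, `expected_volume` (for probe 1.4,
#'   literal mode), `radius`.
#' @export
build_hollow_sphere <- function(radius = 8, layers = 3L, layer_gap = 0.6) {
  atoms <- list()
  for (l in seq_len(layers)) {
    r <- radius + (l - 1L) * layer_gap
    n <- ceiling(4 * pi * r^2 / 0.25)  # ~0.5 A point spacing
    i <- seq_len(n) - 0.5
    zf <- 1 - 2 * i / n
    rho <- sqrt(pmax(0, 1 - zf^2))
    th <- pi * (1 + sqrt(5)) * i
    atoms[[l]] <- cbind(r * rho * cos(th), r * rho * sin(th), r * zf)
  }
  pts <- do.call(rbind, atoms)
  atom <- data.frame(chain = "W", resno = seq_len(nrow(pts)), insert = "",
                     resid = "UNK", elety = "C", elesy = "C", het = TRUE,
                     x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
                     stringsAsFactors = FALSE)
  s <- hw_structure(atom, id = sprintf("sphere_r%.1f", radius))
  list(structure = s, expected_volume = 4 / 3 * pi * (radius - 1.4)^3,
       radius = radius)
}

# Place a single residue's backbone frame at a given CA position with the
# CB direction `dir` (unit); returns the atom data.frame (no O realism
# needed beyond geometry).
place_probe_residue <- function(resid, chain, resno, ca, dir,
                                chis = NULL) {
  dir <- unit(dir)
  ref <- if (abs(dir[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- unit(vcross(dir, ref))
  w <- unit(vcross(dir, u))
  # N and C directions at tetrahedral angles from the requested CB
  # direction; the branch sign is picked so the L-chirality CB placement
  # reproduces `dir`
  mk <- function(beta) {
    nd <- unit(-0.348 * dir + 0.937 * u)
    cd <- unit(-0.350 * dir +
                 0.937 * (cos(beta) * u + sin(beta) * w))
    list(n = ca + 1.458 * nd, cc = ca + 1.525 * cd)
  }
  beta <- deg2rad(123.2)
  cand <- list(mk(beta), mk(-beta))
  err <- vapply(cand, function(p)
    vnorm(place_cb(p$n, ca, p$cc) - (ca + 1.53 * dir)), numeric(1L))
  n <- cand[[which.min(err)]]$n
  cc <- cand[[which.min(err)]]$cc
  o <- place_atom(n, ca, cc, 1.231, 120.8, 133)
  bb <- data.frame(elety = c("N", "CA", "C", "O"),
                   elesy = c("N", "C", "C", "O"),
                   x = c(n[1L], ca[1L], cc[1L], o[1L]),
                   y = c(n[2L], ca[2L], cc[2L], o[2L]),
                   z = c(n[3L], ca[3L], cc[3L], o[3L]),
                   stringsAsFactors = FALSE)
  sc <- build_sidechain_atoms(resid, n, ca, cc, chis)
  at <- rbind(bb, sc)
  at$chain <- chain; at$resno <- resno; at$insert <- ""
  at$resid <- resid; at$het <- FALSE
  at
}

#' Build the sodium-gate phantom
#'
#' A blind vertical bore (radius 4 Angstrom, sealed top, open bottom)
#' through a thick atom shell, with a leucine gate residue whose side
#' chain, in the closed rotamer, plugs the bore below its own CB and, in
#' the open rotamer, hugs the wall.  Companion stub residues provide the
#' barrier-triad positions 3x43 and 6x40; optional blocker stubs occupy
#' the open-rotamer volume (the role Asp 2x50 and Tyr 7x53 play in
#' inactive receptors).
#'
#' @param state `"closed"` or `"open"`: rotamer the leucine is built in.
#' @param blocked_alt Add blocker stubs inside the open-rotamer volume.
#' @param bore_radius,bore_top Geometry knobs (Angstrom).
#' @return A list: `structure`, `numbering` (generic numbers for 2x46,
#'   3x43, 6x40 and any blockers at 2x50/7x53), `closed_chis`,
#'   `open_chis`, `state`.
#' @export
build_gate_phantom <- function(state = c("closed", "open"),
                               blocked_alt = FALSE, bore_radius = 4,
                               bore_top = 16) {
  state <- match.arg(state)
  shell_t <- 4.2
  rmax <- bore_radius + shell_t
  wall <- lattice_atoms(c(-rmax, rmax), c(-rmax, rmax),
                        c(0, bore_top + shell_t), 1.0,
                        function(x, y, z) {
                          r <- sqrt(x^2 + y^2)
                          inside_bore <- r < bore_radius & z < bore_top
                          !inside_bore
                        })
  ca <- c(-(bore_radius - 0.4), 0, 5.2)
  dirv <- unit(c(0.84, 0, -0.55))  # CB points inward and down
  # deterministic chi search: the closed rotamer brings the CG/CD atoms
  # onto the bore axis low in the bore (maximal plug), the open rotamer
  # keeps every side-chain atom as far from the axis as possible (the
  # side chain hugs the wall and the axial column stays open)
  tip_atoms <- function(chis) {
    at <- place_probe_residue("LEU", "G", 46L, ca, dirv, chis = chis)
    at[at$elety %in% c("CG", "CD1", "CD2"), , drop = FALSE]
  }
  chi_grid <- as.matrix(expand.grid(chi1 = seq(-180, 170, 10),
                                    chi2 = seq(-180, 170, 10)))
  radial <- function(sc) sqrt(sc$x^2 + sc$y^2)
  sc_closed <- apply(chi_grid, 1L, function(ch) {
    sc <- tip_atoms(ch); mean(radial(sc)) + 0.3 * mean(sc$z)
  })
  closed_chis <- unname(chi_grid[which.min(sc_closed), ])
  sc_open <- apply(chi_grid, 1L, function(ch) min(radial(tip_atoms(ch))))
  open_chis <- unname(chi_grid[which.max(sc_open), ])
  use <- if (state == "closed") closed_chis else open_chis
  leu <- place_probe_residue("LEU", "G", 46L, ca, dirv, chis = use)
  # triad stubs at the bore wall
  stub <- function(chain, resno, angle_deg, z) {
    th <- deg2rad(angle_deg)
    p <- c((bore_radius + 0.8) * cos(th), (bore_radius + 0.8) * sin(th), z)
    place_probe_residue("ALA", chain, resno, p, c(-cos(th), -sin(th), 0))
  }
  extra <- rbind(stub("H", 43L, 120, 7), stub("I", 40L, 240, 7))
  num <- data.frame(chain = c("G", "H", "I"), resno = c(46L, 43L, 40L),
                    generic = c("2x46", "3x43", "6x40"),
                    stringsAsFactors = FALSE)
  if (blocked_alt) {
    open_leu <- place_probe_residue("LEU", "G", 46L, ca, dirv,
                                    chis = open_chis)
    tip <- open_leu[open_leu$elety %in% c("CG", "CD1", "CD2"), , drop = FALSE]
    ctr <- colMeans(tip[, c("x", "y", "z")])
    # blocker backbones sit well clear of the gate; their side chains
    # point into the volume the open rotamer needs
    blockers <- rbind(
      place_probe_residue("ASP", "J", 50L, ctr + c(0, 4.0, 0.4),
                          c(0, -1, -0.1), chis = c(-175, -20)),
      place_probe_residue("TYR", "K", 53L, ctr + c(0, -4.0, 0.4),
                          c(0, 1, -0.1), chis = c(-175, 90)))
    extra <- rbind(extra, blockers)
    num <- rbind(num, data.frame(chain = c("J", "K"), resno = c(50L, 53L),
                                 generic = c("2x50", "7x53"),
                                 stringsAsFactors = FALSE))
  }
  atom <- rbind(wall, leu, extra)
  s <- hw_structure(atom, id = paste0("gate_", state))
  list(structure = s,
       numbering = numbering_from_table(num$chain, num$resno, num$generic),
       closed_chis = closed_chis, open_chis = open_chis, state = state)
}
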