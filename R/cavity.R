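# Grid-based cavity and channel detection.  A regularly spaced grid is
# placed over the molecule and a voxel counts as open when it lies more
# than the probe radius away from every atom -- literally from the atom
# centers, or (default) from their van der Waals surfaces, which is the
# water-probe convention needed for open/closed decisions.  Open voxels
# are grouped into connected components; a component reaching the grid
# boundary at two or more disjoint loci is a channel.  The escape-channel
# test asks whether a sodium-sized probe seeded just below position 2x46
# can reach the cytosolic grid face.

#' Mark open grid voxels around a structure
#'
#' @param s A [hw_structure].
#' @param spacing Grid spacing in Angstrom.
#' @param probe Probe radius in Angstrom.
#' @param mode `"vdw"` (open when farther than `r_vdw + probe` from every
#'   atom center, i.e. `probe` from every atom surface) or `"literal"`
#'   (open when farther than `probe` from every atom center).
#' @param bounds Optional list with `xlim`, `ylim`, `zlim` overriding the
#'   default grid extent (atoms padded by `pad`).  Cropping the grid
#'   inside a channel's openings is how a through-channel is given
#'   boundary contact.
#' @param pad Padding beyond the atoms for the default bounds.
#' @param clearance_cap Clearances are computed exactly up to this value
#'   (Angstrom) and capped above it.
#' @return An object of class `hw_grid`: `origin`, `spacing`, `dim`,
#'   `clearance` (3-d array of distance to the nearest atom surface or
#'   center, by mode), `open` (3-d logical array), plus the marking
#'   parameters.
#' @export
mark_open_voxels <- function(s, spacing = 1.0, probe = 1.4,
                             mode = c("vdw", "literal"), bounds = NULL,
                             pad = NULL, clearance_cap = 4.5) {
  mode <- match.arg(mode)
  if (spacing <= 0) stop("spacing must be positive")
  at <- s$atom
  if (nrow(at) == 0) stop("empty structure")
  if (is.null(pad)) pad <- probe + 2
  if (is.null(bounds)) {
    bounds <- list(xlim = range(at$x) + c(-pad, pad),
                   ylim = range(at$y) + c(-pad, pad),
                   zlim = range(at$z) + c(-pad, pad))
  }
  origin <- c(bounds$xlim[1L], bounds$ylim[1L], bounds$zlim[1L])
  dims <- as.integer(pmax(1L, floor((c(bounds$xlim[2L], bounds$ylim[2L],
                            bounds$zlim[2L]) - origin) / spacing) + 1L))
  clearance <- array(clearance_cap, dim = dims)
  off <- if (mode == "vdw") vdw_radius(at$elesy) else rep(0, nrow(at))
  axes <- lapply(1:3, function(k) origin[k] + (seq_len(dims[k]) - 1L) * spacing)
  for (a in seq_len(nrow(at))) {
    ctr <- c(at$x[a], at$y[a], at$z[a])
    rmax <- clearance_cap + off[a]
    rng <- lapply(1:3, function(k) {
      lo <- ceiling((ctr[k] - rmax - origin[k]) / spacing) + 1L
      hi <- floor((ctr[k] + rmax - origin[k]) / spacing) + 1L
      seq.int(max(1L, lo), min(dims[k], hi))
    })
    if (any(vapply(rng, length, integer(1L)) == 0L)) next
    dx2 <- (axes[[1L]][rng[[1L]]] - ctr[1L])^2
    dy2 <- (axes[[2L]][rng[[2L]]] - ctr[2L])^2
    dz2 <- (axes[[3L]][rng[[3L]]] - ctr[3L])^2
    d <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`)) - off[a]
    block <- clearance[rng[[1L]], rng[[2L]], rng[[3L]], drop = FALSE]
    clearance[rng[[1L]], rng[[2L]], rng[[3L]]] <- pmin(block, array(d, dim(block)))
  }
  out <- list(origin = origin, spacing = spacing, dim = dims,
              clearance = clearance, open = clearance > probe,
              probe = probe, mode = mode, bounds = bounds,
              clearance_cap = clearance_cap)
  class(out) <- "hw_grid"
  out
}

#' @export
print.hw_grid <- function(x, ...) {
  cat(sprintf("<hw_grid> %d x %d x %d @ %.2f A (%s mode, probe %.2f): %d open voxels\n",
              x$dim[1L], x$dim[2L], x$dim[3L], x$spacing, x$mode, x$probe,
              sum(x$open)))
  if (!is.null(x$component))
    cat(sprintf("  %d components\n", max(0, x$component, na.rm = TRUE)))
  invisible(x)
}

# Linear voxel indices of face-adjacent (or corner-adjacent) neighbour
# pairs among `cells` (linear indices) in a grid of dimension `dims`.
voxel_edges <- function(cells, dims, connectivity = 6L) {
  inside <- array(FALSE, dim = dims)
  inside[cells] <- TRUE
  idx <- arrayInd(cells, dims)
  shifts <- if (connectivity == 6L) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    sh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    sh <- sh[rowSums(abs(sh)) > 0, , drop = FALSE]
    sh[sh[, 1L] > 0 | (sh[, 1L] == 0 & sh[, 2L] > 0) |
         (sh[, 1L] == 0 & sh[, 2L] == 0 & sh[, 3L] > 0), , drop = FALSE]
  }
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(shifts))) {
    nb <- sweep(idx, 2L, as.numeric(shifts[r, ]), `+`)
    okrange <- nb[, 1L] >= 1 & nb[, 1L] <= dims[1L] &
      nb[, 2L] >= 1 & nb[, 2L] <= dims[2L] &
      nb[, 3L] >= 1 & nb[, 3L] <= dims[3L]
    lin <- rep(NA_integer_, nrow(nb))
    lin[okrange] <- (nb[okrange, 3L] - 1L) * dims[1L] * dims[2L] +
      (nb[okrange, 2L] - 1L) * dims[1L] + nb[okrange, 1L]
    lin[!okrange] <- 1L
    ok <- okrange & inside[lin]
    from <- c(from, cells[ok]); to <- c(to, lin[ok])
  }
  cbind(from, to)
}

# Connected components over a logical 3-d array; returns an integer array
# (NA where closed), labels ordered by decreasing size.
flood_components <- function(open, connectivity = 6L) {
  dims <- dim(open)
  cells <- which(open)
  lab <- array(NA_integer_, dim = dims)
  if (length(cells) == 0) return(lab)
  edges <- voxel_edges(cells, dims, connectivity)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(rbind(edges[, 1L], edges[, 2L])),
           ncol = 2L, byrow = TRUE), directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(cells),
                                    igraph::V(g)$name))
  comp <- igraph::components(g)
  memb <- comp$membership[as.character(cells)]
  sizes <- table(memb)
  rank <- match(memb, names(sort(sizes, decreasing = TRUE)))
  lab[cells] <- rank
  lab
}

#' Label connected open components of a grid
#'
#' @param grid A `hw_grid` from [mark_open_voxels()].
#' @param connectivity 6 (face neighbours; default, so channels cannot
#'   leak diagonally through a one-voxel wall) or 26.
#' @return The grid with an integer `component` array (labels ordered by
#'   decreasing size, `NA` on closed voxels) and `connectivity`.
#' @export
label_components <- function(grid, connectivity = 6L) {
  stopifnot(inherits(grid, "hw_grid"))
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  grid$component <- flood_components(grid$open, connectivity)
  grid$connectivity <- connectivity
  grid
}

# Boundary-face membership of voxel array indices.
on_face <- function(idx, dims) {
  cbind(xmin = idx[, 1L] == 1L, xmax = idx[, 1L] == dims[1L],
        ymin = idx[, 2L] == 1L, ymax = idx[, 2L] == dims[2L],
        zmin = idx[, 3L] == 1L, zmax = idx[, 3L] == dims[3L])
}

# Maximin ("widest path") bottleneck clearance between two voxel sets
# restricted to one component: the largest c such that `from` and `to`
# are still connected using only voxels with clearance >= c.
bottleneck_clearance <- function(grid, cells, from, to) {
  if (length(from) == 0 || length(to) == 0) return(NA_real_)
  cl <- grid$clearance[cells]
  lv <- sort(unique(cl))
  connected_at <- function(th) {
    keep <- cells[cl >= th - 1e-9]
    if (!any(from %in% keep) || !any(to %in% keep)) return(FALSE)
    lab <- flood_components(
      array(seq_len(prod(grid$dim)) %in% keep, dim = grid$dim),
      grid$connectivity %||% 6L)
    lf <- unique(lab[intersect(from, keep)])
    lt <- unique(lab[intersect(to, keep)])
    length(intersect(lf[!is.na(lf)], lt[!is.na(lt)])) > 0
  }
  lo <- 1L; hi <- length(lv)
  if (!connected_at(lv[lo])) return(NA_real_)
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (connected_at(lv[mid])) lo <- mid else hi <- mid - 1L
  }
  lv[lo]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify one open component
#'
#' @param grid A labeled `hw_grid` (see [label_components()]).
#' @param component Component label.
#' @return An object of class `hw_channel`: `component`, `n_voxels`,
#'   `volume` (A^3), `faces` (named logical, which grid faces are
#'   touched), `n_loci` (disjoint boundary-contact patches),
#'   `min_pore_radius` (bottleneck clearance between the two largest
#'   boundary loci for channels; maximum clearance otherwise) and
#'   `verdict` in `{"enclosed_cavity", "channel", "open_cleft"}`.
#' @export
classify_component <- function(grid, component) {
  stopifnot(inherits(grid, "hw_grid"), !is.null(grid$component))
  cells <- which(!is.na(grid$component) & grid$component == component)
  if (length(cells) == 0) stop("no such component: ", component)
  dims <- grid$dim
  idx <- arrayInd(cells, dims)
  faces <- on_face(idx, dims)
  bcells <- cells[rowSums(faces) > 0]
  loci <- list()
  if (length(bcells) > 0) {
    sub <- array(FALSE, dims); sub[bcells] <- TRUE
    blab <- flood_components(sub, 26L)
    memb <- blab[bcells]
    loci <- split(bcells, memb)
    loci <- loci[order(-vapply(loci, length, integer(1L)))]
  }
  verdict <- if (length(loci) == 0) "enclosed_cavity"
  else if (length(loci) >= 2L) "channel" else "open_cleft"
  mpr <- if (verdict == "channel")
    bottleneck_clearance(grid, cells, loci[[1L]], loci[[2L]])
  else max(grid$clearance[cells])
  out <- list(component = component, n_voxels = length(cells),
              volume = length(cells) * grid$spacing^3,
              faces = colSums(faces) > 0, n_loci = length(loci),
              min_pore_radius = mpr, verdict = verdict)
  class(out) <- "hw_channel"
  out
}

#' @export
print.hw_channel <- function(x, ...) {
  cat(sprintf("<hw_channel> component %d: %s, %d voxels (%.0f A^3), %d boundary loci, pore radius %.2f A\n",
              x$component, x$verdict, x$n_voxels, x$volume, x$n_loci,
              x$min_pore_radius))
  invisible(x)
}

#' Sodium escape-channel test below a generic position
#'
#' Seeds the open-space component at the voxel nearest to a point
#' `below_offset` Angstrom toward the cytosol from the CB atom of the
#' start residue (the base of its side chain; the side-chain centroid
#' itself would move with the rotamer under study).  The verdict is
#' `"open"` when that component reaches the cytosolic grid face and the
#' bottleneck clearance from seed to that face is at least `ion_radius`.
#' When no open voxel lies within `snap` of the seed point the test
#' reports `"closed"` with a seeding diagnostic.
#'
#' @param s A [hw_structure].
#' @param numbering A `hw_numbering` table resolving `start`.
#' @param start Generic position of the gate residue.
#' @param ion_radius Probe ion radius in Angstrom (sodium 1.02).
#' @param below_offset Seed offset toward the cytosol in Angstrom.
#' @param snap Maximum seed-to-voxel snap distance in Angstrom.
#' @param spacing,probe,mode,bounds Grid parameters, see
#'   [mark_open_voxels()].  By default the grid is cropped 1.5 Angstrom
#'   inside the structure's z extent so membrane-spanning channels reach
#'   the grid faces.
#' @param cytosol `"zmin"` or `"zmax"`: which z face is the cytosol
#'   (default `"zmin"`, the -z convention).
#' @return A list: `verdict` (`"open"`/`"closed"`), `reason`,
#'   `min_pore_radius`, `component` (a `hw_channel` or `NULL`), `seed`
#'   (the seed point), `grid` (the labeled `hw_grid`).
#' @export
escape_channel_test <- function(s, numbering, start = "2x46",
                                ion_radius = 1.02, below_offset = 2,
                                snap = 5, spacing = 1.0, probe = 1.4,
                                mode = "vdw", bounds = NULL,
                                cytosol = c("zmin", "zmax")) {
  cytosol <- match.arg(cytosol)
  hit <- generic_lookup(numbering, start)
  if (is.null(hit)) stop("start position ", start, " is not numbered")
  res <- residue_atoms(s, hit$chain, hit$resno, hit$insert %||% "")
  if (nrow(res) == 0) stop("start residue has no atoms")
  ref <- res[res$elety == "CB", , drop = FALSE]
  if (nrow(ref) == 0) ref <- res[res$elety == "CA", , drop = FALSE]
  zdir <- if (cytosol == "zmin") -1 else 1
  seed <- c(ref$x[1L], ref$y[1L], ref$z[1L] + zdir * below_offset)
  if (is.null(bounds)) {
    at <- s$atom
    pad <- probe + 2
    bounds <- list(xlim = range(at$x) + c(-pad, pad),
                   ylim = range(at$y) + c(-pad, pad),
                   zlim = range(at$z) + c(1.5, -1.5))
  }
  grid <- mark_open_voxels(s, spacing = spacing, probe = probe, mode = mode,
                           bounds = bounds)
  grid <- label_components(grid)
  cells <- which(grid$open)
  if (length(cells) == 0)
    return(list(verdict = "closed", reason = "no open voxels",
                min_pore_radius = NA_real_, component = NULL, seed = seed,
                grid = grid))
  idx <- arrayInd(cells, grid$dim)
  xyz <- sweep((idx - 1) * grid$spacing, 2L, grid$origin, `+`)
  d2 <- colSums((t(xyz) - seed)^2)
  if (min(d2) > snap^2)
    return(list(verdict = "closed", reason = "seeding: no open voxel near seed point",
                min_pore_radius = NA_real_, component = NULL, seed = seed,
                grid = grid))
  seed_cell <- cells[which.min(d2)]
  comp_id <- grid$component[seed_cell]
  chan <- classify_component(grid, comp_id)
  face <- if (cytosol == "zmin") "zmin" else "zmax"
  comp_cells <- which(!is.na(grid$component) & grid$component == comp_id)
  cidx <- arrayInd(comp_cells, grid$dim)
  fcells <- comp_cells[on_face(cidx, grid$dim)[, face]]
  if (length(fcells) == 0)
    return(list(verdict = "closed", reason = "component does not reach the cytosolic face",
                min_pore_radius = NA_real_, component = chan, seed = seed,
                grid = grid))
  mpr <- bottleneck_clearance(grid, comp_cells, seed_cell, fcells)
  verdict <- if (!is.na(mpr) && mpr >= ion_radius) "open" else "closed"
  list(verdict = verdict,
       reason = if (verdict == "open") "path to cytosol wide enough"
       else "pore narrower than ion radius",
       min_pore_radius = mpr, component = chan, seed = seed, grid = grid)
}
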