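#' Parameters of the accessible-volume dye model
#'
#' Geometry of the dye-linker construct used by [compute_av()] and
#' [compute_av3()]. The defaults are the published Atto532/Atto643
#' maleimide-linker values: linker length 21 A, linker width 4.5 A, and the
#' three-radii dye ellipsoid approximations (5.5, 4.5, 1.5) A for the donor
#' and (7.15, 4.5, 1.5) A for the acceptor.
#'
#' @param linker_length Maximum geodesic path length from the attachment
#'   atom (A).
#' @param linker_width Linker diameter (A); path points must clear atom
#'   surfaces by half this value.
#' @param dye_radii Three dye radii (A) for the three-radii model.
#' @param grid_spacing Cubic grid step (A), in `(0, 2]`.
#' @return Object of class `av_params`.
#' @export
av_params <- function(linker_length = 21, linker_width = 4.5,
                      dye_radii = c(5.5, 4.5, 1.5), grid_spacing = 0.9) {
  if (linker_length <= 0) stop("'linker_length' must be > 0")
  if (linker_width <= 0 || any(dye_radii <= 0)) stop("all radii must be > 0")
  if (grid_spacing <= 0 || grid_spacing > 2) stop("'grid_spacing' must lie in (0, 2]")
  structure(list(linker_length = linker_length, linker_width = linker_width,
                 dye_radii = dye_radii, grid_spacing = grid_spacing),
            class = "av_params")
}

# van der Waals radii by element (A)
vdw_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
  r <- tab[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Read a protein structure from a PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] producing the atom table used by
#' the accessible-volume calculations: first model only, alternate location
#' 'A' or blank, HETATM records excluded by default, and van der Waals radii
#' assigned per element from a fixed internal table.
#'
#' @param file Path to a PDB file.
#' @param keep_het Keep HETATM records (default `FALSE`).
#' @return Data frame of class `av_structure` with columns `chain`, `resno`,
#'   `elety` (atom name), `element`, `x`, `y`, `z`, `radius`.
#' @export
read_structure <- function(file, keep_het = FALSE) {
  pdb <- bio3d::read.pdb(file, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  keep <- if (keep_het) rep(TRUE, nrow(at)) else at$type == "ATOM"
  keep <- keep & (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  element <- at$elesy
  if (is.null(element) || all(is.na(element)))
    element <- substr(gsub("[0-9 ]", "", at$elety), 1, 1)
  element[is.na(element) | element == ""] <-
    substr(gsub("[0-9 ]", "", at$elety[is.na(element) | element == ""]), 1, 1)
  out <- data.frame(chain = at$chain, resno = at$resno, elety = at$elety,
                    element = element,
                    x = at$x, y = at$y, z = at$z,
                    radius = vdw_radius(element),
                    stringsAsFactors = FALSE)
  class(out) <- c("av_structure", "data.frame")
  out
}

new_structure <- function(chain, resno, elety, element, x, y, z, radius) {
  out <- data.frame(chain = chain, resno = resno, elety = elety,
                    element = element, x = x, y = y, z = z, radius = radius,
                    stringsAsFactors = FALSE)
  class(out) <- c("av_structure", "data.frame")
  out
}

#' Toy atomic geometries for accessible-volume validation
#'
#' Generates minimal structures with analytically known accessible volumes:
#' \describe{
#'   \item{`lone_atom`}{a single attachment atom; the AV is a full sphere of
#'     the linker length.}
#'   \item{`planar_wall`}{a dense square wall of atoms in the `z = 0` plane
#'     with the attachment atom at the origin and a small aperture around
#'     it; the AV approximates the upper hemisphere, whose centroid sits at
#'     `3L/8` above the plane.}
#'   \item{`spherical_cavity`}{atoms on a sphere around the central
#'     attachment atom; the AV is confined to the cavity.}
#' }
#' The attachment atom is chain "A", residue 1, atom name "X1" (selector
#' `"A:1:X1"`).
#'
#' @param type One of `"lone_atom"`, `"planar_wall"`, `"spherical_cavity"`.
#' @param extent Wall edge length (A).
#' @param spacing Wall / shell atom spacing (A).
#' @param atom_radius Van der Waals radius assigned to the toy atoms (A).
#' @param aperture Radius around the attachment kept free of wall atoms (A).
#' @param wall_z Height of the wall atom plane (A); a small negative offset
#'   places the wall just below the attachment so the accessible volume is a
#'   clean upper hemisphere.
#' @param cavity_radius Radius of the spherical cavity (A).
#' @return An `av_structure` data frame.
#' @export
generate_toy_structure <- function(type = c("lone_atom", "planar_wall",
                                            "spherical_cavity"),
                                   extent = 60, spacing = 1.5,
                                   atom_radius = 1.7, aperture = 0,
                                   wall_z = 0, cavity_radius = 15) {
  type <- match.arg(type)
  att <- new_structure("A", 1L, "X1", "C", 0, 0, 0, atom_radius)
  if (type == "lone_atom") return(att)
  if (type == "planar_wall") {
    g <- seq(-extent / 2, extent / 2, by = spacing)
    xy <- expand.grid(x = g, y = g)
    keep <- sqrt(xy$x^2 + xy$y^2) > aperture
    xy <- xy[keep, ]
    wall <- new_structure("W", 2L, "W", "C", xy$x, xy$y,
                          rep(wall_z, nrow(xy)),
                          rep(atom_radius, nrow(xy)))
    out <- rbind(att, wall)
  } else {
    # near-uniform shell by Fibonacci lattice, point count set by spacing
    npt <- max(50L, ceiling(4 * pi * cavity_radius^2 / spacing^2))
    i <- seq_len(npt) - 0.5
    phi <- acos(1 - 2 * i / npt)
    theta <- pi * (1 + sqrt(5)) * i
    shell <- new_structure("W", 2L, "W", "C",
                           cavity_radius * sin(phi) * cos(theta),
                           cavity_radius * sin(phi) * sin(theta),
                           cavity_radius * cos(phi),
                           rep(atom_radius, npt))
    out <- rbind(att, shell)
  }
  class(out) <- c("av_structure", "data.frame")
  out
}

parse_site <- function(site) {
  parts <- strsplit(site, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("site selector must be 'chain:resno:atom'")
  list(chain = parts[1], resno = as.integer(parts[2]), elety = parts[3])
}

attachment_coords <- function(structure, site) {
  s <- parse_site(site)
  hit <- structure$chain == s$chain & structure$resno == s$resno &
    structure$elety == s$elety
  if (!any(hit)) stop("attachment atom ", site, " not found in structure")
  idx <- which(hit)[1]
  list(xyz = c(structure$x[idx], structure$y[idx], structure$z[idx]),
       chain = s$chain, resno = s$resno)
}

run_av_kernel <- function(structure, site, params, dye_radii) {
  att <- attachment_coords(structure, site)
  # the attachment residue's own atoms do not count as obstacles
  obst <- structure[!(structure$chain == att$chain &
                        structure$resno == att$resno), , drop = FALSE]
  kr <- av_grid_kernel(as.matrix(obst[, c("x", "y", "z")]),
                       obst$radius, att$xyz,
                       params$linker_length, params$linker_width / 2,
                       dye_radii, params$grid_spacing)
  kr$attachment <- att$xyz
  kr
}

cells_to_coords <- function(cells, kr) {
  n <- kr$n; half <- kr$half; sp <- kr$spacing
  i <- floor(cells / (n * n))
  j <- floor(cells / n) %% n
  k <- cells %% n
  cbind(x = kr$attachment[1] + (i - half) * sp,
        y = kr$attachment[2] + (j - half) * sp,
        z = kr$attachment[3] + (k - half) * sp)
}

new_av <- function(points, weights, attachment, spacing, dye_radii, params) {
  weights <- weights / sum(weights)
  mp <- colSums(points * weights)
  structure(list(points = points, weights = weights,
                 attachment = attachment, mean_position = unname(mp),
                 volume = nrow(points) * spacing^3, n_points = nrow(points),
                 spacing = spacing, dye_radii = dye_radii, params = params),
            class = "accessible_volume")
}

#' Single-radius accessible volume of a dye around a label site
#'
#' Breadth-first geodesic search on a cubic grid from the attachment atom: a
#' grid point belongs to the accessible volume iff a path of length at most
#' `linker_length` reaches it whose every point clears all atom surfaces by
#' half the linker width, and the point itself clears all atom surfaces by
#' `dye_radius`. Atoms of the attachment residue are not obstacles.
#'
#' @param structure An `av_structure` (from [read_structure()] or
#'   [generate_toy_structure()]).
#' @param site Label-site selector `"chain:resno:atom"`, e.g. `"A:61:SG"`.
#' @param params An [av_params()].
#' @param dye_radius Dye radius (A) used for the endpoint clearance.
#' @return Object of class `accessible_volume`: grid `points` with uniform
#'   `weights`, `mean_position`, `volume` (A^3) and the parameters used.
#' @export
compute_av <- function(structure, site, params = av_params(),
                       dye_radius = params$dye_radii[1]) {
  kr <- run_av_kernel(structure, site, params, dye_radius)
  cells <- kr$avs[[1]]
  if (length(cells) == 0L)
    stop("buried site: no sterically allowed dye positions at ", site)
  pts <- cells_to_coords(cells, kr)
  new_av(pts, rep(1, nrow(pts)), kr$attachment, params$grid_spacing,
         dye_radius, params)
}

#' Three-radii accessible volume
#'
#' Union of the three single-radius accessible volumes of the three-radii
#' dye model; each grid point is weighted by the number of component AVs
#' containing it (renormalised), so positions allowed for every dye
#' orientation count more than marginal ones.
#'
#' @inheritParams compute_av
#' @return Object of class `accessible_volume` with non-uniform weights.
#' @export
compute_av3 <- function(structure, site, params = av_params()) {
  kr <- run_av_kernel(structure, site, params, params$dye_radii)
  counts <- table(unlist(lapply(kr$avs, as.vector)))
  if (length(counts) == 0L)
    stop("buried site: no sterically allowed dye positions at ", site)
  cells <- as.numeric(names(counts))
  pts <- cells_to_coords(cells, kr)
  new_av(pts, as.vector(counts), kr$attachment, params$grid_spacing,
         params$dye_radii, params)
}

#' @export
print.accessible_volume <- function(x, ...) {
  cat(sprintf("accessible volume: %d grid points, volume %.1f A^3 (spacing %.2f A)\n",
              x$n_points, x$volume, x$spacing))
  cat(sprintf("  attachment (%.2f, %.2f, %.2f); mean dye position (%.2f, %.2f, %.2f)\n",
              x$attachment[1], x$attachment[2], x$attachment[3],
              x$mean_position[1], x$mean_position[2], x$mean_position[3]))
  invisible(x)
}

#' Inter-dye distance and FRET statistics of an AV pair
#'
#' Monte-Carlo estimates over weighted point pairs of two accessible
#' volumes: the mean inter-dye distance `mean_RDA`, the distance between
#' mean dye positions `Rmp`, the AV-averaged FRET efficiency `mean_E`, and
#' the efficiency-equivalent distance `R_meanE = R0 ((1-mean_E)/mean_E)^(1/6)`
#' (the distance a single-point dye pair would need to give `mean_E`).
#'
#' @param av_donor,av_acceptor `accessible_volume` objects.
#' @param R0 Forster radius (A).
#' @param n_samples Number of sampled point pairs.
#' @param seed Integer seed (sampling is deterministic given it).
#' @return Object of class `av_pair_stats` with fields `mean_RDA`, `Rmp`,
#'   `mean_E`, `R_meanE`, and Monte-Carlo standard errors `se_RDA`, `se_E`.
#' @export
av_pair_stats <- function(av_donor, av_acceptor, R0 = 59,
                          n_samples = 1e5, seed = 1L) {
  stopifnot(inherits(av_donor, "accessible_volume"),
            inherits(av_acceptor, "accessible_volume"))
  set.seed(seed)
  i <- sample.int(av_donor$n_points, n_samples, replace = TRUE,
                  prob = av_donor$weights)
  j <- sample.int(av_acceptor$n_points, n_samples, replace = TRUE,
                  prob = av_acceptor$weights)
  d <- sqrt(rowSums((av_donor$points[i, , drop = FALSE] -
                       av_acceptor$points[j, , drop = FALSE])^2))
  E <- 1 / (1 + (d / R0)^6)
  mean_E <- mean(E)
  structure(list(mean_RDA = mean(d),
                 Rmp = sqrt(sum((av_donor$mean_position -
                                   av_acceptor$mean_position)^2)),
                 mean_E = mean_E,
                 R_meanE = R0 * ((1 - mean_E) / mean_E)^(1 / 6),
                 se_RDA = stats::sd(d) / sqrt(n_samples),
                 se_E = stats::sd(E) / sqrt(n_samples),
                 R0 = R0, n_samples = n_samples),
            class = "av_pair_stats")
}

#' @export
print.av_pair_stats <- function(x, ...) {
  cat("AV pair statistics (R0 =", x$R0, "A):\n")
  cat(sprintf("  mean R_DA  = %.2f A (MC se %.3f)\n", x$mean_RDA, x$se_RDA))
  cat(sprintf("  Rmp        = %.2f A\n", x$Rmp))
  cat(sprintf("  <E>        = %.4f (MC se %.5f)\n", x$mean_E, x$se_E))
  cat(sprintf("  R(<E>)     = %.2f A\n", x$R_meanE))
  invisible(x)
}

#' Write an accessible volume as pseudo-atoms in PDB format
#'
#' @param av An `accessible_volume`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_av_pdb <- function(av, file) {
  p <- av$points
  lines <- sprintf(
    "HETATM%5d  AV  AVC A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(nrow(p)) %% 100000, 1L, p[, 1], p[, 2], p[, 3], 1, 0)
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Download a PDB entry (network required)
#'
#' Convenience fetcher for the worked structure-based examples; downloads
#' a PDB entry via [bio3d::get.pdb()] into `dir` and returns the file path.
#' Fails with an informative error when the machine is offline.
#'
#' @param id Four-character PDB accession.
#' @param dir Download directory.
#' @return Path to the downloaded file.
#' @export
fetch_pdb <- function(id, dir = tempdir()) {
  path <- tryCatch(suppressWarnings(bio3d::get.pdb(id, path = dir)),
                   error = function(e) NA_character_)
  if (is.na(path) || !file.exists(path))
    stop("could not download PDB entry ", id,
         " (network unavailable?); provide a local file instead")
  path
}
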