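#' @rdname dpd_state
#' @export
new_dpd_state <- function(positions, velocities, species, box, bonds,
                          rod = NULL, time = 0) {
  stopifnot(is.matrix(positions), ncol(positions) == 3,
            nrow(positions) == length(species),
            all(dim(velocities) == dim(positions)))
  colnames(positions) <- colnames(velocities) <- c("x", "y", "z")
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  storage.mode(bonds) <- "integer"
  structure(list(positions = positions, velocities = velocities,
                 species = as.integer(species), box = as.numeric(box),
                 bonds = bonds, rod = rod, time = time),
            class = "dpd_state")
}

#' DPD system state
#'
#' A `dpd_state` holds wrapped bead positions and velocities, per-bead
#' species labels (solvent, strand, crosslink, rod), the periodic box, the
#' bond list and, when a rod is present, the rigid-body state: centre of
#' mass (wrapped and unwrapped), orientation quaternion, COM velocity and
#' angular momentum. Rod bead coordinates are always regenerated from the
#' rigid pose, so intra-rod geometry is exact by construction.
#'
#' @param positions,velocities N x 3 matrices (r_c, r_c/tau).
#' @param species integer codes 1-4 for solvent, strand, crosslink, rod.
#' @param box box edge lengths (r_c).
#' @param bonds two-column integer matrix of bonded bead pairs.
#' @param rod rigid-body state list or NULL.
#' @param time current simulation time (tau).
#' @name dpd_state
NULL

#' @export
print.dpd_state <- function(x, ...) {
  n <- table(factor(species_levels()[x$species], levels = species_levels()))
  cat("DPD state:", nrow(x$positions), "beads in box",
      paste(signif(x$box, 5), collapse = " x "), "r_c, t =", x$time, "tau\n")
  cat(" ", paste(names(n), n, sep = ": ", collapse = ", "), "\n")
  cat(" ", nrow(x$bonds), "bonds;",
      if (is.null(x$rod)) "no rod" else
        paste0("rod with ", length(x$rod$idx), " beads"), "\n")
  invisible(x)
}

#' Rod axis unit vector of the current state
#' @param state a `dpd_state` with a rod.
#' @return length-3 unit vector (lab frame).
#' @export
rod_axis <- function(state) {
  stopifnot(!is.null(state$rod))
  quat_to_matrix(state$rod$quat)[, 3]
}

#' Write / read a state as extended XYZ plus a JSON sidecar
#'
#' The `.xyz` file carries species, positions and velocities in extended-XYZ
#' layout; the `.json` sidecar carries the box, bond list, rod pose and
#' simulation time, which extended XYZ cannot express.
#'
#' @param state a `dpd_state`.
#' @param prefix output path without extension.
#' @return `write_state` returns the prefix invisibly; `read_state` returns
#'   the reconstructed `dpd_state`.
#' @export
write_state <- function(state, prefix) {
  xyz <- paste0(prefix, ".xyz")
  lines <- c(
    as.character(nrow(state$positions)),
    sprintf('Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3:vel:R:3 Time=%g',
            state$box[1], state$box[2], state$box[3], state$time),
    sprintf("%s %.10g %.10g %.10g %.10g %.10g %.10g",
            species_levels()[state$species],
            state$positions[, 1], state$positions[, 2], state$positions[, 3],
            state$velocities[, 1], state$velocities[, 2], state$velocities[, 3]))
  writeLines(lines, xyz)
  side <- list(box = state$box, time = state$time,
               bonds = unname(state$bonds))
  if (!is.null(state$rod)) {
    side$rod <- list(idx = state$rod$idx, com = state$rod$com,
                     com_un = state$rod$com_un, quat = state$rod$quat,
                     vel = state$rod$vel, angmom = state$rod$angmom,
                     mass = state$rod$mass, inertia = state$rod$inertia,
                     body = unname(state$rod$spec$body),
                     length_L = state$rod$spec$length_L,
                     diameter_d = state$rod$spec$diameter_d)
  }
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_state
#' @export
read_state <- function(prefix) {
  lines <- readLines(paste0(prefix, ".xyz"))
  n <- as.integer(lines[1])
  parts <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  sp <- match(vapply(parts, `[`, "", 1), species_levels())
  num <- t(vapply(parts, function(p) as.numeric(p[2:7]), numeric(6)))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  bonds <- if (length(side$bonds)) matrix(as.integer(side$bonds), ncol = 2)
           else matrix(integer(0), 0, 2)
  rod <- NULL
  if (!is.null(side$rod)) {
    r <- side$rod
    spec <- structure(list(length_L = r$length_L, diameter_d = r$diameter_d,
                           body = matrix(as.numeric(r$body), ncol = 3),
                           mass = r$mass, inertia = as.numeric(r$inertia)),
                      class = "rod_spec")
    rod <- list(spec = spec, idx = as.integer(r$idx), com = as.numeric(r$com),
                com_un = as.numeric(r$com_un), quat = as.numeric(r$quat),
                vel = as.numeric(r$vel), angmom = as.numeric(r$angmom),
                mass = r$mass, inertia = as.numeric(r$inertia))
  }
  new_dpd_state(num[, 1:3, drop = FALSE], num[, 4:6, drop = FALSE], sp,
                as.numeric(side$box), bonds, rod = rod, time = side$time)
}
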