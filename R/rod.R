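#' Build a rigid rod of beads
#'
#' Fills a capped cylinder (spherocylinder) of total length `length_L` and
#' diameter `diameter_d` with beads on a cubic grid of pitch `bead_spacing`.
#' The rod is volume-filled rather than shell-only so that network strands
#' cannot thread through the soft-core body. The body frame is centred at the
#' centre of mass with the rod axis along z; the inertia tensor is computed
#' by direct summation over beads and diagonalised, and the body coordinates
#' are rotated into the principal frame (long axis kept along z).
#'
#' @param length_L rod length including the cap allowance (r_c).
#' @param diameter_d rod diameter (r_c).
#' @param bead_spacing grid pitch (r_c); must not exceed 0.5 r_c, otherwise
#'   strand beads could leak through the soft repulsive body.
#' @param mass_per_bead mass of each constituent bead (m = 1 by default).
#' @return An object of class `rod_spec`: body-frame bead positions, total
#'   mass, principal (diagonal) inertia and the full inertia tensor.
#' @export
#' @examples
#' rod <- build_rod(6.7, 4.69)     # L/a_x = 2.0, d/a_x = 1.4 at a_x = 3.35
#' nrow(rod$body)
build_rod <- function(length_L, diameter_d, bead_spacing = 0.5,
                      mass_per_bead = 1) {
  stopifnot(length_L >= diameter_d, diameter_d > 0, bead_spacing > 0)
  if (bead_spacing > 0.5)
    stop("bead_spacing > 0.5 r_c rejected: strands could thread through ",
         "the soft-core body")
  s <- bead_spacing
  half_seg <- max(0, (length_L - diameter_d) / 2) # cylindrical section
  rad <- diameter_d / 2
  nxy <- floor(rad / s)
  nz <- floor((length_L / 2) / s)
  g <- expand.grid(x = s * (-nxy:nxy), y = s * (-nxy:nxy), z = s * (-nz:nz))
  dz <- pmax(0, abs(g$z) - half_seg)
  keep <- g$x^2 + g$y^2 + dz^2 <= rad^2 + 1e-12
  body <- as.matrix(g[keep, , drop = FALSE])
  if (nrow(body) == 0) body <- matrix(0, 1, 3, dimnames = list(NULL, c("x", "y", "z")))
  body <- sweep(body, 2, colMeans(body))
  m <- rep(mass_per_bead, nrow(body))
  inertia <- rod_inertia(body, m)
  eig <- eigen(inertia, symmetric = TRUE)
  # principal frame, long axis (largest bead extent) mapped to body z
  R <- eig$vectors
  if (det(R) < 0) R[, 3] <- -R[, 3]
  rotated <- body %*% R
  ext <- apply(rotated, 2, function(u) diff(range(u)))
  ord <- order(ext) # long axis last -> z
  rotated <- rotated[, ord, drop = FALSE]
  moments <- eig$values[ord]
  colnames(rotated) <- c("x", "y", "z")
  structure(list(length_L = length_L, diameter_d = diameter_d,
                 bead_spacing = bead_spacing, body = rotated,
                 mass = sum(m), inertia = moments,
                 inertia_tensor = rod_inertia(rotated, m)),
            class = "rod_spec")
}

#' Inertia tensor of a bead cloud by direct summation
#'
#' `sum_i m_i (|r_i|^2 I - r_i r_i^T)` about the centre of mass frame the
#' coordinates are given in.
#'
#' @param body n x 3 matrix of bead coordinates.
#' @param masses per-bead masses (recycled).
#' @return 3 x 3 inertia tensor.
#' @export
rod_inertia <- function(body, masses = 1) {
  m <- rep_len(masses, nrow(body))
  I <- matrix(0, 3, 3)
  r2 <- rowSums(body^2)
  for (a in 1:3) for (b in 1:3) {
    I[a, b] <- sum(m * ((a == b) * r2 - body[, a] * body[, b]))
  }
  I
}

#' @export
print.rod_spec <- function(x, ...) {
  cat("Rigid rod: L =", x$length_L, "r_c, d =", x$diameter_d, "r_c,",
      nrow(x$body), "beads (pitch", x$bead_spacing, ")\n")
  cat("  mass =", x$mass, " principal inertia =",
      paste(signif(x$inertia, 4), collapse = ", "), "\n")
  invisible(x)
}

# unit quaternion rotating the body z axis onto `axis`
quat_from_axis <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  c_ <- sum(z * axis)
  if (c_ > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (c_ < -1 + 1e-12) return(c(0, 1, 0, 0)) # 180 deg about x
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  s <- sqrt((1 + c_) * 2)
  q <- c(s / 2, v / s)
  q / sqrt(sum(q^2))
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
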