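# shared fixture builders; everything is generated in code at test time

two_bead_state <- function(r, box = 5, v1 = c(0, 0, 0), v2 = c(0, 0, 0),
                           species = c(1L, 1L)) {
  new_dpd_state(matrix(c(1, 1, 1, 1 + r, 1, 1), 2, 3, byrow = TRUE),
                rbind(v1, v2), species, rep(box, 3),
                matrix(integer(0), 0, 2))
}

small_rod_system <- function(seed = 1, L_over_ax = 2.1, d_over_ax = 1.4,
                             cells = 3, a_x = 3.35, relax_iter = 300) {
  p <- dpd_params()
  net <- build_network(network_spec(cells, a_x = a_x, seed = seed), p,
                       relax_iter = relax_iter)
  rod <- build_rod(L_over_ax * a_x, d_over_ax * a_x,
                   bead_spacing = if (d_over_ax < 0.5) 0.3 else 0.5)
  # lateral pose on a cell-centre column (half-integer lattice coordinates)
  ctr <- (floor(cells / 2) + c(0.5, 0.5, 0)) * a_x
  st <- place_rod(net$state, rod, ctr, params = p, seed = seed + 1)
  list(state = st, params = p, a_x = a_x, topology = net$topology)
}

quat_to_matrix_exported <- function(q) rodnet:::quat_to_matrix(q)

# unwrap coordinates relative to the first row (minimum image)
minimg_coords <- function(x, box) {
  d <- sweep(x, 2, x[1, ])
  d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  sweep(d, 2, x[1, ], "+")
}

min_distance_between <- function(A, B, box) {
  min(rodnet:::min_pair_distance_to_set(A, B, box))
}

# cache expensive runs shared between test blocks within one session
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}
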