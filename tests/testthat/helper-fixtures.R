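# Shared fixture builders and brute-force oracles, all generated in code.

# a tiny section built directly from arrays (bypasses the generator)
make_section <- function(u, theta, salinity, no3, d15n, cell_area, years) {
  structure(list(u = u, theta = theta, salinity = salinity, no3 = no3,
                 d15n_no3 = d15n, cell_area = cell_area, years = years,
                 truth = NULL),
            class = "section_series")
}

# uniform little section: nd x nl cells, constant or per-year core velocity
uniform_section <- function(u_val, nd = 2, nl = 3, ny = 12, cell_area = 1e5,
                            t_c = 4, s = 35, no3 = 10) {
  d <- c(nd, nl, ny)
  make_section(u = array(rep(u_val, each = nd * nl), d),
               theta = array(t_c, d), salinity = array(s, d),
               no3 = array(no3, d), d15n = array(5, d),
               cell_area = matrix(cell_area, nd, nl),
               years = seq(2000, length.out = ny))
}

# brute-force transport: explicit triple loop over cells
loop_transport <- function(section, mask) {
  ny <- length(section$years)
  out <- numeric(ny)
  for (t in seq_len(ny)) {
    acc <- 0
    for (i in seq_len(dim(section$u)[1])) {
      for (j in seq_len(dim(section$u)[2])) {
        if (mask[i, j, t]) {
          acc <- acc + section$u[i, j, t] * section$cell_area[i, j]
        }
      }
    }
    out[t] <- acc / 1e6
  }
  out
}

# brute-force nitrate flux (mol/s)
loop_nitrate_flux <- function(section, mask) {
  ny <- length(section$years)
  out <- numeric(ny)
  for (t in seq_len(ny)) {
    acc <- 0
    for (i in seq_len(dim(section$u)[1])) {
      for (j in seq_len(dim(section$u)[2])) {
        if (mask[i, j, t]) {
          acc <- acc + section$no3[i, j, t] * 1e-3 *
            section$u[i, j, t] * section$cell_area[i, j]
        }
      }
    }
    out[t] <- acc
  }
  out
}

# brute-force normal-equations OLS slope, independent of lm's QR path
ne_slope <- function(x, y) {
  X <- cbind(1, x)
  solve(crossprod(X), crossprod(X, y))[2]
}

# exact isotope mixing in 15N/14N ratio space (oracle for mix_delta)
ratio_mix_delta <- function(masses, deltas, r_std = 0.0036765) {
  r <- (deltas / 1000 + 1) * r_std
  x15 <- r / (1 + r)             # atom fraction 15N
  x_mix <- sum(masses * x15) / sum(masses)
  (x_mix / (1 - x_mix) / r_std - 1) * 1000
}

# total 15N-equivalent mass of a box state (linear-delta bookkeeping)
state_isotope_mass <- function(state) {
  state$n_barents * state$delta_no3 + state$p_barents * state$delta_pom
}
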