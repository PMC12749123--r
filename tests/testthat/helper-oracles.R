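# Independent brute-force oracles and small fixture builders.  The oracles
# deliberately use naive all-pairs / all-cells double loops so they share no
# code path with the package implementations they check.

# Brute-force coverage: every cell center against every atom, no windowing.
brute_coverage <- function(frame, spec, grid, leaflet = "upper") {
  assignment <- assign_leaflets(frame, spec)
  glycerol_z <- compute_glycerol_plane(frame, spec, leaflet, assignment)
  sgn <- if (leaflet == "upper") 1 else -1
  keys <- paste(assignment$res_name, assignment$res_id, sep = ":")
  keep <- keys[assignment$leaflet == leaflet]
  sel <- paste(frame$atoms$res_name, frame$atoms$res_id, sep = ":") %in% keep
  atoms <- frame$atoms[sel, , drop = FALSE]
  roles <- memdefect:::atom_roles(frame$atoms, spec)[sel]
  radii <- memdefect:::atom_radii(atoms, spec)
  cx <- memdefect:::grid_centers_x(grid)
  cy <- memdefect:::grid_centers_y(grid)
  centers <- expand.grid(ix = seq_len(grid$nx), iy = seq_len(grid$ny))
  covered_head <- matrix(FALSE, grid$nx, grid$ny)
  covered_above <- matrix(FALSE, grid$nx, grid$ny)
  max_z <- matrix(NA_real_, grid$nx, grid$ny)
  deep_u <- sgn * glycerol_z - 0.1
  mi <- function(d, L) d - L * round(d / L)
  for (c_i in seq_len(nrow(centers))) {
    px <- cx[centers$ix[c_i]]; py <- cy[centers$iy[c_i]]
    d <- sqrt(mi(atoms$x - px, grid$Lx)^2 + mi(atoms$y - py, grid$Ly)^2)
    hit <- d <= radii
    if (!any(hit)) next
    i <- centers$ix[c_i]; j <- centers$iy[c_i]
    u <- sgn * atoms$z[hit]
    max_z[i, j] <- sgn * max(u)
    if (any(u > deep_u)) covered_above[i, j] <- TRUE
    if (any(roles[hit] == "head")) covered_head[i, j] <- TRUE
  }
  list(covered_head = covered_head, covered_above = covered_above,
       max_z = max_z)
}

# Brute-force merge: all-pairs center distances with wrap, then transitive
# closure by repeated label propagation.
brute_merge <- function(cells, grid, merge_distance = 0.3) {
  n <- nrow(cells)
  if (!n) return(list())
  cx <- memdefect:::grid_centers_x(grid)[cells[, 1]]
  cy <- memdefect:::grid_centers_y(grid)[cells[, 2]]
  mi <- function(d, L) d - L * round(d / L)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- sqrt(mi(cx[i] - cx[j], grid$Lx)^2 + mi(cy[i] - cy[j], grid$Ly)^2)
    adj[i, j] <- d <= merge_distance + 1e-12
  }
  labels <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      m <- min(labels[adj[i, ]])
      if (m < labels[i]) { labels[i] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  unname(lapply(split(seq_len(n), labels),
                function(ix) cells[ix, , drop = FALSE]))
}

# Components as a canonical multiset of sorted member-cell key strings.
component_signature <- function(comps) {
  sort(vapply(comps, function(m) {
    paste(sort(paste(m[, 1], m[, 2], sep = ",")), collapse = ";")
  }, character(1)))
}

# Brute-force pair energy: explicit double loop with minimum image.
brute_pair_energy <- function(frame, spec, set_a, set_b, cutoff = 1.2) {
  atoms <- frame$atoms
  pa <- memdefect:::atom_params(atoms[set_a, , drop = FALSE], spec)
  pb <- memdefect:::atom_params(atoms[set_b, , drop = FALSE], spec)
  f <- 138.935485
  mi <- function(d, L) d - L * round(d / L)
  coul <- 0; lj <- 0
  for (i in seq_along(set_a)) for (j in seq_along(set_b)) {
    a <- atoms[set_a[i], ]; b <- atoms[set_b[j], ]
    r <- sqrt(mi(a$x - b$x, frame$box[1])^2 +
                mi(a$y - b$y, frame$box[2])^2 +
                mi(a$z - b$z, frame$box[3])^2)
    if (r > cutoff || r == 0) next
    coul <- coul + f * pa$charge[i] * pb$charge[j] / r
    sig <- (pa$sigma[i] + pb$sigma[j]) / 2
    eps <- sqrt(pa$epsilon[i] * pb$epsilon[j])
    lj <- lj + 4 * eps * ((sig / r)^12 - (sig / r)^6)
  }
  list(coulomb = coul, lennard_jones = lj)
}

# A frame of free atoms with their own one-off parameter table, for energy
# oracle tests.
random_charged_system <- function(na, nb, box = c(5, 5, 5), seed = 1) {
  set.seed(seed)
  n <- na + nb
  atoms <- data.frame(serial = seq_len(n),
                      atom_name = paste0("X", seq_len(n)),
                      res_name = rep(c("RNDA", "RNDB"), c(na, nb)),
                      res_id = rep(c(1L, 2L), c(na, nb)),
                      x = runif(n, 0, box[1]), y = runif(n, 0, box[2]),
                      z = runif(n, 0, box[3]))
  top <- default_topology()
  top$params <- rbind(top$params,
                      data.frame(res_name = atoms$res_name,
                                 atom_name = atoms$atom_name,
                                 charge = round(runif(n, -1, 1), 3),
                                 sigma = round(runif(n, 0.2, 0.5), 3),
                                 epsilon = round(runif(n, 0, 1), 3)))
  list(frame = mem_frame(atoms, box), topology = top,
       set_a = seq_len(na), set_b = na + seq_len(nb))
}

# Two opposite unit point charges r nm apart, with zeroed LJ.
unit_charge_system <- function(r = 1.0, box = c(10, 10, 10)) {
  atoms <- data.frame(serial = 1:2, atom_name = c("N", "O"),
                      res_name = c("S001", "LPC"), res_id = c(1L, 2L),
                      x = c(1, 1 + r), y = 5, z = 5)
  top <- default_topology()
  top$params <- rbind(top$params,
                      data.frame(res_name = c("S001", "LPC"),
                                 atom_name = c("N", "O"),
                                 charge = c(1, -1), sigma = 0, epsilon = 0))
  list(frame = mem_frame(atoms, box), topology = top)
}

# Compact protein-membrane contact with one aimed N-H...O hydrogen bond;
# everything within a 3 nm blob so rigid motions never cross the minimum
# image boundary of the 12 nm box.
aimed_contact_system <- function() {
  lip <- do.call(rbind, lapply(1:4, function(k) {
    x <- 5 + 0.8 * ((k - 1) %% 2); y <- 5 + 0.8 * ((k - 1) %/% 2)
    data.frame(atom_name = c("Q1", "O1", "G1", "C1A"),
               res_name = "LPC", res_id = k,
               x = x, y = y, z = c(6.4, 6.4, 6.0, 5.7))
  }))
  # donor N above the lipid O1 of residue 1, H on the N-O axis
  prot <- data.frame(atom_name = c("N", "H1", "CA", "O"),
                     res_name = "S001", res_id = 1L,
                     x = 5, y = 5, z = c(6.69, 6.59, 6.89, 6.99))
  atoms <- rbind(lip, prot)
  atoms$serial <- seq_len(nrow(atoms))
  frame <- mem_frame(atoms[, c("serial", "atom_name", "res_name", "res_id",
                               "x", "y", "z")], c(12, 12, 12))
  top <- default_topology()
  top$params <- rbind(top$params,
                      data.frame(res_name = "S001",
                                 atom_name = c("N", "H1", "CA", "O"),
                                 charge = c(0.5, 0, 0, -0.5),
                                 sigma = 0.3, epsilon = 0.5))
  list(frame = frame, topology = top)
}

rotate_frame <- function(frame, angles, shift) {
  # rotation about the centroid, then rigid translation
  cx <- c(mean(frame$atoms$x), mean(frame$atoms$y), mean(frame$atoms$z))
  Rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)), 3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, byrow = TRUE)
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, byrow = TRUE)
  R <- Rz(angles[3]) %*% Ry(angles[2]) %*% Rx(angles[1])
  pos <- t(as.matrix(frame$atoms[, c("x", "y", "z")]))
  new <- t(R %*% (pos - cx) + cx + shift)
  a <- frame$atoms
  a$x <- new[, 1]; a$y <- new[, 2]; a$z <- new[, 3]
  mem_frame(a, frame$box, frame$label)
}

small_bilayer <- function(n = 64, seed = 1, preset = "chol0", kappa = 0) {
  generate_bilayer(synthetic_membrane_spec(
    n_lipids_per_leaflet = n, composition = membrane_preset(preset),
    condensation = kappa, seed = seed))
}
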