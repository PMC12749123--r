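# Synthetic bead-lipid bilayers with controllable packing defects.
#
# Geometry (z relative to the bilayer midplane; mirrored for the lower
# leaflet): phospho head beads Q1/O1 at +1.4 nm, glycerol bead G1 at
# +1.0 nm, tail beads 0.3 and 0.5 nm below the glycerol level; sterol head
# R1/O1 at +1.35 (hydroxyl H at +1.45), sterol neck bead E1 0.05 nm below
# the glycerol level, or 0.5 nm below when the sterol is "condensed"
# (>= 3 of its 4 lattice neighbours are sterols).  On the default 0.8 nm
# lattice the 0.75 nm phospho head radius covers every grid cell with
# margin (max cell-center distance a/sqrt(2) + clipped jitter ~ 0.71 nm),
# so a sterol-free membrane has exactly zero defect cells; sterol clusters
# open defects whose depth class tracks condensation.

HEAD_DZ <- 0.4      # head beads above the glycerol level, nm
STEROL_HEAD_DZ <- 0.35
GLYCEROL_Z <- 1.0   # glycerol level above the midplane, nm
NECK_UP_DZ <- -0.05    # sterol neck relative to glycerol level
NECK_DOWN_DZ <- -0.5   # condensed sterol neck
TAIL_DZ <- c(-0.3, -0.5)
JITTER_CLIP <- 0.1

#' Composition presets
#'
#' Mole-fraction presets for SV-like membranes: `chol0` =
#' 12% PS + 20% PE + 68% PC, `chol10` = 12/20/58 + 10% sterol,
#' `chol40` = 12/20/28 + 40% sterol.
#'
#' @param name `"chol0"`, `"chol10"` or `"chol40"`.
#' @return Named fractions over (PS, PE, PC, sterol).
#' @export
membrane_preset <- function(name = c("chol0", "chol10", "chol40")) {
  switch(match.arg(name),
         chol0 = c(PS = 0.12, PE = 0.20, PC = 0.68, sterol = 0),
         chol10 = c(PS = 0.12, PE = 0.20, PC = 0.58, sterol = 0.10),
         chol40 = c(PS = 0.12, PE = 0.20, PC = 0.28, sterol = 0.40))
}

#' Specify a synthetic membrane
#'
#' @param n_lipids_per_leaflet lipids per leaflet; must be a perfect square
#'   (>= 4) so the lattice is complete and the no-defect guarantee holds.
#' @param lattice_spacing nm (default 0.8).
#' @param jitter_sd in-plane positional jitter SD, nm (default 0.05,
#'   hard-clipped at 0.1 to preserve headgroup coverage).
#' @param composition fractions over (PS, PE, PC, sterol) summing to 1;
#'   see [membrane_preset()].
#' @param condensation kappa in [0, 1]: 0 = random sterol placement, 1 =
#'   all sterols grown as a single connected patch.
#' @param box_z box height, nm (default 12).
#' @param seed integer RNG seed.
#' @return A `synthetic_membrane_spec`.
#' @export
synthetic_membrane_spec <- function(n_lipids_per_leaflet = 256,
                                    lattice_spacing = 0.8,
                                    jitter_sd = 0.05,
                                    composition = membrane_preset("chol0"),
                                    condensation = 0,
                                    box_z = 12,
                                    seed = 1) {
  if (n_lipids_per_leaflet < 4)
    stop_mem("need at least 4 lipids per leaflet")
  side <- sqrt(n_lipids_per_leaflet)
  if (abs(side - round(side)) > 1e-9)
    stop_mem("n_lipids_per_leaflet must be a perfect square (got %d)",
             n_lipids_per_leaflet)
  if (abs(sum(composition) - 1) > 1e-9)
    stop_mem("composition fractions must sum to 1 (got %.6f)",
             sum(composition))
  if (length(composition) != 4 ||
      !all(c("PS", "PE", "PC", "sterol") %in% names(composition)))
    stop_mem("composition must be named fractions over PS, PE, PC, sterol")
  if (condensation < 0 || condensation > 1)
    stop_mem("condensation must lie in [0, 1]")
  structure(list(n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
                 side = as.integer(round(side)),
                 lattice_spacing = lattice_spacing,
                 jitter_sd = jitter_sd,
                 composition = composition[c("PS", "PE", "PC", "sterol")],
                 condensation = condensation,
                 box_z = box_z, seed = as.integer(seed)),
            class = "synthetic_membrane_spec")
}

#' Largest-remainder apportionment of composition fractions
#'
#' @param fractions non-negative fractions summing to 1.
#' @param n total count to apportion.
#' @return Integer counts summing to `n`; remainders are assigned to the
#'   largest fractional parts (ties to the earlier entry).
#' @export
largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

# Sterol site selection on an side x side torus: round(kappa * n) sites grow
# as one rook-connected patch from a random seed site, the rest are uniform
# over the remaining sites.
place_sterols <- function(side, n_sterol, kappa) {
  n_sites <- side * side
  if (n_sterol == 0) return(integer(0))
  n_clustered <- round(kappa * n_sterol)
  chosen <- integer(0)
  if (n_clustered > 0) {
    start <- sample.int(n_sites, 1)
    cluster <- start
    in_cluster <- logical(n_sites)
    in_cluster[start] <- TRUE
    while (length(cluster) < n_clustered) {
      frontier <- unique(unlist(lapply(cluster, rook_neighbors, side = side)))
      frontier <- frontier[!in_cluster[frontier]]
      nxt <- frontier[sample.int(length(frontier), 1)]
      cluster <- c(cluster, nxt)
      in_cluster[nxt] <- TRUE
    }
    chosen <- cluster
  }
  n_random <- n_sterol - length(chosen)
  if (n_random > 0) {
    pool <- setdiff(seq_len(n_sites), chosen)
    chosen <- c(chosen, pool[sample.int(length(pool), n_random)])
  }
  sort(chosen)
}

rook_neighbors <- function(site, side) {
  i <- (site - 1) %% side
  j <- (site - 1) %/% side
  ii <- c((i + 1) %% side, (i - 1) %% side, i, i)
  jj <- c(j, j, (j + 1) %% side, (j - 1) %% side)
  ii + jj * side + 1
}

#' Generate a synthetic bilayer
#'
#' Builds two mirrored leaflets of bead pseudo-lipids on a jittered square
#' lattice.  Species counts follow largest-remainder rounding of the
#' composition; sterol sites are placed by the condensation parameter (see
#' [synthetic_membrane_spec()]); sterols with >= 3 sterol lattice
#' neighbours are "condensed" and drop their neck bead below the deep
#' plane.  Output is a pure function of the spec (bit-identical for a
#' fixed seed).  With no sterols the headgroup layer covers every grid
#' cell, so the defect pipeline reports zero defects.
#'
#' @param spec a `synthetic_membrane_spec` (or arguments forwarded to it).
#' @return List with `frame` (a [mem_frame]), `topology` (a
#'   `lipid_topology`), and `layout` (per-leaflet species lattice, for
#'   inspection and tests).
#' @export
generate_bilayer <- function(spec = synthetic_membrane_spec(), ...) {
  if (!inherits(spec, "synthetic_membrane_spec"))
    stop_mem("spec must be a synthetic_membrane_spec")
  side <- spec$side
  a <- spec$lattice_spacing
  n <- spec$n_lipids_per_leaflet
  mid <- spec$box_z / 2
  counts <- largest_remainder(spec$composition, n)
  names(counts) <- names(spec$composition)

  with_local_seed(spec$seed, {
    leaf <- lapply(c(upper = 1, lower = -1), function(sgn) {
      sterol_sites <- place_sterols(side, counts[["sterol"]], spec$condensation)
      species <- rep(NA_character_, n)
      species[sterol_sites] <- "LST"
      pool <- which(is.na(species))
      phos <- c(rep("LPS", counts[["PS"]]), rep("LPE", counts[["PE"]]),
                rep("LPC", counts[["PC"]]))
      species[pool] <- phos[sample.int(length(phos))]
      is_st <- species == "LST"
      n_nb <- vapply(seq_len(n), function(s) sum(is_st[rook_neighbors(s, side)]),
                     numeric(1))
      condensed <- is_st & n_nb >= 3
      jx <- pmin(JITTER_CLIP, pmax(-JITTER_CLIP, stats::rnorm(n, 0, spec$jitter_sd)))
      jy <- pmin(JITTER_CLIP, pmax(-JITTER_CLIP, stats::rnorm(n, 0, spec$jitter_sd)))
      list(species = species, condensed = condensed, jx = jx, jy = jy,
           sgn = sgn)
    })

    res_id <- 0L
    rows <- list()
    for (lf in leaf) {
      for (s in seq_len(n)) {
        res_id <- res_id + 1L
        i <- (s - 1) %% side
        j <- (s - 1) %/% side
        x <- (i + 0.5) * a + lf$jx[s]
        y <- (j + 0.5) * a + lf$jy[s]
        gz <- mid + lf$sgn * GLYCEROL_Z
        zz <- function(dz) gz + lf$sgn * dz   # dz relative to glycerol level
        sp <- lf$species[s]
        at <- if (sp == "LST") {
          neck <- if (lf$condensed[s]) NECK_DOWN_DZ else NECK_UP_DZ
          data.frame(atom_name = c("R1", "O1", "HO1", "E1", "C1A", "C2A"),
                     x = x, y = y,
                     z = c(zz(STEROL_HEAD_DZ), zz(STEROL_HEAD_DZ),
                           zz(STEROL_HEAD_DZ + 0.1), zz(neck),
                           zz(TAIL_DZ[1]), zz(TAIL_DZ[2])))
        } else {
          data.frame(atom_name = c("Q1", "O1", "G1", "C1A", "C2A", "C1B", "C2B"),
                     x = c(x, x, x, x + 0.12, x + 0.12, x - 0.12, x - 0.12),
                     y = y,
                     z = c(zz(HEAD_DZ), zz(HEAD_DZ), zz(0),
                           zz(TAIL_DZ[1]), zz(TAIL_DZ[2]),
                           zz(TAIL_DZ[1]), zz(TAIL_DZ[2])))
        }
        at$res_name <- sp
        at$res_id <- res_id
        rows[[length(rows) + 1L]] <- at
      }
    }
    atoms <- do.call(rbind, rows)
    atoms$serial <- seq_len(nrow(atoms))
    atoms <- atoms[, c("serial", "atom_name", "res_name", "res_id",
                       "x", "y", "z")]
    frame <- mem_frame(atoms, box = c(side * a, side * a, spec$box_z),
                       label = "synthetic bilayer")
    list(frame = frame, topology = default_topology(),
         layout = list(counts = counts,
                       upper = leaf$upper, lower = leaf$lower,
                       side = side, spec = spec))
  })
}

#' Carve a ground-truth packing defect into a frame
#'
#' Removes headgroup coverage from exactly `n_cells` contiguous grid cells
#' of one leaflet.  All headgroup atoms overlapping a target cell are
#' deleted; cells outside the target that thereby lose coverage are
#' re-covered with tiny patch beads (residue PAT, bead D1, radius 0.03 nm)
#' at their centers, so the surrounding coverage is untouched.  For a
#' shallow defect a tail bead is added over each target cell just above
#' the deep plane; for a deep defect every remaining leaflet atom above
#' the deep plane that overlaps a target cell is lowered well below it.
#' The carved region is kept at least 0.5 nm away from any pre-existing
#' defect cell so it cannot merge with one.
#'
#' @param frame a [mem_frame] (typically from [generate_bilayer()]).
#' @param spec the matching `lipid_topology`.
#' @param leaflet `"upper"` or `"lower"`.
#' @param n_cells number of grid cells to expose.
#' @param depth_class `"deep"` or `"shallow"`.
#' @param cell_size grid cell size, nm.
#' @param seed RNG seed for the target-region choice.
#' @return The modified frame; `attr(frame, "carved")` accumulates a list
#'   of `(cells, class)` ground-truth records.
#' @export
carve_defect <- function(frame, spec, leaflet = "upper", n_cells = 1,
                         depth_class = c("shallow", "deep"),
                         cell_size = 0.1, seed = 1) {
  depth_class <- match.arg(depth_class)
  grid <- build_grid(frame, cell_size)
  assignment <- assign_leaflets(frame, spec)
  map <- project_and_classify_cells(frame, spec, grid, leaflet, assignment)
  sgn <- map$leaflet_sign
  glycerol_u <- sgn * map$glycerol_z

  covered <- map$covered_head
  existing <- which(!covered, arr.ind = TRUE)
  candidate <- covered
  if (nrow(existing)) {
    cx <- grid_centers_x(grid); cy <- grid_centers_y(grid)
    ex <- cx[existing[, 1]]; ey <- cy[existing[, 2]]
    cand_idx <- which(candidate, arr.ind = TRUE)
    dx <- min_image(outer(cx[cand_idx[, 1]], ex, "-"), grid$Lx)
    dy <- min_image(outer(cy[cand_idx[, 2]], ey, "-"), grid$Ly)
    near <- apply(dx^2 + dy^2 <= 0.5^2, 1, any)
    candidate[cand_idx[near, , drop = FALSE]] <- FALSE
  }
  if (sum(candidate) < n_cells)
    stop_mem("n_cells = %d exceeds the free area available for carving", n_cells)

  target <- with_local_seed(seed, grow_region(candidate, grid, n_cells))
  if (is.null(target))
    stop_mem("could not place a contiguous region of %d cells", n_cells)

  tx <- grid_centers_x(grid)[target[, 1]]
  ty <- grid_centers_y(grid)[target[, 2]]

  atoms <- frame$atoms
  lsel <- which(leaflet_atom_sel(frame, spec, assignment, leaflet))
  roles <- atom_roles(atoms, spec)[lsel]
  radii <- atom_radii(atoms[lsel, , drop = FALSE], spec)
  dxm <- min_image(outer(atoms$x[lsel], tx, "-"), grid$Lx)
  dym <- min_image(outer(atoms$y[lsel], ty, "-"), grid$Ly)
  overlaps_target <- rowSums(sqrt(dxm^2 + dym^2) <= radii) > 0

  drop_idx <- lsel[overlaps_target & roles == "head"]
  dropped_heads <- atoms[drop_idx, , drop = FALSE]

  if (depth_class == "deep") {
    u <- sgn * atoms$z[lsel]
    lower_idx <- lsel[overlaps_target & roles != "head" &
                        u > glycerol_u - 0.12]
    atoms$z[lower_idx] <- sgn * (glycerol_u - 0.6)
  }

  if (length(drop_idx)) atoms <- atoms[-drop_idx, , drop = FALSE]

  next_res <- max(atoms$res_id) + 1L
  next_serial <- max(atoms$serial) + 1L
  extra <- list()
  if (depth_class == "shallow") {
    extra[[1]] <- data.frame(serial = next_serial + seq_along(tx) - 1L,
                             atom_name = "C1", res_name = "PAT",
                             res_id = next_res + seq_along(tx) - 1L,
                             x = tx, y = ty,
                             z = sgn * (glycerol_u - 0.05))
    next_serial <- next_serial + length(tx)
    next_res <- next_res + length(tx)
  }

  # re-cover non-target cells that lost their covering heads
  if (nrow(dropped_heads)) {
    hrad <- atom_radii(dropped_heads, spec)
    affected <- unique(do.call(rbind, lapply(seq_len(nrow(dropped_heads)),
      function(k) cells_in_radius(dropped_heads$x[k], dropped_heads$y[k],
                                  hrad[k], grid))))
    tkey <- paste(target[, 1], target[, 2])
    affected <- affected[!(paste(affected[, 1], affected[, 2]) %in% tkey),
                         , drop = FALSE]
    if (nrow(affected)) {
      leaf_keys <- unique(residue_key(frame$atoms[lsel, , drop = FALSE]))
      roles_now <- atom_roles(atoms, spec)
      head_now <- !is.na(roles_now) & roles_now == "head" &
        residue_key(atoms) %in% leaf_keys
      still_cov <- cells_covered_by(affected, atoms[head_now, , drop = FALSE],
                                    spec, grid)
      bare <- affected[!still_cov, , drop = FALSE]
      if (nrow(bare)) {
        bx <- grid_centers_x(grid)[bare[, 1]]
        by <- grid_centers_y(grid)[bare[, 2]]
        extra[[length(extra) + 1L]] <-
          data.frame(serial = next_serial + seq_along(bx) - 1L,
                     atom_name = "D1", res_name = "PAT",
                     res_id = next_res + seq_along(bx) - 1L,
                     x = bx, y = by,
                     z = sgn * (glycerol_u + HEAD_DZ))
      }
    }
  }
  if (length(extra)) {
    extra_df <- do.call(rbind, extra)
    extra_df$element <- infer_element(extra_df$atom_name)
    atoms <- rbind(atoms, extra_df[, names(atoms)])
  }
  out <- mem_frame(atoms, frame$box, frame$label)
  carved <- attr(frame, "carved") %||% list()
  carved[[length(carved) + 1L]] <- list(cells = target, class = depth_class,
                                        leaflet = leaflet)
  attr(out, "carved") <- carved
  out
}

# Cells whose centers lie within `r` of (x, y), as an index matrix.
cells_in_radius <- function(x, y, r, grid) {
  nwx <- ceiling(r / grid$cell_x) + 1L
  nwy <- ceiling(r / grid$cell_y) + 1L
  icx <- floor((x - grid$origin[1]) / grid$cell_x) + 1L
  icy <- floor((y - grid$origin[2]) / grid$cell_y) + 1L
  is <- (icx - nwx):(icx + nwx)
  js <- (icy - nwy):(icy + nwy)
  cx <- grid$origin[1] + (is - 0.5) * grid$cell_x
  cy <- grid$origin[2] + (js - 0.5) * grid$cell_y
  dx <- min_image(cx - x, grid$Lx)
  dy <- min_image(cy - y, grid$Ly)
  hit <- which(outer(dx^2, dy^2, "+") <= r * r, arr.ind = TRUE)
  iw <- ((is - 1L) %% grid$nx) + 1L
  jw <- ((js - 1L) %% grid$ny) + 1L
  unique(cbind(iw[hit[, 1]], jw[hit[, 2]]))
}

# For each cell (rows of index matrix), is it covered by any of the heads?
cells_covered_by <- function(cells, heads, spec, grid) {
  if (!nrow(heads)) return(rep(FALSE, nrow(cells)))
  r <- atom_radii(heads, spec)
  cx <- grid_centers_x(grid)[cells[, 1]]
  cy <- grid_centers_y(grid)[cells[, 2]]
  dx <- min_image(outer(cx, heads$x, "-"), grid$Lx)
  dy <- min_image(outer(cy, heads$y, "-"), grid$Ly)
  d2 <- dx^2 + dy^2
  rowSums(sweep(d2, 2, r^2, "<=")) > 0
}

# Grow a rook-contiguous region of n cells inside the candidate mask;
# returns NULL after repeated failures.
grow_region <- function(candidate, grid, n_cells, max_tries = 100) {
  cand_idx <- which(candidate, arr.ind = TRUE)
  for (try in seq_len(max_tries)) {
    start <- cand_idx[sample.int(nrow(cand_idx), 1), ]
    region <- matrix(start, ncol = 2)
    in_region <- paste(start[1], start[2])
    while (nrow(region) < n_cells) {
      frontier <- unique(do.call(rbind, lapply(seq_len(nrow(region)), function(k) {
        i <- region[k, 1]; j <- region[k, 2]
        cbind(((c(i + 1, i - 1, i, i) - 1) %% grid$nx) + 1,
              ((c(j, j, j + 1, j - 1) - 1) %% grid$ny) + 1)
      })))
      keys <- paste(frontier[, 1], frontier[, 2])
      ok <- !(keys %in% in_region) & candidate[frontier]
      frontier <- frontier[ok, , drop = FALSE]
      if (!nrow(frontier)) break
      pick <- frontier[sample.int(nrow(frontier), 1), ]
      region <- rbind(region, pick)
      in_region <- c(in_region, paste(pick[1], pick[2]))
    }
    if (nrow(region) == n_cells) return(unname(region))
  }
  NULL
}

#' Sample synthetic defect areas from a shifted exponential
#'
#' I.i.d. draws `fit_min + Exponential(mean A0)`, matching the fitted form
#' of the small-defect size distribution.
#'
#' @param A0 decay constant, A^2.
#' @param n number of samples.
#' @param fit_min shift, A^2 (default 5).
#' @param seed RNG seed.
#' @return Numeric vector of areas in A^2.
#' @export
sample_defect_areas <- function(A0, n, fit_min = 5, seed = NULL) {
  if (A0 <= 0) stop_mem("A0 must be positive")
  if (n < 1) stop_mem("n must be at least 1")
  with_local_seed(seed, fit_min + stats::rexp(n, rate = 1 / A0))
}

#' Add a bead-chain probe protein above a membrane
#'
#' A pseudo-protein of `n_residues` bead residues (backbone N with bonded
#' H, CA, carbonyl O per residue; names S001, S002, ...) laid out as a
#' serpentine `placement` nm above the upper headgroup layer.  Residue
#' charges follow the recycled `charges` pattern and sit on the N bead;
#' LJ parameters are appended to the topology's parameter table, so
#' H-bond and energy analyses work directly on the result.
#'
#' @param frame membrane [mem_frame].
#' @param spec matching `lipid_topology`.
#' @param n_residues number of residues (default 60, the N-terminal
#'   segment length analysed).
#' @param placement distance above the top headgroup atoms, nm (default 5,
#'   the initial protein-membrane separation).
#' @param charges per-residue charge pattern (e), recycled.
#' @param res_spacing in-plane bead spacing, nm.
#' @return List with `frame` (membrane + protein) and `topology`
#'   (parameters extended).
#' @export
generate_probe_protein <- function(frame, spec, n_residues = 60,
                                   placement = 5, charges = 0,
                                   res_spacing = 0.5) {
  if (n_residues < 1) stop_mem("n_residues must be >= 1")
  lip <- lipid_atom_sel(frame, spec)
  if (!any(lip)) stop_mem("frame has no lipid atoms to place the protein above")
  ztop <- max(frame$atoms$z[lip])
  zp <- ztop + placement
  q <- rep_len(charges, n_residues)

  per_row <- max(1L, floor(frame$box[1] / res_spacing) - 1L)
  i <- seq_len(n_residues) - 1L
  px <- (i %% per_row + 0.5) * res_spacing
  py <- (i %/% per_row + 0.5) * res_spacing

  res_names <- sprintf("S%03d", seq_len(n_residues))
  atoms <- do.call(rbind, lapply(seq_len(n_residues), function(k) {
    data.frame(atom_name = c("N", "H1", "CA", "O"),
               res_name = res_names[k], res_id = k,
               x = c(px[k], px[k], px[k] + 0.2, px[k] + 0.3),
               y = py[k],
               z = c(zp, zp + 0.1, zp, zp))
  }))
  atoms$serial <- max(frame$atoms$serial) + seq_len(nrow(atoms))
  atoms$element <- infer_element(atoms$atom_name)
  combined <- rbind(frame$atoms, atoms[, names(frame$atoms)])

  prot_params <- do.call(rbind, lapply(seq_len(n_residues), function(k) {
    data.frame(res_name = res_names[k],
               atom_name = c("N", "H1", "CA", "O"),
               charge = c(q[k], 0, 0, 0),
               sigma = c(0.33, 0.04, 0.36, 0.30),
               epsilon = c(0.7, 0.05, 0.45, 0.65))
  }))
  topology <- new_lipid_topology(spec$lipids, spec$radii,
                                 rbind(spec$params, prot_params))
  list(frame = mem_frame(combined, frame$box, frame$label),
       topology = topology)
}
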