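#' Geometric hydrogen-bond criteria
#'
#' The widely used geometric criterion: donor-acceptor distance at most
#' `d_max` and hydrogen-donor-acceptor angle at most `angle_max`.
#'
#' @param d_max donor-acceptor distance cutoff, nm (default 0.35).
#' @param angle_max H-donor-acceptor angle cutoff, degrees (default 30).
#' @return An `hbond_criteria` object.
#' @export
hbond_criteria <- function(d_max = 0.35, angle_max = 30) {
  if (d_max <= 0) stop_mem("d_max must be positive")
  if (angle_max <= 0 || angle_max > 90)
    stop_mem("angle_max must be in (0, 90] degrees")
  structure(list(d_max = d_max, angle_max = angle_max),
            class = "hbond_criteria")
}

#' Non-bonded interaction parameters
#'
#' Plain-truncation cutoff scheme: pair terms are summed for minimum-image
#' distances up to `cutoff` (default 1.2 nm = 12 A) with no shift, reaction
#' field or reciprocal-space term.  Coulomb prefactor
#' f = 138.935485 kJ mol^-1 nm e^-2; Lennard-Jones cross terms by
#' Lorentz-Berthelot combination (arithmetic sigma, geometric epsilon).
#'
#' @param cutoff nm, default 1.2.
#' @return A `nonbonded_params` object.
#' @export
nonbonded_params <- function(cutoff = 1.2) {
  if (cutoff <= 0) stop_mem("cutoff must be positive")
  structure(list(cutoff = cutoff, coulomb_f = 138.935485,
                 combining = "lorentz-berthelot"),
            class = "nonbonded_params")
}

# Protein = atoms of residues that are not lipid species in the topology.
protein_atom_sel <- function(frame, spec) {
  !(frame$atoms$res_name %in% lipid_resnames(spec))
}

lipid_atom_sel <- function(frame, spec) {
  frame$atoms$res_name %in% lipid_resnames(spec)
}

#' Find protein-membrane hydrogen bonds in a frame
#'
#' Hydrogens are attached to their donor geometrically: an H atom within
#' 0.12 nm (minimum image) of an N, O or S heavy atom belongs to that
#' donor.  All donor-H...acceptor triplets crossing the protein/membrane
#' boundary that satisfy the distance and angle criteria are reported.
#'
#' @param frame a [mem_frame].
#' @param spec a `lipid_topology` (defines which residues are lipids).
#' @param criteria an [hbond_criteria()].
#' @return Data.frame of class `hbond_records` with donor, hydrogen and
#'   acceptor serials, distance (nm) and angle (degrees).
#' @export
find_hbonds <- function(frame, spec, criteria = hbond_criteria()) {
  atoms <- frame$atoms
  box <- frame$box
  is_h <- atoms$element == "H"
  if (!any(is_h))
    stop_mem("frame has no hydrogens; H-less structures cannot be H-bond analyzed")
  heavy_don <- which(atoms$element %in% c("N", "O", "S"))
  if (!length(heavy_don)) return(empty_hbond_records())
  is_lip <- lipid_atom_sel(frame, spec)
  if (!any(is_lip) || all(is_lip))
    stop_mem("both protein and membrane atoms must be present")

  pos <- as.matrix(atoms[, c("x", "y", "z")])
  # attach hydrogens to the nearest N/O/S within 0.12 nm
  hd <- min_image_dist(pos[is_h, , drop = FALSE],
                       pos[heavy_don, , drop = FALSE], box)
  h_idx <- which(is_h)
  nearest <- apply(hd, 1, which.min)
  ok <- hd[cbind(seq_along(h_idx), nearest)] <= 0.12
  donors <- heavy_don[nearest[ok]]
  hydros <- h_idx[ok]
  if (!length(donors)) return(empty_hbond_records())

  acceptors <- heavy_don  # any N/O/S can accept
  recs <- list()
  for (m in seq_along(donors)) {
    d <- donors[m]; h <- hydros[m]
    acc <- acceptors[is_lip[acceptors] != is_lip[d] & acceptors != d]
    if (!length(acc)) next
    dv <- vapply(1:3, function(k) min_image(pos[acc, k] - pos[d, k], box[k]),
                 numeric(length(acc)))
    dv <- matrix(dv, ncol = 3)
    dist_da <- sqrt(rowSums(dv^2))
    close <- dist_da <= criteria$d_max
    if (!any(close)) next
    hv <- vapply(1:3, function(k) min_image(pos[h, k] - pos[d, k], box[k]),
                 numeric(1))
    cosang <- (dv[close, , drop = FALSE] %*% hv) /
      (dist_da[close] * sqrt(sum(hv^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    hit <- ang <= criteria$angle_max
    if (!any(hit)) next
    recs[[length(recs) + 1L]] <- data.frame(
      donor = atoms$serial[d], hydrogen = atoms$serial[h],
      acceptor = atoms$serial[acc[close][hit]],
      distance = dist_da[close][hit], angle = ang[hit])
  }
  out <- if (length(recs)) do.call(rbind, recs) else empty_hbond_records()
  class(out) <- c("hbond_records", "data.frame")
  out
}

empty_hbond_records <- function() {
  data.frame(donor = integer(0), hydrogen = integer(0),
             acceptor = integer(0), distance = numeric(0),
             angle = numeric(0))
}

#' Hydrogen-bond counts along a trajectory
#'
#' Per-frame protein-membrane H-bond counts with mean and population SD
#' across frames.  Passing a list of trajectories treats each as an
#' independent run and additionally reports the ensemble mean (mean of run
#' means) and the SD of run means.
#'
#' @param traj a [mem_trajectory] or a list of them (runs).
#' @inheritParams find_hbonds
#' @return An `hbond_timeseries` list with `counts` (per run), `mean`,
#'   `sd`, and for multiple runs `run_means`, `ensemble_mean`,
#'   `ensemble_sd`.
#' @export
hbond_timeseries <- function(traj, spec, criteria = hbond_criteria()) {
  runs <- if (inherits(traj, "mem_trajectory")) list(traj) else traj
  if (!length(runs)) stop_mem("empty trajectory")
  counts <- lapply(runs, function(tr) {
    if (!length(tr$frames)) stop_mem("empty trajectory")
    vapply(tr$frames, function(fr) nrow(find_hbonds(fr, spec, criteria)),
           integer(1))
  })
  all_counts <- unlist(counts)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  run_means <- vapply(counts, mean, numeric(1))
  structure(list(counts = counts,
                 mean = mean(all_counts), sd = pop_sd(all_counts),
                 run_means = run_means,
                 ensemble_mean = mean(run_means),
                 ensemble_sd = pop_sd(run_means),
                 criteria = criteria),
            class = "hbond_timeseries")
}

#' @export
print.hbond_timeseries <- function(x, ...) {
  cat(sprintf("<hbond_timeseries> %d run(s), %d frames: mean %.2f +/- %.2f H-bonds",
              length(x$counts), length(unlist(x$counts)), x$mean, x$sd))
  if (length(x$counts) > 1)
    cat(sprintf(" (ensemble %.2f +/- %.2f over runs)", x$ensemble_mean,
                x$ensemble_sd))
  cat("\n")
  invisible(x)
}

#' Cutoff-truncated pair interaction energy between two atom sets
#'
#' Coulomb: sum of f q_i q_j / r_ij; Lennard-Jones: sum of
#' 4 eps_ij [(sig_ij/r_ij)^12 - (sig_ij/r_ij)^6], over cross pairs with
#' minimum-image r_ij at most the cutoff.  Plain truncation: these are
#' cutoff-scheme energies for relative and ensemble comparisons, not
#' Ewald/PME totals.
#'
#' @param frame a [mem_frame].
#' @param spec a `lipid_topology` carrying the charge/LJ table.
#' @param set_a,set_b disjoint integer vectors of atom row indices.
#' @param params a [nonbonded_params()].
#' @return An `energy_breakdown` with `coulomb` and `lennard_jones`
#'   (kJ/mol).
#' @export
pair_energy <- function(frame, spec, set_a, set_b,
                        params = nonbonded_params()) {
  if (length(intersect(set_a, set_b)))
    stop_mem("atom selections overlap")
  atoms <- frame$atoms
  pa <- atom_params(atoms[set_a, , drop = FALSE], spec)
  pb <- atom_params(atoms[set_b, , drop = FALSE], spec)
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  r <- min_image_dist(pos[set_a, , drop = FALSE],
                      pos[set_b, , drop = FALSE], frame$box)
  within <- r <= params$cutoff & r > 0
  if (!any(within)) {
    return(structure(list(coulomb = 0, lennard_jones = 0,
                          cutoff = params$cutoff, label = frame$label),
                     class = "energy_breakdown"))
  }
  qq <- outer(pa$charge, pb$charge)
  coul <- sum(params$coulomb_f * qq[within] / r[within])
  sig <- outer(pa$sigma, pb$sigma, "+") / 2
  eps <- sqrt(outer(pa$epsilon, pb$epsilon))
  sr6 <- (sig[within] / r[within])^6
  lj <- sum(4 * eps[within] * (sr6^2 - sr6))
  structure(list(coulomb = coul, lennard_jones = lj,
                 cutoff = params$cutoff, label = frame$label),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> Coulomb %.4f, Lennard-Jones %.4f kJ/mol (cutoff %.2f nm, plain truncation)\n",
              x$coulomb, x$lennard_jones, x$cutoff))
  if (!is.null(x$blocks_coulomb)) {
    cat("Coulomb blocks (residue group x lipid species):\n")
    print(round(x$blocks_coulomb, 4))
  }
  invisible(x)
}

residue_decade <- function(res_id) {
  grp <- rep("other", length(res_id))
  ok <- res_id >= 1 & res_id <= 60
  grp[ok] <- paste0((res_id[ok] - 1) %/% 10 * 10 + 1, "-",
                    (res_id[ok] - 1) %/% 10 * 10 + 10)
  grp
}

#' Protein-membrane energy decomposed by residue decade and lipid species
#'
#' Blocks are [pair_energy()] restricted to protein residues of one decade
#' (1-10, 11-20, ..., 51-60; residues outside 1-60 go to "other" with a
#' warning) crossed with lipids of one species; block sums reproduce the
#' totals.
#'
#' @inheritParams pair_energy
#' @param protein_sel,membrane_sel integer atom row indices; defaults
#'   select non-lipid vs lipid residues.
#' @return An `energy_breakdown` with `blocks_coulomb` and `blocks_lj`
#'   matrices (group x species).
#' @export
group_energy <- function(frame, spec, protein_sel = NULL,
                         membrane_sel = NULL, params = nonbonded_params()) {
  protein_sel <- protein_sel %||% which(protein_atom_sel(frame, spec))
  membrane_sel <- membrane_sel %||% which(lipid_atom_sel(frame, spec))
  atoms <- frame$atoms
  grp <- residue_decade(atoms$res_id[protein_sel])
  if (any(grp == "other"))
    warning("protein residue(s) outside 1-60 assigned to group 'other'")
  grp_levels <- c("1-10", "11-20", "21-30", "31-40", "41-50", "51-60")
  if (any(grp == "other")) grp_levels <- c(grp_levels, "other")
  species <- sort(unique(atoms$res_name[membrane_sel]))

  bc <- matrix(0, length(grp_levels), length(species),
               dimnames = list(grp_levels, species))
  bl <- bc
  for (g in grp_levels) {
    pa <- protein_sel[grp == g]
    if (!length(pa)) next
    for (s in species) {
      mb <- membrane_sel[atoms$res_name[membrane_sel] == s]
      if (!length(mb)) next
      e <- pair_energy(frame, spec, pa, mb, params)
      bc[g, s] <- e$coulomb
      bl[g, s] <- e$lennard_jones
    }
  }
  structure(list(coulomb = sum(bc), lennard_jones = sum(bl),
                 blocks_coulomb = bc, blocks_lj = bl,
                 cutoff = params$cutoff, label = frame$label),
            class = "energy_breakdown")
}

#' Per-contact-lipid interaction energy
#'
#' Divides the total protein-membrane energy by the number of contact
#' lipids: lipid residues with at least one atom within the cutoff
#' (minimum image) of any protein atom.  With zero contact lipids the
#' average is flagged undefined rather than reported as 0.
#'
#' @inheritParams group_energy
#' @return List with `per_lipid_coulomb`, `per_lipid_lj`,
#'   `per_lipid_total` (kJ/mol per lipid), `n_contact_lipids`, `defined`,
#'   and the underlying `total` breakdown.
#' @export
per_lipid_energy <- function(frame, spec, protein_sel = NULL,
                             membrane_sel = NULL,
                             params = nonbonded_params()) {
  protein_sel <- protein_sel %||% which(protein_atom_sel(frame, spec))
  membrane_sel <- membrane_sel %||% which(lipid_atom_sel(frame, spec))
  total <- pair_energy(frame, spec, protein_sel, membrane_sel, params)
  pos <- as.matrix(frame$atoms[, c("x", "y", "z")])
  r <- min_image_dist(pos[membrane_sel, , drop = FALSE],
                      pos[protein_sel, , drop = FALSE], frame$box)
  contact_atom <- apply(r <= params$cutoff, 1, any)
  keys <- residue_key(frame$atoms[membrane_sel, , drop = FALSE])
  n_contact <- length(unique(keys[contact_atom]))
  defined <- n_contact > 0
  list(per_lipid_coulomb = if (defined) total$coulomb / n_contact else NA_real_,
       per_lipid_lj = if (defined) total$lennard_jones / n_contact else NA_real_,
       per_lipid_total = if (defined)
         (total$coulomb + total$lennard_jones) / n_contact else NA_real_,
       n_contact_lipids = n_contact, defined = defined, total = total)
}

#' Interaction-energy time series with ensemble statistics
#'
#' Per-frame Coulomb/Lennard-Jones totals for each run; run means; ensemble
#' mean and SD of run means (matching the convention of averaging several
#' independent simulations and quoting the SD across them).
#'
#' @param traj a [mem_trajectory] or list of them (runs).
#' @inheritParams group_energy
#' @return An `energy_timeseries` list with a per-frame data.frame
#'   (`run`, `frame`, `coulomb`, `lennard_jones`, `total`), `run_means`,
#'   `ensemble_mean`, `ensemble_sd`.
#' @export
energy_timeseries <- function(traj, spec, protein_sel = NULL,
                              membrane_sel = NULL,
                              params = nonbonded_params()) {
  runs <- if (inherits(traj, "mem_trajectory")) list(traj) else traj
  if (!length(runs)) stop_mem("empty trajectory")
  rows <- list()
  for (ri in seq_along(runs)) {
    tr <- runs[[ri]]
    if (!length(tr$frames)) stop_mem("empty trajectory (run %d)", ri)
    ps <- protein_sel %||% which(protein_atom_sel(tr$frames[[1]], spec))
    ms <- membrane_sel %||% which(lipid_atom_sel(tr$frames[[1]], spec))
    for (fi in seq_along(tr$frames)) {
      e <- pair_energy(tr$frames[[fi]], spec, ps, ms, params)
      rows[[length(rows) + 1L]] <-
        data.frame(run = ri, frame = fi, coulomb = e$coulomb,
                   lennard_jones = e$lennard_jones,
                   total = e$coulomb + e$lennard_jones)
    }
  }
  df <- do.call(rbind, rows)
  run_means <- tapply(df$total, df$run, mean)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  structure(list(per_frame = df,
                 run_means = as.numeric(run_means),
                 ensemble_mean = mean(run_means),
                 ensemble_sd = pop_sd(as.numeric(run_means)),
                 params = params),
            class = "energy_timeseries")
}

#' @export
print.energy_timeseries <- function(x, ...) {
  cat(sprintf("<energy_timeseries> %d frames in %d run(s): ensemble %.3f +/- %.3f kJ/mol (cutoff scheme)\n",
              nrow(x$per_frame), length(x$run_means), x$ensemble_mean,
              x$ensemble_sd))
  invisible(x)
}
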