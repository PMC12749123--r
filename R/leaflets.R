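#' Assign lipid residues to bilayer leaflets
#'
#' The bilayer normal is taken as +z ("upper" = larger z).  The midplane is
#' the mean z of all lipid phosphorus atoms; if the system carries none
#' (e.g. the synthetic bead lipids), the mean z of all lipid headgroup
#' atoms is used instead.  Each lipid residue goes to the leaflet on the
#' side of the midplane where its mean headgroup z lies (ties to "upper");
#' residues whose headgroup atoms are absent fall back to the mean z of all
#' their atoms.  The assignment is invariant under rigid translations
#' (any xy shift; z shifts move the midplane along).
#'
#' @param frame a [mem_frame].
#' @param spec a `lipid_topology`.
#' @return A `leaflet_assignment`: data.frame with one row per lipid
#'   residue (`res_name`, `res_id`, `leaflet`) plus attribute `midplane_z`.
#' @export
assign_leaflets <- function(frame, spec) {
  atoms <- frame$atoms
  roles <- atom_roles(atoms, spec)
  is_lipid <- !is.na(roles)
  if (!any(is_lipid)) stop_mem("frame contains no lipid residues")
  key <- residue_key(atoms)
  lip_keys <- unique(key[is_lipid])
  if (length(lip_keys) < 2)
    stop_mem("need at least 2 lipid residues to define leaflets")

  p_sel <- is_lipid & atoms$element == "P"
  midplane_z <- if (any(p_sel)) mean(atoms$z[p_sel])
                else mean(atoms$z[is_lipid & roles == "head"])

  head_z <- tapply(atoms$z[is_lipid & roles == "head"],
                   key[is_lipid & roles == "head"], mean)
  all_z <- tapply(atoms$z[is_lipid], key[is_lipid], mean)
  ref_z <- all_z[lip_keys]
  ref_z[lip_keys %in% names(head_z)] <- head_z[lip_keys[lip_keys %in% names(head_z)]]

  first <- match(lip_keys, key)
  out <- data.frame(res_name = atoms$res_name[first],
                    res_id = atoms$res_id[first],
                    leaflet = ifelse(ref_z >= midplane_z, "upper", "lower"),
                    stringsAsFactors = FALSE)
  attr(out, "midplane_z") <- midplane_z
  class(out) <- c("leaflet_assignment", "data.frame")
  out
}

#' @export
print.leaflet_assignment <- function(x, ...) {
  cat(sprintf("<leaflet_assignment> %d lipid residues (upper %d / lower %d), midplane z = %.3f nm\n",
              nrow(x), sum(x$leaflet == "upper"), sum(x$leaflet == "lower"),
              attr(x, "midplane_z")))
  invisible(x)
}

# Logical index of atoms belonging to lipid residues of one leaflet.
leaflet_atom_sel <- function(frame, spec, assignment, leaflet) {
  leaflet <- match.arg(leaflet, c("upper", "lower"))
  keys <- paste(assignment$res_name, assignment$res_id, sep = ":")
  keep <- keys[assignment$leaflet == leaflet]
  residue_key(frame$atoms) %in% keep
}
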