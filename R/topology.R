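#' Built-in lipid topology and parameter defaults
#'
#' The topology spec maps residue + atom names to analysis roles
#' (headgroup / glycerol / tail), van der Waals radii by element, and
#' per-atom charge and Lennard-Jones parameters.  Defaults cover the
#' all-atom species DOPC, DOPE, DOPS and CHOL (CHARMM-style atom names)
#' and the synthetic bead species LPC, LPE, LPS (phospholipid-like),
#' LST (sterol-like) and PAT (coverage patch) produced by
#' [generate_bilayer()].
#'
#' Roles: `headgroup` atoms define interfacial coverage (a grid cell
#' overlapped by any headgroup atom is not a defect); `glycerol` atoms set
#' the reference plane for the deep/shallow threshold; an empty `tail` set
#' means "every other atom of the residue".  Sterol-like species may have an
#' empty glycerol set (they carry no glycerol backbone) but every lipid
#' must declare headgroup atoms.
#'
#' Radii are element-keyed Bondi radii (H 0.120, C 0.170, N 0.155, O 0.152,
#' P 0.180, S 0.180 nm) plus the synthetic bead pseudo-elements
#' Q 0.75 (phospho head), G 0.17 (glycerol bead), R 0.25 (sterol head),
#' E 0.60 (sterol neck), D 0.03 (patch bead).
#'
#' @return A `lipid_topology` object.
#' @export
default_topology <- function() {
  glyc_pl <- c("C1", "C2", "C3", "O21", "O22", "O31", "O32", "C21", "C31")
  head_pc <- c("N", "C11", "C12", "C13", "C14", "C15", "P",
               "O11", "O12", "O13", "O14")
  head_pe <- c("N", "C11", "C12", "P", "O11", "O12", "O13", "O14")
  head_ps <- c("N", "C11", "C12", "C13", "O13A", "O13B", "P",
               "O11", "O12", "O13", "O14")
  lipids <- list(
    DOPC = list(headgroup = head_pc, glycerol = glyc_pl,
                tail = character(0), is_lipid = TRUE),
    DOPE = list(headgroup = head_pe, glycerol = glyc_pl,
                tail = character(0), is_lipid = TRUE),
    DOPS = list(headgroup = head_ps, glycerol = glyc_pl,
                tail = character(0), is_lipid = TRUE),
    CHOL = list(headgroup = c("O3", "H3'"), glycerol = character(0),
                tail = character(0), is_lipid = TRUE),
    LPC = list(headgroup = c("Q1", "O1"), glycerol = "G1",
               tail = c("C1A", "C2A", "C1B", "C2B"), is_lipid = TRUE),
    LPE = list(headgroup = c("Q1", "O1"), glycerol = "G1",
               tail = c("C1A", "C2A", "C1B", "C2B"), is_lipid = TRUE),
    LPS = list(headgroup = c("Q1", "O1"), glycerol = "G1",
               tail = c("C1A", "C2A", "C1B", "C2B"), is_lipid = TRUE),
    LST = list(headgroup = c("R1", "O1", "HO1"), glycerol = character(0),
               tail = c("E1", "C1A", "C2A"), is_lipid = TRUE),
    PAT = list(headgroup = "D1", glycerol = character(0),
               tail = "C1", is_lipid = TRUE)
  )
  radii <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, P = 0.180,
             S = 0.180, Q = 0.75, G = 0.17, R = 0.25, E = 0.60, D = 0.03)
  params <- synthetic_param_table()
  new_lipid_topology(lipids, radii, params)
}

# Charge (e), sigma (nm), epsilon (kJ/mol) for the synthetic bead species.
# PS beads carry the -1 e net headgroup charge; sterols a neutral hydroxyl
# dipole; everything else is apolar.
synthetic_param_table <- function() {
  tab <- rbind(
    data.frame(res_name = "LPC",
               atom_name = c("Q1", "O1", "G1", "C1A", "C2A", "C1B", "C2B"),
               charge = c(0.3, -0.3, 0, 0, 0, 0, 0)),
    data.frame(res_name = "LPE",
               atom_name = c("Q1", "O1", "G1", "C1A", "C2A", "C1B", "C2B"),
               charge = c(0.3, -0.3, 0, 0, 0, 0, 0)),
    data.frame(res_name = "LPS",
               atom_name = c("Q1", "O1", "G1", "C1A", "C2A", "C1B", "C2B"),
               charge = c(0.2, -1.2, 0, 0, 0, 0, 0)),
    data.frame(res_name = "LST",
               atom_name = c("R1", "O1", "HO1", "E1", "C1A", "C2A"),
               charge = c(0.2, -0.6, 0.4, 0, 0, 0)),
    data.frame(res_name = "PAT",
               atom_name = c("D1", "C1"),
               charge = c(0, 0))
  )
  tab$sigma <- ifelse(tab$atom_name == "HO1", 0.04,
                      ifelse(tab$atom_name == "D1", 0.10, 0.47))
  tab$epsilon <- ifelse(tab$atom_name == "HO1", 0.05,
                        ifelse(tab$atom_name == "D1", 0, 0.35))
  tab
}

new_lipid_topology <- function(lipids, radii, params) {
  for (nm in names(lipids)) {
    entry <- lipids[[nm]]
    extra <- setdiff(names(entry), c("headgroup", "glycerol", "tail", "is_lipid"))
    if (length(extra))
      stop_mem("unknown role keyword '%s' for lipid %s", extra[1], nm)
    if (isTRUE(entry$is_lipid %||% TRUE) && !length(entry$headgroup))
      stop_mem("lipid %s has no headgroup atoms", nm)
    lipids[[nm]]$is_lipid <- isTRUE(entry$is_lipid %||% TRUE)
    lipids[[nm]]$glycerol <- entry$glycerol %||% character(0)
    lipids[[nm]]$tail <- entry$tail %||% character(0)
  }
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop_mem("van der Waals radii must be positive")
  if (!is.null(params) && nrow(params)) {
    if (any(!is.finite(params$epsilon)) || any(params$epsilon < 0))
      stop_mem("Lennard-Jones epsilon must be >= 0")
  }
  structure(list(lipids = lipids, radii = radii, params = params),
            class = "lipid_topology")
}

#' @export
print.lipid_topology <- function(x, ...) {
  cat(sprintf("<lipid_topology> %d species (%s), %d elements with radii, %d parameterised atoms\n",
              length(x$lipids), paste(names(x$lipids), collapse = ", "),
              length(x$radii), if (is.null(x$params)) 0L else nrow(x$params)))
  invisible(x)
}

#' Load a topology/parameter configuration
#'
#' Reads a plain-text configuration in a documented TOML dialect and merges
#' it over the built-in defaults of [default_topology()].  Supported syntax:
#' `[table.sub]` headers, `key = value` pairs with string, number, boolean
#' or flat array values, and `#` comments.
#'
#' Schema: `[lipids.RES]` tables with keys `headgroup`, `glycerol`, `tail`
#' (arrays of atom names) and `is_lipid` (boolean); a `[radii]` table of
#' element = radius-in-nm pairs; `[params.RES.ATOM]` tables with `charge`
#' (e), `sigma` (nm) and `epsilon` (kJ/mol).
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @return A `lipid_topology` object.
#' @export
load_topology_spec <- function(path = NULL) {
  base <- default_topology()
  if (is.null(path)) return(base)
  if (!file.exists(path)) stop_mem("topology config not found: %s", path)
  doc <- parse_toml_subset(readLines(path, warn = FALSE), path)

  lipids <- base$lipids
  for (res in names(doc$lipids %||% list())) {
    entry <- doc$lipids[[res]]
    bad <- setdiff(names(entry), c("headgroup", "glycerol", "tail", "is_lipid"))
    if (length(bad))
      stop_mem("%s: unknown role keyword '%s' in [lipids.%s]", path, bad[1], res)
    cur <- lipids[[res]] %||% list(headgroup = character(0),
                                   glycerol = character(0),
                                   tail = character(0), is_lipid = TRUE)
    for (k in names(entry)) cur[[k]] <- entry[[k]]
    cur$headgroup <- as.character(cur$headgroup)
    cur$glycerol <- as.character(cur$glycerol)
    cur$tail <- as.character(cur$tail)
    lipids[[res]] <- cur
  }

  radii <- base$radii
  for (el in names(doc$radii %||% list())) {
    r <- as.numeric(doc$radii[[el]])
    if (!is.finite(r) || r <= 0)
      stop_mem("%s: radius for element %s must be positive", path, el)
    radii[[el]] <- r
  }

  params <- base$params
  for (res in names(doc$params %||% list())) {
    for (at in names(doc$params[[res]])) {
      p <- doc$params[[res]][[at]]
      row <- data.frame(res_name = res, atom_name = at,
                        charge = as.numeric(p$charge %||% 0),
                        sigma = as.numeric(p$sigma %||% 0),
                        epsilon = as.numeric(p$epsilon %||% 0))
      hit <- params$res_name == res & params$atom_name == at
      if (any(hit)) params[hit, ] <- row else params <- rbind(params, row)
    }
  }
  new_lipid_topology(lipids, radii, params)
}

# Minimal TOML-subset parser: nested tables from [a.b.c] headers, scalar and
# flat-array values.  Returns a nested named list.
parse_toml_subset <- function(lines, path = "<config>") {
  doc <- list()
  section <- character(0)
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[[^]]+\\]$", line)) {
      hdr <- sub("^\\[", "", sub("\\]$", "", line))
      section <- trimws(gsub("\"", "", strsplit(hdr, ".", fixed = TRUE)[[1]]))
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z0-9_'\"-]+)\\s*=\\s*(.+)$", line))[[1]]
    if (length(m) != 3)
      stop_mem("%s line %d: cannot parse '%s'", path, i, lines[i])
    key <- gsub("[\"']", "", m[2])
    val <- parse_toml_value(trimws(m[3]), path, i)
    doc <- assign_nested(doc, c(section, key), val)
  }
  doc
}

parse_toml_value <- function(txt, path, lineno) {
  if (grepl("^\\[.*\\]$", txt)) {
    inner <- trimws(sub("^\\[", "", sub("\\]$", "", txt)))
    if (!nzchar(inner)) return(character(0))
    parts <- trimws(strsplit(inner, ",")[[1]])
    return(unlist(lapply(parts, parse_toml_value, path, lineno)))
  }
  if (grepl("^\".*\"$|^'.*'$", txt)) return(substr(txt, 2, nchar(txt) - 1))
  if (txt %in% c("true", "false")) return(txt == "true")
  num <- suppressWarnings(as.numeric(txt))
  if (!is.na(num)) return(num)
  stop_mem("%s line %d: unsupported value '%s'", path, lineno, txt)
}

assign_nested <- function(doc, keys, val) {
  if (length(keys) == 1L) {
    doc[[keys]] <- val
    return(doc)
  }
  k <- keys[1]
  doc[[k]] <- assign_nested(doc[[k]] %||% list(), keys[-1], val)
  doc
}

#' Write a topology spec to a config file
#'
#' Serialises a `lipid_topology` in the same TOML dialect read by
#' [load_topology_spec()], so generated fixtures can travel with their
#' topology.
#'
#' @param spec a `lipid_topology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology_spec <- function(spec, path) {
  fmt_arr <- function(x) paste0("[", paste(sprintf('"%s"', x), collapse = ", "), "]")
  out <- character(0)
  for (res in names(spec$lipids)) {
    e <- spec$lipids[[res]]
    out <- c(out, sprintf("[lipids.%s]", res),
             sprintf("headgroup = %s", fmt_arr(e$headgroup)),
             sprintf("glycerol = %s", fmt_arr(e$glycerol)),
             sprintf("tail = %s", fmt_arr(e$tail)),
             sprintf("is_lipid = %s", tolower(e$is_lipid)), "")
  }
  out <- c(out, "[radii]",
           sprintf("%s = %g", names(spec$radii), spec$radii), "")
  if (!is.null(spec$params) && nrow(spec$params)) {
    p <- spec$params
    for (i in seq_len(nrow(p))) {
      out <- c(out, sprintf("[params.%s.%s]", p$res_name[i], p$atom_name[i]),
               sprintf("charge = %g", p$charge[i]),
               sprintf("sigma = %g", p$sigma[i]),
               sprintf("epsilon = %g", p$epsilon[i]), "")
    }
  }
  writeLines(out, path)
  invisible(path)
}

# ---- role / radius resolution -------------------------------------------

lipid_resnames <- function(spec) {
  names(spec$lipids)[vapply(spec$lipids, function(e) isTRUE(e$is_lipid),
                            logical(1))]
}

# Per-atom role: "head", "glycerol", "tail" for lipid atoms (an empty tail
# set means every non-head non-glycerol atom is tail), NA for non-lipids.
atom_roles <- function(atoms, spec) {
  roles <- rep(NA_character_, nrow(atoms))
  for (res in lipid_resnames(spec)) {
    e <- spec$lipids[[res]]
    sel <- atoms$res_name == res
    if (!any(sel)) next
    roles[sel] <- "tail"
    roles[sel & atoms$atom_name %in% e$glycerol] <- "glycerol"
    roles[sel & atoms$atom_name %in% e$headgroup] <- "head"
  }
  roles
}

# Van der Waals radius per atom; errors naming the first atom whose element
# has no radius entry.
atom_radii <- function(atoms, spec) {
  r <- unname(spec$radii[atoms$element])
  miss <- which(is.na(r))
  if (length(miss)) {
    i <- miss[1]
    stop_mem("no van der Waals radius for element '%s' (atom %s %s:%d serial %d)",
             atoms$element[i], atoms$atom_name[i], atoms$res_name[i],
             atoms$res_id[i], atoms$serial[i])
  }
  r
}

# Charge / LJ parameter lookup; errors naming the first unresolvable atom.
atom_params <- function(atoms, spec) {
  if (is.null(spec$params) || !nrow(spec$params))
    stop_mem("topology spec carries no charge/LJ parameter table")
  key <- paste(atoms$res_name, atoms$atom_name, sep = ":")
  tab_key <- paste(spec$params$res_name, spec$params$atom_name, sep = ":")
  idx <- match(key, tab_key)
  miss <- which(is.na(idx))
  if (length(miss)) {
    i <- miss[1]
    stop_mem("no charge/LJ parameters for atom %s of residue %s:%d (serial %d)",
             atoms$atom_name[i], atoms$res_name[i], atoms$res_id[i],
             atoms$serial[i])
  }
  spec$params[idx, c("charge", "sigma", "epsilon")]
}
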