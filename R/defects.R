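#' Build the analysis grid for a frame
#'
#' Lays a 2D grid over the xy plane of the box.  Cell counts are
#' `round(L/cell_size)` per axis and the actual cell size is recomputed as
#' `L/n` so the grid tiles the box exactly; with the default 0.1 nm cells
#' on a commensurate box each cell has area 0.01 nm^2.
#'
#' @param frame a [mem_frame] (only the box is used).
#' @param cell_size requested grid cell edge, nm (default 0.1).
#' @param periodic logical length-2, whether x and y wrap (default both).
#' @return A `grid_spec`.
#' @export
build_grid <- function(frame, cell_size = 0.1, periodic = c(TRUE, TRUE)) {
  if (!is.numeric(cell_size) || length(cell_size) != 1 ||
      !is.finite(cell_size) || cell_size <= 0)
    stop_mem("cell_size must be a single positive number (nm)")
  Lx <- frame$box[1]; Ly <- frame$box[2]
  nx <- as.integer(round(Lx / cell_size))
  ny <- as.integer(round(Ly / cell_size))
  if (nx < 1 || ny < 1)
    stop_mem("box (%.3f x %.3f nm) is smaller than one grid cell", Lx, Ly)
  structure(list(nx = nx, ny = ny,
                 cell_x = Lx / nx, cell_y = Ly / ny,
                 Lx = Lx, Ly = Ly, origin = c(0, 0),
                 periodic = rep(periodic, length.out = 2)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %.4f x %.4f nm (area %.5f nm^2)\n",
              x$nx, x$ny, x$cell_x, x$cell_y, x$cell_x * x$cell_y))
  invisible(x)
}

cell_area <- function(grid) grid$cell_x * grid$cell_y

grid_centers_x <- function(grid) grid$origin[1] + (seq_len(grid$nx) - 0.5) * grid$cell_x
grid_centers_y <- function(grid) grid$origin[2] + (seq_len(grid$ny) - 0.5) * grid$cell_y

#' Glycerol reference plane of one leaflet
#'
#' Mean z of all glycerol-role atoms of the leaflet's lipids.  The
#' deep/shallow threshold sits `depth_threshold` (default 0.1 nm = 1 A)
#' below this plane, toward the bilayer midplane.
#'
#' @param frame a [mem_frame].
#' @param spec a `lipid_topology`.
#' @param leaflet `"upper"` or `"lower"`.
#' @param assignment optional precomputed [assign_leaflets()] result.
#' @return Glycerol plane z in nm.
#' @export
compute_glycerol_plane <- function(frame, spec, leaflet = "upper",
                                   assignment = NULL) {
  assignment <- assignment %||% assign_leaflets(frame, spec)
  sel <- leaflet_atom_sel(frame, spec, assignment, leaflet)
  roles <- atom_roles(frame$atoms, spec)
  gly <- sel & !is.na(roles) & roles == "glycerol"
  if (!any(gly))
    stop_mem("leaflet '%s' has no glycerol-role atoms", leaflet)
  mean(frame$atoms$z[gly])
}

#' Project leaflet atoms onto the grid and classify coverage
#'
#' Implements the overlap inequality: a grid cell is overlapped by an atom
#' iff the 2D distance (with periodic xy wrap) between the cell center and
#' the atom's xy projection is at most the atom's van der Waals radius.
#' Headgroup atoms define headgroup coverage; all lipid atoms of the
#' leaflet define coverage above the deep plane (glycerol plane minus
#' `depth_threshold`, measured toward the midplane) and the per-cell
#' maximum exposed height.  Protein and solvent atoms never cover cells.
#'
#' @inheritParams compute_glycerol_plane
#' @param grid a `grid_spec` from [build_grid()].
#' @param glycerol_z optional precomputed glycerol plane z.
#' @param depth_threshold depth of the deep plane below the glycerol
#'   region, nm (default 0.1 nm = 1 A).
#' @return A `defect_cell_map` with per-cell logical matrices
#'   `covered_head` and `covered_above`, numeric `max_z` (NA where no atom
#'   overlaps), and the planes used.
#' @export
project_and_classify_cells <- function(frame, spec, grid,
                                       leaflet = "upper",
                                       assignment = NULL,
                                       glycerol_z = NULL,
                                       depth_threshold = 0.1) {
  assignment <- assignment %||% assign_leaflets(frame, spec)
  glycerol_z <- glycerol_z %||%
    compute_glycerol_plane(frame, spec, leaflet, assignment)
  sgn <- if (match.arg(leaflet, c("upper", "lower")) == "upper") 1 else -1

  sel <- leaflet_atom_sel(frame, spec, assignment, leaflet)
  atoms <- frame$atoms[sel, , drop = FALSE]
  roles <- atom_roles(frame$atoms, spec)[sel]
  radii <- if (nrow(atoms)) atom_radii(atoms, spec) else numeric(0)

  u <- sgn * atoms$z                    # depth coordinate: larger = closer to water
  glycerol_u <- sgn * glycerol_z
  deep_u <- glycerol_u - depth_threshold

  covered_head <- matrix(FALSE, grid$nx, grid$ny)
  covered_above <- matrix(FALSE, grid$nx, grid$ny)
  max_u <- matrix(-Inf, grid$nx, grid$ny)

  stamp <- function(k) {
    # linear indices of cells overlapped by atom k
    r <- radii[k]
    nwx <- ceiling(r / grid$cell_x) + 1L
    nwy <- ceiling(r / grid$cell_y) + 1L
    icx <- floor((atoms$x[k] - grid$origin[1]) / grid$cell_x) + 1L
    icy <- floor((atoms$y[k] - grid$origin[2]) / grid$cell_y) + 1L
    is <- (icx - nwx):(icx + nwx)
    js <- (icy - nwy):(icy + nwy)
    cx <- grid$origin[1] + (is - 0.5) * grid$cell_x
    cy <- grid$origin[2] + (js - 0.5) * grid$cell_y
    dx <- cx - atoms$x[k]
    dy <- cy - atoms$y[k]
    if (grid$periodic[1]) dx <- min_image(dx, grid$Lx)
    if (grid$periodic[2]) dy <- min_image(dy, grid$Ly)
    iw <- ((is - 1L) %% grid$nx) + 1L
    jw <- ((js - 1L) %% grid$ny) + 1L
    if (!grid$periodic[1]) { keep <- is >= 1L & is <= grid$nx; iw <- iw[keep]; dx <- dx[keep] }
    if (!grid$periodic[2]) { keep <- js >= 1L & js <= grid$ny; jw <- jw[keep]; dy <- dy[keep] }
    d2 <- outer(dx^2, dy^2, "+")
    hit <- which(d2 <= r * r, arr.ind = TRUE)
    if (!nrow(hit)) return(integer(0))
    # duplicates possible when the window wraps fully around a small box
    unique(cbind(iw[hit[, 1]], jw[hit[, 2]])) %*% c(1L, grid$nx) - grid$nx + 0
  }

  for (k in seq_len(nrow(atoms))) {
    idx <- stamp(k)
    if (!length(idx)) next
    max_u[idx] <- pmax(max_u[idx], u[k])
    if (u[k] > deep_u) covered_above[idx] <- TRUE
    if (roles[k] == "head") covered_head[idx] <- TRUE
  }

  max_z <- sgn * max_u
  max_z[!is.finite(max_u)] <- NA_real_
  structure(list(leaflet = leaflet, grid = grid,
                 covered_head = covered_head,
                 covered_above = covered_above,
                 max_z = max_z,
                 glycerol_z = glycerol_z,
                 deep_plane_z = glycerol_z - sgn * depth_threshold,
                 depth_threshold = depth_threshold,
                 leaflet_sign = sgn),
            class = "defect_cell_map")
}

#' @export
print.defect_cell_map <- function(x, ...) {
  cat(sprintf("<defect_cell_map> leaflet %s, %d x %d cells, %d headgroup-uncovered, glycerol z %.3f nm\n",
              x$leaflet, x$grid$nx, x$grid$ny, sum(!x$covered_head),
              x$glycerol_z))
  invisible(x)
}

#' Classify grid cells as defects
#'
#' A cell is a defect iff no headgroup atom overlaps it; a defect cell is
#' deep iff additionally no lipid atom above the deep plane overlaps it
#' (the highest exposed atom lies below the plane, or no atom underlies the
#' cell at all); otherwise it is shallow.
#'
#' @param map a `defect_cell_map`.
#' @return A character matrix over cells with values `"none"`,
#'   `"shallow"` or `"deep"`.
#' @export
detect_defect_cells <- function(map) {
  cls <- matrix("none", map$grid$nx, map$grid$ny)
  defect <- !map$covered_head
  cls[defect & map$covered_above] <- "shallow"
  cls[defect & !map$covered_above] <- "deep"
  cls
}

#' Merge defect cells into defects
#'
#' Connected components of defect cells under the relation
#' "center-to-center distance <= merge_distance" (default 0.3 nm) with
#' periodic xy wrap; at the default 0.1 nm grid this links up to
#' third-nearest neighbours.  `per_class` mode merges deep and shallow
#' cells separately (per-class size distributions); `all` mode merges every
#' defect cell and labels the merged defect deep if any member cell is deep.
#' Component identity is independent of enumeration order; defects are
#' numbered by their (min row, min column) member.
#'
#' @param cells classification matrix from [detect_defect_cells()], or a
#'   `defect_cell_map`.
#' @param grid the `grid_spec` (taken from the map when `cells` is one).
#' @param merge_distance nm, default 0.3.
#' @param mode `"per_class"` or `"all"`.
#' @param leaflet,frame_index optional labels carried into the result.
#' @return A `defect_set`: data.frame with one row per defect
#'   (`defect_id`, `leaflet`, `class`, `n_cells`, `area_nm2`, `frame`),
#'   member cells in `attr(, "cells")`.
#' @export
merge_cells_to_defects <- function(cells, grid = NULL, merge_distance = 0.3,
                                   mode = c("per_class", "all"),
                                   leaflet = NA_character_,
                                   frame_index = NA_integer_) {
  mode <- match.arg(mode)
  if (inherits(cells, "defect_cell_map")) {
    grid <- cells$grid
    if (is.na(leaflet)) leaflet <- cells$leaflet
    cells <- detect_defect_cells(cells)
  }
  if (is.null(grid)) stop_mem("grid must be supplied with a raw cell matrix")
  if (merge_distance < min(grid$cell_x, grid$cell_y))
    warning("merge_distance below the cell size: components degenerate to single cells")

  offsets <- merge_offsets(grid, merge_distance)
  groups <- if (mode == "per_class") list(deep = "deep", shallow = "shallow")
            else list(all = c("deep", "shallow"))

  out <- list()
  for (gname in names(groups)) {
    sel <- which(matrix(cells %in% groups[[gname]], grid$nx, grid$ny),
                 arr.ind = TRUE)
    if (!nrow(sel)) next
    comp <- connect_cells(sel, grid, offsets)
    for (ci in seq_along(comp)) {
      members <- comp[[ci]]
      cls <- if (mode == "per_class") gname
             else if (any(cells[members] == "deep")) "deep" else "shallow"
      out[[length(out) + 1L]] <- list(members = members, class = cls)
    }
  }
  # stable ordering by (min row, min col)
  if (length(out)) {
    ord <- order(vapply(out, function(d) min(d$members[, 1]), numeric(1)),
                 vapply(out, function(d) min(d$members[, 2]), numeric(1)),
                 vapply(out, function(d) d$class, character(1)))
    out <- out[ord]
  }
  df <- data.frame(defect_id = seq_along(out),
                   leaflet = rep(leaflet, length(out)),
                   class = vapply(out, function(d) d$class, character(1)),
                   n_cells = vapply(out, function(d) nrow(d$members), integer(1)),
                   frame = rep(frame_index, length(out)),
                   stringsAsFactors = FALSE)
  df$area_nm2 <- df$n_cells * cell_area(grid)
  attr(df, "cells") <- lapply(out, function(d) d$members)
  attr(df, "grid") <- grid
  attr(df, "mode") <- mode
  class(df) <- c("defect_set", "data.frame")
  df
}

# Integer cell offsets (di, dj) within merge range, excluding (0, 0);
# half-plane only (each pair visited once).
merge_offsets <- function(grid, merge_distance) {
  mx <- floor(merge_distance / grid$cell_x + 1e-9)
  my <- floor(merge_distance / grid$cell_y + 1e-9)
  off <- expand.grid(di = -mx:mx, dj = 0:my)
  off <- off[off$dj > 0 | (off$dj == 0 & off$di > 0), , drop = FALSE]
  d2 <- (off$di * grid$cell_x)^2 + (off$dj * grid$cell_y)^2
  off[d2 <= merge_distance^2 + 1e-12, , drop = FALSE]
}

# Union-find over the given cells (2-col index matrix) with wrapped
# neighbour offsets.  Returns a list of member matrices.
connect_cells <- function(sel, grid, offsets) {
  n <- nrow(sel)
  id <- matrix(0L, grid$nx, grid$ny)
  id[sel] <- seq_len(n)
  uf <- make_union_find(n)
  for (o in seq_len(nrow(offsets))) {
    ni <- sel[, 1] + offsets$di[o]
    nj <- sel[, 2] + offsets$dj[o]
    if (grid$periodic[1]) ni <- ((ni - 1L) %% grid$nx) + 1L
    if (grid$periodic[2]) nj <- ((nj - 1L) %% grid$ny) + 1L
    ok <- ni >= 1L & ni <= grid$nx & nj >= 1L & nj <= grid$ny
    if (!any(ok)) next
    nb <- id[cbind(ni[ok], nj[ok])]
    src <- which(ok)[nb > 0L]
    nb <- nb[nb > 0L]
    for (m in seq_along(src)) uf$union(src[m], nb[m])
  }
  roots <- uf$roots()
  lapply(split(seq_len(n), roots), function(ix) sel[ix, , drop = FALSE])
}

#' @export
print.defect_set <- function(x, ...) {
  cat(sprintf("<defect_set> %d defects (%d deep, %d shallow), total area %.4f nm^2 [%s merge]\n",
              nrow(x), sum(x$class == "deep"), sum(x$class == "shallow"),
              sum(x$area_nm2), attr(x, "mode")))
  invisible(x)
}

#' Per-frame defect statistics
#'
#' Counts, total and mean areas and the leaflet-area fraction, reported for
#' deep, shallow and total.  With zero defects the mean area is `NA` and
#' flagged undefined rather than reported as 0.
#'
#' @param defects a `defect_set` from one frame and leaflet.
#' @param leaflet_area leaflet area in nm^2; defaults to the grid's
#'   `Lx * Ly`.
#' @return A `defect_frame_stats` data.frame with rows deep/shallow/total.
#' @export
frame_defect_stats <- function(defects, leaflet_area = NULL) {
  grid <- attr(defects, "grid")
  leaflet_area <- leaflet_area %||% (grid$Lx * grid$Ly)
  one <- function(cls) {
    rows <- if (identical(cls, "total")) defects
            else defects[defects$class == cls, , drop = FALSE]
    n <- nrow(rows)
    tot <- sum(rows$area_nm2)
    data.frame(class = cls, n_defects = n, total_area_nm2 = tot,
               mean_area_nm2 = if (n) tot / n else NA_real_,
               mean_defined = n > 0L,
               area_fraction = tot / leaflet_area,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("deep"), one("shallow"), one("total"))
  attr(out, "leaflet_area") <- leaflet_area
  class(out) <- c("defect_frame_stats", "data.frame")
  out
}

#' Aggregate defect statistics across frames
#'
#' Per-class mean and standard deviation (population SD across frames) of
#' counts, areas and area fractions, plus the ratio of mean defect counts
#' to a reference aggregate (e.g. the cholesterol-free membrane).
#'
#' @param stats_list list of `defect_frame_stats`, one per frame.
#' @param reference optional `defect_aggregate` to take count ratios
#'   against.
#' @return A `defect_aggregate` data.frame.
#' @export
aggregate_trajectory_stats <- function(stats_list, reference = NULL) {
  if (!length(stats_list)) stop_mem("no per-frame statistics to aggregate")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  classes <- c("deep", "shallow", "total")
  rows <- lapply(classes, function(cls) {
    pick <- function(col) vapply(stats_list, function(s)
      s[[col]][s$class == cls], numeric(1))
    n <- pick("n_defects"); ta <- pick("total_area_nm2")
    af <- pick("area_fraction")
    ma <- vapply(stats_list, function(s) {
      v <- s$mean_area_nm2[s$class == cls]
      if (is.na(v)) 0 else v
    }, numeric(1))
    data.frame(class = cls, n_frames = length(stats_list),
               n_defects_mean = mean(n), n_defects_sd = pop_sd(n),
               total_area_mean = mean(ta), total_area_sd = pop_sd(ta),
               mean_area_mean = mean(ma), mean_area_sd = pop_sd(ma),
               area_fraction_mean = mean(af), area_fraction_sd = pop_sd(af),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(reference)) {
    ref_counts <- reference$n_defects_mean[match(classes, reference$class)]
    if (ref_counts[classes == "total"] == 0)
      stop_mem("reference aggregate has zero mean defect count")
    out$ratio_to_reference <- ifelse(ref_counts > 0,
                                     out$n_defects_mean / ref_counts,
                                     NA_real_)
  }
  class(out) <- c("defect_aggregate", "data.frame")
  out
}

#' Run the full packing-defect pipeline
#'
#' Convenience wrapper: leaflet assignment, glycerol plane, grid projection,
#' defect-cell classification, merging and per-frame statistics for a frame
#' or trajectory.
#'
#' @param x a [mem_frame] or [mem_trajectory].
#' @param spec a `lipid_topology`.
#' @param leaflet `"upper"`, `"lower"` or `"both"`.
#' @param cell_size,merge_distance,depth_threshold analysis parameters, nm.
#' @param mode merge mode, see [merge_cells_to_defects()].
#' @param frames optional integer vector of frame indices to analyse.
#' @return A `defect_analysis`: per-frame stats table, defect areas per
#'   class, and the aggregate.
#' @export
analyze_defects <- function(x, spec, leaflet = "upper", cell_size = 0.1,
                            merge_distance = 0.3, depth_threshold = 0.1,
                            mode = c("per_class", "all"), frames = NULL) {
  mode <- match.arg(mode)
  traj <- if (inherits(x, "mem_frame")) mem_trajectory(list(x)) else x
  if (!inherits(traj, "mem_trajectory"))
    stop_mem("x must be a mem_frame or mem_trajectory")
  frames <- frames %||% seq_along(traj$frames)
  leaflets <- if (leaflet == "both") c("upper", "lower") else leaflet

  per_frame <- list()
  stats_list <- list()
  areas <- list(deep = numeric(0), shallow = numeric(0), all = numeric(0))
  for (fi in frames) {
    fr <- traj$frames[[fi]]
    assignment <- assign_leaflets(fr, spec)
    grid <- build_grid(fr, cell_size)
    for (lf in leaflets) {
      map <- project_and_classify_cells(fr, spec, grid, lf, assignment,
                                        depth_threshold = depth_threshold)
      defects <- merge_cells_to_defects(map, merge_distance = merge_distance,
                                        mode = mode, frame_index = fi)
      st <- frame_defect_stats(defects)
      stats_list[[length(stats_list) + 1L]] <- st
      st2 <- st
      st2$frame <- fi
      st2$leaflet <- lf
      per_frame[[length(per_frame) + 1L]] <- st2
      areas$all <- c(areas$all, defects$area_nm2 * 100)  # nm^2 -> A^2
      for (cls in c("deep", "shallow"))
        areas[[cls]] <- c(areas[[cls]],
                          defects$area_nm2[defects$class == cls] * 100)
    }
  }
  structure(list(per_frame = do.call(rbind, per_frame),
                 stats_list = stats_list,
                 areas_A2 = areas,
                 aggregate = aggregate_trajectory_stats(stats_list),
                 params = list(leaflet = leaflet, cell_size = cell_size,
                               merge_distance = merge_distance,
                               depth_threshold = depth_threshold,
                               mode = mode)),
            class = "defect_analysis")
}

#' @export
print.defect_analysis <- function(x, ...) {
  cat(sprintf("<defect_analysis> %d frame-leaflet records, mode %s\n",
              length(x$stats_list), x$params$mode))
  print(x$aggregate)
  invisible(x)
}

#' @export
summary.defect_analysis <- function(object, ...) {
  cat("Packing-defect analysis (",
      sprintf("cell %.3g nm, merge %.3g nm, depth threshold %.3g nm, %s merge",
              object$params$cell_size, object$params$merge_distance,
              object$params$depth_threshold, object$params$mode),
      ")\n", sep = "")
  print(object$aggregate)
  invisible(object$aggregate)
}
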