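# Internal helpers: RNG scoping, periodic-boundary arithmetic, union-find.

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the
# caller's RNG state afterwards.  All stochastic generator functions route
# through this so that outputs are pure functions of (arguments, seed).
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Minimum-image displacement for an orthorhombic box: wraps each component
# of dx into (-L/2, L/2].
min_image <- function(dx, L) {
  dx - L * round(dx / L)
}

# Wrap coordinates into [0, L).
wrap_coord <- function(x, L) {
  x - L * floor(x / L)
}

# Minimum-image distance matrix between two point sets (n x 3 matrices)
# in an orthorhombic box (length-3).  Returns an na x nb matrix.
min_image_dist <- function(a, b, box) {
  dx <- min_image(outer(a[, 1], b[, 1], "-"), box[1])
  dy <- min_image(outer(a[, 2], b[, 2], "-"), box[2])
  dz <- min_image(outer(a[, 3], b[, 3], "-"), box[3])
  sqrt(dx * dx + dy * dy + dz * dz)
}

# Disjoint-set union-find kept in a closure to avoid copy-on-modify churn.
# Roots are always the smallest member index, so component labels are
# independent of the order in which unions are applied.
make_union_find <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) {
      nxt <- parent[i]
      parent[i] <<- root
      i <- nxt
    }
    root
  }
  union <- function(i, j) {
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    invisible(NULL)
  }
  roots <- function() vapply(seq_len(n), find, integer(1))
  list(find = find, union = union, roots = roots)
}

# Unique residue key: residue identity within a frame is the (res_name,
# res_id) pair (GRO residue numbers wrap; protein and lipid numbering may
# overlap).
residue_key <- function(atoms) paste(atoms$res_name, atoms$res_id, sep = ":")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mem <- function(...) stop(sprintf(...), call. = FALSE)
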