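# Palaeobiogeographic regionalization and spatial standardization of
# occurrence data.

# Unit icosahedron vertices and faces (faces recovered as the 20
# equilateral triangles over the 12 vertices).
icosa_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v / sqrt(rowSums(v^2))
}

icosa_faces <- function(v) {
  d <- as.matrix(stats::dist(v))
  edge <- min(d[d > 0]) + 1e-9
  faces <- list()
  for (i in 1:10) for (j in (i + 1):11) for (k in (j + 1):12) {
    if (d[i, j] < edge && d[i, k] < edge && d[j, k] < edge) {
      faces[[length(faces) + 1L]] <- c(i, j, k)
    }
  }
  do.call(rbind, faces)
}

#' Icosahedral hexagonal grid cell centres
#'
#' Subdivides each icosahedron face at frequency `resolution` and
#' projects the vertices to the sphere, yielding `10 * resolution^2 + 2`
#' near-equal-area cell centres (the Voronoi cells are hexagons plus the
#' 12 pentagons at the icosahedron vertices).
#'
#' @param resolution subdivision frequency (>= 1); 3 gives 92 cells.
#' @return data frame `cell_id`, `lat`, `lon` (degrees), plus unit `x`,
#'   `y`, `z`.
#' @export
hex_grid <- function(resolution = 3) {
  stopifnot(resolution >= 1)
  v <- icosa_vertices()
  f <- icosa_faces(v)
  pts <- list()
  for (r in seq_len(nrow(f))) {
    A <- v[f[r, 1], ]
    B <- v[f[r, 2], ]
    C <- v[f[r, 3], ]
    for (i in 0:resolution) for (j in 0:(resolution - i)) {
      p <- ((resolution - i - j) * A + i * B + j * C) / resolution
      pts[[length(pts) + 1L]] <- p / sqrt(sum(p^2))
    }
  }
  m <- do.call(rbind, pts)
  key <- apply(round(m, 6), 1, paste, collapse = "/")
  m <- m[!duplicated(key), , drop = FALSE]
  data.frame(
    cell_id = seq_len(nrow(m)),
    lat = asin(pmin(1, pmax(-1, m[, 3]))) * 180 / pi,
    lon = atan2(m[, 2], m[, 1]) * 180 / pi,
    x = m[, 1], y = m[, 2], z = m[, 3]
  )
}

# nearest grid cell (max dot product on the unit sphere) for lat/lon degrees
assign_cells <- function(lat, lon, grid) {
  if (any(lat < -90 | lat > 90 | lon < -180 | lon > 180, na.rm = TRUE)) {
    stop("coordinates outside [-90, 90] x [-180, 180]")
  }
  la <- lat * pi / 180
  lo <- lon * pi / 180
  u <- cbind(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
  dots <- u %*% t(as.matrix(grid[, c("x", "y", "z")]))
  grid$cell_id[max.col(dots)]
}

#' Bin occurrences into a hexagonal grid and build the grid--taxon matrix
#'
#' Each occurrence maps to exactly one cell (nearest centre on the
#' sphere). Only occupied cells enter the matrix.
#'
#' @param records occurrence table with `paleolat`, `paleolng`, `genus`.
#' @param resolution grid subdivision frequency (see [hex_grid()]).
#' @param grid optional precomputed [hex_grid()] (e.g. to share one grid
#'   across time slices).
#' @return object of class `grid_taxon_matrix`: list with `cells`
#'   (occupied cells: `cell_id`, `lat`, `lon`, `n_occ`), `pa` (binary
#'   occupied-cell x genus matrix) and `cell_of` (per-record cell id).
#' @export
hex_bin <- function(records, resolution = 3, grid = NULL) {
  grid <- grid %||% hex_grid(resolution)
  cell <- assign_cells(records$paleolat, records$paleolng, grid)
  occ_cells <- sort(unique(cell))
  genera <- sort(unique(records$genus))
  pa <- matrix(FALSE, length(occ_cells), length(genera),
               dimnames = list(occ_cells, genera))
  pa[cbind(match(cell, occ_cells), match(records$genus, genera))] <- TRUE
  cells <- grid[match(occ_cells, grid$cell_id), c("cell_id", "lat", "lon")]
  cells$n_occ <- as.integer(table(factor(cell, levels = occ_cells)))
  rownames(cells) <- NULL
  structure(list(cells = cells, pa = pa, cell_of = cell, grid = grid),
            class = "grid_taxon_matrix")
}

#' Modified Forbes dissimilarity between cell assemblages
#'
#' For two cells sharing `a` taxa with `b` and `c` unshared,
#' `n = a + b + c`, the corrected Forbes similarity is
#' \deqn{F' = \frac{a(n + \sqrt n)}{a(n + \sqrt n) + \tfrac{3}{2} b c}}
#' and the dissimilarity `1 - F'`: 0 for identical assemblages, 1 for
#' disjoint ones. Cells with no taxa are excluded with a warning.
#'
#' @param x a `grid_taxon_matrix` or binary cell x taxon matrix.
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
forbes_dissimilarity <- function(x) {
  pa <- if (inherits(x, "grid_taxon_matrix")) x$pa else x
  pa <- matrix(as.numeric(pa), nrow(pa), dimnames = dimnames(pa))
  rich <- rowSums(pa)
  if (any(rich == 0)) {
    warning("excluding ", sum(rich == 0), " empty cell(s)")
    pa <- pa[rich > 0, , drop = FALSE]
    rich <- rich[rich > 0]
  }
  if (nrow(pa) < 2L) stop("need >= 2 non-empty cells")
  a <- pa %*% t(pa)
  b <- outer(rich, rep(1, length(rich))) - a
  cc <- t(b)
  n <- a + b + cc
  num <- a * (n + sqrt(n))
  f <- num / (num + 1.5 * b * cc)
  f[!is.finite(f)] <- 0
  diag(f) <- 1
  d <- 1 - f
  (d + t(d)) / 2
}

#' Biogeographic regionalization by two independent methods
#'
#' Method A: partitioning around medoids on the modified-Forbes
#' dissimilarity matrix, with `k` chosen by average silhouette width over
#' `k_range`. Method B: greedy modularity community detection on the
#' cell co-occurrence graph weighted by shared-taxon counts. Both
#' labelings are returned with their adjusted-Rand agreement; the caller
#' delimits regions with reference to both -- the function never
#' auto-selects a final region set.
#'
#' @param x a `grid_taxon_matrix` or binary cell x taxon matrix.
#' @param k_range candidate cluster counts for PAM (default `2:8`).
#' @return list with `assignments` (data frame: `cell_id`, `region_pam`,
#'   `region_network`), `k_pam`, `silhouette`, `agreement` (ARI).
#' @export
regionalize <- function(x, k_range = 2:8) {
  pa <- if (inherits(x, "grid_taxon_matrix")) x$pa else x
  ids <- if (inherits(x, "grid_taxon_matrix")) x$cells$cell_id
         else seq_len(nrow(pa))
  nc <- nrow(pa)
  if (nc < 2L) {
    return(list(assignments = data.frame(cell_id = ids, region_pam = 1L,
                                         region_network = 1L),
                k_pam = 1L, silhouette = NA_real_, agreement = 1))
  }
  d <- stats::as.dist(forbes_dissimilarity(pa))
  k_range <- k_range[k_range < nc & k_range >= 2]
  if (length(k_range) == 0L) {
    # too few cells to partition: one region
    pam_lab <- rep(1L, nc)
    k_best <- 1L
    sil_best <- NA_real_
  } else {
    sil <- rep(-Inf, length(k_range))
    fits <- vector("list", length(k_range))
    for (i in seq_along(k_range)) {
      fits[[i]] <- cluster::pam(d, k_range[i])
      sil[i] <- fits[[i]]$silinfo$avg.width
    }
    best <- which.max(sil)
    pam_lab <- fits[[best]]$clustering
    k_best <- k_range[best]
    sil_best <- sil[best]
  }
  shared <- (pa %*% t(pa)) * 1
  diag(shared) <- 0
  g <- igraph::graph_from_adjacency_matrix(shared, mode = "undirected",
                                           weighted = TRUE)
  net_lab <- if (igraph::ecount(g) == 0) seq_len(nc)
             else igraph::membership(igraph::cluster_fast_greedy(g))
  list(
    assignments = data.frame(cell_id = ids,
                             region_pam = as.integer(pam_lab),
                             region_network = as.integer(net_lab)),
    k_pam = k_best,
    silhouette = sil_best,
    # igraph expects community ids below the vertex count; relabel to
    # 0-based before comparing (ARI is label-permutation invariant)
    agreement = igraph::compare(as.integer(factor(pam_lab)) - 1L,
                                as.integer(factor(net_lab)) - 1L,
                                method = "adjusted.rand")
  )
}

#' Subset occurrences to a moving spatial window
#'
#' A window is a per-time-bin set of grid cells tracking a focal region
#' as it drifts; the per-bin cell count and area are reported so that
#' "relatively stable in size" is auditable.
#'
#' @param records occurrence table with coordinates, `max_ma`, `min_ma`.
#' @param bins data frame `bin`, `max_ma`, `min_ma` (oldest first).
#' @param window_cells named list: for every bin name, the cell ids
#'   forming the window in that bin (error if a bin is missing).
#' @param resolution,grid grid specification as in [hex_bin()].
#' @return list with `subsets` (named list of record subsets; empty
#'   subsets are kept and logged in the audit) and `audit` (per bin:
#'   records in/out, window cell count, window area in km^2).
#' @export
spatial_window <- function(records, bins, window_cells, resolution = 3,
                           grid = NULL) {
  grid <- grid %||% hex_grid(resolution)
  missing_bins <- setdiff(bins$bin, names(window_cells))
  if (length(missing_bins)) {
    stop("window not defined in bin(s): ", paste(missing_bins, collapse = ", "))
  }
  cell <- assign_cells(records$paleolat, records$paleolng, grid)
  mid <- (records$max_ma + records$min_ma) / 2
  cell_area <- 4 * pi * 6371^2 / nrow(grid)
  subsets <- list()
  audit <- NULL
  for (i in seq_len(nrow(bins))) {
    bn <- as.character(bins$bin[i])
    inb <- mid <= bins$max_ma[i] & mid > bins$min_ma[i]
    keep <- inb & cell %in% window_cells[[bn]]
    subsets[[bn]] <- records[keep, , drop = FALSE]
    audit <- rbind(audit, data.frame(
      bin = bn, n_in_bin = sum(inb), n_in_window = sum(keep),
      n_cells = length(window_cells[[bn]]),
      area_km2 = length(window_cells[[bn]]) * cell_area
    ))
  }
  list(subsets = subsets, audit = audit)
}

# great-circle MST length (km) over cell centres
mst_length_km <- function(cells) {
  if (nrow(cells) < 2L) return(0)
  d <- geosphere::distm(cbind(cells$lon, cells$lat)) / 1000
  sum(vegan::spantree(stats::as.dist(d))$dist)
}

#' Spatial standardization by minimum spanning tree length
#'
#' Per time bin, occurrences are binned into grid cells and the MST over
#' occupied cell centres (great-circle edges, km) is measured. While the
#' MST length exceeds the threshold, the cell with the fewest occurrences
#' is removed and the tree rebuilt; among equally data-poor cells the
#' one whose deletion most reduces the MST length goes first, with the
#' cell id as a deterministic final tie-break. With
#' `threshold = "median"` the per-dataset median of the raw per-bin MST
#' lengths is used, which equalizes the spatial footprint across bins.
#'
#' @param records occurrence table with coordinates, `genus`, `max_ma`,
#'   `min_ma`.
#' @param bins data frame `bin`, `max_ma`, `min_ma`.
#' @param resolution,grid grid specification as in [hex_bin()].
#' @param threshold `"median"` or a length in km.
#' @return list with `records` (surviving rows, all bins), `audit` (per
#'   bin: raw and final MST length, cells before/after, removals) and
#'   `threshold` (km).
#' @export
mst_standardize <- function(records, bins, resolution = 3, grid = NULL,
                            threshold = "median") {
  grid <- grid %||% hex_grid(resolution)
  cell <- assign_cells(records$paleolat, records$paleolng, grid)
  mid <- (records$max_ma + records$min_ma) / 2
  bin_of <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(bins))) {
    inb <- mid <= bins$max_ma[i] & mid > bins$min_ma[i]
    bin_of[inb] <- as.character(bins$bin[i])
  }
  per_bin <- function(bn) {
    rows <- which(bin_of == bn)
    tab <- table(cell[rows])
    cells <- grid[match(as.integer(names(tab)), grid$cell_id),
                  c("cell_id", "lat", "lon")]
    cells$n_occ <- as.integer(tab)
    list(rows = rows, cells = cells)
  }
  state <- lapply(as.character(bins$bin), per_bin)
  names(state) <- as.character(bins$bin)
  raw_len <- vapply(state, function(s) mst_length_km(s$cells), numeric(1))
  thr <- if (identical(threshold, "median")) stats::median(raw_len)
         else as.numeric(threshold)
  audit <- NULL
  steps <- list()
  keep_rows <- integer(0)
  for (bn in names(state)) {
    s <- state[[bn]]
    cells <- s$cells
    len <- mst_length_km(cells)
    lens <- len
    removed <- 0L
    while (len > thr && nrow(cells) > 1L) {
      cand <- which(cells$n_occ == min(cells$n_occ))
      if (length(cand) > 1L) {
        red <- vapply(cand, function(i) {
          mst_length_km(cells[-i, , drop = FALSE])
        }, numeric(1))
        cand <- cand[order(red, cells$cell_id[cand])][1L]
      }
      cells <- cells[-cand, , drop = FALSE]
      len <- mst_length_km(cells)
      lens <- c(lens, len)
      removed <- removed + 1L
    }
    steps[[bn]] <- lens
    rows <- s$rows[cell[s$rows] %in% cells$cell_id]
    keep_rows <- c(keep_rows, rows)
    audit <- rbind(audit, data.frame(
      bin = bn, raw_mst_km = raw_len[[bn]], final_mst_km = len,
      n_cells_raw = nrow(s$cells), n_cells_final = nrow(cells),
      n_removed = removed
    ))
  }
  list(records = records[sort(keep_rows), , drop = FALSE],
       audit = audit, steps = steps, threshold = thr)
}
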