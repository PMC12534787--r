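#' Tunnel-finder parameters
#'
#' Parameter set for the built-in grid tunnel finder and for centerline
#' bookkeeping. Defaults mirror the standard tunnel-detection setup for
#' heme proteins: probe radius 5 A, interior threshold 1.1 A, origin radius
#' 5 A, bottleneck radius 1.2 A, surface cover radius 10 A. `grid_spacing`
#' controls the voxel size of the finder only.
#'
#' @param probe_radius Probe radius (A) separating bulk solvent from the
#'   protein interior; voxels at least this far from any atom count as
#'   solvent-exposed.
#' @param interior_threshold Minimum clearance (A) for a voxel to be
#'   traversable at all.
#' @param origin_radius Maximum distance (A) from the cofactor centroid at
#'   which the search may start.
#' @param bottleneck_radius Minimum acceptable tunnel bottleneck (A);
#'   narrower paths are discarded.
#' @param surface_cover_radius Radius (A) used both to delimit the
#'   near-boundary shell that counts as "outside" and to declare two tunnel
#'   exits distinct.
#' @param grid_spacing Voxel edge length (A) of the finder grid.
#' @return A `tg_tunnel_params` list.
#' @export
tunnel_params <- function(probe_radius = 5, interior_threshold = 1.1,
                          origin_radius = 5, bottleneck_radius = 1.2,
                          surface_cover_radius = 10, grid_spacing = 0.6) {
  p <- list(
    probe_radius = probe_radius, interior_threshold = interior_threshold,
    origin_radius = origin_radius, bottleneck_radius = bottleneck_radius,
    surface_cover_radius = surface_cover_radius, grid_spacing = grid_spacing
  )
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1 && v > 0,
                  logical(1)))) {
    stop("all tunnel parameters must be positive scalars", call. = FALSE)
  }
  if (bottleneck_radius > probe_radius) {
    stop("`bottleneck_radius` must not exceed `probe_radius`", call. = FALSE)
  }
  structure(p, class = "tg_tunnel_params")
}

empty_tunnels <- function() {
  tibble::tibble(
    tunnel_id = integer(), point = integer(),
    x = double(), y = double(), z = double(),
    radius = double(), arc_length = double()
  )
}

arc_lengths <- function(xyz) {
  if (nrow(xyz) < 2) return(rep(0, nrow(xyz)))
  seg <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

#' Read tunnel centerline profiles from MOLE-style JSON
#'
#' Accepts the tunnel profile layout exported by MOLE-like tools: a document
#' holding a list of tunnels, each an ordered list of centerline nodes with
#' coordinates and a local free radius. Field names are matched
#' case-insensitively (`X`/`x`, `FreeRadius`/`Radius`/`radius`; tunnels under
#' `Channels$Tunnels`, `Tunnels` or `tunnels`). Arc lengths and bottlenecks
#' are recomputed from the node coordinates, never trusted from the file.
#'
#' @param path Path to a JSON file.
#' @return A tibble of centerline points with columns `tunnel_id`, `point`,
#'   `x`, `y`, `z`, `radius`, `arc_length`; zero rows when the file holds no
#'   tunnels. Tunnels with fewer than two nodes are skipped with a warning.
#' @export
read_mole_tunnels <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed tunnel JSON '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  tl <- doc[["Channels"]][["Tunnels"]] %||% doc[["Tunnels"]] %||%
    doc[["tunnels"]] %||% list()
  out <- purrr::imap(tl, function(tun, i) {
    nodes <- tun[["Profile"]] %||% tun[["profile"]] %||% tun[["nodes"]] %||%
      tun[["points"]]
    if (is.null(nodes) || length(nodes) < 2) {
      warning("tunnel ", i, " in '", path, "' has fewer than 2 nodes; skipped",
              call. = FALSE)
      return(NULL)
    }
    get_num <- function(node, keys) {
      for (k in keys) if (!is.null(node[[k]])) return(as.numeric(node[[k]]))
      NA_real_
    }
    xyz <- t(vapply(nodes, function(nd) c(
      get_num(nd, c("X", "x")), get_num(nd, c("Y", "y")),
      get_num(nd, c("Z", "z"))
    ), numeric(3)))
    rad <- vapply(nodes, get_num, numeric(1),
                  keys = c("FreeRadius", "Radius", "radius", "free_radius"))
    if (anyNA(xyz) || anyNA(rad)) {
      stop("tunnel ", i, " in '", path, "': node missing coordinates or radius",
           call. = FALSE)
    }
    bad <- which(rad <= 0)
    if (length(bad)) {
      stop("tunnel ", i, " in '", path, "': nonpositive radius at node ",
           bad[1], call. = FALSE)
    }
    tibble::tibble(
      tunnel_id = as.integer(tun[["Id"]] %||% tun[["id"]] %||% i),
      point = seq_len(nrow(xyz)),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      radius = rad, arc_length = arc_lengths(xyz)
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) empty_tunnels() else out
}

#' Per-tunnel bottleneck radii
#'
#' @param tunnels A centerline tibble as returned by [read_mole_tunnels()] or
#'   [find_tunnels()].
#' @return Tibble `tunnel_id`, `bottleneck` (A), `length` (arc length, A),
#'   `n_points`.
#' @export
tunnel_bottlenecks <- function(tunnels) {
  if (is.null(tunnels) || nrow(tunnels) == 0) {
    return(tibble::tibble(tunnel_id = integer(), bottleneck = double(),
                          length = double(), n_points = integer()))
  }
  tunnels %>%
    dplyr::group_by(.data$tunnel_id) %>%
    dplyr::summarise(bottleneck = min(.data$radius),
                     length = max(.data$arc_length),
                     n_points = dplyr::n(), .groups = "drop")
}

#' Find tunnels from the cofactor to the surface on a clearance grid
#'
#' A deliberately simple stand-in for a full tunnel-detection program, so the
#' pipeline runs without external software: the protein is voxelised, each
#' voxel is assigned its clearance (distance to the nearest protein heavy
#' atom, atom centers without van der Waals radii), and a widest-bottleneck
#' (max-min clearance) Dijkstra search runs from the open voxel nearest the
#' cofactor centroid to the solvent shell near the bounding-box boundary.
#' Up to `k` tunnels with pairwise exit separation greater than
#' `surface_cover_radius` are returned, widest first; tunnels narrower than
#' `bottleneck_radius` are discarded. Voxel paths are smoothed with a short
#' moving average and radii are re-read from the clearance field.
#'
#' @param structure A `tg_structure` with cofactor atoms.
#' @param params A [tunnel_params()] list.
#' @param k Maximum number of distinct tunnels to return.
#' @param seed Integer; permutes the neighbour expansion order so equal-cost
#'   ties are broken reproducibly.
#' @return A centerline tibble (`tunnel_id`, `point`, `x`, `y`, `z`,
#'   `radius`, `arc_length`), zero rows when no tunnel at least
#'   `bottleneck_radius` wide reaches the surface.
#' @export
find_tunnels <- function(structure, params = tunnel_params(), k = 5, seed = 1) {
  stopifnot(inherits(structure, "tg_structure"))
  if (nrow(cofactor_atoms(structure)) == 0) {
    stop("tunnel search requires cofactor atoms", call. = FALSE)
  }
  pa <- protein_atoms(structure)
  coords <- atom_matrix(pa)
  sp <- params$grid_spacing
  pad <- params$probe_radius + 2 * sp
  lo <- apply(coords, 2, min) - pad
  hi <- apply(coords, 2, max) + pad
  dims <- as.integer(ceiling((hi - lo) / sp))
  cap <- params$probe_radius + sp

  field <- grid_distance_field(coords, lo, sp, dims, cap)
  open <- field >= params$interior_threshold

  # interior/exterior classification, so the search cannot leave the protein
  # and crawl along the solvent shell: bulk solvent is the probe-open region
  # connected to the box boundary; its probe-radius dilation is "exterior"
  # and absorbs paths (a tunnel ends where it meets the molecular surface)
  bulk <- flood_from_boundary(field >= params$probe_radius, dims)
  outside <- open & dilate_mask(bulk, dims, as.integer(ceiling(
    params$probe_radius / sp)))

  # voxel centers
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ii <- (seq_len(nx) - 0.5) * sp + lo[1]
  jj <- (seq_len(ny) - 0.5) * sp + lo[2]
  kk <- (seq_len(nz) - 0.5) * sp + lo[3]

  # source voxel: open voxel nearest the cofactor centroid, within origin_radius
  cen <- cofactor_centroid(structure)
  cx <- rep(ii, times = ny * nz)
  cy <- rep(rep(jj, each = nx), times = nz)
  cz <- rep(kk, each = nx * ny)
  d_cen2 <- (cx - cen[1])^2 + (cy - cen[2])^2 + (cz - cen[3])^2
  cand <- which(open & !outside)
  if (length(cand) == 0) {
    message("no open voxels; no tunnels found for ", structure$id)
    return(empty_tunnels())
  }
  src <- cand[which.min(d_cen2[cand])]
  if (sqrt(d_cen2[src]) > params$origin_radius) {
    message("no open voxel within origin_radius of the cofactor centroid; ",
            "no tunnels found for ", structure$id)
    return(empty_tunnels())
  }

  neigh_order <- with_local_seed(seed, sample.int(6L)) - 1L

  # one search per tunnel: after accepting an exit, voxels within
  # surface_cover_radius of it are closed and the search repeats, so distinct
  # tunnels never share a surface neighbourhood (exits are > surface_cover
  # apart) and a second channel is found through its own mouth rather than by
  # crawling along the surface from the first
  picked <- integer(0)
  paths <- list()
  open_now <- open
  for (rep in seq_len(k)) {
    res <- widest_path_grid(field, dims, open_now, outside, src - 1L,
                            neigh_order)
    best <- res$best
    parent <- res$parent
    exits <- which(outside & open_now & best >= params$bottleneck_radius)
    if (length(exits) == 0) break
    e <- exits[order(-best[exits], exits)][1]
    idx <- integer(0)
    v <- e
    repeat {  # parent[] is 0-based, -1 marks the source
      idx <- c(v, idx)
      pv <- parent[v]
      if (pv < 0L) break
      v <- pv + 1L
    }
    picked <- c(picked, e)
    paths[[length(paths) + 1]] <- idx
    # close only the surface shell around the accepted exit: the next search
    # may reuse interior passages but must surface > surface_cover away
    near <- outside &
      (cx - cx[e])^2 + (cy - cy[e])^2 + (cz - cz[e])^2 <=
        params$surface_cover_radius^2
    open_now <- open_now & !near
  }
  if (length(picked) == 0) {
    message("no tunnel wider than the bottleneck radius found for ",
            structure$id)
    return(empty_tunnels())
  }

  tunnels <- purrr::imap(paths, function(idx, tid) {
    xyz <- cbind(cx[idx], cy[idx], cz[idx])
    xyz <- smooth_path(xyz, window = 5L)
    # radii re-read from the clearance field at the nearest voxel
    gi <- pmin(pmax(floor((xyz[, 1] - lo[1]) / sp), 0), nx - 1)
    gj <- pmin(pmax(floor((xyz[, 2] - lo[2]) / sp), 0), ny - 1)
    gk <- pmin(pmax(floor((xyz[, 3] - lo[3]) / sp), 0), nz - 1)
    rad <- field[gi + nx * (gj + ny * gk) + 1]
    tibble::tibble(
      tunnel_id = tid, point = seq_len(nrow(xyz)),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      radius = rad, arc_length = arc_lengths(xyz)
    )
  })
  tunnels <- purrr::keep(tunnels, function(tb) min(tb$radius) >= params$bottleneck_radius)
  if (length(tunnels) == 0) {
    message("no tunnel wider than the bottleneck radius found for ",
            structure$id)
    return(empty_tunnels())
  }
  dplyr::bind_rows(tunnels) %>%
    dplyr::group_by(.data$tunnel_id) %>%
    dplyr::mutate(tunnel_id = dplyr::cur_group_id()) %>%
    dplyr::ungroup()
}

# centered moving average keeping the endpoints fixed
smooth_path <- function(xyz, window = 5L) {
  n <- nrow(xyz)
  if (n <= 2 || window < 3) return(xyz)
  half <- window %/% 2
  out <- xyz
  for (i in seq_len(n)) {
    a <- max(1, i - half); b <- min(n, i + half)
    out[i, ] <- colMeans(xyz[a:b, , drop = FALSE])
  }
  out[1, ] <- xyz[1, ]
  out[n, ] <- xyz[n, ]
  out
}

#' Export tunnel centerlines as TSV
#'
#' @param tunnels A centerline tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tunnel_tsv <- function(tunnels, path) {
  readr::write_tsv(tunnels, path)
  invisible(path)
}
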