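# in-code fixtures and independent oracles shared across the suite

# a random blob structure: n_res residues x atoms_per residue at random
# coordinates, plus a small random cofactor group
random_structure <- function(n_res = 40, atoms_per = 3, n_cof = 3,
                             box = 30, seed = 1) {
  set.seed(seed)
  n_at <- n_res * atoms_per
  atoms <- tibble::tibble(
    serial = seq_len(n_at + n_cof),
    name = c(rep(c("CA", "CB", "CG")[seq_len(atoms_per)], n_res),
             sprintf("C%d", seq_len(n_cof))),
    element = "C",
    chain = "A",
    resno = c(rep(seq_len(n_res), each = atoms_per), rep(n_res + 1L, n_cof)),
    ins = "",
    aa = c(rep(sample(c("A", "L", "G", "F", "R", "W"), n_res, replace = TRUE),
               each = atoms_per), rep(NA_character_, n_cof)),
    x = stats::runif(n_at + n_cof, 0, box),
    y = stats::runif(n_at + n_cof, 0, box),
    z = stats::runif(n_at + n_cof, 0, box),
    is_cofactor = c(rep(FALSE, n_at), rep(TRUE, n_cof))
  )
  residues <- dplyr::distinct(atoms[!atoms$is_cofactor, ],
                              chain, resno, ins, aa)
  st <- tunnelgrad:::new_structure(sprintf("RND%03d", seed), atoms, residues)
  attr(st, "cofactor_resid") <- "HEM"
  st
}

res_key <- function(df) {
  sort(paste(df$chain, df$resno, df$ins, sep = "/"))
}

# exhaustive nearest-atom oracle: for each query point, sort ALL protein
# atoms by (distance, serial), take the first n_atoms, map to residues,
# union over points
oracle_nearest_union <- function(structure, pts, n_atoms = 5) {
  pa <- protein_atoms(structure)
  out <- lapply(seq_len(nrow(pts)), function(i) {
    d <- sqrt((pa$x - pts[i, 1])^2 + (pa$y - pts[i, 2])^2 +
                (pa$z - pts[i, 3])^2)
    o <- order(d, pa$serial)[seq_len(min(n_atoms, nrow(pa)))]
    unique(pa[o, c("chain", "resno", "ins")])
  })
  dplyr::distinct(dplyr::bind_rows(out))
}

# wrap raw centerline points as a single-tunnel tibble (native nodes)
as_tunnel <- function(pts, radius = 2) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  tibble::tibble(
    tunnel_id = 1L, point = seq_len(nrow(pts)),
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    radius = radius, arc_length = c(0, cumsum(seg))
  )
}

# independent widest-bottleneck oracle: enumerate candidate bottleneck
# thresholds from high to low and BFS-check connectivity of source to any
# target over voxels with field >= threshold (targets absorb, as in the
# search contract); the first connecting threshold is the optimum
oracle_widest_bottleneck <- function(field, dims, open, target, source) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  neighbours <- function(v) {
    v0 <- v - 1L
    i <- v0 %% nx; j <- (v0 %/% nx) %% ny; k <- v0 %/% (nx * ny)
    out <- integer(0)
    if (i > 0) out <- c(out, v - 1L)
    if (i < nx - 1) out <- c(out, v + 1L)
    if (j > 0) out <- c(out, v - nx)
    if (j < ny - 1) out <- c(out, v + nx)
    if (k > 0) out <- c(out, v - nx * ny)
    if (k < nz - 1) out <- c(out, v + nx * ny)
    out
  }
  for (thr in sort(unique(field[open]), decreasing = TRUE)) {
    ok <- open & field >= thr
    if (!ok[source]) next
    seen <- logical(length(field))
    seen[source] <- TRUE
    queue <- source
    hit <- FALSE
    while (length(queue) > 0 && !hit) {
      v <- queue[1]; queue <- queue[-1]
      if (target[v] && v != source) { hit <- TRUE; break }
      if (target[v]) next
      for (w in neighbours(v)) {
        if (ok[w] && !seen[w]) {
          if (target[w]) { hit <- TRUE }
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    if (hit) return(thr)
  }
  -1
}

# write delimited text fixtures
write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
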