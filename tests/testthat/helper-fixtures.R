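# Shared fixture builders: tiny structures, hand-built ligands, text-format
# fixtures written to tempfiles, and a brute-force symmetric-RMSD oracle.

tiny_pdb_text <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C")
}

pdb_with_water_text <- function() {
  c(tiny_pdb_text()[1:2],
    "HETATM    3  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O")
}

write_fixture <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

ethanol_sdf_text <- function() {
  c("ethanol", "  fixture", "",
    "  9  8  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.0000    1.3000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.4000    0.9000    0.5000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.4000   -0.9000    0.5000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.4000    0.0000   -1.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.9000   -0.5000    0.9000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.9000   -0.5000   -0.9000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    3.0000    1.3000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  2  3  1  0", "  1  4  1  0", "  1  5  1  0",
    "  1  6  1  0", "  2  7  1  0", "  2  8  1  0", "  3  9  1  0",
    "M  END", "$$$$")
}

# quick structure from element vector + coordinate matrix (+ bonds)
make_ligand <- function(elements, xyz, bonds = NULL, name = "lig") {
  as_structure(
    tibble::tibble(element = elements, x = xyz[, 1], y = xyz[, 2],
                   z = xyz[, 3], is_hetero = TRUE, residue_name = "LIG"),
    name = name, kind = "ligand", bonds = bonds)
}

make_protein_atoms <- function(xyz, elements = "C") {
  as_structure(
    tibble::tibble(element = elements, x = xyz[, 1], y = xyz[, 2],
                   z = xyz[, 3], is_hetero = FALSE, residue_name = "GLY"),
    name = "prot", kind = "protein")
}

hexagon_xyz <- function(r = 1.4) {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  cbind(r * cos(ang), r * sin(ang), 0)
}

ring_bonds <- function(n, orders = 1L) {
  tibble::tibble(i = seq_len(n), j = c(seq_len(n)[-1], 1L),
                 order = rep_len(orders, n))
}

# apply a rigid rotation about z plus translation
rigid_move <- function(s, angle = 0, shift = c(0, 0, 0)) {
  rot <- matrix(c(cos(angle), -sin(angle), 0,
                  sin(angle), cos(angle), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- cbind(s$x, s$y, s$z) %*% t(rot)
  out <- s
  out$x <- xyz[, 1] + shift[1]
  out$y <- xyz[, 2] + shift[2]
  out$z <- xyz[, 3] + shift[3]
  out
}

# relabel atoms of a structure by permutation p (atom k becomes row p[k])
permute_atoms <- function(s, p) {
  inv <- order(p)
  bonds <- attr(s, "bonds")
  if (!is.null(bonds)) {
    bonds$i <- inv[bonds$i]
    bonds$j <- inv[bonds$j]
  }
  out <- s[p, ]
  attr(out, "mol_name") <- attr(s, "mol_name")
  attr(out, "kind") <- attr(s, "kind")
  attr(out, "bonds") <- bonds
  class(out) <- class(s)
  out
}

# brute-force oracle: minimum RMSD over ALL element-preserving,
# bond-and-order-preserving permutations (exhaustive recursion)
brute_symmetric_rmsd <- function(pred, ref) {
  hp <- heavy_atoms(pred)
  hr <- heavy_atoms(ref)
  stopifnot(nrow(hp) == nrow(hr))
  adj <- function(s) {
    b <- attr(s, "bonds")
    if (is.null(b)) b <- perceive_bonds(s)
    m <- matrix(0L, nrow(s), nrow(s))
    m[cbind(b$i, b$j)] <- b$order
    m[cbind(b$j, b$i)] <- b$order
    m
  }
  ar <- adj(hr)
  ap <- adj(hp)
  n <- nrow(hr)
  cand <- lapply(seq_len(n), function(i) which(hp$element == hr$element[i]))
  best <- Inf
  perm <- integer(n)
  used <- logical(n)
  recurse <- function(i) {
    if (i > n) {
      if (all(ap[perm, perm] == ar)) {
        r <- sqrt(mean((hp$x[perm] - hr$x)^2 + (hp$y[perm] - hr$y)^2 +
                         (hp$z[perm] - hr$z)^2))
        best <<- min(best, r)
      }
      return(invisible())
    }
    for (a in cand[[i]]) {
      if (!used[a]) {
        used[a] <<- TRUE
        perm[i] <<- a
        recurse(i + 1)
        used[a] <<- FALSE
      }
    }
  }
  recurse(1)
  best
}

# labelled feature tables + full target objects for pipeline tests
make_targets <- function(n, seed = 0, accuracy = 0.6, ...) {
  cfg <- scenario_config(n_targets = n, seed = seed,
                         program_accuracy = accuracy, ...)
  lapply(seq_len(n), function(i) {
    tg <- generate_target(cfg, i)
    grid <- build_grid(tg$protein)
    tab <- filter_empty(featurize_target(grid, tg$report))
    tg$table <- label_rows(tab, tg$truth$crystal_ligand)
    tg
  })
}

make_labelled_tables <- function(n, seed = 0, accuracy = 0.6, ...) {
  lapply(make_targets(n, seed, accuracy, ...), `[[`, "table")
}

# predicted top-1 site centroid for one generated target under a model
predict_site <- function(model, target) {
  scored <- score_voxels(model, target$table)
  ranked <- rank_voxels(scored)
  suppressWarnings(map_to_cavity(ranked[1, ], target$report$cavities))
}

# -- hand-built ligand library for the symmetry oracle --------------------

ligand_library <- function() {
  hex <- hexagon_xyz()
  sq <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1.5, 0), c(0, 1.5, 0))
  lib <- list(
    benzene = make_ligand(rep("C", 6), hex, ring_bonds(6, c(1L, 2L))),
    cyclohexane = make_ligand(rep("C", 6), hex, ring_bonds(6, 1L)),
    pyridine = make_ligand(c("N", rep("C", 5)), hex, ring_bonds(6, 1L)),
    furanish = make_ligand(c("O", rep("C", 4)),
                           rbind(c(0, 1.2, 0), c(1.1, 0.4, 0), c(0.7, -1, 0),
                                 c(-0.7, -1, 0), c(-1.1, 0.4, 0)),
                           ring_bonds(5, 1L)),
    square = make_ligand(rep("C", 4), sq, ring_bonds(4, 1L)),
    chain3 = make_ligand(c("C", "N", "O"),
                         rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.6, 0.6, 0)),
                         tibble::tibble(i = 1:2, j = 2:3, order = 1L)),
    chain4 = make_ligand(rep("C", 4),
                         rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0),
                               c(4.5, 0, 0)),
                         tibble::tibble(i = 1:3, j = 2:4, order = 1L)),
    tbutyl = make_ligand(rep("C", 4),
                         rbind(c(0, 0, 0), c(1.5, 0, 0), c(-0.75, 1.3, 0),
                               c(-0.75, -1.3, 0)),
                         tibble::tibble(i = c(1, 1, 1), j = 2:4, order = 1L)),
    neopentane = make_ligand(rep("C", 5),
                             rbind(c(0, 0, 0), c(1.5, 0, 0), c(-1.5, 0, 0),
                                   c(0, 1.5, 0), c(0, -1.5, 0)),
                             tibble::tibble(i = rep(1L, 4), j = 2:5,
                                            order = 1L)),
    diol = make_ligand(c("C", "C", "O", "O"),
                       rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.1, 0),
                             c(2.2, -1.1, 0)),
                       tibble::tibble(i = c(1, 2, 2), j = c(2, 3, 4),
                                      order = 1L)),
    toluene = make_ligand(rep("C", 7), rbind(hex, c(2.9, 0, 0)),
                          dplyr::bind_rows(ring_bonds(6, c(1L, 2L)),
                                           tibble::tibble(i = 1L, j = 7L,
                                                          order = 1L)))
  )
  lib
}

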