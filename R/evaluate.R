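#' Binding-site distance and hit classification
#'
#' Euclidean distance between the predicted site centroid and the mass
#' centre of the crystal ligand, classified against the standard 8
#' Angstrom threshold (a hit is *strictly* within the threshold).
#'
#' @param prediction A one-row `vd_site_prediction`, or a length-3
#'   numeric centroid.
#' @param crystal_ligand A ligand `vd_structure`, or a length-3 numeric
#'   centroid.
#' @param target_id Optional identifier carried into the result.
#' @param threshold Hit threshold in Angstrom (default 8).
#' @return A one-row tibble: `target_id`, `predicted_x/y/z`,
#'   `true_x/y/z`, `distance`, `hit_8A`.
#' @export
site_distance <- function(prediction, crystal_ligand, target_id = NA_character_,
                          threshold = 8) {
  pred <- if (is.numeric(prediction) && length(prediction) == 3) {
    unname(prediction)
  } else c(prediction$site_x, prediction$site_y, prediction$site_z)
  true <- if (is.numeric(crystal_ligand) && length(crystal_ligand) == 3) {
    unname(crystal_ligand)
  } else unname(centroid(crystal_ligand))
  d <- sqrt(sum((pred - true)^2))
  tibble::tibble(target_id = target_id,
                 predicted_x = pred[1], predicted_y = pred[2], predicted_z = pred[3],
                 true_x = true[1], true_y = true[2], true_z = true[3],
                 distance = d, hit_8A = d < threshold)
}

#' Plain heavy-atom RMSD under the given atom correspondence
#'
#' \eqn{\sqrt{\sum_i \left[(x_i - x_{i,ref})^2 + (y_i - y_{i,ref})^2 +
#' (z_i - z_{i,ref})^2\right] / N}} over the \eqn{N} heavy atoms, in
#' file order. No superposition is performed: docking convention places
#' both poses in the receptor frame already.
#'
#' @param pred,ref `vd_structure`s with the same heavy-atom count.
#' @return RMSD in Angstrom.
#' @export
plain_rmsd <- function(pred, ref) {
  hp <- heavy_atoms(pred); hr <- heavy_atoms(ref)
  if (nrow(hp) != nrow(hr)) {
    abort(sprintf("heavy-atom count mismatch: %d vs %d", nrow(hp), nrow(hr)))
  }
  sqrt(mean((hp$x - hr$x)^2 + (hp$y - hr$y)^2 + (hp$z - hr$z)^2))
}

# covalent radii (Angstrom) for distance-based bond perception
covalent_radius <- function(el) {
  radii <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
             Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39)
  r <- radii[el]
  r[is.na(r)] <- 1.2  # generous default for uncommon elements
  unname(r)
}

#' Perceive bonds from interatomic distances
#'
#' Used when a ligand arrives without connectivity (e.g. from PDB):
#' two heavy atoms are bonded when their distance is at most the sum of
#' covalent radii plus `tol`. All perceived bonds get order 1 and the
#' result is flagged as perceived.
#'
#' @param s A `vd_structure` (heavy atoms are used).
#' @param tol Tolerance added to the covalent-radius sum (default
#'   0.45 Angstrom).
#' @return Bond tibble (`i`, `j`, `order`) with attribute
#'   `"perceived" = TRUE`.
#' @export
perceive_bonds <- function(s, tol = 0.45) {
  hv <- heavy_atoms(s)
  xyz <- cbind(hv$x, hv$y, hv$z)
  d <- as.matrix(stats::dist(xyz))
  rr <- outer(covalent_radius(hv$element), covalent_radius(hv$element), "+")
  hit <- which(d <= rr + tol & d > 0.4 & upper.tri(d), arr.ind = TRUE)
  bonds <- tibble::tibble(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]),
                          order = 1L)
  attr(bonds, "perceived") <- TRUE
  bonds
}

ligand_graph <- function(atoms, bonds, element_codes) {
  g <- igraph::make_empty_graph(n = nrow(atoms), directed = FALSE)
  if (nrow(bonds) > 0) {
    g <- igraph::add_edges(g, rbind(bonds$i, bonds$j))
    igraph::E(g)$order <- bonds$order
  }
  igraph::V(g)$color <- element_codes[atoms$element]
  g
}

#' Symmetry-corrected heavy-atom RMSD
#'
#' The minimum of [plain_rmsd()] over all automorphisms of the
#' element- and bond-labelled molecular graph: chemically equivalent
#' atom relabelings (e.g. ring flips, rotating a ring's atom numbering)
#' must not inflate the RMSD. Correspondences are enumerated by VF2
#' graph-isomorphism search with element vertex colours and bond-order
#' edge colours. Connectivity is taken from each structure's bond
#' attribute (SDF/MOL2) and perceived from distances otherwise.
#'
#' For pathological ligands whose automorphism count exceeds `cap`
#' (default one million) the search is not attempted; the identity
#' correspondence is used and the result flagged.
#'
#' @param pred,ref `vd_structure`s of the same molecule (equal element
#'   multiset and bond graph).
#' @param target_id Optional identifier carried into the result.
#' @param cap Automorphism-count cap (default `1e6`).
#' @param threshold Pose hit threshold in Angstrom (default 2).
#' @return A one-row tibble: `target_id`, `rmsd`, `hit_2A`,
#'   `n_heavy_atoms`, `automorphism_count`, `bonds_perceived`,
#'   `capped`.
#' @export
symmetric_rmsd <- function(pred, ref, target_id = NA_character_,
                           cap = 1e6, threshold = 2) {
  hp <- heavy_atoms(pred); hr <- heavy_atoms(ref)
  if (nrow(hp) != nrow(hr) ||
      !identical(sort(hp$element), sort(hr$element))) {
    abort("pred and ref are not the same molecule (element multisets differ)")
  }
  bp <- attr(hp, "bonds"); br <- attr(hr, "bonds")
  perceived <- FALSE
  if (is.null(bp)) { bp <- perceive_bonds(hp); perceived <- TRUE }
  if (is.null(br)) { br <- perceive_bonds(hr); perceived <- TRUE }
  codes <- setNames(seq_along(unique(c(hp$element, hr$element))),
                    unique(c(hp$element, hr$element)))
  g_ref <- ligand_graph(hr, br, codes)
  g_pred <- ligand_graph(hp, bp, codes)

  n_auto <- tryCatch(
    suppressWarnings(as.numeric(
      igraph::count_automorphisms(g_ref,
                                  colors = igraph::V(g_ref)$color)$group_size)),
    error = function(e) NA_real_)
  if (!is.na(n_auto) && n_auto > cap) {
    warn(sprintf("automorphism count %g exceeds cap %g; using identity correspondence",
                 n_auto, cap))
    r <- plain_rmsd(hp, hr)
    return(tibble::tibble(target_id = target_id, rmsd = r,
                          hit_2A = r < threshold, n_heavy_atoms = nrow(hp),
                          automorphism_count = n_auto,
                          bonds_perceived = perceived, capped = TRUE))
  }
  maps <- igraph::graph.get.isomorphisms.vf2(
    g_ref, g_pred,
    vertex.color1 = igraph::V(g_ref)$color,
    vertex.color2 = igraph::V(g_pred)$color,
    edge.color1 = if (igraph::ecount(g_ref) > 0) igraph::E(g_ref)$order else NULL,
    edge.color2 = if (igraph::ecount(g_pred) > 0) igraph::E(g_pred)$order else NULL)
  if (length(maps) == 0) {
    abort("pred and ref molecular graphs are not isomorphic")
  }
  ref_xyz <- cbind(hr$x, hr$y, hr$z)
  pred_xyz <- cbind(hp$x, hp$y, hp$z)
  # each VF2 map is indexed by a pred vertex and yields its ref partner
  rmsds <- vapply(maps, function(m) {
    m <- as.integer(m)
    sqrt(mean(rowSums((pred_xyz - ref_xyz[m, , drop = FALSE])^2)))
  }, numeric(1))
  r <- min(rmsds)
  tibble::tibble(target_id = target_id, rmsd = r, hit_2A = r < threshold,
                 n_heavy_atoms = nrow(hp),
                 automorphism_count = length(maps),
                 bonds_perceived = perceived, capped = FALSE)
}

#' Summarise site or pose evaluation results per dataset
#'
#' Computes, per dataset, the accuracy (fraction of hits), mean and
#' median of the underlying metric (centroid distance for site results,
#' RMSD for pose results), plus an unweighted cross-dataset `"Average"`
#' row (each dataset contributes equally regardless of size).
#'
#' @param results Tibble of [site_distance()] or [symmetric_rmsd()]
#'   rows; an optional `dataset` column groups them (single dataset
#'   `"all"` otherwise).
#' @return A `vd_benchmark_summary` tibble: `dataset`, `n`, `accuracy`,
#'   `mean`, `median`, `metric`.
#' @export
summarize_benchmark <- function(results) {
  if (nrow(results) == 0) abort("no results to summarise")
  metric <- if ("distance" %in% names(results)) "distance" else if
    ("rmsd" %in% names(results)) "rmsd" else
    abort("results must carry a 'distance' or 'rmsd' column")
  hit_col <- if (metric == "distance") "hit_8A" else "hit_2A"
  if (!"dataset" %in% names(results)) results$dataset <- "all"
  per <- results |>
    dplyr::group_by(.data$dataset) |>
    dplyr::summarise(n = dplyr::n(),
                     accuracy = mean(.data[[hit_col]]),
                     mean = mean(.data[[metric]]),
                     median = median(.data[[metric]]),
                     .groups = "drop")
  avg <- tibble::tibble(dataset = "Average", n = sum(per$n),
                        accuracy = mean(per$accuracy),
                        mean = mean(per$mean), median = mean(per$median))
  out <- dplyr::bind_rows(per, avg)
  out$metric <- metric
  structure(out, class = c("vd_benchmark_summary", class(out)))
}

#' Plot a benchmark summary
#'
#' Accuracy, mean and median panels per dataset, mirroring the usual
#' presentation of site- and pose-prediction benchmarks.
#'
#' @param object A `vd_benchmark_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.vd_benchmark_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("dataset", "accuracy", "mean", "median")],
    -"dataset", names_to = "panel", values_to = "value")
  long$panel <- factor(long$panel, levels = c("accuracy", "mean", "median"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dataset, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Benchmark summary (",
                                 object$metric[1], ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
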