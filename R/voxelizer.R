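#' Build the voxel grid over a protein
#'
#' An axis-aligned cubic lattice covering the protein's padded
#' heavy-atom bounding box. The default 10 Angstrom edge samples the
#' whole structure coarsely enough that a binding site concentrates in
#' one box; the default 5 Angstrom padding keeps surface-adjacent poses
#' in bounds.
#'
#' @param protein A `vd_structure`.
#' @param resolution Voxel edge length in Angstrom (default 10).
#' @param padding Angstrom added on every side of the bounding box
#'   (default 5).
#' @return A `vd_grid`: list with `origin` (minimum corner), `resolution`,
#'   `dims` (nx, ny, nz) and `padding`.
#' @export
build_grid <- function(protein, resolution = 10, padding = 5) {
  if (resolution <= 0) abort("resolution must be positive")
  if (padding < 0) abort("padding must be non-negative")
  hv <- heavy_atoms(protein)
  lo <- c(min(hv$x), min(hv$y), min(hv$z)) - padding
  hi <- c(max(hv$x), max(hv$y), max(hv$z)) + padding
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / resolution - 1e-9)))
  structure(list(origin = unname(lo), resolution = resolution,
                 dims = dims, padding = padding),
            class = "vd_grid")
}

#' @export
print.vd_grid <- function(x, ...) {
  cat(sprintf("<vd_grid> %d x %d x %d voxels of %g A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$resolution,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Assign points to voxels
#'
#' Containing-box assignment under floor indexing with half-open
#' intervals `[lo, hi)`: a point exactly on a box boundary belongs to
#' the higher box. Points outside the grid (possible for far-flung
#' decoy poses) are clamped to the nearest boundary voxel with a
#' warning, which preserves the partition property.
#'
#' @param points Numeric matrix or data frame with 3 columns (x, y, z),
#'   or a single length-3 vector.
#' @param grid A `vd_grid`.
#' @return Integer matrix of 0-based voxel indices, one row per point.
#' @export
assign_voxel <- function(points, grid) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  idx <- floor(sweep(sweep(points, 2, grid$origin), 2, grid$resolution, "/"))
  clamped <- sweep(pmax(idx, 0), 2, grid$dims - 1L, pmin)
  if (any(clamped != idx)) {
    warn(sprintf("%d point(s) outside the grid clamped to boundary voxels",
                 sum(rowSums(clamped != idx) > 0)))
  }
  storage.mode(clamped) <- "integer"
  dimnames(clamped) <- list(NULL, c("ix", "iy", "iz"))
  clamped
}

#' Voxel centers for 0-based indices
#'
#' @param idx Integer matrix of voxel indices (columns ix, iy, iz).
#' @param grid A `vd_grid`.
#' @return Numeric matrix of center coordinates.
#' @export
voxel_center <- function(idx, grid) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3, byrow = TRUE)
  ctr <- sweep((as.matrix(idx) + 0.5) * grid$resolution, 2, grid$origin, "+")
  dimnames(ctr) <- list(NULL, c("cx", "cy", "cz"))
  ctr
}

meta_cols <- c("target_id", "ix", "iy", "iz", "cx", "cy", "cz", "label")

#' Feature columns of a voxel feature table
#'
#' @param table A voxel feature table.
#' @return Character vector of feature column names (everything except
#'   the voxel metadata and label columns).
#' @export
feature_cols <- function(table) setdiff(names(table), meta_cols)

#' Compute per-voxel consensus features for one target
#'
#' Every voxel of the grid gets one row. For each docking program P:
#' `sampled_pose_number_P_at_location` (how many of P's poses fall in
#' the voxel), `P_distance` (distance from the voxel center to the
#' nearest assigned pose mass-centre, missing when none) and
#' `P_best_score` (best score among assigned poses under P's score
#' polarity). For each cavity tool T: `T_min_pose_id` (best cavity rank
#' assigned to the voxel), `T_distance`, and T's descriptor columns
#' copied from the best-ranked assigned cavity. Programs recorded as
#' failures yield missing values everywhere (resolved later by mean
#' imputation).
#'
#' @param grid A `vd_grid`.
#' @param report A `vd_report`.
#' @param target_id Optional override of the report's target id.
#' @return A voxel feature table (tibble, one row per voxel, label
#'   `"unlabeled"`), with the grid stored in attribute `"grid"`.
#' @export
featurize_target <- function(grid, report, target_id = report$target_id) {
  dims <- grid$dims
  all_idx <- as.matrix(expand.grid(ix = 0:(dims[1] - 1L),
                                   iy = 0:(dims[2] - 1L),
                                   iz = 0:(dims[3] - 1L)))
  ctr <- voxel_center(all_idx, grid)
  tab <- tibble::tibble(
    target_id = target_id,
    ix = as.integer(all_idx[, 1]), iy = as.integer(all_idx[, 2]),
    iz = as.integer(all_idx[, 3]),
    cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3]
  )
  key <- voxel_key(tab$ix, tab$iy, tab$iz, dims)

  poses <- report$poses
  pose_key <- if (nrow(poses) > 0) {
    pidx <- suppressWarnings(assign_voxel(cbind(poses$x, poses$y, poses$z), grid))
    voxel_key(pidx[, 1], pidx[, 2], pidx[, 3], dims)
  } else integer()

  for (p in docking_programs()) {
    lab <- program_label(p)
    cnt_col <- paste0("sampled_pose_number_", lab, "_at_location")
    dst_col <- paste0(lab, "_distance")
    sc_col <- paste0(lab, "_best_score")
    if (p %in% report$failures) {
      tab[[cnt_col]] <- NA_real_; tab[[dst_col]] <- NA_real_; tab[[sc_col]] <- NA_real_
      next
    }
    sel <- which(poses$program == p)
    cnt <- rep(0, nrow(tab)); dst <- rep(NA_real_, nrow(tab)); bsc <- rep(NA_real_, nrow(tab))
    if (length(sel) > 0) {
      pk <- pose_key[sel]
      cnt <- as.numeric(tabulate_key(pk, nrow(tab)))
      pol <- score_polarity(p)
      for (k in unique(pk)) {
        rows <- sel[pk == k]
        d <- sqrt((poses$x[rows] - tab$cx[k])^2 + (poses$y[rows] - tab$cy[k])^2 +
                  (poses$z[rows] - tab$cz[k])^2)
        dst[k] <- min(d)
        sc <- poses$score[rows]
        sc <- sc[!is.na(sc)]
        if (length(sc) > 0) bsc[k] <- if (pol < 0) min(sc) else max(sc)
      }
    }
    tab[[cnt_col]] <- cnt; tab[[dst_col]] <- dst; tab[[sc_col]] <- bsc
  }

  cavities <- report$cavities
  cav_key <- if (nrow(cavities) > 0) {
    cidx <- suppressWarnings(assign_voxel(cbind(cavities$x, cavities$y, cavities$z), grid))
    voxel_key(cidx[, 1], cidx[, 2], cidx[, 3], dims)
  } else integer()

  for (tl in cavity_tools()) {
    lab <- program_label(tl)
    id_col <- paste0(lab, "_min_pose_id")
    dst_col <- paste0(lab, "_distance")
    failed <- tl %in% report$failures
    sel <- which(cavities$tool == tl)
    desc_names <- unique(unlist(purrr::map(cavities$descriptors[sel], names)))
    mid <- rep(NA_real_, nrow(tab)); dst <- rep(NA_real_, nrow(tab))
    desc_vals <- purrr::map(desc_names, ~ rep(NA_real_, nrow(tab)))
    names(desc_vals) <- desc_names
    if (!failed && length(sel) > 0) {
      ck <- cav_key[sel]
      for (k in unique(ck)) {
        rows <- sel[ck == k]
        best <- rows[which.min(cavities$cavity_id[rows])]
        mid[k] <- min(cavities$cavity_id[rows])
        d <- sqrt((cavities$x[rows] - tab$cx[k])^2 + (cavities$y[rows] - tab$cy[k])^2 +
                  (cavities$z[rows] - tab$cz[k])^2)
        dst[k] <- min(d)
        dd <- cavities$descriptors[[best]]
        for (nm in intersect(desc_names, names(dd))) desc_vals[[nm]][k] <- dd[[nm]]
      }
    }
    tab[[id_col]] <- mid; tab[[dst_col]] <- dst
    for (nm in desc_names) tab[[paste0(lab, "_", nm)]] <- desc_vals[[nm]]
  }

  tab$label <- "unlabeled"
  tab <- dplyr::relocate(tab, "label", .after = "cz")
  attr(tab, "grid") <- grid
  tab
}

voxel_key <- function(ix, iy, iz, dims) {
  1L + ix + dims[1] * (iy + dims[2] * iz)
}

tabulate_key <- function(key, nbins) tabulate(key, nbins = nbins)

count_cols <- function(table) {
  grep("^sampled_pose_number_.*_at_location$", names(table), value = TRUE)
}

min_id_cols <- function(table) {
  grep("_min_pose_id$", names(table), value = TRUE)
}

#' Drop voxels that received no pose and no cavity
#'
#' Empty grid boxes carry no consensus signal and are removed before
#' model training and scoring. A row is empty when every pose count is
#' zero (or missing) and no cavity was assigned. Idempotent.
#'
#' @param table A voxel feature table.
#' @return The filtered table (grid attribute preserved).
#' @export
filter_empty <- function(table) {
  cc <- count_cols(table); ic <- min_id_cols(table)
  cnts <- as.matrix(table[, cc, drop = FALSE])
  cnts[is.na(cnts)] <- 0
  has_pose <- rowSums(cnts) > 0
  has_cav <- if (length(ic) > 0) {
    rowSums(!is.na(as.matrix(table[, ic, drop = FALSE]))) > 0
  } else rep(FALSE, nrow(table))
  keep <- has_pose | has_cav
  if (!any(keep)) abort("all voxels are empty: no program produced any output")
  out <- table[keep, ]
  attr(out, "grid") <- attr(table, "grid")
  out
}

#' Label voxels with the crystal-ligand binding site
#'
#' The voxel containing the co-crystallised ligand's mass centre is the
#' single positive example; every other retained voxel is negative. If
#' no program touched that voxel (so it was removed by
#' [filter_empty()]), the row is re-inserted with missing features so
#' the positive example survives into training (filled later by mean
#' imputation).
#'
#' @param table A voxel feature table (typically after [filter_empty()]).
#' @param crystal_ligand A `vd_structure`, or a length-3 numeric
#'   centroid.
#' @param grid The grid; defaults to the table's `"grid"` attribute.
#' @return The labelled table.
#' @export
label_rows <- function(table, crystal_ligand, grid = attr(table, "grid")) {
  if (is.null(grid)) abort("no grid attached to the table; pass `grid`")
  cen <- if (is.numeric(crystal_ligand) && length(crystal_ligand) == 3) {
    crystal_ligand
  } else centroid(crystal_ligand)
  idx <- suppressWarnings(assign_voxel(cen, grid))
  table$label <- "negative"
  hit <- which(table$ix == idx[1] & table$iy == idx[2] & table$iz == idx[3])
  if (length(hit) == 1L) {
    table$label[hit] <- "positive"
  } else {
    ctr <- voxel_center(idx, grid)
    new_row <- table[0, ]
    new_row[1, "target_id"] <- table$target_id[1]
    new_row[1, c("ix", "iy", "iz")] <- as.list(as.integer(idx))
    new_row[1, c("cx", "cy", "cz")] <- as.list(as.numeric(ctr))
    new_row$label <- "positive"
    for (cc in count_cols(table)) new_row[[cc]] <- 0
    table <- dplyr::bind_rows(table, new_row)
  }
  grid_attr <- grid
  attr(table, "grid") <- grid_attr
  table
}

#' Fit and apply mean-value imputation
#'
#' Missing feature values (a program that failed, reported no score, or
#' never touched a voxel) are replaced with the arithmetic mean of the
#' observed values of that feature over the training tables. Columns
#' with no observed value at all are filled with 0 and flagged.
#' Inference-time tables are imputed with the training means only.
#'
#' @param tables A list of voxel feature tables (or a single table).
#' @return `fit_impute()`: named numeric vector of column means with
#'   attribute `"all_missing"` listing fully-missing columns.
#' @export
fit_impute <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  big <- dplyr::bind_rows(tables)
  fc <- feature_cols(big)
  means <- vapply(fc, function(cc) {
    v <- big[[cc]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  all_missing <- names(means)[is.na(means)]
  means[is.na(means)] <- 0
  if (length(all_missing) > 0) {
    warn(paste0("feature(s) with no observed value imputed as 0: ",
                paste(all_missing, collapse = ", ")))
  }
  attr(means, "all_missing") <- all_missing
  means
}

#' @rdname fit_impute
#' @param table A voxel feature table.
#' @param column_means Means from [fit_impute()].
#' @return `apply_impute()`: the table with every missing feature cell
#'   replaced; the cells filled are recorded in attribute `"imputed"`
#'   (tibble of row/feature). Columns in `column_means` absent from the
#'   table are added fully imputed; idempotent.
#' @export
apply_impute <- function(table, column_means) {
  filled <- list()
  for (cc in setdiff(names(column_means), names(table))) {
    table[[cc]] <- column_means[[cc]]
    filled[[cc]] <- seq_len(nrow(table))
  }
  for (cc in intersect(names(column_means), feature_cols(table))) {
    miss <- which(is.na(table[[cc]]))
    if (length(miss) > 0) {
      table[[cc]][miss] <- column_means[[cc]]
      filled[[cc]] <- miss
    }
  }
  imputed <- if (length(filled) == 0) {
    tibble::tibble(row = integer(), feature = character())
  } else {
    tibble::tibble(
      row = unlist(filled, use.names = FALSE),
      feature = rep(names(filled), lengths(filled))
    )
  }
  attr(table, "imputed") <- imputed
  table
}
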