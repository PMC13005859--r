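#' Write a cohort to disk
#'
#' Serializes a cohort as a JSON manifest plus plain-text payloads:
#' one TSV matrix per trial (regions as rows, header row of timepoint
#' indices), a behavioral CSV and a region-to-network CSV. The manifest
#' records the format version, TR, generator seed and per-trial shapes,
#' which is enough to reproduce deterministic stages bit-for-bit.
#'
#' @param cohort A `bold_cohort` with series.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bold_cohort"), !is.null(cohort$trials))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trials <- lapply(cohort$trials, function(tr) {
    fn <- sprintf("%s_%s.tsv", tr$subject, tr$trial)
    df <- data.frame(region = rownames(tr$X), tr$X, check.names = FALSE)
    write.table(df, file.path(dir, fn), sep = "\t", quote = FALSE,
                row.names = FALSE)
    data.frame(subject = tr$subject, trial = tr$trial, scene = tr$scene,
               duration_s = tr$duration_s, n_timepoints = tr$n_timepoints,
               path = fn, stringsAsFactors = FALSE)
  })
  trials <- do.call(rbind, trials)
  write.csv(cohort$behavior, file.path(dir, "behavior.csv"),
            row.names = FALSE)
  nm <- cohort$config$network_labels
  write.csv(data.frame(region = names(nm), network = unname(nm)),
            file.path(dir, "network_map.csv"), row.names = FALSE)
  manifest <- list(version = "1.0",
                   tr_s = cohort$config$tr_s,
                   seed = cohort$config$seed,
                   n_regions = cohort$config$n_regions,
                   subjects = unique(cohort$behavior$subject),
                   behavior = "behavior.csv",
                   network_map = "network_map.csv",
                   trials = trials)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}

#' Read a cohort from a manifest
#'
#' Validates the manifest exhaustively before materializing anything:
#' all referenced files must exist and every matrix must have the number
#' of timepoints the manifest declares; all violations are reported in a
#' single error.
#'
#' @param manifest_path Path to `manifest.json` written by
#'   [write_cohort()].
#' @return A `bold_cohort`.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop_("manifest not found: %s", manifest_path)
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  refs <- c(m$behavior, m$network_map, m$trials$path)
  missing <- refs[!file.exists(file.path(dir, refs))]
  if (length(missing) > 0)
    stop_("manifest references missing file(s): %s",
          paste(missing, collapse = ", "))
  behavior <- read.csv(file.path(dir, m$behavior), stringsAsFactors = FALSE)
  netmap <- read.csv(file.path(dir, m$network_map), stringsAsFactors = FALSE)
  labels <- setNames(netmap$network, netmap$region)
  shape_errors <- character(0)
  trials <- vector("list", nrow(m$trials))
  for (i in seq_len(nrow(m$trials))) {
    row <- m$trials[i, ]
    tab <- read.table(file.path(dir, row$path), sep = "\t", header = TRUE,
                      check.names = FALSE)
    X <- as.matrix(tab[, -1, drop = FALSE])
    rownames(X) <- tab$region
    if (ncol(X) != row$n_timepoints) {
      shape_errors <- c(shape_errors,
                        sprintf("%s: %d columns vs declared %d",
                                row$path, ncol(X), row$n_timepoints))
      next
    }
    trials[[i]] <- new_trial_series(row$subject, row$trial, row$scene,
                                    row$duration_s, X, m$tr_s)
  }
  if (length(shape_errors) > 0)
    stop_("matrix shape mismatch: %s", paste(shape_errors, collapse = "; "))
  structure(list(trials = trials, behavior = behavior,
                 config = list(tr_s = m$tr_s, seed = m$seed,
                               n_regions = m$n_regions,
                               network_labels = labels)),
            class = "bold_cohort")
}

#' Extract regional time-series from a 4D volume and a label atlas
#'
#' Optional volumetric front-end: reads a 4D NIfTI series and a 3D
#' integer-label atlas, resamples the atlas onto the series grid with
#' nearest-neighbor interpolation (label volumes must never be
#' interpolated continuously), and emits per-region summed and mean
#' time-series. Regions are matched against `network_table`, which must
#' cover every nonzero label present in the resampled atlas.
#'
#' @param series_path Path to the 4D NIfTI series.
#' @param atlas_path Path to the 3D integer-label NIfTI atlas.
#' @param network_table Data frame with columns `label` (integer),
#'   `region` (id) and optionally `network`.
#' @return List with `sum` and `mean` (region x timepoint matrices,
#'   rownames from `network_table$region`), `voxel_counts`, and
#'   `network_table`.
#' @export
extract_roi_series <- function(series_path, atlas_path, network_table) {
  assert_columns(network_table, c("label", "region"), "network_table")
  series <- RNifti::readNifti(series_path)
  atlas <- RNifti::readNifti(atlas_path)
  sdim <- dim(series)
  if (length(sdim) != 4) stop_("series must be 4D, got %dD", length(sdim))
  adim <- dim(atlas)
  if (length(adim) != 3) stop_("atlas must be 3D, got %dD", length(adim))
  A_epi <- RNifti::xform(series)
  A_atl <- RNifti::xform(atlas)
  if (identical(sdim[1:3], adim) &&
      isTRUE(all.equal(unclass(A_epi), unclass(A_atl), tolerance = 1e-6))) {
    lab <- array(as.integer(round(atlas)), dim = adim)
  } else {
    # nearest-neighbor pull: map every series voxel center through world
    # space into atlas voxel indices (0-based convention of the xforms)
    grid <- as.matrix(expand.grid(i = seq_len(sdim[1]) - 1,
                                  j = seq_len(sdim[2]) - 1,
                                  k = seq_len(sdim[3]) - 1))
    world <- cbind(grid, 1) %*% t(unclass(A_epi))
    vox <- round(world %*% t(solve(unclass(A_atl))))[, 1:3]
    inside <- vox[, 1] >= 0 & vox[, 1] < adim[1] &
      vox[, 2] >= 0 & vox[, 2] < adim[2] &
      vox[, 3] >= 0 & vox[, 3] < adim[3]
    if (!any(inside))
      stop_("series and atlas volumes do not overlap in world space")
    lab <- array(0L, dim = sdim[1:3])
    idx <- vox[inside, , drop = FALSE] + 1
    lab[grid[inside, , drop = FALSE] + 1] <-
      as.integer(round(atlas[idx]))
  }
  present <- sort(setdiff(unique(as.integer(lab)), 0L))
  unknown <- setdiff(present, network_table$label)
  if (length(unknown) > 0)
    stop_("atlas label(s) absent from network_table: %s",
          paste(unknown, collapse = ", "))
  n_tp <- sdim[4]
  smat <- matrix(NA_real_, nrow(network_table), n_tp,
                 dimnames = list(network_table$region, seq_len(n_tp)))
  mmat <- smat
  counts <- setNames(integer(nrow(network_table)), network_table$region)
  vol <- array(series, dim = c(prod(sdim[1:3]), n_tp))
  labv <- as.integer(lab)
  for (r in seq_len(nrow(network_table))) {
    sel <- labv == network_table$label[r]
    counts[r] <- sum(sel)
    if (counts[r] > 0) {
      sub <- vol[sel, , drop = FALSE]
      smat[r, ] <- colSums(sub)
      mmat[r, ] <- colMeans(sub)
    }
  }
  list(sum = smat, mean = mmat, voxel_counts = counts,
       network_table = network_table)
}

#' Write accumulated event features as TSV
#'
#' One row per (trial, network): subject, trial, network, count and the
#' comma-joined event timepoints.
#'
#' @param ef An `event_features` from [accumulate_events()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_event_features <- function(ef, path) {
  nets <- colnames(ef$counts)
  rows <- do.call(rbind, lapply(seq_len(nrow(ef$meta)), function(i) {
    data.frame(subject = ef$meta$subject[i], trial = ef$meta$trial[i],
               network = nets,
               count = as.integer(ef$counts[i, nets]),
               event_timepoints = vapply(nets, function(nw)
                 paste(ef$events[[i]][[nw]], collapse = ","), ""),
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a robustness grid to disk
#'
#' One TSV per network (theta_min, theta_max, pvalue, pearson_r) plus a
#' JSON summary of the significant fractions.
#'
#' @param rg A `robustness_grid`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_robustness_grid <- function(rg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nw in unique(rg$results$network)) {
    sub <- rg$results[rg$results$network == nw,
                      c("theta_min", "theta_max", "pvalue", "pearson_r")]
    write.table(sub, file.path(dir, sprintf("grid_%s.tsv", nw)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(alpha = rg$alpha, seed = rg$seed,
                            significant_fraction =
                              as.list(rg$significant_fraction)),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Write cohort FC features to disk
#'
#' The trials x edges matrix as TSV plus the edge-index map as CSV
#' (edge_id, region_i, region_j).
#'
#' @param feats Output of [cohort_fc()] or [random_window_control()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_fc_features <- function(feats, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(data.frame(trial_key = rownames(feats$fc), feats$fc,
                         check.names = FALSE),
              file.path(dir, "fc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ei <- feats$edge_index
  write.csv(ei[, intersect(c("edge_id", "region_i", "region_j", "i", "j"),
                           names(ei))],
            file.path(dir, "edge_index.csv"), row.names = FALSE)
  write.csv(feats$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}
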