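#' Quality-control filter for cell records
#'
#' Retains only cells that passed QC, are positive for the fluorescent
#' reporter (tdTomato in the Cre/reporter design this models), and are
#' classified as neuronal (excitatory or inhibitory).  Input order is
#' preserved.
#'
#' @param cells data frame with one row per cell and columns \code{cell_id},
#'   \code{dataset_id}, \code{class_label} (\code{"excitatory"},
#'   \code{"inhibitory"} or \code{"unknown"}), \code{reporter_positive},
#'   \code{qc_pass} (logicals)
#' @return the retained rows, same column order
#' @export
qc_filter_cells <- function(cells) {
  need <- c("cell_id", "class_label", "reporter_positive", "qc_pass")
  miss <- setdiff(need, names(cells))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  keep <- cells$qc_pass & cells$reporter_positive &
    cells$class_label %in% c("excitatory", "inhibitory")
  out <- cells[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no cells survive QC filtering")
  nc_log(sprintf("qc_filter_cells: %d in, %d retained", nrow(cells), nrow(out)))
  rownames(out) <- NULL
  out
}

# Properties whose raw values are log10-transformed before analysis, to
# mitigate right skew.
LOG10_PROPERTIES <- c("input_resistance", "tau", "capacitance", "rheobase",
                      "max_firing_frequency", "ahp_amplitude",
                      "adaptation_ratio", "io_slope", "latency",
                      "branchiness", "max_branch_order", "total_length",
                      "total_volume")

#' Transform a cell-level property table
#'
#' Applies per-property transforms declared in the metadata (currently
#' \code{"none"} or \code{"log10"}) and enforces the sag validity rule: sag is
#' only interpretable when measured at a comparable holding voltage, so it is
#' set to missing for cells whose \code{vm_for_sag} falls outside
#' [-110, -90] mV or whose \code{resting_potential} is below -80 mV.
#' Non-positive values hitting a log10 transform become missing with a
#' warning (adaptation ratio and AHP amplitude can legitimately be <= 0).
#'
#' @param props data frame, one row per cell; must contain \code{cell_id};
#'   property columns named in \code{meta$property}; optionally
#'   \code{vm_for_sag} and \code{resting_potential} (mV) when a \code{sag}
#'   column is present
#' @param meta data frame with columns \code{property}, \code{transform}
#'   (\code{"none"}/\code{"log10"}), \code{family} (\code{"ephys"}/\code{"morph"})
#' @return the transformed table
#' @export
transform_properties <- function(props, meta) {
  stopifnot(is.data.frame(props), is.data.frame(meta))
  unknown <- setdiff(meta$property, names(props))
  if (length(unknown) > 0)
    stop("properties in metadata absent from table: ",
         paste(unknown, collapse = ", "))
  bad_tr <- setdiff(meta$transform, c("none", "log10"))
  if (length(bad_tr) > 0) stop("unknown transform: ", paste(bad_tr, collapse = ", "))

  out <- props
  if ("sag" %in% meta$property && "sag" %in% names(out)) {
    vm <- out[["vm_for_sag"]]
    rp <- out[["resting_potential"]]
    invalid <- rep(FALSE, nrow(out))
    if (!is.null(vm)) invalid <- invalid | is.na(vm) | vm < -110 | vm > -90
    if (!is.null(rp)) invalid <- invalid | (!is.na(rp) & rp < -80)
    if (any(invalid, na.rm = TRUE)) {
      nc_log(sprintf("transform_properties: sag invalidated for %d cells",
                     sum(invalid)))
      out$sag[invalid] <- NA_real_
    }
  }
  for (p in meta$property[meta$transform == "log10"]) {
    v <- out[[p]]
    nonpos <- !is.na(v) & v <= 0
    if (any(nonpos)) {
      warning(sprintf("%d non-positive '%s' values set to missing before log10",
                      sum(nonpos), p))
      v[nonpos] <- NA_real_
    }
    out[[p]] <- log10(v)
  }
  out
}

#' Branch points per micron of neurite
#'
#' @param n_branches branch count
#' @param total_length total neurite length in microns
#' @return branchiness (branches per micron); missing with a warning where
#'   total_length <= 0
#' @export
derive_branchiness <- function(n_branches, total_length) {
  bad <- !is.na(total_length) & total_length <= 0
  if (any(bad)) warning(sum(bad), " cells with non-positive total_length; branchiness set to missing")
  out <- n_branches / total_length
  out[bad] <- NA_real_
  out
}

#' Group cells into cell types and apply per-analysis size thresholds
#'
#' Cell types are defined by Cre line x layer (possibly a layer group) x
#' class.  A type enters the electrophysiology analysis only if it has at
#' least \code{min_ephys} cells in both the RNA-seq and ephys modalities, and
#' the morphology analysis only with at least \code{min_morph} cells in both
#' RNA-seq and morphology.
#'
#' @param cells data frame with columns \code{cell_id}, \code{cre_line},
#'   \code{layer}, \code{class_label}, and logical modality columns
#'   \code{has_rnaseq}, \code{has_ephys}, \code{has_morph}
#' @param grouping data frame with columns \code{type_id}, \code{cre_line},
#'   \code{layer}, \code{class_label}; several rows may share a
#'   \code{type_id} to merge layers
#' @param min_ephys,min_morph cell-count minima per modality pair
#' @return data frame of type definitions with member lists (list-columns)
#'   and retention flags per analysis
#' @export
assign_cell_types <- function(cells, grouping, min_ephys = 6, min_morph = 3) {
  key <- function(df) paste(df$cre_line, df$layer, df$class_label, sep = "|")
  gk <- key(grouping)
  if (anyDuplicated(gk))
    stop("grouping keys mapped to multiple type_ids: ",
         paste(unique(gk[duplicated(gk)]), collapse = ", "))
  ck <- key(cells)
  hit <- match(ck, gk)
  if (anyNA(hit))
    stop("cells matching no grouping key: ",
         paste(utils::head(cells$cell_id[is.na(hit)], 5), collapse = ", "))
  type_of <- grouping$type_id[hit]

  ids <- unique(grouping$type_id)
  rows <- lapply(ids, function(tid) {
    sel <- which(type_of == tid)
    sub <- cells[sel, , drop = FALSE]
    cls <- unique(grouping$class_label[grouping$type_id == tid])
    if (length(cls) != 1)
      stop("type ", tid, " mixes cell classes: ", paste(cls, collapse = ", "))
    mr <- sub$cell_id[sub$has_rnaseq]
    me <- sub$cell_id[sub$has_ephys]
    mm <- sub$cell_id[sub$has_morph]
    data.frame(type_id = tid,
               cre_line = grouping$cre_line[match(tid, grouping$type_id)],
               class_label = cls,
               n_rnaseq = length(mr), n_ephys = length(me), n_morph = length(mm),
               retained_ephys = length(mr) >= min_ephys & length(me) >= min_ephys,
               retained_morph = length(mr) >= min_morph & length(mm) >= min_morph,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  memb <- lapply(ids, function(tid) {
    sel <- which(type_of == tid)
    sub <- cells[sel, , drop = FALSE]
    list(rnaseq = sub$cell_id[sub$has_rnaseq],
         ephys = sub$cell_id[sub$has_ephys],
         morph = sub$cell_id[sub$has_morph])
  })
  names(memb) <- ids
  attr(out, "members") <- memb
  nc_log(sprintf("assign_cell_types: %d types, %d retained (ephys), %d retained (morph)",
                 nrow(out), sum(out$retained_ephys), sum(out$retained_morph)))
  out
}
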