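#' Atlas definition: labelled parcellation plus ROI table
#'
#' Couples a label volume (nonnegative integers, 0 = background) with an
#' ordered ROI table. The row order of `roi_table` is fixed and defines the
#' column order of every lesion load vector derived from the atlas. The
#' reference cohort atlas has 150 ROIs: 123 grey-matter regions, 21
#' white-matter tracts and 6 commissural-tract portions, all left-hemisphere.
#'
#' @param labels 3-D integer array of voxel labels.
#' @param grid a [voxel_grid()].
#' @param roi_table data.frame with columns `label` (positive integer, unique),
#'   `name` (character) and `tissue_class` (one of `"grey"`, `"white"`,
#'   `"commissural"`).
#' @return An `atlas_definition`.
#' @export
atlas_definition <- function(labels, grid, roi_table) {
  vol <- brain_volume(labels, grid)
  lab <- vol$data
  if (anyNA(lab) || any(lab != round(lab)) || min(lab) < 0) {
    stop("atlas labels must be nonnegative integers", call. = FALSE)
  }
  roi_table <- as.data.frame(roi_table)
  required <- c("label", "name", "tissue_class")
  if (!all(required %in% names(roi_table))) {
    stop("`roi_table` needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  roi_table$label <- as.integer(roi_table$label)
  roi_table$name <- as.character(roi_table$name)
  roi_table$tissue_class <- as.character(roi_table$tissue_class)
  if (anyDuplicated(roi_table$label)) {
    stop("duplicate labels in `roi_table`", call. = FALSE)
  }
  if (!all(roi_table$tissue_class %in% c("grey", "white", "commissural"))) {
    stop("tissue_class must be grey, white or commissural", call. = FALSE)
  }
  present <- sort(unique(lab[lab > 0]))
  if (!all(present %in% roi_table$label)) {
    stop("label volume contains labels absent from `roi_table`: ",
         paste(setdiff(present, roi_table$label), collapse = ", "),
         call. = FALSE)
  }
  if (!all(roi_table$label %in% present)) {
    stop("ROI(s) with zero voxels in label volume: ",
         paste(setdiff(roi_table$label, present), collapse = ", "),
         call. = FALSE)
  }
  counts <- tabulate(lab[lab > 0], nbins = max(roi_table$label))
  structure(
    list(labels = array(as.integer(lab), dim(lab)), grid = vol$grid,
         roi_table = roi_table, n_rois = nrow(roi_table),
         voxel_counts = counts[roi_table$label]),
    class = "atlas_definition"
  )
}

#' @export
print.atlas_definition <- function(x, ...) {
  cat("<atlas_definition> ", x$n_rois, " ROIs (",
      paste(table(factor(x$roi_table$tissue_class,
                         c("grey", "white", "commissural"))),
            c("grey", "white", "commissural"), collapse = ", "),
      ") on ", paste(x$grid$dims, collapse = "x"), " grid\n", sep = "")
  invisible(x)
}

#' Read / write the ROI lookup table
#'
#' Tab-delimited, three columns: `label`, `name`, `tissue_class`.
#'
#' @param path file path.
#' @return data.frame (for the reader); `path` invisibly (for the writer).
#' @export
read_roi_table <- function(path) {
  if (!file.exists(path)) stop("no such ROI table: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("label", "name", "tissue_class")
  if (!all(required %in% names(tab))) {
    stop("ROI table must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  tab[required]
}

#' @rdname read_roi_table
#' @param roi_table data.frame as in [atlas_definition()].
#' @export
write_roi_table <- function(roi_table, path) {
  utils::write.table(roi_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load an atlas from a label volume and ROI table file
#'
#' @param volume_path NIfTI label volume.
#' @param table_path tab-delimited ROI table.
#' @return An `atlas_definition`.
#' @export
load_atlas <- function(volume_path, table_path) {
  vol <- load_volume(volume_path, expect_binary = FALSE)
  atlas_definition(vol$data, vol$grid, read_roi_table(table_path))
}
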