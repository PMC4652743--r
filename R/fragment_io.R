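#' Default target-to-fragment map for the multiplex assay
#'
#' Maps each assay target to a dye and an expected amplicon size with a
#' matching tolerance.  The hTERT splice variants share one primer pair
#' (single dye); the alpha deletion removes 36 bp and the beta deletion
#' 182 bp from the full-length amplicon, so the four variants separate
#' cleanly by fragment size.  hTR and GAPDH are carried on a second dye.
#' These sizes are the simulator's convention; real runs supply their own
#' map matching their primer design.
#'
#' @param tolerance_bp Half-width of the size-matching window in base pairs.
#' @return A `target_map` data frame with columns `target`, `dye`,
#'   `size_bp`, `tolerance_bp`.
#' @export
default_target_map <- function(tolerance_bp = 1) {
  out <- data.frame(
    target = c("hTR", "GAPDH", "a+b+", "a-b+", "a+b-", "a-b-"),
    dye = c("HEX", "HEX", "FITC", "FITC", "FITC", "FITC"),
    size_bp = c(125, 90, 457, 421, 275, 239),
    tolerance_bp = tolerance_bp
  )
  class(out) <- c("target_map", "data.frame")
  out
}

#' Validate a target map
#'
#' Checks required columns and that size windows within one dye are
#' disjoint.
#'
#' @param target_map A `target_map` data frame.
#' @return The map, invisibly, if valid.
#' @export
validate_target_map <- function(target_map) {
  req <- c("target", "dye", "size_bp", "tolerance_bp")
  miss <- setdiff(req, names(target_map))
  if (length(miss))
    stop("target map is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(target_map$target))
    stop("duplicated targets in target map", call. = FALSE)
  if (any(target_map$size_bp <= 0) || any(target_map$tolerance_bp < 0))
    stop("target map sizes must be positive and tolerances >= 0",
         call. = FALSE)
  for (d in unique(target_map$dye)) {
    sub <- target_map[target_map$dye == d, ]
    if (nrow(sub) < 2) next
    sub <- sub[order(sub$size_bp), ]
    lo <- sub$size_bp - sub$tolerance_bp
    hi <- sub$size_bp + sub$tolerance_bp
    if (any(hi[-nrow(sub)] >= lo[-1]))
      stop("overlapping size windows within dye '", d, "'", call. = FALSE)
  }
  invisible(target_map)
}

# assign each record to a target (or "unassigned") by dye + size window;
# records on the size-standard dye are never assigned
assign_targets <- function(peaks, target_map, size_standard_dye = "ROX") {
  target <- rep("unassigned", nrow(peaks))
  usable <- !(peaks$dye %in% size_standard_dye)
  for (r in seq_len(nrow(target_map))) {
    hit <- usable &
      peaks$dye == target_map$dye[r] &
      abs(peaks$size_bp - target_map$size_bp[r]) <= target_map$tolerance_bp[r]
    target[hit] <- target_map$target[r]
  }
  target
}

#' Read and annotate a CE fragment-peak table
#'
#' Reads a comma-separated peak export (one row per called peak) and assigns
#' every record to an assay target by dye and fragment-size window.  Records
#' on the size-standard dye are excluded from assignment; records matching
#' no window are labelled `"unassigned"`.  When several in-window peaks
#' exist for one (sample, target) — e.g. PCR stutter — only the
#' maximum-area peak is retained (ties broken by smaller size).
#'
#' @param path CSV file with at least the columns `sample_id`, `dye`,
#'   `size_bp`, `height`, `area`; optional `day`, `condition` and `cells`
#'   columns are carried through.
#' @param target_map A `target_map`; see [default_target_map()].
#' @param size_standard_dye Dye label(s) of the sizing standard
#'   (default `"ROX"`).
#' @return An annotated `peak_table` data frame with a `target` column.
#' @export
read_peak_table <- function(path, target_map = default_target_map(),
                            size_standard_dye = "ROX") {
  validate_target_map(target_map)
  peaks <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "dye", "size_bp", "height", "area")
  miss <- setdiff(req, names(peaks))
  if (length(miss))
    stop("peak table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  annotate_peak_table(peaks, target_map, size_standard_dye)
}

#' @rdname read_peak_table
#' @param peaks An in-memory peak data frame (same columns as the CSV).
#' @export
annotate_peak_table <- function(peaks, target_map = default_target_map(),
                                size_standard_dye = "ROX") {
  validate_target_map(target_map)
  peaks$target <- assign_targets(peaks, target_map, size_standard_dye)
  assigned <- peaks[peaks$target != "unassigned", , drop = FALSE]
  rest <- peaks[peaks$target == "unassigned", , drop = FALSE]
  if (nrow(assigned)) {
    # max-area rule per (sample, target); ties -> smaller size
    ord <- order(assigned$sample_id, assigned$target, -assigned$area,
                 assigned$size_bp)
    assigned <- assigned[ord, , drop = FALSE]
    keep <- !duplicated(assigned[, c("sample_id", "target")])
    assigned <- assigned[keep, , drop = FALSE]
  }
  out <- rbind(assigned, rest)
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Write a peak table to CSV
#'
#' @param peaks A `peak_table` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  write.csv(peaks, path, row.names = FALSE)
  invisible(path)
}

#' Collapse an annotated peak table to a sample-by-target abundance matrix
#'
#' @param peaks An annotated `peak_table` (with `target` and `cells`
#'   columns); unassigned records are dropped.  Missing (sample, target)
#'   combinations get area 0.
#' @return An `abundance_matrix` data frame: one row per sample with
#'   `sample_id`, `day`, `condition`, `cells` and one raw-area column per
#'   target.
#' @export
collapse_to_matrix <- function(peaks) {
  if (!("target" %in% names(peaks)))
    stop("peak table has no 'target' column; annotate it first",
         call. = FALSE)
  if (!("cells" %in% names(peaks)))
    stop("peak table has no 'cells' column (cell count per sample)",
         call. = FALSE)
  peaks <- peaks[peaks$target != "unassigned", , drop = FALSE]
  meta_cols <- intersect(c("sample_id", "day", "condition", "cells"),
                         names(peaks))
  if (!nrow(peaks)) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(ALL_TARGETS)),
                                  ALL_TARGETS), check.names = FALSE)
    out <- cbind(data.frame(sample_id = character(), day = integer(),
                            condition = character(), cells = integer()),
                 out)
    class(out) <- c("abundance_matrix", "data.frame")
    return(out)
  }
  cc <- unique(peaks[, c("sample_id", "cells")])
  if (anyDuplicated(cc$sample_id))
    stop("conflicting cell counts for sample(s): ",
         paste(unique(cc$sample_id[duplicated(cc$sample_id)]),
               collapse = ", "), call. = FALSE)
  meta <- unique(peaks[, meta_cols, drop = FALSE])
  meta <- meta[order(meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  areas <- matrix(0, nrow = nrow(meta), ncol = length(ALL_TARGETS),
                  dimnames = list(NULL, ALL_TARGETS))
  ridx <- match(peaks$sample_id, meta$sample_id)
  cidx <- match(peaks$target, ALL_TARGETS)
  ok <- !is.na(cidx)
  areas[cbind(ridx[ok], cidx[ok])] <- peaks$area[ok]
  out <- cbind(meta, as.data.frame(areas, check.names = FALSE))
  class(out) <- c("abundance_matrix", "data.frame")
  out
}
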