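# Purity-index assignment of anatomical nodes to functional systems and
# intra-/inter-module labelling of edges.

#' Assign regions to functional systems by the purity index
#'
#' Each region is assigned the modal (most frequent) nonzero functional-
#' system label among its voxels; the purity index is the modal count
#' divided by the total nonzero count. Ties are broken toward the lowest
#' system index and flagged. Regions carrying a subcortical flag are
#' assigned to the eighth, subcortical module regardless of their counts.
#'
#' @param label_counts data frame as produced by
#'   [generate_voxel_label_counts()]: a `region` column, one count column
#'   per cortical system (any subset of [system_names()] order is accepted
#'   as long as columns are named by system), and a logical `subcortical`
#'   column.
#' @return object of class `module_partition`: data frame with `region`,
#'   `system`, `purity`, `tie`.
#' @export
assign_systems_by_purity <- function(label_counts) {
  stopifnot(is.data.frame(label_counts), "region" %in% names(label_counts))
  sys_cols <- intersect(system_names()[1:7], names(label_counts))
  if (!length(sys_cols)) stop("no system count columns found")
  counts <- as.matrix(label_counts[, sys_cols, drop = FALSE])
  if (any(counts < 0)) stop("negative voxel counts")
  subcortical <- if ("subcortical" %in% names(label_counts))
    as.logical(label_counts$subcortical) else rep(FALSE, nrow(counts))
  totals <- rowSums(counts)
  if (any(totals == 0 & !subcortical))
    stop(sprintf("region(s) with no nonzero-label voxels: %s",
                 paste(label_counts$region[totals == 0 & !subcortical],
                       collapse = ", ")))
  best <- max.col(counts, ties.method = "first")   # lowest index on ties
  tie <- rowSums(counts == counts[cbind(seq_len(nrow(counts)), best)]) > 1
  purity <- ifelse(totals > 0,
                   counts[cbind(seq_len(nrow(counts)), best)] / totals, 1)
  system <- sys_cols[best]
  system[subcortical] <- "subcortical"
  tie[subcortical] <- FALSE
  out <- data.frame(region = label_counts$region, system = system,
                    purity = purity, tie = tie, stringsAsFactors = FALSE)
  class(out) <- c("module_partition", "data.frame")
  out
}

#' Classify edges as intra- or inter-module
#'
#' @param edges two-column matrix of node indices (rows of the partition).
#' @param partition an [assign_systems_by_purity()] result.
#' @return data frame with one row per edge: `i`, `j`, `system_i`,
#'   `system_j`, `type` (`"intra"`/`"inter"`) and a symmetric,
#'   order-independent `category` string (`"intra:limbic"` or
#'   `"inter:default_mode-frontoparietal"`, systems sorted).
#' @export
label_edges_by_module <- function(edges, partition) {
  stopifnot(inherits(partition, "module_partition"))
  edges <- as.matrix(edges)
  stopifnot(ncol(edges) == 2,
            all(edges >= 1), all(edges <= nrow(partition)))
  si <- partition$system[edges[, 1L]]
  sj <- partition$system[edges[, 2L]]
  intra <- si == sj
  category <- ifelse(intra, paste0("intra:", si),
                     paste0("inter:", pmin(si, sj), "-", pmax(si, sj)))
  data.frame(i = edges[, 1L], j = edges[, 2L],
             system_i = si, system_j = sj,
             type = ifelse(intra, "intra", "inter"),
             category = category, stringsAsFactors = FALSE)
}

#' Tally edge categories
#'
#' @param edge_labels a [label_edges_by_module()] result.
#' @return named integer vector of counts per category, descending.
#' @export
edge_category_counts <- function(edge_labels) {
  sort(table(edge_labels$category), decreasing = TRUE)
}
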