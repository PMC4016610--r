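#' Mutually exclusive clustering of entities
#'
#' @param ids Entity identifiers.
#' @param clusters Cluster label per entity.
#' @return An `fs_partition` tibble with columns `id`, `cluster`.
#' @export
partition <- function(ids, clusters) {
  ids <- as.character(ids); clusters <- as.character(clusters)
  if (length(ids) != length(clusters)) stopf("ids and clusters differ in length")
  if (anyDuplicated(ids)) stopf("an entity may belong to only one cluster")
  structure(tibble::tibble(id = ids, cluster = clusters),
            class = c("fs_partition", class(tibble::tibble())))
}

# named list: cluster label -> character vector of member ids
partition_sets <- function(part) {
  stopifnot(inherits(part, "fs_partition"))
  split(part$id, part$cluster)
}

#' Cluster size table of a partition
#'
#' @param x An `fs_partition`.
#' @param ... Unused.
#' @return Tibble `cluster`, `n` sorted by decreasing size.
#' @export
#' @exportS3Method generics::glance
glance.fs_partition <- function(x, ...) {
  dplyr::arrange(dplyr::count(tibble::as_tibble(x), .data$cluster, name = "n"),
                 dplyr::desc(.data$n), .data$cluster)
}
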