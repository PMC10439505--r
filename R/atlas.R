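#' Generate a block-contiguous network atlas
#'
#' Assigns `n_parcels` nodes to `n_networks` functional networks as
#' contiguous blocks of near-equal size (the first `n_parcels %% n_networks`
#' networks receive one extra node), mimicking the layout of standard
#' parcellations in which nodes of one network occupy consecutive indices.
#' The assignment is fully deterministic; `seed` is accepted for interface
#' uniformity with the other generators.
#'
#' @param n_parcels number of nodes (>= 1).
#' @param n_networks number of network labels (<= `n_parcels`).
#' @param seed unused; assignments are deterministic.
#' @return data frame with columns `node_id` (1..P), `label` ("n<i>") and
#'   `network` ("net<k>").
#' @examples
#' table(gen_atlas(10, 3)$network)  # block sizes 4, 3, 3
#' @export
gen_atlas <- function(n_parcels, n_networks, seed = NULL) {
  stopifnot(n_parcels >= 1, n_networks >= 1)
  if (n_networks > n_parcels)
    stop("invalid atlas config: n_networks (", n_networks,
         ") exceeds n_parcels (", n_parcels, ")")
  sizes <- rep(n_parcels %/% n_networks, n_networks)
  extra <- n_parcels %% n_networks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  data.frame(
    node_id = seq_len(n_parcels),
    label = paste0("n", seq_len(n_parcels)),
    network = rep(paste0("net", seq_len(n_networks)), times = sizes),
    stringsAsFactors = FALSE
  )
}

validate_atlas <- function(atlas) {
  stopifnot(is.data.frame(atlas),
            all(c("node_id", "network") %in% names(atlas)))
  if (!identical(as.integer(atlas$node_id), seq_len(nrow(atlas))))
    stop("atlas node_id must be contiguous 1..P in order")
  if (anyNA(atlas$network)) stop("every node needs a network label")
  invisible(atlas)
}

#' Read/write an atlas lookup table (TSV: node_id, label, network)
#' @param path file path.
#' @param atlas data frame as returned by [gen_atlas()].
#' @return `read_atlas()` returns the atlas data frame.
#' @export
read_atlas <- function(path) {
  atlas <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_atlas(atlas)
}

#' @rdname read_atlas
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(atlas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
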