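#' Canonical seven-network assignment for a 200-parcel cortex
#'
#' Returns the packaged parcel-to-network lookup modelled on a 200-parcel
#' functional parcellation grouped into the seven canonical large-scale
#' resting-state networks (visual, sensorimotor, dorsal attention, ventral
#' attention, limbic, frontoparietal, default mode). Parcels of a network are
#' contiguous in index order, which fixes a reproducible ordering for the
#' synthetic gradient geometry.
#'
#' @param P integer, number of parcels. Only scaling of the canonical block
#'   sizes is supported; `P` must be a multiple-free rescale target with at
#'   least `7` parcels.
#' @return A `network_assignment`: data.frame with columns `parcel_id`
#'   (1-based integer) and `network` (factor with levels in first-appearance
#'   order).
#' @examples
#' tab <- canonical_networks()
#' table(tab$network)
#' @export
canonical_networks <- function(P = 200L) {
  P <- as.integer(P)
  if (P < 7L) stop("need at least one parcel per network")
  base_sizes <- c(Vis = 29L, SMN = 35L, DAN = 26L, VAN = 26L,
                  Limbic = 12L, FPN = 26L, DMN = 46L)
  if (P == 200L) {
    sizes <- base_sizes
  } else {
    sizes <- pmax(1L, as.integer(round(base_sizes * P / 200)))
    # adjust the largest network so sizes sum to P exactly
    sizes[which.max(sizes)] <- sizes[which.max(sizes)] + (P - sum(sizes))
    if (any(sizes < 1L)) stop("cannot place 7 non-empty networks in ", P, " parcels")
  }
  network_assignment(data.frame(
    parcel_id = seq_len(P),
    network = rep(names(sizes), times = sizes),
    stringsAsFactors = FALSE
  ))
}

#' Construct a network assignment
#'
#' Validates a parcel-to-network table: every parcel assigned exactly once,
#' network labels kept as a factor in first-appearance order.
#'
#' @param df data.frame with columns `parcel_id`, `network`.
#' @return A validated `network_assignment` data.frame.
#' @export
network_assignment <- function(df) {
  stopifnot(is.data.frame(df), all(c("parcel_id", "network") %in% names(df)))
  df$parcel_id <- as.integer(df$parcel_id)
  if (anyNA(df$parcel_id)) stop("non-integer parcel_id in network lookup")
  if (anyDuplicated(df$parcel_id))
    stop("duplicate parcel_id in network lookup: ",
         paste(unique(df$parcel_id[duplicated(df$parcel_id)]), collapse = ", "))
  if (!setequal(df$parcel_id, seq_len(nrow(df))))
    stop("parcel_id must cover 1..P without gaps")
  df <- df[order(df$parcel_id), , drop = FALSE]
  rownames(df) <- NULL
  df$network <- factor(as.character(df$network),
                       levels = unique(as.character(df$network)))
  class(df) <- c("network_assignment", "data.frame")
  df
}

n_networks <- function(assign) nlevels(assign$network)
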